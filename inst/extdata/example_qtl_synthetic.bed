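# synthetic example QTL annotation (BED 0-based half-open); not from any real database
1	4999999	12000000	QTL_bcs_1	body condition score
1	30000000	36000000	QTL_mfd_1	mean fiber diameter
2	9999999	14500000	QTL_sv_1	semen volume
2	24000000	30000000	QTL_bcs_2	body condition score
3	1999999	8000000	QTL_mph_1	muscle pH
3	33000000	40000000	QTL_lp_1	lambing potential
4	14999999	21000000	QTL_mfd_2	mean fiber diameter
5	4999999	9500000	QTL_my_1	milk yield
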