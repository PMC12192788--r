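---
title: "Detecting and interpreting runs of homozygosity and heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting runs of homozygosity and heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
library(dplyr)
```

## The model

A run of homozygosity (ROH) is a contiguous stretch of the genome over
which an individual's SNP genotypes are homozygous, indicating that the
two chromosome copies descend from a common ancestral haplotype
(autozygosity). Long ROH arise from recent inbreeding — few meioses
have had the chance to break them up — while short ROH reflect distant
ancestry. Runs of heterozygosity (ROHet) are the mirror image:
heterozygosity-rich stretches maintained by outbreeding, admixture or
balancing selection. From ROH one derives the genomic inbreeding
coefficient

$$F_{ROH}(t) \;=\; \frac{\sum_{\text{ROH},\; L > t} L}{\sum_{c \in \text{autosomes}} (\max_c \text{pos} - \min_c \text{pos})},$$

the fraction of the SNP-covered autosomal genome lying in ROH longer
than a threshold $t$, and analogously $D_{ROHet}(t)$ for ROHet. The
denominator uses SNP spans, not assembly chromosome lengths, because an
array only interrogates the covered interval.

## The consecutive scanning method

Detection uses the consecutive-SNP method: markers are scanned in map
order, without sliding windows. A candidate run grows marker by marker
while three constraints hold:

* no adjacent-marker gap exceeds `max_gap_bp` (default 1 Mb) — a larger
  gap unconditionally terminates the run, since a run bridged across an
  uncovered megabase is unsupported by data;
* at most `max_opposite` markers of the opposite called state are
  absorbed (1 for ROH, 3 for ROHet) — tolerating genotyping errors;
* at most `max_missing` missing calls are absorbed (1 for ROH, 2 for
  ROHet).

When the next marker would violate a constraint, the run is closed and
*trimmed* so that its first and last markers are called in the target
state — tolerated markers cannot extend a run's ends — then reported if
it spans at least `min_snps` markers (30 / 15) and `min_length_bp`
(0.5 Mb / 1 Mb). The scan resumes at the violating marker, whose
allowance budget is fresh, so reported runs are pairwise disjoint.

Disjointness matters more than it may seem. An alternative reading of
"maximal run" — every marker interval satisfying the constraints and
contained in no other — produces *overlapping* runs whenever two
tolerated-marker configurations flank the same homozygous core (e.g.
`H…H h H…H h H…H` with a one-het allowance), and summing their lengths
double-counts the core. On gene-drop simulations this inflated
$F_{ROH}$ by roughly 20% over the truth fraction. The greedy
left-to-right semantics implemented here keeps each base pair counted
at most once and matches how consecutive-method tools in this field
behave; the test suite pins it against an independent naive re-scan
oracle on thousands of random chromosomes.

ROHet detection is the same scanner with the target state switched to
heterozygous. Its minimum length defaults to 1 Mb; because coverage
summaries conventionally report a >0.5 Mb class, the pipeline preset
uses `default_rohet_config(5e5)` so that class is populated. Both
settings are reachable by configuration and neither is privileged by
the code.

Run length is `end_bp - start_bp`, the distance between the flanking
SNPs of the run. With this convention $F_{ROH}$ of a completely
homozygous genome is exactly 1, because numerator and denominator are
both sums of SNP spans.

## Quality control

The cascade runs in a fixed order, each step on the survivors of the
previous one: sample call rate (retained iff strictly > 0.95), removal
of non-autosomal markers, SNP missingness (removed iff strictly
> 20 %), pooled-population minor allele frequency (removed iff
strictly < 5 %), and an exact Hardy–Weinberg test per population
(removed at p < 1e-5 in *any* population). All thresholds are strict
inequalities, following the usual wording ("exceeding", "below").

The HWE p-value is the standard conditional exact test: given the
observed allele counts, the probability of each feasible heterozygote
count is evaluated in closed form via log-factorials, and the p-value
sums the probabilities not exceeding that of the observed count. Two
design points deserve note. First, "per population separately" is
ambiguous between removing markers deviating in *any* versus *every*
population; remove-if-any is implemented, the conservative choice in
multi-breed QC (a marker genotyping badly in one breed is suspect
everywhere). Second, no mid-p correction is applied, keeping the test
exactly reproducible by enumeration.

A caveat the simulator makes visible: strongly inbred cohorts deviate
from Hardy–Weinberg genuinely (excess homozygosity), so the HWE filter
removes real markers in such populations, thinning marker density.
That is faithful to how this QC behaves on real inbred breeds and is
one reason the filter tests at a stringent 1e-5 rather than 0.05.

## Islands and annotation overlap

For each population, the incidence of each SNP is the fraction of
individuals with at least one ROH covering its position (overlapping
runs of one individual are unioned first). The top 1 % of markers by
incidence — ties at the cut included, so the result is
permutation-invariant — are flagged, and maximal blocks of
map-consecutive flagged markers form islands; a single unflagged
marker splits a block, and blocks of fewer than 2 markers are
discarded (a single SNP is not a "continuous region"; configurable).
Thresholds are computed within each population by default, since a
breed with little ROH would otherwise contribute no islands at a
pooled threshold; a dataset-wide threshold is available by flag.
Island–annotation overlap uses 1-based inclusive intervals throughout
(a 1 bp intersection counts), with annotations read from local
BED-like files converted from BED's 0-based half-open convention.

## Between-population tests

Per-animal run counts and summed lengths are heavily tied, non-normal
quantities (the Shapiro–Wilk wrapper is provided to verify this), so
comparisons use the two-sided Wilcoxon rank-sum test with midranks. In
auto mode the exact p-value is enumerated when both samples have at
most 10 observations and no ties; otherwise the normal approximation
with tie and continuity corrections is used. When the pooled sample is
completely tied, the statistic sits at its null expectation and p = 1
by convention. Raw p-values are the primary output; a Bonferroni
column (across pairs within statistic and class) is reported alongside
but not applied, since no multiple-testing policy is assumed.

## The simulator: what it emulates, what it does not

The generator exists so every pipeline stage can be checked against
ground truth. Its default genome — 5 chromosomes × 50 Mb × 1,000
uniformly placed SNPs, allele frequencies uniform on [0.05, 0.5],
1 cM/Mb — is a desk-scale stand-in for a livestock 50k array (26
autosomes, ~48k markers); the full scale is reachable by raising the
parameters, and tests state the sizes they use.

**Planted mode** draws background genotypes per SNP from
Hardy–Weinberg proportions and overwrites specified tracts: autozygous
tracts become homozygous with the allele drawn by frequency,
heterozygous tracts become forced heterozygotes. Genotyping error
(symmetric state flip with probability ε) and missingness are applied
afterwards, so the recorded truth intervals remain exact. Because the
background itself is ~64 % homozygous per SNP, a detected run would
otherwise legitimately extend past a planted tract into flanking
homozygous stretches; the generator therefore plants opposite-state
*guard* markers immediately outside each tract (4 per side, exceeding
both opposite-state allowances). With guards, zero error and zero
missingness, recovery is exact at the tract's first and last SNP, and
the tests assert precisely that.

**Pedigree mode** gene-drops founder haplotypes through a pedigree:
each meiosis draws a Poisson number of crossovers (mean = genetic
length in Morgans; Haldane model, no interference) at uniform
positions. Truth autozygosity is read off the haplotype origins —
maximal regions where both copies descend from the same founder
haplotype — so the classical expectations are testable: full-sib
offspring have E[F] = 0.25 with convergence as genome length grows.
Presets cover full-sib, half-sib, first-cousin and outbred matings,
and `generate_breed_cohort()` mixes them into multi-breed datasets
with a shared map.

What the simulator does *not* model: linkage-disequilibrium structure,
allele-frequency differentiation between breeds, ascertainment bias of
array SNPs, crossover interference, and selection. Passing tests
therefore demonstrate that the algorithms recover the autozygosity
that is present, not that real array data are this clean; in real data
the allowance parameters do the work that the error model only
sketches.

## Numerical and scale choices

* Exact HWE probabilities are computed in log space and normalised
  before summation; the tie comparison uses a 1e-12 relative slack so
  equal-probability configurations are included deterministically.
* The scanner precomputes, for every window start, the furthest
  budget-respecting end via order-statistic lookups on cumulative
  counts, so a chromosome scan is vectorised and the greedy walk costs
  one iteration per run. Oracle equivalence, not the scan strategy,
  defines correctness.
* Chromosome labels sort numerically when numeric ("2" before "10"),
  then lexically; marker sorting is stable and idempotent.
* Test problem sizes: the scanner oracle runs on 1,000 random
  chromosomes of up to 200 SNPs; pedigree recovery uses 50 replicates
  of 50 full-sib offspring on 20 × 100 Mb chromosomes (20 Morgans);
  the end-to-end determinism check uses nine cohorts of 50–104
  individuals (772 total) on a 5,000-SNP genome. These sizes make the
  classical expectations sharp (the full-sib mean stabilises within
  ±0.05) while keeping the default suite quick to run.

## Known limitations

* PLINK *text* PED/MAP is the only genotype input; binary BED/BIM/FAM
  and VCF are out of scope.
* Allele labelling after a PED round-trip is canonical (first observed
  allele becomes the A allele), so datasets written by other tools may
  swap homozygote codes at markers where only one class was observed;
  run detection is invariant to this.
* `length_bp = end_bp − start_bp` means single-SNP "runs" have length
  0 and can never pass a positive length threshold — intended.
* The Wilcoxon exact mode refuses tied data rather than silently
  approximating; auto mode handles the switch.
* Island calling reports regions, not causal variants; overlap with
  QTL intervals is positional evidence only.
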