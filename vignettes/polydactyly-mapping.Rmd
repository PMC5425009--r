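---
title: "Mapping a dominant trait locus with polyloc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant trait locus with polyloc: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyloc)
```

## The mapping problem

Polydactyly in the Beijing fatty (BF) chicken behaves as a completely
dominant autosomal trait: purebred BF birds are homozygous for the
dominant allele (Po), and crosses of the purebred line produce only
polydactylous offspring. `polyloc` implements the full localization
strategy built around that observation:

1. a **backcross GWAS** — a purebred BF male is crossed to a wild-type
   SZ female, the F1 sire is backcrossed to SZ dams, and the cohort
   (founders, F1, dams, F2) is tested SNP by SNP for association with
   case/control status;
2. a **resequencing comparison** — small divergent panels (three
   polydactylous vs three normal birds, presumed homozygous) are scanned
   for windows of extreme differentiation and for opposite-homozygous
   fixed differences;
3. **inheritance analytics** — penetrance per mating, a reciprocal-cross
   test against sex linkage, exact segregation tests, and a
   genotype-by-phenotype contingency analysis of the candidate variant in
   an independent validation panel.

Because no genotype data are deposited with the original study, the
package ships a first-class simulator that generates inputs with the
statistical structure these analyses assume. All downstream code is
agnostic to whether its VCF/FAM/BED inputs are simulated or real.

## The synthetic cohort

`sim_config()` fixes the study design; `simulate_backcross()` and
`simulate_divergent_panels()` realize it.

**Genome.** The default genome is a deliberate miniature: chromosomes
"1" (20 Mb), "2" (15 Mb) and "9" (5 Mb), with 1,667 variant sites each
(5,001 total, ~1 site per 8 kb). Three chromosomes of unequal length
keep per-chromosome count/density comparisons meaningful while the whole
pipeline runs in seconds; the causal variant sits at 8.46 Mb on
chromosome "2", inside a miniature analog of the LMBR1 interval, so
Mb-scale window coordinates look like the real analysis.

**Founder divergence.** Neutral allele frequencies for the two breeds
are drawn from a Balding–Nichols model: an ancestral frequency
`p ~ U(0.05, 0.95)` per site and breed frequencies
`Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = founder_fst`. The default
`founder_fst = 0.15` is a typical differentiation level for distinct
indigenous chicken breeds. At `F = 0` both breeds share identical
frequencies exactly.

**Sweep.** Across `causal_pos ± sweep_halfwidth` (default ±200 kb,
matching the ~400 kb outlier region scale of the motivating study) BF
founders are fixed for the alternate (dominant) haplotype and SZ for the
reference. The divergent panels are both drawn from BF neutral
frequencies and differ systematically only there — the idealization of
"same breed, divergently selected at one locus".

**Transmission.** Gametes recombine under the Haldane map at
`recomb_rate` cM/Mb (default 3, a chicken macrochromosome scale): the
per-interval recombination fraction is `0.5 (1 - exp(-2 d r))`, applied
as a Markov switch process along each chromosome, which is equivalent to
Poisson crossovers without interference. Sex is recorded (alternating)
but transmission is autosomal throughout; the W/Z system is not modelled
because the design's conclusion is autosomal inheritance.

**Phenotype.** An individual with at least one causal allele is affected
with probability `penetrance` (default 1); non-carriers are never
affected. Each simulation stage (site placement, frequencies, founder
haplotypes, transmission, phenotypes, panels) uses its own seed stream
derived from `seed`, so enlarging the site panel does not perturb the
phenotype draws, and a given seed reproduces byte-identical VCF/FAM
output.

What the generator does **not** emulate: genotyping error and allele
dropout, linkage disequilibrium within founder breeds (neutral sites are
exchangeable given their frequencies), coalescent ancestry, InDel
mutational realism (InDels are SNV-like sites with multi-base alleles,
present only so the opposite-homozygote scan can separate variant
types), and polydactyly subtype morphology. Passing tests therefore
certify the statistical machinery and its conventions, not robustness to
real-data artifacts.

## Quality control

A site is retained iff MAF ≥ 0.05, missing rate ≤ 0.5 and exact
Hardy–Weinberg p ≥ 1e-6 (the complements of the discard rules used with
the original RAD genotypes). MAF is computed on non-missing alleles; a
site with no calls fails with reason `MISS`. The HWE test is the exact
conditional test: given the allele counts, all heterozygote counts of
the right parity are enumerated and the p-value is the sum of
probabilities not exceeding the observed configuration's — the test
agrees with brute-force enumeration for every genotype triple with
n ≤ 30 in the test suite.

LD pruning is the greedy 50-SNP / 5-SNP / r² > 0.2 window convention
(dosage correlation, pairwise-complete): within each window the
worst-correlated pair loses its lower-MAF member (tie: the later site).
The original study reports only the resulting marker count, never its
rule, so the pruned count is a convention, not a target.

## Population structure

`ibs_matrix()` computes allele-sharing similarity
(`1 - |g_i - g_j| / 2`, averaged over co-called sites);
`classical_mds()` embeds the distance `1 - IBS` by double-centering and
eigendecomposition, zero-filling non-positive components. Signs are
fixed (largest loading positive) so output is reproducible. The first
two components are the association covariates, mirroring the original
analysis.

One property deserves honesty: in this backcross every F2 shares a
single F1 sire, so sibship relatedness carries variance comparable to
breed ancestry at `founder_fst = 0.15` and ~5,000 markers. The ancestry
gradient therefore lands on component 1 or 2 depending on the seed
rather than always dominating component 1. The tested (and reliably
true) property is that the plane of the two covariates orders the
ancestry groups monotonically — BF founder, then F1, then the F2 mean,
then the SZ birds — along the BF-to-SZ direction. This is also the
practical reason the pipeline keeps both components as covariates and
cross-checks association with a GRM mixed model.

## Association

**Logistic arm.** Case status is regressed on alt-allele dosage plus the
two MDS covariates; samples missing the genotype are dropped per site.
p-values are Wald. Detected (quasi-)separation — non-convergence, fitted
probabilities at the boundary, or an implausibly large effect — triggers
a Firth-penalized refit (Jeffreys-prior score correction), which always
yields finite estimates; this matters here because a completely
penetrant dominant locus in a backcross separates the phenotype
perfectly, and the design's extreme odds ratios imply near-separation
throughout the candidate region. For Firth-refit sites the reported
p-value is the penalized likelihood-ratio p rather than Wald: under
separation the Wald statistic degenerates (the Hauck–Donner effect makes
it *less* significant at the causal site than at imperfectly linked
neighbors), while the likelihood ratio preserves the evidence ordering.

**Mixed-model arm.** The binary phenotype enters as a 0/1 quantitative
trait, as GREML-type tools do for case/control. The GRM is the standard
standardized-dosage matrix over polymorphic sites (missing calls
mean-imputed). REML for `y = Xb + g + e` is solved exactly in one
dimension: the GRM eigendecomposition turns the two-component problem
into a profiled likelihood in the heritability ratio, maximized by a
coarse grid plus golden-section refinement. This is the EMMA-style
formulation; with a single GRM it finds the same optimum an AI-REML
iteration would, without convergence tuning. Components are clamped at
zero; a non-PSD GRM is shifted by its smallest eigenvalue with a
warning. Per-site tests are then GLS with `V = sigma_g^2 G +
sigma_e^2 I` held fixed (no per-SNP refit, no leave-one-chromosome-out),
with exact-GLS Wald variances; missing dosages are mean-imputed to keep
the scan a single whitened matrix operation.

A caveat the simulation exposes: with penetrance 1 the phenotype vector
*is* the carrier indicator, while the causal site's additive dosage codes
the BF founder as 2. A linked site whose dosage happens to equal the
phenotype exactly (BF founder heterozygous, full co-transmission through
the 98 meioses) is then a strictly better additive predictor, and in
roughly a third of seeds such a site takes the genome-wide minimum MLM
p-value, 10–100 kb from the causal position. This is correct GLS
behavior on a dominant trait with an additively coded founder, not an
optimization failure; the logistic arm, whose likelihood saturates under
separation, ranks the causal site first essentially always.

**Significance** is `p < alpha / m` (strict), with `m` the number of
tested sites; significant hits are annotated with the nearest gene
(distance 0 inside a gene, else the gap to the nearer interval end, ties
to the first-listed gene; BED intervals are 0-based half-open, VCF
positions 1-based, and the conversions are centralized and round-trip
tested).

## Selection scan

Per-site differentiation uses the Weir & Cockerham (1984) two-population
estimator from genotype counts — the sample-size correction is essential
at three diploids per panel; a Hudson estimator is available for
comparison. Windows are anchored at 0, advance by the step while the
start is inside the chromosome, and truncate at its end (100 kb / 10 kb
defaults). The window statistic is the ratio of sums
`sum(a) / sum(a + b + c)`, the standard low-bias aggregation (per-site
averaging is available behind a flag); it is clipped to [0, 1] for
reporting with the raw value retained.

Windows with fewer than `min_snps = 10` usable sites are reported but
excluded from the **empirical distribution**: at 3-vs-3 sample size,
sparse windows are noise, and letting them shape the threshold would be
reckless. The threshold itself is the lower bound of the highest 0.1% —
the minimum among the top `ceiling(0.001 N)` qualifying windows, taken
verbatim rather than an interpolated quantile. Outlier *candidacy*,
however, extends to any reported window with data: at desk-scale site
density (~11 sites per 100 kb window against `min_snps = 10`),
qualification inside a genuinely swept interval is a coin flip per
window, and restricting candidacy to qualifying windows fragments the
swept region or clips its edges. Isolated sparse windows elsewhere are
kept in check by region ranking: merged regions (overlapping or
bookended windows) are ranked by peak F_st and then by the number of
merged windows, so a contiguous swept block always outranks a lone
high-value sparse window. On the default fixture the top region contains
the causal position in 50/50 seeds, and window/step variants (50 kb/5 kb,
200 kb/20 kb) reproduce the same region.

Opposite homozygotes — every sample of one panel homozygous for one
allele, every sample of the other homozygous for the other — are scanned
with SNPs and InDels distinguished; by default any missing call
disqualifies a site (`require_complete = TRUE`). Per-chromosome counts
and per-Mb densities reproduce the observation pattern that a short
chromosome can be the densest without carrying the most sites.

## Inheritance analytics

Per-mating penetrance is grouped by sire by default (the breeding design
selects roosters first); "penetrance above 90%" is a strict inequality.
The reciprocal-cross test pools offspring by carrier-parent sex into a
2×2 table and applies the two-sided Fisher exact test (sum of table
probabilities ≤ observed; no mid-p), eliminating sex linkage when the
orientations agree. `dominance_expectation()` gives the Mendelian
affected fraction for any parental dosage pair times penetrance;
`segregation_fit()` is the two-sided exact binomial test against it.
`genotype_phenotype_table()` tabulates phenotype against the three
genotype classes, collapses to carrier/non-carrier for the dominant
model, and reports carrier penetrance plus a Fisher exact p on the
collapsed table. The packaged 138-bird validation fixture reproduces the
published genotype-by-phenotype counts cell for cell, with zero affected
non-carriers — the dominant-model signature.

## Numerical conventions and degenerate inputs

* Genotypes are alt-allele dosages; phased and unphased GT are treated
  identically; `./.` is missing.
* Multiallelic VCF records error under strict mode or are dropped with a
  warning.
* The exact HWE and Fisher tests use a `1 + 1e-7` relative slack when
  comparing point probabilities, the standard guard against ties lost to
  floating point.
* Monomorphic sites: excluded from the GRM; `NA` effect in the MLM;
  components (0, 0, 0) and an undefined ratio in the F_st scan.
* A phenotype without both classes, a pair of samples with no shared
  calls, or an empty gene chromosome raise errors or warnings naming the
  offender.
* Sweep regions exceeding chromosome bounds are clipped with a warning;
  `n_families > n_f2` is a configuration error.

## Problem sizes and runtime

The default fixture (112 samples × 5,001 sites, 3-vs-3 panels) runs the
full pipeline in a few seconds; the test suite's heaviest case — 50
seeded replicates of the complete localization — completes in about four
minutes on one core, and the exhaustive oracle sweeps (all HWE triples
and Fisher tables with n ≤ 30, the REML likelihood grid) in under a
minute. These sizes were chosen so properties are measured with real
replication while the suite stays interactive.

## Known limitations

* The genome-scale counts of the motivating study (hundreds of thousands
  of RAD SNPs, millions of resequencing variants, absolute
  opposite-homozygote counts, the F_st threshold of 0.72) depend on the
  unavailable raw data and are out of scope by design.
* The MLM's additive coding penalizes a dominant causal site when fully
  penetrant founders are in the cohort (see above); a dominance-coded
  test would remove this but would depart from the reference pipeline.
* Three diploids per panel make per-site F_st extremely coarse; only
  windowed statistics are interpretable, which is exactly why the
  pipeline thresholds on windows.
* The simulator's breeds have no within-breed LD, so LD-pruning results
  on simulated data are optimistic relative to real genotypes.
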