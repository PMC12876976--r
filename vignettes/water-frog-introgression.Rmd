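---
title: "Genotyping, introgression and population-system association in hybridogenetic water frogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping, introgression and population-system association in hybridogenetic water frogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtseqpop)
library(dplyr)
```

## The biological setting

The edible frog *Pelophylax esculentus* (genotype LR) is a hybridogenetic
hybrid of *P. lessonae* (LL) and *P. ridibundus* (RR). In its germline one
parental chromosome set is excluded and the other is transmitted clonally;
hybridity is restored each generation by backcrossing with the coexisting
parental species. Which genome is excluded depends on the *population
system* (POPSYS): in L-E systems hybrids coexist with *P. lessonae* and
transmit the R genome, in R-E systems with *P. ridibundus*, and all-hybrid
(E) populations maintain themselves through mixtures of diploid LR and
triploid LLR/RRL frogs. Pure *P. ridibundus* populations (all-R) complete
the picture.

`gtseqpop` implements the statistical pipeline for studying this system
with GT-Seq amplicon data (genotyping-in-thousands by sequencing): many
individuals genotyped at a panel of exonic SNPs in gametogenic genes.
The questions the pipeline answers are (i) how much gene flow
(introgression) there is between the L and R genomes, (ii) which SNPs are
associated with the population system rather than with geography, and
(iii) how well multilocus genotypes (MLGs) built from those SNPs predict
the system an individual comes from.

## Genotype calling

The raw input is a pileup-like table of per-individual, per-site base
counts. A site is called only when its total coverage reaches
`min_total_coverage` (default 10 reads). Among covered sites the two
most-abundant bases are considered: the site is heterozygous when the
second base accounts for at least `min_relative_coverage` (default 20%,
boundary inclusive) of the total, otherwise homozygous for the top base.
Any third or fourth base is treated as sequencing error. The 20% rule is
deliberately permissive: a diploid heterozygote has an expected minor-base
fraction of 50%, and amplification dosage effects push it down. Raising
the threshold produces false homozygotes, most severely in triploids —
which is why the caller is diploid-oriented and triploids (flagged by
their diagnostic read dosage, below) are excluded from the frequency
analyses rather than genotyped.

Ties between the second and third base are broken alphabetically
(A < C < G < T); this matters only in degenerate cases and makes the
caller fully deterministic. Calls concatenate in panel order into IUPAC
consensus strings (missing sites become `N`), the storage format for all
multilocus work.

Taxon assignment uses the species-diagnostic subpanel: pooling reads over
covered diagnostic sites, the fraction of L-specific reads estimates the
L-allele dosage, and the individual is classified to the nearest of
0 (RR), 1/3 (RRL), 1/2 (LR), 2/3 (LLR), 1 (LL).

## Allele frequencies and species-specific SNPs

Frequencies are computed per SNP, genotype class, and *population unit*.
Populations contributing fewer than 4 individuals of a genotype class are
pooled with other small samples of the same POPSYS and geographical
region (an explicit metadata column: the convention pools named regions,
not distance-based clusters); unmergeable small samples are excluded.
SNPs called in fewer than 5 individuals of any analyzed taxon are dropped.
A homozygote for the tracked ("designated") nucleotide contributes two
alleles, a heterozygote one, over a denominator of two alleles per called
individual, so pooling conserves allele counts exactly.

A SNP is *species-specific* when its designated allele is essentially
fixed (frequency at or above 0.95) in exactly one parental species and
essentially absent (at or below 0.05) in the other, judged on
species-wide pooled frequencies — the classification is global, not per
population. The designated nucleotide defaults to the major allele among
LL individuals, but all downstream estimators work from the *expected
fixed state* (0 or 1) inferred from the pooled frequencies, which makes
them invariant to which physical base a table happens to track.

## Introgression rates

For a species-specific SNP and a focal parental species, the
introgressed-allele frequency in a population unit is the absolute
deviation of the observed frequency from the expected fixed state,
`ir = |f - expected|`. Averaging non-missing cells row-wise gives
`IR_SNP`, column-wise `IR_POP`, and overall `IR_mean` with a standard
deviation across all cells. We report the sample SD (denominator N-1) as
`ir_sd` — on the packaged worked example it reproduces the published
"0.003 +/- 0.0134" exactly, which the population SD does not — and emit
the population SD (`ir_sd_n`) alongside.

The packaged worked example (`published_snp_frequencies()`) carries printed,
two-decimal frequencies. Re-deriving summaries from printed cells
reproduces the published values at table precision except in three
entries where the original averaged unrounded frequencies (differences
of one unit in the third decimal); comparisons therefore use half-up
rounding at three decimals and treat those entries at their cell-derived
values.

## Association with the population system

Because L-E, R-E, E and all-R populations have a strongly biased
geographic distribution, a SNP-system association must be separated from
latitude/longitude gradients. Per SNP the pipeline runs:

* a Kruskal-Wallis test of unit frequencies across systems (tie-corrected
  H, chi-squared p);
* a weighted-least-squares logistic regression of the empirical logits
  `log(f/(1-f))` on `POPSYS + LAT + LON`. Frequencies are clamped to
  `[1e-10, 1 - 1e-10]` before the logit. The weights are the Berkson
  minimum-logit chi-square weights `n f (1-f)` with `n` the unit allele
  count — the standard weighting for grouped proportions (plain `n`
  weights are available as an option). Per-predictor type III F tests
  compare the full model against the model with that predictor dropped
  under identical weights, which makes them invariant to dummy coding;
  R² and adjusted R² are reported in percent on the weighted scale. A
  goodness-of-fit chi-square bins the fitted logits into 5 equal-count
  classes and compares observed and fitted allele counts per class
  (degrees of freedom: classes minus parameters, floored at 1);
* forward stepwise selection over {POPSYS, LAT, LON} with entry at type
  III p <= 0.05, ties broken by the fixed term order.

The weighting scheme, the class count of the goodness-of-fit test, and
the stepwise entry threshold are documented conventions: grouped-logit
WLS is underdetermined without them, and different choices shift F
statistics without changing which predictors matter. For that reason the
per-SNP F values of the original analysis are not digit-for-digit
targets; the package instead validates this module by construction —
coefficients must equal a direct weighted normal-equation solve to 1e-8,
the POPSYS test must hold its nominal 5% size under the null, and
planted system shifts of 0.4 across 10 units per level must be detected
with at least 90% power.

## Multilocus genotypes, distances, discriminant analysis

MLGs are the IUPAC strings of diploid individuals over the
system-associated SNP panel; identical strings within a genotype class
collapse into one MLG with a multiplicity, and an MLG records every
system it occurs in. Each MLG enters subsequent analyses once —
multiplicities describe, they do not weight.

Distances between MLGs are uncorrected p-distances with ambiguity codes
treated as *average states*: identical symbols (including identical
ambiguity codes) contribute zero, otherwise a site contributes the mean
mismatch over the Cartesian product of the two codes' resolutions, and
sites with `N` are deleted pairwise. UPGMA (average linkage, node height
half the cluster distance) clusters the resulting matrix into an
ultrametric tree.

For discriminant analysis each base is encoded by its proton count
(A = 70, T = 66, C = 58, G = 78), a quantitative scale proportional to
nucleotide mass. Ambiguity codes take the mean of their constituents
(e.g. R = 74), preserving the dosage ordering A < R < G; missing sites
are mean-imputed per variable with a logged count. Variables enter a
linear discriminant model by forward stepwise selection on Wilks'
lambda: the partial F-to-enter is
`((lambda_p / lambda_{p+1}) - 1) (n - g - p) / (g - 1)`, with entry at
F >= 4.0 and at most 50 steps, matching the F-to-enter interface of
classical stepwise discriminant procedures. Note what that implies: each
noise variable has roughly the upper-tail probability of F(1, n-g) of
entering by chance (about 5% at the default threshold), and once the
classes are separated, *redundant* diagnostic variables legitimately
stay out — a selected set should be read as a sufficient panel, not an
exhaustive list of informative sites. The reported accuracy is
resubstitution ("percent correctly classified"), with leave-one-out
cross-validation emitted alongside as the honest generalization figure.

Linkage disequilibrium between SNP pairs within a taxon is the composite
genotypic correlation: the Pearson correlation of designated-allele
dosages (0/1/2) across individuals, requiring no phasing.

## Sequence-level statistics

`cds_stats()` records coding-sequence length and GC content (Ns excluded
from the GC denominator — the convention is documented since it is not
universal) and excludes sequences with more than 5% ambiguous bases.
`p_distance()` computes uncorrected nucleotide or amino-acid distances
on pre-aligned CDS (standard code, frame 1) with pairwise deletion of
gaps and ambiguous sites. Genes whose intraspecific distance *range*
(max minus min of pairwise distances; the summary chosen because a
single introgressed allele inflates the spread, not necessarily the
mean) exceeds the 95th percentile of the range distribution are flagged
as introgression candidates. `simple_ols()` backs the descriptive
regressions among length, GC, exon number and divergence.

## The cohort simulator

`simulate_cohort()` generates the full data triplet (read counts,
metadata, truth) the pipeline consumes. Dosages follow the genotype
definitions (LL = 2 L alleles, RR = 2 R, LR = 1 + 1, LLR = 2 L + 1 R,
RRL = 1 L + 2 R). Introgression is modelled per allele copy in the
parental species: each RR copy independently carries the L-specific base
with probability `introgression_rate_rr` (symmetrically for LL), so the
planted rate is exactly the expected introgressed-allele frequency the
estimator should recover. Per-site coverage is negative binomial
(default mean 200, dispersion 5) — amplicon coverage is overdispersed
relative to Poisson, and no empirical coverage distribution is published
for this assay, so these defaults are conventions, not reproductions.
Sequencing error substitutes a read's base uniformly among the other
three bases with probability `error_rate` (default 0.001). Population-
system effects are planted as unit-level allele-frequency overrides
(`popsys_effect`), which is what the association module estimates. The
default population table mirrors the scale of the real cohort: 460 RR in
11 populations, 116 LL in 3, LR hybrids across L-E/R-E/E systems, and a
small triploid contingent.

What the simulator deliberately omits: read-level FASTQ structure, PCR
duplicates and primer artifacts, within-amplicon haplotypes (one site
per SNP: the analysis treats SNPs independently), allele-specific
amplification bias, and linkage between SNPs (each SNP draws
independently, which is also why planted LD tests construct their pairs
directly). Passing tests therefore validate the estimators under the
stated statistical model, not the upstream wet-lab and mapping steps.

## Numerical choices and degenerate inputs

* Thresholds are boundary-inclusive where the rules say "at least"
  (20% relative coverage; frequency 0.95).
* All-zero base counts are a no-call, not an error; an all-missing
  introgression matrix is an error.
* Comparisons against printed tables use half-up rounding
  (`round_half_up()`), since printed tables do not use banker's
  rounding.
* UPGMA merge ties resolve to the lowest-index pair; stepwise procedures
  break ties by fixed candidate order — all outputs are deterministic
  given a seed.
* The Kruskal-Wallis statistic degenerates when every value is tied; H
  is reported as 0 with p = 1.
* Problem sizes in the test-suite simulations (cohorts of 150-800
  individuals, 16 SNPs, 200-500 replicate regressions) were chosen so
  each stochastic check sits at least 3 standard errors from its
  decision boundary.

## Known limitations

Triploid allele dosages are flagged but never genotyped; the Borovec
convention (sex-separated frequencies for populations with uncertain
system assignment) is available via `allele_frequencies(by_sex = TRUE)`
but off by default; introgression estimates cannot distinguish true
gene flow from incomplete lineage sorting or parallel substitution, and
no attempt is made to; and the association module's F statistics depend
on the documented weighting conventions, so cross-software comparisons
should be made at the level of selected predictors, not decimals.
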