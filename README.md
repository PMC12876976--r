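# gtseqpop

Population-genetic analysis of GT-Seq amplicon SNP panels in the
hybridogenetic water frog complex (*Pelophylax lessonae* [LL],
*P. ridibundus* [RR] and their hybrid *P. esculentus* [LR]), for
researchers studying hybrid zones, clonal inheritance and gene flow
between parental genomes.

The package covers the full desk side of such a study:

* **Genotype calling** from per-site base counts with the
  coverage-threshold rule: a site needs COV_tot ≥ 10 reads; the second
  base is called when it reaches ≥ 20% of COV_tot, giving IUPAC
  genotypes and per-individual consensus sequences; taxon/ploidy
  assignment from diagnostic read dosages (nearest of 0, 1/3, 1/2, 2/3,
  1 L-read fraction).
* **Allele frequencies** per SNP × genotype class × population unit,
  with pooling of small same-system, same-region samples and the
  fewer-than-five-individuals SNP filter; classification of SNPs as
  species-specific (designated allele ≥ 0.95 in exactly one parental
  species).
* **Introgression rates** from species-specific SNPs:
  ir(snp, unit) = |f − expected fixed state|, summarized as IR_SNP
  (row means), IR_POP (column means) and IR_mean ± SD over all cells.
* **Population-system association**: Kruskal–Wallis tests and
  weighted-least-squares logistic regression of empirical logits on
  POPSYS + latitude + longitude (Berkson weights n·f·(1−f)), type III
  F tests, stepwise selection, and a binned goodness-of-fit χ².
* **Multilocus genotypes**: ambiguity-averaged uncorrected p-distances,
  UPGMA trees, atomic-number encoding (A = 70, T = 66, C = 58, G = 78)
  and stepwise linear discriminant analysis (Wilks' Λ, F-to-enter 4.0,
  ≤ 50 steps), plus composite genotypic LD.
* **CDS statistics**: length, GC, N-content filtering, nt/aa
  p-distances, 95th-percentile divergence-range outliers, simple OLS.
* A **cohort simulator** producing read counts + metadata + truth with
  tunable introgression rates, coverage, error and planted
  population-system effects, so every stage is testable end to end.

## Worked example

The package ships the published per-population frequencies of
L-specific nucleotides at 16 species-specific SNPs (11 RR units, 3 LL
units) and reproduces the published introgression summaries from them:

```r
library(gtseqpop)

t1  <- published_snp_frequencies()
cls <- classify_snps(t1)
rr  <- ir_summaries(introgression_cells(t1, cls, "RR"))
ll  <- ir_summaries(introgression_cells(t1, cls, "LL"))
rr
#> <ir_summary> 16 SNPs x 11 units (175 cells)
#> IR_mean = 0.0102 +/- 0.0359 (sd, N-1; N: 0.0358)
ll
#> <ir_summary> 16 SNPs x 3 units (46 cells)
#> IR_mean = 0.00348 +/- 0.0134 (sd, N-1; N: 0.0132)
```

So the mean introgression rate is about 1% per population into
*P. ridibundus* and 0.3% into *P. lessonae* — introgression is real but
rare, and asymmetric. Per-SNP and per-unit views come from
`tidy(rr)`, `rr$ir_snp`, `rr$ir_pop` and `autoplot(rr)`; for example
`rr$ir_pop` shows the Bulgarian all-R unit Sur at 0.028 (driven by two
*smc1a* SNPs at frequency 0.21) while most units sit at 0.

A simulated end-to-end run:

```r
cfg <- sim_config(introgression_rate_rr = 0.05, seed = 1)
co  <- simulate_cohort(cfg)
calls <- call_genotypes(co$counts)
units <- pool_populations(co$metadata)
des   <- designate_alleles(calls, co$metadata, cfg$snp_panel)
freqs <- allele_frequencies(calls, co$metadata, units, cfg$snp_panel, des)
snps  <- classify_snps(freqs)
ir_summaries(introgression_cells(freqs, snps, "RR"))$ir_mean
#> [1] 0.04557835
```

which recovers the planted 5% rate within binomial error.

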