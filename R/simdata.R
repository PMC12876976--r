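#' Default species-diagnostic SNP panel
#'
#' A 16-SNP panel over 13 gametogenic genes, mirroring the scale of the
#' species-specific marker set used for introgression estimation in
#' Central European water frogs. Each SNP is a single biallelic site with
#' a *P. lessonae* (L) base and a *P. ridibundus* (R) base.
#'
#' @param n_snps Number of SNPs to keep (head of the panel), at most 16.
#' @return Tibble with columns `snp`, `gene`, `marker`, `pos`,
#'   `species_specific`, `l_base`, `r_base`.
#' @export
default_snp_panel <- function(n_snps = 16) {
  stopifnot(n_snps >= 1, n_snps <= 16)
  genes <- c(
    "adcy9", "adcy9", "hat1", "henmt1", "hormad1", "hormad1", "itpr1",
    "map3k7", "msh2", "parn", "plk1", "rbbp8", "smc1a", "smc1a", "ywhaz",
    "zfp36"
  )
  l <- c("A", "C", "C", "C", "C", "A", "T", "G", "G", "G", "C", "A", "C", "C", "T", "C")
  r <- c("G", "T", "T", "A", "T", "G", "C", "A", "A", "T", "G", "G", "T", "G", "C", "A")
  tibble::tibble(
    snp = sprintf("snp%02d", seq_along(genes)),
    gene = genes,
    marker = paste(genes, sprintf("s%02d", seq_along(genes)), sep = "_"),
    pos = 1L,
    species_specific = TRUE,
    l_base = l,
    r_base = r
  )[seq_len(n_snps), ]
}

#' Default population table for a simulated cohort
#'
#' Emulates the sampling design of the field study the package targets:
#' pure *P. ridibundus* (RR) from all-R and R-E populations, *P. lessonae*
#' (LL) from L-E populations, and diploid hybrids (LR) across the three
#' mixed systems, on a rough central/eastern European coordinate grid.
#'
#' @return Tibble with columns `population`, `popsys`, `region`, `lat`,
#'   `lon` and per-genotype sample sizes `n_LL`, `n_RR`, `n_LR`, `n_LLR`,
#'   `n_RRL`.
#' @export
default_populations <- function() {
  tibble::tribble(
    ~population, ~popsys, ~region, ~lat, ~lon, ~n_LL, ~n_RR, ~n_LR, ~n_LLR, ~n_RRL,
    "Cit", "all-R", "south", 42.2, 27.5, 0L, 42L, 0L, 0L, 0L,
    "Zel", "all-R", "south", 42.5, 27.3, 0L, 40L, 0L, 0L, 0L,
    "Sur", "all-R", "south", 43.0, 25.0, 0L, 44L, 0L, 0L, 0L,
    "Kap", "all-R", "south", 43.4, 24.1, 0L, 40L, 0L, 0L, 0L,
    "Bul", "all-R", "south", 42.0, 27.8, 0L, 42L, 0L, 0L, 0L,
    "Olt", "all-R", "south", 44.2, 24.4, 0L, 44L, 0L, 0L, 0L,
    "Alb", "all-R", "south", 41.2, 19.8, 0L, 40L, 0L, 0L, 0L,
    "Dol", "all-R", "east", 48.8, 24.0, 0L, 42L, 0L, 0L, 0L,
    "Kos", "all-R", "east", 48.0, 21.0, 0L, 42L, 0L, 0L, 0L,
    "Kar", "R-E", "oder", 53.8, 14.6, 0L, 42L, 30L, 0L, 0L,
    "Leb", "R-E", "oder", 52.3, 14.5, 0L, 42L, 30L, 0L, 0L,
    "Trn", "L-E", "czech", 49.4, 14.3, 40L, 0L, 30L, 0L, 0L,
    "Cet", "L-E", "croatia", 43.4, 16.4, 38L, 0L, 28L, 0L, 0L,
    "Ger", "L-E", "german", 53.2, 13.9, 38L, 0L, 28L, 10L, 0L,
    "Hyb", "E", "german", 54.0, 12.0, 0L, 0L, 30L, 14L, 6L
  )
}

#' Build a simulation configuration
#'
#' Defines the synthetic GT-Seq cohort: the SNP panel, the populations
#' with per-genotype sample sizes, introgression rates into the parental
#' species, and the sequencing noise model. With a fixed `seed` the
#' simulated cohort is bit-identical across runs.
#'
#' @param snp_panel Tibble as produced by [default_snp_panel()].
#' @param populations Tibble as produced by [default_populations()].
#' @param introgression_rate_rr Probability that an allele copy in an RR
#'   individual carries the L-specific base (per copy, independent).
#' @param introgression_rate_ll Symmetric rate for R-specific bases in LL.
#' @param coverage_mean Mean reads per individual-site (negative binomial).
#' @param coverage_dispersion Negative-binomial size parameter; smaller
#'   values give more overdispersed amplicon coverage.
#' @param error_rate Per-read probability of a miscall to a uniformly
#'   chosen different base.
#' @param popsys_effect Optional tibble (`snp`, `popsys`, `f`) overriding
#'   the designated-(L)-allele frequency of a SNP for every allele copy of
#'   individuals in populations of that system; used to plant
#'   population-system associations at non-diagnostic SNPs.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(snp_panel = default_snp_panel(),
                       populations = default_populations(),
                       introgression_rate_rr = 0,
                       introgression_rate_ll = 0,
                       coverage_mean = 200,
                       coverage_dispersion = 5,
                       error_rate = 0.001,
                       popsys_effect = NULL,
                       seed = 1L) {
  if (nrow(snp_panel) == 0) stop("configuration error: zero SNPs in panel")
  if (nrow(populations) == 0) stop("configuration error: zero populations")
  probs <- c(introgression_rate_rr, introgression_rate_ll, error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  size_cols <- c("n_LL", "n_RR", "n_LR", "n_LLR", "n_RRL")
  stopifnot(all(size_cols %in% names(populations)))
  if (any(as.matrix(populations[size_cols]) < 0)) stop("sample sizes must be >= 0")
  structure(
    list(
      snp_panel = tibble::as_tibble(snp_panel),
      populations = tibble::as_tibble(populations),
      introgression_rate_rr = introgression_rate_rr,
      introgression_rate_ll = introgression_rate_ll,
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      error_rate = error_rate,
      popsys_effect = if (is.null(popsys_effect)) NULL else tibble::as_tibble(popsys_effect),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config> ", nrow(x$snp_panel), " SNPs, ", nrow(x$populations),
    " populations, coverage ", x$coverage_mean, ", error ", x$error_rate,
    ", introgression RR/LL ", x$introgression_rate_rr, "/",
    x$introgression_rate_ll, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# Genome composition per genotype class, in fixed copy order.
GENOTYPE_ORIGINS <- list(
  LL = c("L", "L"),
  RR = c("R", "R"),
  LR = c("L", "R"),
  LLR = c("L", "L", "R"),
  RRL = c("L", "R", "R")
)

#' Simulate a GT-Seq cohort
#'
#' Draws true allele multisets for every individual at every panel SNP
#' (dosages follow the genotype class: LL = 2 L copies, RR = 2 R, LR =
#' 1 L + 1 R, LLR = 2 L + 1 R, RRL = 1 L + 2 R), applies per-copy
#' introgression replacement in the parental species, then simulates
#' reads: per-site coverage from a negative binomial, each read drawn
#' uniformly from the allele copies and miscalled to a uniform different
#' base with probability `error_rate`.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `gtseq_cohort` with tibbles `counts`
#'   (individual, marker, pos, nA, nC, nG, nT), `metadata` (individual,
#'   taxon, population, popsys, region, lat, lon, sex, ploidy) and
#'   `truth` (individual, snp, alleles, n_l, introgressed).
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 42))
#' dplyr::count(cohort$metadata, taxon)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$snp_panel
  pops <- config$populations

  meta <- purrr::pmap_dfr(pops, function(population, popsys, region, lat, lon,
                                         n_LL, n_RR, n_LR, n_LLR, n_RRL, ...) {
    sizes <- c(LL = n_LL, RR = n_RR, LR = n_LR, LLR = n_LLR, RRL = n_RRL)
    taxon <- rep(names(sizes), sizes)
    if (length(taxon) == 0) {
      return(NULL)
    }
    tibble::tibble(
      individual = sprintf("%s_%s_%03d", population, taxon,
                           stats::ave(seq_along(taxon), taxon, FUN = seq_along)),
      taxon = taxon,
      population = population,
      popsys = popsys,
      region = region,
      lat = lat,
      lon = lon,
      ploidy = ifelse(taxon %in% c("LLR", "RRL"), 3L, 2L)
    )
  })
  if (is.null(meta) || nrow(meta) == 0) stop("configuration error: no individuals")
  meta$sex <- sample(c("f", "m"), nrow(meta), replace = TRUE)
  meta <- dplyr::select(
    meta, "individual", "taxon", "population", "popsys", "region",
    "lat", "lon", "sex", "ploidy"
  )

  grid <- tidyr::crossing(meta, panel)

  # Designated-(L)-allele probability per copy for frequency-driven SNPs.
  eff <- config$popsys_effect
  freq_for <- function(snp, popsys) {
    if (!is.null(eff)) {
      hit <- eff$f[eff$snp == snp & eff$popsys == popsys]
      if (length(hit) >= 1) {
        return(hit[1])
      }
    }
    0.5
  }

  n <- nrow(grid)
  alleles <- character(n)
  n_l <- integer(n)
  introgressed <- logical(n)
  nA <- nC <- nG <- nT <- integer(n)
  cov <- stats::rnbinom(n, size = config$coverage_dispersion, mu = config$coverage_mean)

  for (i in seq_len(n)) {
    origins <- GENOTYPE_ORIGINS[[grid$taxon[i]]]
    driven_by_freq <- !grid$species_specific[i] ||
      (!is.null(eff) && any(eff$snp == grid$snp[i]))
    if (driven_by_freq) {
      f <- freq_for(grid$snp[i], grid$popsys[i])
      is_l <- stats::runif(length(origins)) < f
      copies <- ifelse(is_l, grid$l_base[i], grid$r_base[i])
      intro <- FALSE
    } else {
      copies <- ifelse(origins == "L", grid$l_base[i], grid$r_base[i])
      intro <- FALSE
      if (grid$taxon[i] == "RR" && config$introgression_rate_rr > 0) {
        flip <- stats::runif(length(copies)) < config$introgression_rate_rr
        copies[flip] <- grid$l_base[i]
        intro <- any(flip)
      } else if (grid$taxon[i] == "LL" && config$introgression_rate_ll > 0) {
        flip <- stats::runif(length(copies)) < config$introgression_rate_ll
        copies[flip] <- grid$r_base[i]
        intro <- any(flip)
      }
    }
    alleles[i] <- paste(copies, collapse = "")
    n_l[i] <- sum(copies == grid$l_base[i])
    introgressed[i] <- intro

    # Reads: uniform copy choice, then uniform miscall.
    cv <- cov[i]
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    if (cv > 0) {
      per_copy <- as.integer(stats::rmultinom(1, cv, rep(1, length(copies))))
      for (k in seq_along(copies)) {
        nk <- per_copy[k]
        if (nk == 0) next
        nerr <- stats::rbinom(1, nk, config$error_rate)
        counts[copies[k]] <- counts[copies[k]] + (nk - nerr)
        if (nerr > 0) {
          others <- setdiff(BASES, copies[k])
          err <- as.integer(stats::rmultinom(1, nerr, rep(1, 3)))
          counts[others] <- counts[others] + err
        }
      }
    }
    nA[i] <- counts[["A"]]
    nC[i] <- counts[["C"]]
    nG[i] <- counts[["G"]]
    nT[i] <- counts[["T"]]
  }

  counts <- tibble::tibble(
    individual = grid$individual,
    marker = grid$marker,
    pos = grid$pos,
    nA = nA, nC = nC, nG = nG, nT = nT
  )
  truth <- tibble::tibble(
    individual = grid$individual,
    snp = grid$snp,
    alleles = alleles,
    n_l = n_l,
    introgressed = introgressed
  )
  structure(
    list(counts = counts, metadata = meta, truth = truth, config = config),
    class = "gtseq_cohort"
  )
}

#' @export
print.gtseq_cohort <- function(x, ...) {
  cat(
    "<gtseq_cohort> ", dplyr::n_distinct(x$metadata$individual),
    " individuals x ", dplyr::n_distinct(x$counts$marker), " markers (",
    nrow(x$counts), " count rows)\n",
    sep = ""
  )
  invisible(x)
}

#' Write a simulated cohort to a fixture directory
#'
#' Writes `counts.tsv`, `metadata.tsv`, `truth.tsv`, `panel.tsv` and
#' `config.yaml` so that the cohort round-trips through [read_fixture()]
#' and the file readers of the genotyping module.
#'
#' @param cohort A `gtseq_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gtseq_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(cohort$config$snp_panel, file.path(dir, "panel.tsv"))
  cfg <- cohort$config
  scalars <- cfg[c(
    "introgression_rate_rr", "introgression_rate_ll", "coverage_mean",
    "coverage_dispersion", "error_rate", "seed"
  )]
  scalars$populations <- as.list(as.data.frame(cfg$populations))
  if (!is.null(cfg$popsys_effect)) {
    scalars$popsys_effect <- as.list(as.data.frame(cfg$popsys_effect))
  }
  yaml::write_yaml(scalars, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A `gtseq_cohort` (the reconstructed `config` carries the panel,
#'   populations and scalar settings).
#' @export
read_fixture <- function(dir) {
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  panel <- readr::read_tsv(file.path(dir, "panel.tsv"), show_col_types = FALSE)
  pops <- tibble::as_tibble(as.data.frame(cfgl$populations))
  config <- sim_config(
    snp_panel = panel,
    populations = pops,
    introgression_rate_rr = cfgl$introgression_rate_rr,
    introgression_rate_ll = cfgl$introgression_rate_ll,
    coverage_mean = cfgl$coverage_mean,
    coverage_dispersion = cfgl$coverage_dispersion,
    error_rate = cfgl$error_rate,
    popsys_effect = if (!is.null(cfgl$popsys_effect)) {
      tibble::as_tibble(as.data.frame(cfgl$popsys_effect))
    },
    seed = cfgl$seed
  )
  structure(
    list(
      counts = read_pileup(file.path(dir, "counts.tsv")),
      metadata = readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE),
      truth = readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE),
      config = config
    ),
    class = "gtseq_cohort"
  )
}
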