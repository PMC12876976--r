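#' Published per-population frequencies of lessonae-specific nucleotides
#'
#' The printed worked example shipped with the package: frequencies of
#' the L-specific (nu_L-column) nucleotide at 16 species-specific SNPs of
#' 13 gametogenic genes, for 11 *P. ridibundus* (RR) population units and
#' 3 *P. lessonae* (LL) units. `n.a.` cells are `NA`. Values are printed
#' to two decimals; summary rows re-derived from them can therefore
#' differ by one unit in the third decimal from the published summaries
#' in a few cells.
#'
#' @return Tibble (`snp`, `gene`, `nu_l`, `genotype`, `unit`, `popsys`,
#'   `f`, `n_alleles` (NA: not published), `missing`).
#' @export
published_snp_frequencies <- function() {
  path <- system.file("extdata", "published_nuL_frequencies.tsv",
                      package = "gtseqpop", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::transmute(
      snp = .data$snp, gene = .data$gene, nu_l = .data$nu_l,
      genotype = .data$species, unit = .data$unit, popsys = .data$popsys,
      f = .data$f, n_alleles = NA_integer_, missing = is.na(.data$f)
    )
}

#' Per-SNP, per-unit introgression cells
#'
#' For species-specific SNPs restricted to one focal parental species,
#' the introgressed-allele frequency in a population unit is the absolute
#' deviation of the unit's designated-allele frequency from the state
#' expected to be fixed in that species: `ir = |f - expected|`. The
#' expected state comes from the species-wide pooled frequency (via
#' [classify_snps()]), which makes the estimator invariant to which
#' physical base a table row happens to track.
#'
#' @param freqs Allele-frequency tibble (`snp`, `genotype`, `unit`, `f`,
#'   `missing`), e.g. [allele_frequencies()] output or
#'   [published_snp_frequencies()].
#' @param classification [classify_snps()] output (`snp`, `category`,
#'   `expected_LL`, `expected_RR`).
#' @param focal_species `"RR"` or `"LL"`.
#' @return Tibble (`snp`, `unit`, `f`, `expected`, `ir`); `ir` is `NA`
#'   where `f` is missing. SNPs without a defined expected state are
#'   excluded with a warning.
#' @export
introgression_cells <- function(freqs, classification,
                                focal_species = c("RR", "LL")) {
  focal_species <- match.arg(focal_species)
  exp_col <- paste0("expected_", focal_species)
  cls <- classification
  if ("category" %in% names(cls)) {
    cls <- dplyr::filter(cls, .data$category == "species_specific")
  }
  undefined <- cls$snp[is.na(cls[[exp_col]])]
  if (length(undefined) > 0) {
    warning(
      "excluding SNP(s) without a defined expected state in ",
      focal_species, ": ", paste(undefined, collapse = ", ")
    )
    cls <- cls[!cls$snp %in% undefined, ]
  }
  freqs |>
    dplyr::filter(.data$genotype == focal_species) |>
    dplyr::inner_join(
      dplyr::select(cls, "snp", expected = dplyr::all_of(exp_col)),
      by = "snp"
    ) |>
    dplyr::transmute(
      snp = .data$snp, unit = .data$unit, f = .data$f,
      expected = .data$expected,
      ir = abs(.data$f - .data$expected)
    )
}

#' Summarize introgression cells into rates
#'
#' Computes `IR_SNP` (mean over non-missing units per SNP), `IR_POP`
#' (mean over non-missing SNPs per unit), and the grand mean `IR_mean`
#' with its standard deviation over all non-missing SNP x unit cells
#' (`ir_sd`: sample SD, denominator N-1; `ir_sd_n`: population SD
#' alongside). Mean designated-allele frequencies per SNP (`f_bar`) are
#' reported with the per-SNP rates.
#'
#' @param cells Output of [introgression_cells()].
#' @return Object of class `ir_summary` with elements `cells`, `ir_snp`,
#'   `ir_pop`, `ir_mean`, `ir_sd`, `ir_sd_n`, `n_cells`.
#' @export
ir_summaries <- function(cells) {
  ok <- !is.na(cells$ir)
  if (!any(ok)) stop("all introgression cells are missing")
  ir_snp <- cells |>
    dplyr::summarise(
      f_bar = mean(.data$f, na.rm = TRUE),
      ir_snp = mean(.data$ir, na.rm = TRUE),
      n_units = sum(!is.na(.data$ir)),
      .by = "snp"
    )
  ir_pop <- cells |>
    dplyr::summarise(
      ir_pop = mean(.data$ir, na.rm = TRUE),
      n_snps = sum(!is.na(.data$ir)),
      .by = "unit"
    )
  v <- cells$ir[ok]
  structure(
    list(
      cells = cells,
      ir_snp = ir_snp,
      ir_pop = ir_pop,
      ir_mean = mean(v),
      ir_sd = stats::sd(v),
      ir_sd_n = sqrt(mean((v - mean(v))^2)),
      n_cells = length(v)
    ),
    class = "ir_summary"
  )
}

#' @export
print.ir_summary <- function(x, ...) {
  cat(
    "<ir_summary> ", nrow(x$ir_snp), " SNPs x ", nrow(x$ir_pop),
    " units (", x$n_cells, " cells)\n",
    "IR_mean = ", signif(x$ir_mean, 3), " +/- ", signif(x$ir_sd, 3),
    " (sd, N-1; N: ", signif(x$ir_sd_n, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Round half away from zero
#'
#' Fixed-precision rounding with the half-up convention used when
#' comparing against printed tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
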