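#' Filter SNPs by per-taxon sample support
#'
#' Removes SNPs that were called in fewer than `min_per_taxon` individuals
#' of any analyzed taxon class (default 5, i.e. "fewer than five" fails).
#'
#' @param calls Output of [call_genotypes()] joined-able to metadata.
#' @param metadata Sample metadata with `individual` and `taxon`.
#' @param panel Tibble mapping panel sites to SNP ids (`snp`, `marker`,
#'   `pos`).
#' @param taxa Taxon classes that must each reach the threshold; defaults
#'   to the diploid classes present in the metadata.
#' @param min_per_taxon Minimum called individuals per taxon.
#' @return Tibble (`snp`, `retained`, `reason`) where `reason` names the
#'   failing taxon for removed SNPs.
#' @export
filter_markers <- function(calls, metadata, panel,
                           taxa = NULL, min_per_taxon = 5) {
  joined <- calls |>
    dplyr::inner_join(panel[c("snp", "marker", "pos")], by = c("marker", "pos")) |>
    dplyr::inner_join(metadata[c("individual", "taxon")], by = "individual")
  if (nrow(joined) == 0) stop("calls and metadata do not join")
  if (is.null(taxa)) {
    taxa <- intersect(c("LL", "RR", "LR"), unique(joined$taxon))
  }
  support <- joined |>
    dplyr::filter(.data$status == "called", .data$taxon %in% taxa) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$individual),
      .by = c("snp", "taxon")
    ) |>
    tidyr::complete(
      snp = unique(panel$snp), taxon = taxa, fill = list(n = 0L)
    )
  out <- support |>
    dplyr::summarise(
      retained = all(.data$n >= min_per_taxon),
      reason = if (all(.data$n >= min_per_taxon)) NA_character_ else {
        paste0(
          "called in < ", min_per_taxon, " individuals of: ",
          paste(.data$taxon[.data$n < min_per_taxon], collapse = ", ")
        )
      },
      .by = "snp"
    )
  if (!any(out$retained)) warning("no SNP passes the per-taxon support filter")
  out
}

#' Pool small population samples into population units
#'
#' For each genotype class, populations contributing fewer than `min_n`
#' individuals are merged with other below-threshold populations of the
#' same population system and geographical region. Populations at or
#' above the threshold stay unpooled; small populations with no
#' same-system same-region partner are flagged and excluded.
#'
#' @param metadata Sample metadata (`individual`, `taxon`, `population`,
#'   `popsys`, `region`, `lat`, `lon`).
#' @param min_n Minimum per-population sample size per genotype class.
#' @return Tibble (`genotype`, `population`, `unit`, `popsys`, `region`,
#'   `lat`, `lon`, `n`, `pooled`, `excluded`). Unit coordinates are the
#'   member-population means.
#' @export
pool_populations <- function(metadata, min_n = 4) {
  need <- c("individual", "taxon", "population", "popsys", "region", "lat", "lon")
  stopifnot(all(need %in% names(metadata)))
  if (any(is.na(metadata$popsys)) || any(is.na(metadata$region))) {
    stop("every population needs popsys and region labels")
  }
  sizes <- metadata |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$individual),
      lat = .data$lat[1], lon = .data$lon[1],
      .by = c("taxon", "population", "popsys", "region")
    )
  sizes |>
    dplyr::mutate(
      small = .data$n < min_n,
      n_partners = sum(.data$small) - .data$small * 0L, # small pops in group
      .by = c("taxon", "popsys", "region")
    ) |>
    dplyr::mutate(
      n_small = sum(.data$small),
      .by = c("taxon", "popsys", "region")
    ) |>
    dplyr::mutate(
      pooled = .data$small & .data$n_small >= 2,
      excluded = .data$small & .data$n_small < 2,
      unit = dplyr::if_else(
        .data$pooled,
        paste(.data$popsys, .data$region, "pool", sep = "_"),
        .data$population
      )
    ) |>
    dplyr::mutate(
      lat = mean(.data$lat), lon = mean(.data$lon), # unit coordinates
      .by = c("taxon", "unit")
    ) |>
    dplyr::select(
      genotype = "taxon", "population", "unit", "popsys", "region",
      "lat", "lon", "n", "pooled", "excluded"
    )
}

#' Designate a tracked nucleotide per SNP
#'
#' The tracked (designated) nucleotide is the major allele among LL
#' individuals when any are called, falling back to the overall major
#' allele; this is the "nu_L" convention for species-specific SNPs.
#'
#' @param calls Output of [call_genotypes()].
#' @param metadata Sample metadata with `individual`, `taxon`.
#' @param panel Tibble (`snp`, `marker`, `pos`).
#' @return Tibble (`snp`, `designated`).
#' @export
designate_alleles <- function(calls, metadata, panel) {
  long <- calls |>
    dplyr::inner_join(panel[c("snp", "marker", "pos")], by = c("marker", "pos")) |>
    dplyr::inner_join(metadata[c("individual", "taxon")], by = "individual") |>
    dplyr::filter(.data$status == "called") |>
    dplyr::mutate(
      a1 = .data$allele1,
      a2 = dplyr::coalesce(.data$allele2, .data$allele1)
    ) |>
    tidyr::pivot_longer(c("a1", "a2"), values_to = "base")
  major <- function(base) names(sort(table(base), decreasing = TRUE))[1]
  long |>
    dplyr::summarise(
      designated = if (any(.data$taxon == "LL")) {
        major(.data$base[.data$taxon == "LL"])
      } else {
        major(.data$base)
      },
      .by = "snp"
    )
}

#' Allele frequencies per SNP, genotype class and population unit
#'
#' Triploid individuals (LLR, RRL) are dropped with a message. For each
#' (SNP, genotype class, unit) the frequency of the designated nucleotide
#' is computed over called alleles: a homozygote for the designated base
#' contributes 2, a heterozygote carrying it 1, with denominator 2 x
#' called individuals. Units with no called individual are flagged
#' missing.
#'
#' @param calls Output of [call_genotypes()].
#' @param metadata Sample metadata.
#' @param units Output of [pool_populations()] (excluded units dropped).
#' @param panel Tibble (`snp`, `marker`, `pos`).
#' @param designated Tibble (`snp`, `designated`), e.g. from
#'   [designate_alleles()].
#' @param by_sex If `TRUE`, frequencies are additionally computed for male
#'   and female subsets (rows gain a `sex` column with `"all"`, `"f"`,
#'   `"m"`); used for populations with uncertain system assignment.
#' @return Tibble (`snp`, `genotype`, `unit`, `popsys`, `region`, `lat`,
#'   `lon`, `f`, `n_individuals`, `n_alleles`, `missing`, and `sex` when
#'   `by_sex`).
#' @export
allele_frequencies <- function(calls, metadata, units, panel, designated,
                               by_sex = FALSE) {
  n_tri <- sum(metadata$taxon %in% c("LLR", "RRL"))
  if (n_tri > 0) {
    message("excluding ", n_tri, " triploid individuals (LLR/RRL)")
  }
  meta <- dplyr::filter(metadata, !.data$taxon %in% c("LLR", "RRL"))
  units <- dplyr::filter(units, !.data$excluded)

  base_tbl <- calls |>
    dplyr::inner_join(panel[c("snp", "marker", "pos")], by = c("marker", "pos")) |>
    dplyr::inner_join(
      meta[c("individual", "taxon", "population",
             if (by_sex) "sex" else NULL)],
      by = "individual"
    ) |>
    dplyr::inner_join(
      dplyr::select(units, genotype_join = "genotype", "population", "unit",
                    "popsys", "region", "lat", "lon"),
      by = c("taxon" = "genotype_join", "population")
    ) |>
    dplyr::inner_join(designated, by = "snp") |>
    dplyr::filter(.data$status == "called") |>
    dplyr::mutate(
      des_copies = (.data$allele1 == .data$designated) +
        (dplyr::coalesce(.data$allele2, .data$allele1) == .data$designated)
    )

  summarize_freq <- function(tbl) {
    tbl |>
      dplyr::summarise(
        f = sum(.data$des_copies) / (2 * dplyr::n()),
        n_individuals = dplyr::n(),
        n_alleles = 2L * dplyr::n(),
        popsys = .data$popsys[1], region = .data$region[1],
        lat = .data$lat[1], lon = .data$lon[1],
        .by = c("snp", "taxon", "unit")
      ) |>
      dplyr::rename(genotype = "taxon") |>
      dplyr::mutate(missing = .data$n_individuals == 0L)
  }

  out <- summarize_freq(base_tbl)
  if (by_sex) {
    out$sex <- "all"
    per_sex <- base_tbl |>
      dplyr::group_split(.data$sex) |>
      purrr::map_dfr(function(tbl) {
        res <- summarize_freq(tbl)
        res$sex <- tbl$sex[1]
        res
      })
    out <- dplyr::bind_rows(out, per_sex)
  }
  out
}

#' Classify SNPs as species-specific or intraspecific
#'
#' Uses species-wide pooled frequencies of the designated allele (allele
#' counts summed over units, so pooling conserves counts). A SNP is
#' species-specific when its designated allele is at or above 0.95 in
#' exactly one parental species and at or below 0.05 in the other; SNPs
#' polymorphic within one parental species are intraspecific; the rest
#' are uninformative. The expected fixed state per species is the member
#' of {0, 1} nearer to the species-wide frequency when that frequency is
#' <= 0.05 or >= 0.95, else none (NA).
#'
#' @param freqs Output of [allele_frequencies()] (diploid classes).
#' @param threshold Species-specificity frequency threshold.
#' @return Tibble (`snp`, `f_LL`, `f_RR`, `category`, `expected_LL`,
#'   `expected_RR`).
#' @export
classify_snps <- function(freqs, threshold = 0.95) {
  pooled <- freqs |>
    dplyr::filter(.data$genotype %in% c("LL", "RR"), !.data$missing) |>
    dplyr::mutate(
      .w = if (all(is.na(.data$n_alleles))) 1 else as.numeric(.data$n_alleles)
    ) |>
    dplyr::summarise(
      f = sum(.data$f * .data$.w) / sum(.data$.w),
      .by = c("snp", "genotype")
    ) |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "f",
                       names_prefix = "f_")
  if (!"f_LL" %in% names(pooled)) pooled$f_LL <- NA_real_
  if (!"f_RR" %in% names(pooled)) pooled$f_RR <- NA_real_
  expected_state <- function(f, thr) {
    dplyr::case_when(
      is.na(f) ~ NA_real_,
      f >= thr ~ 1,
      f <= 1 - thr ~ 0,
      TRUE ~ NA_real_
    )
  }
  pooled |>
    dplyr::mutate(
      expected_LL = expected_state(.data$f_LL, threshold),
      expected_RR = expected_state(.data$f_RR, threshold),
      poly_L = .data$f_LL > 1 - threshold & .data$f_LL < threshold,
      poly_R = .data$f_RR > 1 - threshold & .data$f_RR < threshold,
      category = dplyr::case_when(
        is.na(.data$f_LL) | is.na(.data$f_RR) ~ "uninformative",
        (.data$f_LL >= threshold & .data$f_RR <= 1 - threshold) |
          (.data$f_RR >= threshold & .data$f_LL <= 1 - threshold) ~
          "species_specific",
        .data$poly_L & !.data$poly_R ~ "intraspecific_L",
        .data$poly_R & !.data$poly_L ~ "intraspecific_R",
        TRUE ~ "uninformative"
      )
    ) |>
    dplyr::select(
      "snp", "f_LL", "f_RR", "category", "expected_LL", "expected_RR"
    )
}
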