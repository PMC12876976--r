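#' Read a per-site base-count (pileup-like) table
#'
#' Expects a tab-separated file with columns `individual`, `marker`,
#' `pos`, `nA`, `nC`, `nG`, `nT` (one row per individual x marker-site;
#' positions are marker-local and 1-based). Malformed rows are reported
#' with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return Tibble with the columns above (`pos` and counts integer).
#' @export
read_pileup <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      individual = readr::col_character(),
      marker = readr::col_character(),
      pos = readr::col_integer(),
      nA = readr::col_integer(),
      nC = readr::col_integer(),
      nG = readr::col_integer(),
      nT = readr::col_integer()
    )
  )
  required <- c("individual", "marker", "pos", "nA", "nC", "nG", "nT")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("pileup file is missing columns: ", paste(missing, collapse = ", "))
  }
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop(
      "malformed pileup lines: ",
      paste(unique(prob$row), collapse = ", ")
    )
  }
  cnt <- as.matrix(tbl[c("nA", "nC", "nG", "nT")])
  bad <- which(rowSums(cnt < 0) > 0)
  if (length(bad) > 0) {
    stop(
      "negative counts at data line(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  if (nrow(tbl) == 0) warning("empty pileup file: ", path)
  tbl
}

#' Call genotypes from base counts
#'
#' Applies the coverage-threshold caller: a site is no-call when its total
#' coverage is below `min_total_coverage` (default 10 reads). Otherwise
#' the two most-abundant bases are considered; the site is heterozygous
#' when the second base reaches at least `min_relative_coverage` (default
#' 20%) of the total, else homozygous for the top base. Additional bases
#' beyond the top two are treated as sequencing error. Ties are broken
#' alphabetically (A < C < G < T).
#'
#' @param counts Tibble with columns `individual`, `marker`, `pos`, `nA`,
#'   `nC`, `nG`, `nT` (e.g. from [read_pileup()] or [simulate_cohort()]).
#' @param min_total_coverage Minimum total reads for a call (COV_tot).
#' @param min_relative_coverage Minimum fraction of total coverage for the
#'   minor base of a heterozygote (COV_min); boundary inclusive.
#' @return Tibble `counts` plus `cov_tot`, `status` (`"called"` /
#'   `"no_call"`), `allele1`, `allele2` (NA when homozygous or no-call)
#'   and `iupac` (`"N"` for no-call).
#' @examples
#' x <- tibble::tibble(individual = "i1", marker = "m", pos = 1L,
#'                     nA = 80L, nC = 0L, nG = 20L, nT = 0L)
#' call_genotypes(x)$iupac # "R"
#' @export
call_genotypes <- function(counts, min_total_coverage = 10,
                           min_relative_coverage = 0.20) {
  stopifnot(min_total_coverage >= 1)
  stopifnot(min_relative_coverage > 0, min_relative_coverage <= 0.5)
  cnt <- as.matrix(counts[c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) stop("negative base counts")
  colnames(cnt) <- BASES
  cov_tot <- rowSums(cnt)

  # Order within each row by count descending, alphabetical tie-break
  # (columns are already in A<C<G<T order, and max.col/order are stable).
  top1 <- integer(nrow(cnt))
  top2 <- integer(nrow(cnt))
  for (i in seq_len(nrow(cnt))) {
    o <- order(-cnt[i, ], BASES)
    top1[i] <- o[1]
    top2[i] <- o[2]
  }
  n2 <- cnt[cbind(seq_len(nrow(cnt)), top2)]
  called <- cov_tot >= min_total_coverage
  het <- called & (n2 / cov_tot >= min_relative_coverage) & n2 > 0

  allele1 <- ifelse(called, BASES[top1], NA_character_)
  allele2 <- ifelse(het, BASES[top2], NA_character_)
  iupac <- rep("N", nrow(cnt))
  iupac[called & !het] <- allele1[called & !het]
  if (any(het)) {
    iupac[het] <- vapply(
      which(het),
      function(i) iupac_code(c(allele1[i], allele2[i])),
      character(1)
    )
  }
  dplyr::mutate(
    tibble::as_tibble(counts),
    cov_tot = as.integer(cov_tot),
    status = ifelse(called, "called", "no_call"),
    allele1 = allele1,
    allele2 = allele2,
    iupac = iupac
  )
}

#' Per-individual IUPAC consensus sequences over a SNP panel
#'
#' Concatenates the IUPAC genotype calls of each individual in panel
#' order; sites that are missing or uncalled become `N`.
#'
#' @param calls Output of [call_genotypes()].
#' @param panel Ordered tibble with columns `snp`, `marker`, `pos`.
#' @return Tibble (`individual`, `sequence`) with
#'   `nchar(sequence) == nrow(panel)`.
#' @export
consensus_sequences <- function(calls, panel) {
  if (nrow(panel) == 0) {
    warning("empty SNP panel: consensus sequences are empty strings")
    return(tibble::tibble(
      individual = unique(calls$individual),
      sequence = ""
    ))
  }
  if (anyDuplicated(paste(panel$marker, panel$pos))) {
    stop("duplicate panel sites")
  }
  key <- dplyr::mutate(panel, .site = dplyr::row_number())
  wide <- calls |>
    dplyr::inner_join(key, by = c("marker", "pos")) |>
    dplyr::select("individual", ".site", "iupac")
  if (anyDuplicated(wide[c("individual", ".site")])) {
    stop("duplicate individual ids at a panel site")
  }
  wide |>
    tidyr::complete(
      individual = unique(calls$individual),
      .site = seq_len(nrow(panel)),
      fill = list(iupac = "N")
    ) |>
    dplyr::arrange(.data$individual, .data$.site) |>
    dplyr::summarise(
      sequence = paste(.data$iupac, collapse = ""),
      .by = "individual"
    )
}

#' Write consensus sequences as FASTA
#'
#' @param seqs Tibble (`individual`, `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(seqs, path) {
  if (anyDuplicated(seqs$individual)) stop("duplicate individual ids")
  x <- Biostrings::BStringSet(seqs$sequence)
  names(x) <- seqs$individual
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assign taxon and ploidy class from diagnostic read dosages
#'
#' Pools reads across species-diagnostic panel sites with adequate
#' coverage, computes the fraction of reads carrying the L-specific base,
#' and classifies each individual by the nearest expected dosage: 0 (RR),
#' 1/3 (RRL), 1/2 (LR), 2/3 (LLR), 1 (LL).
#'
#' @param counts Base-count tibble (see [read_pileup()]).
#' @param panel Diagnostic panel with columns `marker`, `pos`, `l_base`,
#'   `r_base` (only `species_specific` rows are used if that column is
#'   present).
#' @param min_total_coverage Minimum site coverage to contribute reads.
#' @return Tibble (`individual`, `l_fraction`, `taxon`, `ploidy`,
#'   `dosage_distance`, `n_sites`); individuals with no covered
#'   diagnostic site get `taxon = NA` ("unassigned").
#' @export
assign_taxon <- function(counts, panel, min_total_coverage = 10) {
  if ("species_specific" %in% names(panel)) {
    panel <- dplyr::filter(panel, .data$species_specific)
  }
  stopifnot(nrow(panel) > 0)
  dosages <- c(RR = 0, RRL = 1 / 3, LR = 1 / 2, LLR = 2 / 3, LL = 1)
  ploidies <- c(RR = 2L, RRL = 3L, LR = 2L, LLR = 3L, LL = 2L)

  joined <- counts |>
    dplyr::inner_join(
      dplyr::select(panel, "marker", "pos", "l_base", "r_base"),
      by = c("marker", "pos")
    ) |>
    dplyr::mutate(
      cov_tot = .data$nA + .data$nC + .data$nG + .data$nT,
      l_reads = dplyr::case_when(
        .data$l_base == "A" ~ .data$nA, .data$l_base == "C" ~ .data$nC,
        .data$l_base == "G" ~ .data$nG, .data$l_base == "T" ~ .data$nT
      ),
      r_reads = dplyr::case_when(
        .data$r_base == "A" ~ .data$nA, .data$r_base == "C" ~ .data$nC,
        .data$r_base == "G" ~ .data$nG, .data$r_base == "T" ~ .data$nT
      )
    ) |>
    dplyr::filter(.data$cov_tot >= min_total_coverage)

  out <- joined |>
    dplyr::summarise(
      l_fraction = sum(.data$l_reads) / sum(.data$l_reads + .data$r_reads),
      n_sites = dplyr::n(),
      .by = "individual"
    ) |>
    dplyr::mutate(
      taxon = names(dosages)[apply(
        abs(outer(.data$l_fraction, dosages, `-`)), 1, which.min
      )],
      ploidy = unname(ploidies[.data$taxon]),
      dosage_distance = abs(.data$l_fraction - dosages[.data$taxon])
    )
  # Individuals present in counts but with no covered diagnostic site.
  missing <- setdiff(unique(counts$individual), out$individual)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(
        individual = missing, l_fraction = NA_real_, n_sites = 0L,
        taxon = NA_character_, ploidy = NA_integer_,
        dosage_distance = NA_real_
      )
    )
  }
  dplyr::select(
    out, "individual", "l_fraction", "taxon", "ploidy",
    "dosage_distance", "n_sites"
  )
}
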