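#' Descriptive statistics for coding sequences
#'
#' Per FASTA record: coding-sequence length (CDSL, bp), GC content (%,
#' G+C over the non-N length), the percentage of ambiguous bases
#' (`n_frac`), and an exclusion flag for sequences exceeding 5% Ns.
#' Headers in the `gene|species|allele` convention are split into
#' columns when present.
#'
#' @param fasta Path to a (nucleotide, unaligned or aligned) FASTA file.
#' @param max_n_frac Exclusion threshold on the N percentage.
#' @return Tibble (`id`, `gene`, `species`, `allele`, `cdsl`, `gc`,
#'   `n_frac`, `excluded`).
#' @export
cds_stats <- function(fasta, max_n_frac = 5) {
  x <- Biostrings::readDNAStringSet(fasta)
  if (any(Biostrings::width(x) == 0)) stop("empty sequence in ", fasta)
  freq <- Biostrings::alphabetFrequency(x)
  cdsl <- Biostrings::width(x)
  n_n <- cdsl - rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- 100 * rowSums(freq[, c("G", "C"), drop = FALSE]) / (cdsl - n_n)
  parts <- stringr::str_split(names(x), stringr::fixed("|"))
  field <- function(k) {
    purrr::map_chr(parts, ~ if (length(.x) >= k) .x[k] else NA_character_)
  }
  tibble::tibble(
    id = names(x),
    gene = field(1), species = field(2), allele = field(3),
    cdsl = as.integer(cdsl),
    gc = gc,
    n_frac = 100 * n_n / cdsl,
    excluded = 100 * n_n / cdsl > max_n_frac
  )
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Percentage of mismatching sites over compared sites; sites with gaps
#' (`-`) or `N` (nucleotide level) / `X` (amino-acid level) in either
#' sequence are pairwise-deleted. At the amino-acid level both
#' nucleotide sequences are first translated in reading frame 1 with the
#' standard genetic code.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @param level `"nt"` or `"aa"`.
#' @return Distance in percent.
#' @export
p_distance <- function(a, b, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (nchar(a) != nchar(b)) stop("aligned length mismatch")
  if (level == "aa") {
    if (nchar(a) %% 3 != 0) stop("length not divisible by 3 for aa level")
    tr <- function(s) {
      as.character(Biostrings::translate(
        Biostrings::DNAString(s), if.fuzzy.codon = "X"
      ))
    }
    a <- tr(a)
    b <- tr(b)
    skip <- c("X", "-", "*")
  } else {
    skip <- c("N", "-")
  }
  ca <- stringr::str_split_1(toupper(a), "")
  cb <- stringr::str_split_1(toupper(b), "")
  keep <- !(ca %in% skip) & !(cb %in% skip)
  if (!any(keep)) {
    return(NaN)
  }
  100 * mean(ca[keep] != cb[keep])
}

#' Flag genes with outlying intragroup divergence ranges
#'
#' The divergence range of a gene is the spread (max minus min) of its
#' pairwise intraspecific distances; genes whose range exceeds the given
#' percentile of the range distribution are flagged as introgression
#' candidates.
#'
#' @param ranges Tibble (`gene`, `range`) of per-gene distance ranges, or
#'   a tibble (`gene`, `distance`) of pairwise distances from which
#'   ranges are derived.
#' @param percentile Flagging percentile (default 95).
#' @return Input tibble with `range`, `threshold` and `outlier` columns.
#' @export
divergence_outliers <- function(ranges, percentile = 95) {
  if ("distance" %in% names(ranges) && !"range" %in% names(ranges)) {
    ranges <- ranges |>
      dplyr::summarise(
        range = max(.data$distance) - min(.data$distance),
        .by = "gene"
      )
  }
  thr <- stats::quantile(ranges$range, percentile / 100, names = FALSE)
  dplyr::mutate(ranges, threshold = thr, outlier = .data$range > thr)
}

#' Simple ordinary least-squares regression
#'
#' @param y,x Numeric vectors (n >= 3); pairs with NA dropped.
#' @return Tibble (`slope`, `intercept`, `r2`, `p`) with the two-sided
#'   slope test.
#' @export
simple_ols <- function(y, x) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    p = s$coefficients[2, 4]
  )
}
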