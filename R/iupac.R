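# Shared IUPAC nucleotide machinery used by the caller, the MLG distance
# and the atomic-number encoding.

# Resolution sets for the 15 unambiguous + ambiguous codes (no gap support;
# N resolves to all four and is treated as missing by most consumers).
IUPAC_RESOLUTIONS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Look up the IUPAC one-letter code for a set of bases
#'
#' @param bases Character vector of bases drawn from A, C, G, T (1 or 2
#'   distinct values; duplicates are collapsed).
#' @return A single uppercase IUPAC code; `"N"` for an empty set.
#' @examples
#' iupac_code(c("A", "G")) # "R"
#' iupac_code("T")         # "T"
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0) {
    return("N")
  }
  hit <- vapply(
    names(IUPAC_RESOLUTIONS),
    function(code) identical(sort(IUPAC_RESOLUTIONS[[code]]), bases),
    logical(1)
  )
  if (!any(hit)) {
    stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}")
  }
  names(IUPAC_RESOLUTIONS)[hit][1]
}

#' Resolve an IUPAC code to its constituent bases
#'
#' @param code Single uppercase IUPAC letter.
#' @return Character vector of bases (A/C/G/T).
#' @export
iupac_bases <- function(code) {
  out <- IUPAC_RESOLUTIONS[[toupper(code)]]
  if (is.null(out)) stop("unknown IUPAC code: ", code)
  out
}

# Average-states site distance between two IUPAC codes: identical symbols
# (including identical ambiguity codes) score 0; otherwise the mismatch
# fraction over the Cartesian product of the two resolution sets.
iupac_site_distance <- function(a, b) {
  if (a == b) {
    return(0)
  }
  ra <- iupac_bases(a)
  rb <- iupac_bases(b)
  mean(outer(ra, rb, FUN = `!=`))
}

# 15 x 15 lookup of site distances (N excluded: callers pairwise-delete N).
iupac_distance_matrix <- function() {
  codes <- names(IUPAC_RESOLUTIONS)
  m <- matrix(0, length(codes), length(codes), dimnames = list(codes, codes))
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      m[i, j] <- iupac_site_distance(codes[i], codes[j])
    }
  }
  m
}

BASES <- c("A", "C", "G", "T")
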