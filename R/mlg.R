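#' Build multilocus genotypes over a SNP panel
#'
#' Concatenates each diploid individual's IUPAC calls in panel order and
#' collapses identical strings within a genotype class into one MLG with
#' a multiplicity; the population systems an MLG occurs in are recorded
#' (MLGs can be shared between systems).
#'
#' @param calls Output of [call_genotypes()].
#' @param panel Ordered tibble (`snp`, `marker`, `pos`); typically the
#'   SNPs found associated with population system.
#' @param metadata Sample metadata (`individual`, `taxon`, `popsys`).
#' @return Tibble (`mlg_id`, `sequence`, `genotype`, `multiplicity`,
#'   `popsys` (comma-collapsed, sorted), `individuals` (list column)).
#' @export
build_mlgs <- function(calls, panel, metadata) {
  if (nrow(panel) == 0) stop("empty SNP panel")
  dip <- dplyr::filter(metadata, !.data$taxon %in% c("LLR", "RRL"))
  seqs <- consensus_sequences(
    dplyr::semi_join(calls, dip, by = "individual"), panel
  )
  seqs |>
    dplyr::inner_join(
      dip[c("individual", "taxon", "popsys")], by = "individual"
    ) |>
    dplyr::summarise(
      multiplicity = dplyr::n(),
      popsys = paste(sort(unique(.data$popsys)), collapse = ","),
      individuals = list(.data$individual),
      .by = c("sequence", "taxon")
    ) |>
    dplyr::rename(genotype = "taxon") |>
    dplyr::arrange(.data$genotype, dplyr::desc(.data$multiplicity)) |>
    dplyr::mutate(
      mlg_id = sprintf("%s_MLG%03d", .data$genotype,
                       stats::ave(seq_len(dplyr::n()), .data$genotype,
                                  FUN = seq_along)),
      .before = 1
    )
}

#' Write MLGs to FASTA
#'
#' @param mlgs [build_mlgs()] output.
#' @param path Output path. Headers are `mlg_id|genotype|popsys|multiplicity`.
#' @return `path`, invisibly.
#' @export
write_mlg_fasta <- function(mlgs, path) {
  x <- Biostrings::BStringSet(mlgs$sequence)
  names(x) <- sprintf(
    "%s|%s|%s|%d", mlgs$mlg_id, mlgs$genotype, mlgs$popsys, mlgs$multiplicity
  )
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read MLGs from FASTA
#'
#' Accepts headers in the `id|genotype|popsys|multiplicity` convention of
#' [write_mlg_fasta()]; missing fields default to `NA` / multiplicity 1.
#'
#' @param path FASTA path.
#' @return Tibble (`mlg_id`, `sequence`, `genotype`, `multiplicity`,
#'   `popsys`).
#' @export
read_mlg_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  parts <- stringr::str_split(names(x), stringr::fixed("|"))
  tibble::tibble(
    mlg_id = purrr::map_chr(parts, 1),
    sequence = unname(as.character(x)),
    genotype = purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[2] else NA_character_),
    multiplicity = purrr::map_int(
      parts, ~ if (length(.x) >= 4) as.integer(.x[4]) else 1L
    ),
    popsys = purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[3] else NA_character_)
  )
}

#' Ambiguity-averaged uncorrected p-distance between two IUPAC strings
#'
#' Per site: identical symbols (including identical ambiguity codes)
#' contribute 0; otherwise the mismatch fraction averaged over all
#' resolutions of the two codes ("average states"). Sites where either
#' string has `N` are excluded pairwise; the distance is the mean over
#' scored sites.
#'
#' @param a,b Equal-length IUPAC strings.
#' @return Single numeric distance in `[0, 1]` (`NaN` when no site is
#'   scored).
#' @examples
#' ambiguity_pdistance("AR", "AR") # 0
#' ambiguity_pdistance("A", "R")   # 0.5
#' @export
ambiguity_pdistance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequence length mismatch")
  ca <- stringr::str_split_1(toupper(a), "")
  cb <- stringr::str_split_1(toupper(b), "")
  keep <- ca != "N" & cb != "N"
  if (!any(keep)) {
    return(NaN)
  }
  dm <- iupac_dist_lookup()
  mean(dm[cbind(ca[keep], cb[keep])])
}

# Cached 15x15 IUPAC site-distance lookup.
iupac_dist_env <- new.env(parent = emptyenv())
iupac_dist_lookup <- function() {
  if (is.null(iupac_dist_env$m)) iupac_dist_env$m <- iupac_distance_matrix()
  iupac_dist_env$m
}

#' Pairwise MLG distance matrix
#'
#' Applies [ambiguity_pdistance()] to all pairs of sequences.
#'
#' @param seqs Character vector of equal-length IUPAC strings, named (or
#'   a [build_mlgs()] tibble, in which case `mlg_id` names are used).
#' @return Symmetric distance matrix with zero diagonal.
#' @export
mlg_distance <- function(seqs) {
  if (is.data.frame(seqs)) {
    seqs <- stats::setNames(seqs$sequence, seqs$mlg_id)
  }
  n <- length(seqs)
  dm <- iupac_dist_lookup()
  chars <- lapply(seqs, function(s) stringr::str_split_1(toupper(s), ""))
  out <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ca <- chars[[i]]
      cb <- chars[[j]]
      keep <- ca != "N" & cb != "N"
      d <- if (any(keep)) mean(dm[cbind(ca[keep], cb[keep])]) else NaN
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration with node heights at half the cluster
#' distance, returning an ultrametric rooted `phylo` tree. Merge ties are
#' resolved deterministically (lowest index first).
#'
#' @param d Symmetric numeric matrix or `dist` object.
#' @return An [ape::as.phylo()] tree with branch lengths.
#' @export
upgma_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d)) || any(is.nan(d))) stop("NA/NaN in distance matrix")
  stopifnot(nrow(d) >= 2)
  phangorn::upgma(stats::as.dist(d))
}

# Atomic-number (proton-count) values for unambiguous bases.
ATOMIC_NUMBERS <- c(A = 70, T = 66, C = 58, G = 78)

#' Encode IUPAC sequences as atomic-number vectors
#'
#' Each base maps to its nucleotide proton count (A = 70, T = 66, C = 58,
#' G = 78); ambiguity codes map to the mean of their constituent values
#' (preserving dosage ordering, e.g. R = 74 between A and G); `N` maps to
#' `NA`.
#'
#' @param seqs Character vector of IUPAC strings (equal lengths), or a
#'   [build_mlgs()] tibble.
#' @return Numeric matrix, one row per sequence, one column per site
#'   (`site1`, `site2`, ...).
#' @examples
#' atomic_encode("ACGT") # 70 58 78 66
#' @export
atomic_encode <- function(seqs) {
  if (is.data.frame(seqs)) {
    seqs <- stats::setNames(seqs$sequence, seqs$mlg_id)
  }
  codes <- names(IUPAC_RESOLUTIONS)
  vals <- vapply(
    codes,
    function(cd) mean(ATOMIC_NUMBERS[IUPAC_RESOLUTIONS[[cd]]]),
    numeric(1)
  )
  vals[["N"]] <- NA_real_
  enc <- function(s) {
    ch <- stringr::str_split_1(toupper(s), "")
    bad <- setdiff(ch, codes)
    if (length(bad) > 0) stop("unknown character(s): ", paste(bad, collapse = ","))
    unname(vals[ch])
  }
  L <- nchar(seqs[[1]])
  m <- matrix(
    unlist(lapply(seqs, enc)), nrow = length(seqs), ncol = L, byrow = TRUE
  )
  colnames(m) <- paste0("site", seq_len(L))
  rownames(m) <- names(seqs)
  m
}

# Wilks' lambda for a variable subset: det(W)/det(T) over group labels.
wilks_lambda <- function(X, y) {
  X <- as.matrix(X)
  tot <- scale(X, center = TRUE, scale = FALSE)
  Tm <- crossprod(tot)
  Wm <- matrix(0, ncol(X), ncol(X))
  for (g in unique(y)) {
    Xi <- X[y == g, , drop = FALSE]
    ci <- scale(Xi, center = TRUE, scale = FALSE)
    Wm <- Wm + crossprod(ci)
  }
  dT <- det(Tm)
  if (dT <= 0) {
    return(NA_real_)
  }
  det(Wm) / dT
}

#' Stepwise linear discriminant analysis
#'
#' Forward stepwise variable entry on the Wilks' lambda criterion: at
#' each step the candidate whose inclusion most reduces lambda enters if
#' its partial F-to-enter, `F = ((lambda_p / lambda_{p+1}) - 1) *
#' (n - g - p) / (g - 1)`, reaches `f_enter` (default 4.0), up to
#' `max_steps` (default 50) steps. Missing values are mean-imputed per
#' variable (with a message). The discriminant functions for the
#' selected variables come from the pooled within-class covariance
#' (via [MASS::lda()]); the resubstitution classification matrix, the
#' percent correctly classified, and leave-one-out cross-validated
#' accuracy are reported.
#'
#' @param X Numeric matrix (cases x variables), e.g. [atomic_encode()]
#'   output.
#' @param y Class labels (e.g. population systems), length `nrow(X)`.
#' @param f_enter Partial-F threshold for entry.
#' @param max_steps Maximum number of variables entered.
#' @return Object of class `stepwise_lda`: `selected` (variable names in
#'   entry order), `steps` (per-entry lambda and F), `fit` (the
#'   [MASS::lda] object or NULL when nothing entered), `confusion`,
#'   `accuracy` (percent), `cv_accuracy` (percent), `classes`.
#' @export
stepwise_lda <- function(X, y, f_enter = 4.0, max_steps = 50) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need >= 2 classes")
  if (any(table(y) < 2)) stop("need >= 2 cases per class")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n_imp <- sum(is.na(X))
  if (n_imp > 0) {
    message("mean-imputing ", n_imp, " missing value(s)")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  n <- nrow(X)
  g <- nlevels(droplevels(y))

  selected <- character(0)
  lambda_cur <- 1
  steps <- tibble::tibble(
    variable = character(0), lambda = numeric(0), F_enter = numeric(0)
  )
  repeat {
    if (length(selected) >= max_steps) break
    cands <- setdiff(colnames(X), selected)
    if (length(cands) == 0) break
    p <- length(selected)
    trial <- purrr::map_dfr(cands, function(v) {
      lam <- wilks_lambda(X[, c(selected, v), drop = FALSE], y)
      Fv <- if (is.na(lam) || lam <= 0) {
        NA_real_
      } else {
        (lambda_cur / lam - 1) * (n - g - p) / (g - 1)
      }
      tibble::tibble(variable = v, lambda = lam, F_enter = Fv)
    })
    trial <- trial[!is.na(trial$F_enter), ]
    if (nrow(trial) == 0) break
    best <- trial[which.max(trial$F_enter), ]
    if (best$F_enter < f_enter) break
    selected <- c(selected, best$variable)
    lambda_cur <- best$lambda
    steps <- dplyr::bind_rows(steps, best)
  }

  if (length(selected) == 0) {
    return(structure(
      list(
        selected = character(0), steps = steps, fit = NULL,
        confusion = NULL, accuracy = NA_real_, cv_accuracy = NA_real_,
        classes = levels(droplevels(y))
      ),
      class = "stepwise_lda"
    ))
  }

  Xs <- X[, selected, drop = FALSE]
  fit <- tryCatch(
    MASS::lda(Xs, grouping = y),
    error = function(e) {
      stop("singular pooled covariance over selected variables (",
           paste(selected, collapse = ", "), "): ", conditionMessage(e))
    }
  )
  pred <- stats::predict(fit, Xs)$class
  confusion <- table(observed = y, predicted = pred)
  accuracy <- 100 * mean(pred == y)
  cv <- MASS::lda(Xs, grouping = y, CV = TRUE)
  cv_accuracy <- 100 * mean(cv$class == y, na.rm = TRUE)

  structure(
    list(
      selected = selected, steps = steps, fit = fit,
      confusion = confusion, accuracy = accuracy,
      cv_accuracy = cv_accuracy, classes = levels(droplevels(y)),
      scores = stats::predict(fit, Xs)$x, labels = y
    ),
    class = "stepwise_lda"
  )
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat(
    "<stepwise_lda> ", length(x$selected), " variable(s) selected: ",
    paste(x$selected, collapse = ", "), "\n",
    "resubstitution accuracy: ", round(x$accuracy, 1),
    "% (LOO CV: ", round(x$cv_accuracy, 1), "%)\n",
    sep = ""
  )
  invisible(x)
}

#' Pairwise composite linkage disequilibrium within a taxon
#'
#' Computes the composite genotypic correlation r (Burrows-style, no
#' phasing) between SNP pairs as the Pearson correlation of designated-
#' allele dosages (0/1/2) across diploid individuals of one taxon.
#' Monomorphic SNPs give `NA`.
#'
#' @param calls Output of [call_genotypes()].
#' @param metadata Sample metadata (`individual`, `taxon`).
#' @param panel Tibble (`snp`, `marker`, `pos`).
#' @param designated Tibble (`snp`, `designated`).
#' @param taxon Taxon class to analyze (e.g. `"LL"`).
#' @param pairs Optional tibble (`snp1`, `snp2`); defaults to all pairs.
#' @return Tibble (`snp1`, `snp2`, `r`, `n`).
#' @export
pairwise_ld <- function(calls, metadata, panel, designated, taxon,
                        pairs = NULL) {
  ids <- metadata$individual[metadata$taxon == taxon]
  dos <- calls |>
    dplyr::filter(.data$individual %in% ids, .data$status == "called") |>
    dplyr::inner_join(panel[c("snp", "marker", "pos")], by = c("marker", "pos")) |>
    dplyr::inner_join(designated, by = "snp") |>
    dplyr::mutate(
      dosage = (.data$allele1 == .data$designated) +
        (dplyr::coalesce(.data$allele2, .data$allele1) == .data$designated)
    ) |>
    dplyr::select("individual", "snp", "dosage") |>
    tidyr::pivot_wider(names_from = "snp", values_from = "dosage")
  m <- as.matrix(dos[-1])
  snps <- colnames(m)
  if (is.null(pairs)) {
    pairs <- tidyr::crossing(snp1 = snps, snp2 = snps) |>
      dplyr::filter(.data$snp1 <= .data$snp2)
  }
  purrr::pmap_dfr(pairs, function(snp1, snp2) {
    x <- m[, snp1]
    y <- m[, snp2]
    ok <- !is.na(x) & !is.na(y)
    r <- if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      NA_real_
    } else {
      stats::cor(x[ok], y[ok])
    }
    tibble::tibble(snp1 = snp1, snp2 = snp2, r = r, n = sum(ok))
  })
}
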