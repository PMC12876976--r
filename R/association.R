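#' Kruskal-Wallis test of unit frequencies across population systems
#'
#' Rank-based H statistic with tie correction and a chi-squared p-value
#' on k - 1 degrees of freedom (wraps [stats::kruskal.test()]). When
#' every value is identical the tie correction degenerates; H is reported
#' as 0 and p as 1.
#'
#' @param f Numeric vector of per-unit frequencies.
#' @param groups Population-system labels, one per unit.
#' @return Tibble (`H`, `df`, `p`).
#' @export
kw_test <- function(f, groups) {
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab == 0)) {
    stop("empty group(s): ", paste(names(tab)[tab == 0], collapse = ", "))
  }
  if (length(unique(f)) == 1) {
    return(tibble::tibble(H = 0, df = length(tab) - 1L, p = 1))
  }
  k <- stats::kruskal.test(f, groups)
  tibble::tibble(
    H = unname(k$statistic),
    df = unname(k$parameter),
    p = unname(k$p.value)
  )
}

#' Per-system median frequencies
#'
#' @param f Numeric vector of per-unit frequencies (NA skipped).
#' @param groups Population-system labels.
#' @return Tibble (`popsys`, `median_f`, `n`); empty groups get `NA`.
#' @export
popsys_medians <- function(f, groups) {
  tibble::tibble(popsys = as.character(groups), f = f) |>
    dplyr::summarise(
      median_f = stats::median(.data$f, na.rm = TRUE),
      n = sum(!is.na(.data$f)),
      .by = "popsys"
    )
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Weighted residual/total sums of squares about the weighted mean.
wls_ss <- function(y, fitted_y, w) {
  ybar <- sum(w * y) / sum(w)
  c(sse = sum(w * (y - fitted_y)^2), sst = sum(w * (y - ybar)^2))
}

#' Weighted-least-squares logistic regression of grouped frequencies
#'
#' Fits the empirical-logit regression for grouped proportions: the
#' response is `logit(f)` per population unit (frequencies clamped to
#' `[f_floor, 1 - f_floor]`), the weights are the Berkson minimum-logit
#' chi-square weights `n * f * (1 - f)` with `n` the allele count per
#' unit (option `weights = "n"` uses plain counts). Reports the overall
#' ANOVA F test, per-predictor type III sums-of-squares F tests (full
#' model vs. the model with that predictor dropped, identical weights,
#' hence invariant to factor coding), R-squared and adjusted R-squared on
#' the weighted scale (percent), and a goodness-of-fit chi-squared that
#' bins the fitted logits into equal-count classes and compares observed
#' and fitted allele counts per class.
#'
#' @param data Tibble with one row per population unit: the response
#'   frequency, the unit allele count, and the predictor columns.
#' @param f,n Column names (strings) of the frequency and count columns.
#' @param predictors Character vector of predictor column names
#'   (categorical columns are dummy-coded by the model matrix).
#' @param f_floor Clamp for frequencies at 0 or 1.
#' @param weights `"berkson"` (default) or `"n"`.
#' @param gof_classes Number of equal-count classes for the
#'   goodness-of-fit test.
#' @return Object of class `wls_logit`: coefficient table, `anova_F`,
#'   `anova_p`, `type3` tibble (`term`, `df`, `F`, `p`), `r2`, `r2_adj`
#'   (percent), `gof` (`chisq`, `df`, `p`), fitted values, and the call
#'   ingredients needed for refitting.
#' @export
wls_logistic <- function(data, f = "f", n = "n", predictors,
                         f_floor = 1e-10,
                         weights = c("berkson", "n"),
                         gof_classes = 5) {
  weights <- match.arg(weights)
  stopifnot(all(c(f, n, predictors) %in% names(data)))
  data <- tibble::as_tibble(data)
  data <- data[stats::complete.cases(data[c(f, n, predictors)]), ]
  fv <- pmin(pmax(data[[f]], f_floor), 1 - f_floor)
  nv <- data[[n]]
  y <- logit(fv)
  w <- if (weights == "berkson") nv * fv * (1 - fv) else nv

  fit_terms <- function(terms) {
    if (length(terms) == 0) {
      form <- stats::as.formula("y ~ 1")
    } else {
      form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    }
    df <- data
    df$y <- y
    stats::lm(form, data = df, weights = w)
  }

  full <- fit_terms(predictors)
  if (full$rank < ncol(stats::model.matrix(full))) {
    ali <- colnames(stats::model.matrix(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; aliased: ", paste(ali, collapse = ", "))
  }
  for (p_ in predictors) {
    if (is.character(data[[p_]]) || is.factor(data[[p_]])) {
      lev <- table(data[[p_]])
      if (any(lev == 1)) {
        warning(
          "level(s) of ", p_, " with a single unit: ",
          paste(names(lev)[lev == 1], collapse = ", ")
        )
      }
    }
  }

  n_obs <- length(y)
  p_full <- full$rank
  df_res <- n_obs - p_full
  ss <- wls_ss(y, stats::fitted(full), w)
  mse <- ss[["sse"]] / df_res

  # Overall ANOVA F (model vs intercept-only).
  df_model <- p_full - 1
  if (df_model > 0) {
    anova_F <- ((ss[["sst"]] - ss[["sse"]]) / df_model) / mse
    anova_p <- stats::pf(anova_F, df_model, df_res, lower.tail = FALSE)
  } else {
    anova_F <- NA_real_
    anova_p <- NA_real_
  }

  # Type III: drop each predictor wholesale from the full model.
  type3 <- tibble::tibble(
    term = character(0), df = integer(0), F = numeric(0), p = numeric(0)
  )
  if (length(predictors) > 0) type3 <- purrr::map_dfr(predictors, function(term) {
    red <- fit_terms(setdiff(predictors, term))
    sse_red <- wls_ss(y, stats::fitted(red), w)[["sse"]]
    ddf <- full$rank - red$rank
    Fv <- ((sse_red - ss[["sse"]]) / ddf) / mse
    tibble::tibble(
      term = term, df = ddf, F = Fv,
      p = stats::pf(Fv, ddf, df_res, lower.tail = FALSE)
    )
  })

  r2 <- 100 * (1 - ss[["sse"]] / ss[["sst"]])
  r2_adj <- 100 * (1 - (ss[["sse"]] / df_res) / (ss[["sst"]] / (n_obs - 1)))

  # GOF: equal-count classes of fitted logits; observed vs fitted allele
  # counts (successes and failures) per class.
  eta <- stats::fitted(full)
  phat <- inv_logit(eta)
  k <- min(gof_classes, n_obs)
  cls <- cut(rank(eta, ties.method = "first"),
             breaks = k, labels = FALSE)
  obs_s <- tapply(nv * fv, cls, sum)
  exp_s <- tapply(nv * phat, cls, sum)
  obs_f <- tapply(nv * (1 - fv), cls, sum)
  exp_f <- tapply(nv * (1 - phat), cls, sum)
  keep <- exp_s > 0 & exp_f > 0
  chisq <- sum((obs_s[keep] - exp_s[keep])^2 / exp_s[keep]) +
    sum((obs_f[keep] - exp_f[keep])^2 / exp_f[keep])
  gof_df <- max(k - p_full, 1)
  gof_p <- stats::pchisq(chisq, gof_df, lower.tail = FALSE)

  coefs <- summary(full)$coefficients
  structure(
    list(
      coefficients = tibble::tibble(
        term = rownames(coefs),
        estimate = coefs[, 1], std_error = coefs[, 2],
        statistic = coefs[, 3], p_value = coefs[, 4]
      ),
      anova_F = anova_F, anova_p = anova_p,
      df_model = df_model, df_residual = df_res,
      type3 = type3, r2 = r2, r2_adj = r2_adj,
      gof = tibble::tibble(chisq = chisq, df = gof_df, p = gof_p),
      fitted_logit = unname(eta), fitted_f = unname(phat),
      observed_f = unname(fv), n = unname(nv), weights_used = unname(w),
      predictors = predictors, weighting = weights,
      f_floor = f_floor, data = data, f_col = f, n_col = n,
      selected = FALSE
    ),
    class = "wls_logit"
  )
}

#' @export
print.wls_logit <- function(x, ...) {
  cat(
    "<wls_logit> predictors: ", paste(x$predictors, collapse = " + "),
    if (x$selected) " (stepwise-selected)" else "", "\n",
    "F(", x$df_model, ",", x$df_residual, ") = ", signif(x$anova_F, 4),
    ", p = ", signif(x$anova_p, 3),
    "; R2 = ", round(x$r2, 1), "%, R2_adj = ", round(x$r2_adj, 1), "%\n",
    sep = ""
  )
  invisible(x)
}

#' Forward stepwise selection for the WLS-logistic model
#'
#' Terms from `candidates` enter one at a time: at each step every
#' remaining candidate is tested by its type III F-test given the current
#' terms, and the one with the smallest p-value enters if p <= `alpha`
#' (ties broken by the fixed candidate order). The returned fit carries
#' `selected = TRUE`.
#'
#' @inheritParams wls_logistic
#' @param candidates Terms eligible for entry, in fixed order.
#' @param alpha Entry threshold on the type III p-value.
#' @return A `wls_logit` for the selected terms, or for the intercept
#'   with an empty `type3` table when nothing enters (`terms` element
#'   lists the selection).
#' @export
stepwise_wls <- function(data, f = "f", n = "n",
                         candidates = c("popsys", "lat", "lon"),
                         alpha = 0.05, f_floor = 1e-10,
                         weights = c("berkson", "n")) {
  weights <- match.arg(weights)
  current <- character(0)
  remaining <- candidates
  repeat {
    if (length(remaining) == 0) break
    trials <- purrr::map_dfr(remaining, function(term) {
      fit <- wls_logistic(
        data, f = f, n = n, predictors = c(current, term),
        f_floor = f_floor, weights = weights
      )
      row <- fit$type3[fit$type3$term == term, ]
      tibble::tibble(term = term, p = row$p)
    })
    trials <- trials[order(trials$p, match(trials$term, candidates)), ]
    if (nrow(trials) == 0 || is.na(trials$p[1]) || trials$p[1] > alpha) break
    current <- c(current, trials$term[1])
    remaining <- setdiff(remaining, current)
  }
  if (length(current) == 0) {
    fit <- wls_logistic(
      data, f = f, n = n, predictors = character(0),
      f_floor = f_floor, weights = weights
    )
    fit$significant <- FALSE
  } else {
    fit <- wls_logistic(
      data, f = f, n = n, predictors = current,
      f_floor = f_floor, weights = weights
    )
    fit$significant <- TRUE
  }
  fit$selected <- TRUE
  fit
}

#' Association screen of SNP frequencies with population systems
#'
#' Runs, for every SNP of one genotype class, the Kruskal-Wallis test
#' across systems, the full WLS-logistic model (`popsys + lat + lon`),
#' and forward stepwise selection; per-system medians are reported. A
#' Benjamini-Hochberg adjusted column for the Kruskal-Wallis p-values is
#' emitted alongside the raw values.
#'
#' @param freqs [allele_frequencies()] output restricted (or restrictable
#'   via `genotype_class`) to one genotype class; needs `snp`, `unit`,
#'   `popsys`, `lat`, `lon`, `f`, `n_alleles`.
#' @param genotype_class Genotype class to analyze (e.g. `"LR"`).
#' @param alpha Stepwise entry threshold.
#' @param weights Passed to [wls_logistic()].
#' @return Tibble with one row per SNP: medians per system (wide),
#'   `kw_H`, `kw_p`, `kw_p_bh`, model `F`, `p`, `r2`, `r2_adj`, `gof_p`,
#'   `selected_terms`, `popsys_selected`, and the per-term type III
#'   results nested in `type3`.
#' @export
associate_snps <- function(freqs, genotype_class = "LR", alpha = 0.05,
                           weights = c("berkson", "n")) {
  weights <- match.arg(weights)
  if ("genotype" %in% names(freqs)) {
    freqs <- dplyr::filter(freqs, .data$genotype == genotype_class)
  }
  if ("missing" %in% names(freqs)) {
    freqs <- dplyr::filter(freqs, !.data$missing)
  }
  out <- freqs |>
    dplyr::group_split(.data$snp) |>
    purrr::map_dfr(function(d) {
      med <- popsys_medians(d$f, d$popsys) |>
        tidyr::pivot_wider(
          id_cols = NULL, names_from = "popsys",
          values_from = "median_f", names_prefix = "median_"
        )
      kw <- kw_test(d$f, d$popsys)
      dd <- dplyr::rename(d, n = "n_alleles")
      full <- wls_logistic(dd, predictors = c("popsys", "lat", "lon"),
                           weights = weights)
      sel <- stepwise_wls(dd, alpha = alpha, weights = weights)
      dplyr::bind_cols(
        tibble::tibble(snp = d$snp[1]),
        med,
        tibble::tibble(
          kw_H = kw$H, kw_p = kw$p,
          F = full$anova_F, p = full$anova_p,
          r2 = full$r2, r2_adj = full$r2_adj,
          gof_p = full$gof$p,
          selected_terms = paste(sel$predictors, collapse = "+"),
          popsys_selected = "popsys" %in% sel$predictors,
          type3 = list(full$type3)
        )
      )
    })
  out$kw_p_bh <- stats::p.adjust(out$kw_p, method = "BH")
  out
}
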