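#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficient table of a WLS-logistic fit
#'
#' @param x A `wls_logit` object.
#' @param ... Unused.
#' @return Tibble (`term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`).
#' @method tidy wls_logit
#' @export
tidy.wls_logit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary of a WLS-logistic fit
#'
#' @param x A `wls_logit` object.
#' @param ... Unused.
#' @return Tibble (`F`, `p`, `r2`, `r2_adj`, `gof_chisq`, `gof_p`,
#'   `df_model`, `df_residual`, `selected`).
#' @method glance wls_logit
#' @export
glance.wls_logit <- function(x, ...) {
  tibble::tibble(
    F = x$anova_F, p = x$anova_p, r2 = x$r2, r2_adj = x$r2_adj,
    gof_chisq = x$gof$chisq, gof_p = x$gof$p,
    df_model = x$df_model, df_residual = x$df_residual,
    selected = x$selected
  )
}

#' Tidy the per-SNP and per-unit introgression rates
#'
#' @param x An `ir_summary` object.
#' @param ... Unused.
#' @return Long tibble of the non-summary cells (`snp`, `unit`, `f`,
#'   `expected`, `ir`).
#' @method tidy ir_summary
#' @export
tidy.ir_summary <- function(x, ...) {
  x$cells
}

#' One-row summary of introgression rates
#'
#' @param x An `ir_summary` object.
#' @param ... Unused.
#' @return Tibble (`ir_mean`, `ir_sd`, `ir_sd_n`, `n_cells`, `n_snps`,
#'   `n_units`).
#' @method glance ir_summary
#' @export
glance.ir_summary <- function(x, ...) {
  tibble::tibble(
    ir_mean = x$ir_mean, ir_sd = x$ir_sd, ir_sd_n = x$ir_sd_n,
    n_cells = x$n_cells, n_snps = nrow(x$ir_snp), n_units = nrow(x$ir_pop)
  )
}

#' Tidy the entry path of a stepwise discriminant analysis
#'
#' @param x A `stepwise_lda` object.
#' @param ... Unused.
#' @return Tibble (`variable`, `lambda`, `F_enter`) in entry order.
#' @method tidy stepwise_lda
#' @export
tidy.stepwise_lda <- function(x, ...) {
  x$steps
}

#' One-row summary of a stepwise discriminant analysis
#'
#' @param x A `stepwise_lda` object.
#' @param ... Unused.
#' @return Tibble (`n_selected`, `accuracy`, `cv_accuracy`, `n_classes`).
#' @method glance stepwise_lda
#' @export
glance.stepwise_lda <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    accuracy = x$accuracy,
    cv_accuracy = x$cv_accuracy,
    n_classes = length(x$classes)
  )
}
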