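#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of introgression cells
#'
#' Tiles of the per-SNP, per-unit introgressed-allele frequencies, the
#' visual counterpart of the introgression-rate table.
#'
#' @param object An `ir_summary` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ir_summary
#' @export
autoplot.ir_summary <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(
    cells,
    ggplot2::aes(x = .data$unit, y = .data$snp, fill = .data$ir)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = "IR") +
    ggplot2::labs(
      x = "population unit", y = "SNP",
      title = sprintf(
        "Introgression rates (mean %.3f +/- %.3f)",
        object$ir_mean, object$ir_sd
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Observed frequencies against fitted log-odds
#'
#' The diagnostic view of the grouped logistic fit: observed unit
#' frequencies plotted against the fitted logits, with the logistic
#' curve overlaid.
#'
#' @param object A `wls_logit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wls_logit
#' @export
autoplot.wls_logit <- function(object, ...) {
  d <- tibble::tibble(
    eta = object$fitted_logit,
    f = object$observed_f,
    n = object$n
  )
  curve <- tibble::tibble(
    eta = seq(min(d$eta) - 0.5, max(d$eta) + 0.5, length.out = 200)
  )
  curve$f <- 1 / (1 + exp(-curve$eta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eta, y = .data$f)) +
    ggplot2::geom_line(data = curve, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::labs(
      x = "fitted log-odds", y = "observed frequency",
      title = sprintf(
        "WLS logistic fit (R2 = %.1f%%, p = %.3g)",
        object$r2, object$anova_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Discriminant-score scatter of classified MLGs
#'
#' Cases on the first two linear discriminant axes, coloured by observed
#' class. With a single discriminant axis the second coordinate is a
#' jittered zero line.
#'
#' @param object A `stepwise_lda` object with at least one selected
#'   variable.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stepwise_lda
#' @export
autoplot.stepwise_lda <- function(object, ...) {
  if (is.null(object$fit)) stop("no variables were selected; nothing to plot")
  sc <- object$scores
  d <- tibble::tibble(
    LD1 = sc[, 1],
    LD2 = if (ncol(sc) >= 2) sc[, 2] else 0,
    class = object$labels
  )
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$LD1, y = .data$LD2, colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      title = sprintf(
        "Stepwise LDA (%d variables, %.1f%% correct)",
        length(object$selected), object$accuracy
      )
    ) +
    ggplot2::theme_minimal()
}
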