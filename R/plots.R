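#' Plot a binder-count fit
#'
#' Scatter of binder counts against structural content with the fitted
#' exponential or reciprocal curve overlaid.
#'
#' @param object A [fit_binder_model()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binder_fit
#' @export
autoplot.binder_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200)
  )
  grid$y <- predict(object, grid)
  lab <- if (object$model == "exponential") {
    sprintf("y == e^{%.2f + %.2f*x}", object$alpha, object$beta)
  } else {
    sprintf("y == frac(1, %.2f + %.2f*x)", object$alpha, object$beta)
  }
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "structural content", y = "protein binders",
      subtitle = parse(text = lab)[[1]]
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of an LFQ differential result
#'
#' Log-ratio against significance for one RNA condition, coloured by the
#' released / kept / static classification.
#'
#' @param diff An [lfq_differential()] result.
#' @param sig_neglog_p Significance threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, sig_neglog_p = 1.3) {
  classed <- classify_release(diff, sig_neglog_p) |>
    dplyr::filter(.data$testable)
  ggplot2::ggplot(
    classed,
    ggplot2::aes(x = .data$log_ratio, y = .data$neglog_p, colour = .data$label)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_hline(yintercept = sig_neglog_p, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(released = "black", kept = "firebrick", static = "grey60")
    ) +
    ggplot2::labs(
      x = "log2(RNA / background)", y = "-log10 p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Intra- versus inter-molecular contact scores
#'
#' Scatter of the length-normalized RNA-protein contact score against the
#' intra-RNA score across complexes, annotated with the Pearson correlation.
#'
#' @param scores A [contact_scores()] result.
#' @return A ggplot object.
#' @export
plot_contact_trend <- function(scores) {
  r <- dataset_correlation(scores)
  ggplot2::ggplot(
    scores,
    ggplot2::aes(x = .data$internal_score, y = .data$external_score)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    ggplot2::labs(
      x = "internal contacts (intra-RNA, log2)",
      y = "external contacts (RNA-protein, log2)",
      subtitle = sprintf("Pearson r = %.2f", r)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve of an interaction score against release labels
#'
#' Plots the ROC curve of a per-protein score for separating a positive from
#' a negative protein set, annotated with the rank-sum AUC.
#'
#' @inheritParams roc_auc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, positives, negatives) {
  auc <- roc_auc(scores, positives, negatives)
  if (is.data.frame(scores)) scores <- setNames(scores$score, scores$protein_id)
  s <- c(scores[positives], scores[negatives])
  truth <- rep(c(TRUE, FALSE), c(length(positives), length(negatives)))
  ord <- order(s, decreasing = TRUE)
  pts <- tibble::tibble(
    tpr = c(0, cumsum(truth[ord]) / sum(truth)),
    fpr = c(0, cumsum(!truth[ord]) / sum(!truth))
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      subtitle = sprintf("AUC = %.3f", auc)
    ) +
    ggplot2::theme_minimal()
}
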