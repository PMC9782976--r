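#' ROC curve of an evaluation
#'
#' @param object An [cv_auc()] / [heldout_eval()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ekbn_eval
#' @export
autoplot.ekbn_eval <- function(object, ...) {
  pts <- roc_points(object$scores, object$labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                      object$auc, object$ci[[1]], object$ci[[2]])
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve coordinates
#'
#' @param scores,labels As in [roc_auc()].
#' @return A tibble of `(threshold, fpr, tpr)` points.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  ord <- order(-scores)
  tp <- cumsum(y[ord] == 1L)
  fp <- cumsum(y[ord] == 0L)
  tibble::tibble(
    threshold = c(Inf, scores[ord]),
    fpr = c(0, fp / sum(y == 0L)),
    tpr = c(0, tp / sum(y == 1L))
  )
}

#' Integrated-ranking plot with EKFs highlighted
#'
#' @param object An [integrate_rankings()] result.
#' @param cohort Optional cohort supplying the EKF flags.
#' @param top How many top features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ekbn_integrated
#' @export
autoplot.ekbn_integrated <- function(object, cohort = NULL, top = 20L, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::slice_min(.data$rank, n = top)
  d$ekf <- if (!is.null(cohort)) d$feature %in% cohort_ekfs(cohort) else FALSE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wrs,
                                  y = stats::reorder(.data$feature, -.data$rank),
                                  colour = .data$ekf)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(.data$feature, -.data$rank)),
                          linewidth = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "#d95f02"),
                                 name = "EKF") +
    ggplot2::labs(x = "Weighted ranking score (lower = more important)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Arc-strength heatmap
#'
#' @param object A [bootstrap_arc_strength()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ekbn_strength
#' @export
autoplot.ekbn_strength <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08519c",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to", y = "from", fill = "strength") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Trace of the incremental model-building run
#'
#' @param object An [hitl_bn_run()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ekbn_hitl
#' @export
autoplot.ekbn_hitl <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$incumbent_auc),
                       colour = "grey60", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$candidate_auc,
                                     colour = .data$accepted), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "#1b9e77"),
                                 name = "accepted") +
    ggplot2::labs(x = "EKF index in the integrated list",
                  y = "Cross-validated AUC") +
    ggplot2::theme_minimal()
}
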