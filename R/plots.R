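#' @importFrom rlang .data
NULL

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}

#' Plot a learning curve
#'
#' Mean accuracy at the selected (best) multiple per method, as a function
#' of the number of training trials per class.
#'
#' @param lc A tibble from [learning_curve()] (optionally with a `subject`
#'   column, in which case accuracies are averaged over subjects).
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(lc) {
  need_ggplot()
  best <- lc[lc$best, , drop = FALSE]
  if ("subject" %in% names(best)) {
    agg <- stats::aggregate(accuracy ~ method + n_train, data = best, FUN = mean)
  } else {
    agg <- as.data.frame(best[, c("method", "n_train", "accuracy")])
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$n_train, y = .data$accuracy,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training trials per class", y = "test accuracy",
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot per-trial classification scores
#'
#' Strip plot of the scalar classifier scores, separated by true class when
#' available and shaped by provenance — a direct view of how augmentation
#' populates the feature space.
#'
#' @param scores A tibble from [export_scores()].
#' @return A ggplot object.
#' @export
plot_scores <- function(scores) {
  need_ggplot()
  df <- as.data.frame(scores)
  df$class <- if (!is.null(df$label)) factor(df$label) else factor(df$predicted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$score,
                                        colour = .data$class))
  p <- if (!is.null(df$provenance)) {
    p + ggplot2::geom_jitter(ggplot2::aes(shape = .data$provenance),
                             width = 0.15, height = 0)
  } else {
    p + ggplot2::geom_jitter(width = 0.15, height = 0)
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(y = "classification score") +
    ggplot2::theme_minimal()
}
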