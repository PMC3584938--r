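#' Plot evaluation curves
#'
#' `autoplot()` draws the natural plot for a `gopred_curves` tibble:
#' precision-recall for threshold/top-N sweeps, ROC when `type = "roc"`,
#' and threshold profiles for weighted and semantic sweeps. When curves
#' from several methods are row-bound with a `method` column, one line per
#' method is drawn.
#'
#' @param object a `gopred_curves` tibble (from [threshold_curves()],
#'   [topn_curves()], [weighted_curves()] or [semantic_curves()]).
#' @param type `"pr"` (default), `"roc"`, or `"profile"` (metric vs
#'   threshold).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gopred_curves <- function(object, type = c("pr", "roc", "profile"),
                                   ...) {
  type <- match.arg(type)
  df <- as_tibble(object)
  aes_method <- if ("method" %in% names(df)) {
    ggplot2::aes(colour = .data$method)
  } else NULL
  if (type == "pr" && all(c("precision", "recall") %in% names(df))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$recall,
                                          y = .data$precision)) +
      ggplot2::labs(x = "Recall", y = "Precision")
  } else if (type == "pr" && all(c("w_precision", "w_recall") %in% names(df))) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$w_recall,
                                          y = .data$w_precision)) +
      ggplot2::labs(x = "Weighted recall", y = "Weighted precision")
  } else if (type == "roc") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                          y = .data$recall)) +
      ggplot2::labs(x = "False positive rate", y = "True positive rate")
  } else {
    key <- attr(object, "sweep") %||% "threshold"
    val <- intersect(c("similarity", "f1", "precision", "w_precision"),
                     names(df))[1]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[key]],
                                          y = .data[[val]])) +
      ggplot2::labs(x = key, y = val)
  }
  if (!is.null(aes_method)) {
    p <- p + ggplot2::geom_path(ggplot2::aes(colour = .data$method))
  } else {
    p <- p + ggplot2::geom_path()
  }
  p + ggplot2::theme_minimal()
}

#' Precision-recall plot for one or more prediction methods
#'
#' Convenience wrapper: row-binds named curve tibbles and draws them with
#' [autoplot.gopred_curves()].
#'
#' @param ... named `gopred_curves` tibbles (names become the legend).
#' @param type passed to `autoplot()`.
#' @return a ggplot object.
#' @export
plot_curves <- function(..., type = "pr") {
  curves <- list(...)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    stop("plot_curves() needs named arguments (one per method)",
         call. = FALSE)
  }
  df <- bind_rows(lapply(names(curves), function(nm) {
    mutate(as_tibble(curves[[nm]]), method = nm)
  }))
  attrs <- attributes(curves[[1]])
  out <- structure(df, class = c("gopred_curves", class(df)),
                   sweep = attrs$sweep)
  ggplot2::autoplot(out, type = type)
}
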