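#' Plot methods for pipeline result objects
#'
#' `autoplot()` methods return ggplot objects: a stepped survival curve for
#' `km_curve`, the ROC curve for `roc_result`, the CV-accuracy profile for
#' `rfe_result`, the null-accuracy histogram with the observed value for
#' `perm_null`, and the p-value landscape over candidate cutoffs for
#' `cutoff_scan` (significant cutoffs, p < 0.05, drawn in black; the optimal
#' cutoff marked).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name autoplot-tamsig
NULL

#' @rdname autoplot-tamsig
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- as.data.frame(object)
  grouped <- "group" %in% names(df)
  pad <- function(d) {           # anchor each curve at S(0) = 1
    dplyr::bind_rows(
      dplyr::slice(dplyr::mutate(d, time = 0, survival = 1), 1), d)
  }
  df <- if (grouped) {
    dplyr::bind_rows(lapply(split(df, df$group), pad))
  } else {
    pad(df)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival))
  p <- if (grouped) {
    p + ggplot2::geom_step(ggplot2::aes(color = .data$group))
  } else {
    p + ggplot2::geom_step()
  }
  p + ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  color = NULL)
}

#' @rdname autoplot-tamsig
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' @rdname autoplot-tamsig
#' @export
autoplot.rfe_result <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$size, y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimal_size,
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "Feature-subset size", y = "Mean CV accuracy")
}

#' @rdname autoplot-tamsig
#' @export
autoplot.perm_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(x = "Null mean CV accuracy", y = "Rounds",
                  subtitle = sprintf("observed = %.3f, p = %.4g",
                                     object$observed, object$p_value))
}

#' @rdname autoplot-tamsig
#' @export
autoplot.cutoff_scan <- function(object, ...) {
  df <- object$candidates
  df$significant <- !is.na(df$p) & df$p < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(color = .data$significant)) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "grey70"),
                                guide = "none") +
    ggplot2::geom_vline(xintercept = object$optimal_cutoff,
                        linetype = "dashed", color = "red") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dotted") +
    ggplot2::labs(x = "Candidate cutoff", y = expression(-log[10](p)))
}
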