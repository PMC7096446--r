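# S3 methods for fitted objects: print, tidy, glance, augment, autoplot.

#' @export
print.rout_fit <- function(x, ...) {
  cat("Robust charge-balance fit (ROUT-style outlier detection)\n")
  cat(sprintf("  points: %d (%d inliers, %d outliers)\n",
              x$n, x$n_inlier, x$n - x$n_inlier))
  cat(sprintf("  inlier OLS: slope = %.4f, intercept = %.2f\n",
              x$slope, x$intercept))
  cat(sprintf("  charge ratio (1/slope) = %.3f\n", x$charge_ratio))
  cat(sprintf("  RSDR = %.3f\n", x$rsdr))
  cat(sprintf("  Pearson r (inliers) = %.4f, p = %.3g\n",
              x$pearson_r, x$p_value))
  invisible(x)
}

#' Tidy a robust charge-balance fit
#'
#' @param x A `rout_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `robust_estimate`).
#' @method tidy rout_fit
#' @export
tidy.rout_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope),
                 robust_estimate = c(x$robust_intercept, x$robust_slope))
}

#' One-row summary of a robust charge-balance fit
#'
#' @inheritParams tidy.rout_fit
#' @return One-row tibble: `slope`, `intercept`, `charge_ratio`, `rsdr`,
#'   `pearson_r`, `p_value`, `n`, `n_inlier`, `n_outlier`.
#' @method glance rout_fit
#' @export
glance.rout_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 charge_ratio = x$charge_ratio, rsdr = x$rsdr,
                 pearson_r = x$pearson_r, p_value = x$p_value,
                 n = x$n, n_inlier = x$n_inlier,
                 n_outlier = x$n - x$n_inlier)
}

#' Per-point data of a robust charge-balance fit
#'
#' @inheritParams tidy.rout_fit
#' @return Tibble with `x`, `y`, `residual`, `t_ratio`, `p`, `outlier`.
#' @method augment rout_fit
#' @export
augment.rout_fit <- function(x, ...) x$points

#' Scatter plot of a charge-balance fit
#'
#' Capsid charge against genome charge with the inlier fit line; outliers
#' are marked.
#'
#' @param object A `rout_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rout_fit
#' @export
autoplot.rout_fit <- function(object, ...) {
  d <- object$points
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "firebrick"),
                                 name = "outlier") +
    ggplot2::labs(x = "genome charge magnitude (Q_genome)",
                  y = "total capsid charge (Total Q_max)") +
    ggplot2::theme_minimal()
}

#' Charge profile plot of one protein
#'
#' Net charge of every fixed-frame window along the protein, with the
#' maximal window highlighted.
#'
#' @param sequence Amino-acid string.
#' @param frame Window length (default 30).
#' @return A ggplot object.
#' @export
plot_charge_profile <- function(sequence, frame = 30L) {
  w <- scan_fixed(sequence, frame)
  best <- max_fixed_window(sequence, frame)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$start, y = .data$q)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::annotate("point", x = best$start, y = best$q,
                      colour = "firebrick", size = 2) +
    ggplot2::labs(x = "window start (residue)",
                  y = sprintf("net charge (frame %d)", frame)) +
    ggplot2::theme_minimal()
}

#' Heatmap of positional charge-window frequencies
#'
#' @param heatmap_tbl Output of [positional_heatmap()].
#' @param by Name of the grouping column (default `"family"`).
#' @return A ggplot object.
#' @export
plot_positional_heatmap <- function(heatmap_tbl, by = "family") {
  ggplot2::ggplot(heatmap_tbl,
                  ggplot2::aes(x = .data$bin / 100,
                               y = .data[[by]],
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "frequency") +
    ggplot2::labs(x = "normalized position", y = NULL) +
    ggplot2::theme_minimal()
}
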