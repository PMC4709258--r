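# Plot methods for the main result types.

#' Plot an empirical CDF with its bootstrap bands
#'
#' @param object A [ecdf_with_bands()] result.
#' @param fit Optional [fit_nb()] result; its CDF is overlaid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clonedyn_ecdf <- function(object, fit = NULL, ...) {
  p <- ggplot(object, aes(x = .data$size, y = .data$ecdf)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "grey70", alpha = 0.5) +
    geom_step(linewidth = 0.7) +
    labs(x = "clone size (surface cells)",
         y = "cumulative probability") +
    theme_minimal()
  if (!is.null(fit)) {
    grid <- 0:max(object$size)
    curve <- tibble(size = grid, cdf = pnb_rq(grid, fit$r, fit$q, fit$mu))
    p <- p + geom_line(data = curve, aes(y = .data$cdf),
                       color = "steelblue", linewidth = 0.8)
  }
  p
}

#' Plot a fitted negative binomial against the data
#'
#' Empirical CDF of the sizes with the fitted negative binomial CDF
#' overlaid.
#'
#' @param object An [fit_nb()] result.
#' @param sizes The sizes that were fitted.
#' @param ... Passed to [ecdf_with_bands()].
#' @return A ggplot.
#' @export
autoplot.nbfit <- function(object, sizes, ...) {
  autoplot(ecdf_with_bands(sizes, ...), fit = object)
}

#' Plot a merging-factor calibration sweep
#'
#' @param sweep A [merging_sweep()] result.
#' @param reference Optional horizontal reference value (e.g. an observed
#'   compound size) drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_merging_sweep <- function(sweep, reference = NULL) {
  p <- ggplot(sweep, aes(x = .data$p_color, y = .data$estimate)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high),
                fill = "grey70", alpha = 0.5) +
    geom_line() +
    geom_point() +
    labs(x = "per-color labeling probability",
         y = "merging factor (progenitors per compound)") +
    theme_minimal()
  if (!is.null(reference)) {
    p <- p + geom_hline(yintercept = reference, linetype = "dashed")
  }
  p
}

#' Histogram of clone surface fractions
#'
#' @param clones An [aggregate_clones()] table.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_clone_sizes <- function(clones, bins = 30) {
  ggplot(filter(clones, .data$total_sa_fraction > 0),
         aes(x = .data$total_sa_fraction)) +
    geom_histogram(bins = bins, fill = "grey40") +
    labs(x = "clone surface fraction", y = "clones") +
    theme_minimal()
}
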