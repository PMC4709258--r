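# Progenitor-number estimators: clonal (reciprocal mean surface fraction
# with corrections) and mosaic (corrected cluster count), with bootstrap
# confidence intervals.

#' Percentile-bootstrap confidence interval of a statistic
#'
#' @param x Numeric sample (non-empty).
#' @param statistic Function of a numeric vector returning one number
#'   (default [mean()]).
#' @param B Number of bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed Optional integer seed; the interval is deterministic given
#'   the seed.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `method`, `B`, `n`; the bootstrap replicates are attached as the
#'   `"resamples"` attribute so downstream transformations can propagate
#'   the uncertainty.
#' @examples
#' bootstrap_ci(rexp(50), B = 200, seed = 1)
#' @export
bootstrap_ci <- function(x, statistic = mean, B = 1000, level = 0.95,
                         seed = NULL) {
  if (length(x) == 0) abort("empty sample")
  assert_number(B, "B", lower = 100)
  boots <- with_seed_or_stream(seed, {
    idx <- matrix(sample.int(length(x), length(x) * B, replace = TRUE),
                  ncol = B)
    apply(idx, 2, function(i) statistic(x[i]))
  })
  alpha <- (1 - level) / 2
  ci <- quantile(boots, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble(
    estimate = statistic(x),
    conf.low = ci[1],
    conf.high = ci[2],
    level = level,
    method = "bootstrap",
    B = B,
    n = length(x)
  )
  attr(out, "resamples") <- boots
  out
}

#' Mean clone surface fraction
#'
#' Mean of the per-clone total surface fraction over surface-visible
#' monoclonal clones, with a percentile-bootstrap confidence interval. The
#' reciprocal of this mean, after corrections, counts the founding
#' progenitors. Clones with zero visible surface area carry no surface
#' measurement and are excluded; they are what the surface-contact
#' correction of [estimate_n_clonal()] accounts for.
#'
#' @param clones A clone table from [aggregate_clones()] (at least 2
#'   surface-visible clones).
#' @inheritParams bootstrap_ci
#' @return A one-row tibble as in [bootstrap_ci()], with bootstrap
#'   replicates attached.
#' @export
mean_clone_surface_fraction <- function(clones, B = 1000, level = 0.95,
                                        seed = NULL) {
  if (!("total_sa_fraction" %in% names(clones))) {
    abort("`clones` must come from aggregate_clones()")
  }
  x <- clones$total_sa_fraction[clones$total_sa_fraction > 0]
  if (length(x) < 2) abort("need at least 2 surface-visible clones")
  bootstrap_ci(x, statistic = mean, B = B, level = level, seed = seed)
}

#' Count progenitors from monoclonal surface fractions
#'
#' The number of progenitors contributing to the organ surface is the
#' reciprocal of the mean clone surface fraction, `1 / A_single`. Two
#' corrections scale it up to all founding progenitors: division by the
#' fraction of clones/fragments contacting the surface (invisible clones
#' are never measured) and by the monoclonality confidence of the
#' fragment-count filter (a minority of "clones" are really several,
#' inflating `A_single`):
#' `N = (1 / A_single) / f_surface / p_mono`.
#'
#' The confidence interval is propagated by applying the same
#' transformation to the bootstrap replicates of `A_single`; `f_surface`
#' and `p_mono` are held fixed by default. Optionally the surface-contact
#' fraction's own uncertainty is propagated by drawing it from a normal
#' distribution truncated to (0, 1].
#'
#' @param a_single The result of [mean_clone_surface_fraction()] (with
#'   bootstrap replicates attached), or a bare number for a point estimate.
#' @param f_surface Surface-contact fraction, in (0, 1].
#' @param p_mono Monoclonality confidence, in (0, 1].
#' @param f_surface_se Optional standard error of `f_surface`; when given,
#'   each bootstrap replicate draws its own truncated-normal `f_surface`.
#' @param seed Seed for the optional `f_surface` draws.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `method`, and the correction factors `a_single`, `f_surface`,
#'   `p_mono`.
#' @examples
#' estimate_n_clonal(0.0057, f_surface = 0.82, p_mono = 0.88)
#' @export
estimate_n_clonal <- function(a_single, f_surface = 0.82, p_mono = 0.88,
                              f_surface_se = NULL, seed = NULL) {
  assert_number(f_surface, "f_surface", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(p_mono, "p_mono", lower = 0, upper = 1, strict_lower = TRUE)
  transform <- function(a, fs) 1 / (a * fs * p_mono)
  if (is.numeric(a_single) && is.null(dim(a_single))) {
    assert_number(a_single, "a_single", lower = 0, upper = 1,
                  strict_lower = TRUE, strict_upper = TRUE)
    return(tibble(
      estimate = transform(a_single, f_surface),
      conf.low = NA_real_, conf.high = NA_real_, level = NA_real_,
      method = "point",
      a_single = a_single, f_surface = f_surface, p_mono = p_mono
    ))
  }
  boots <- attr(a_single, "resamples")
  if (is.null(boots)) {
    abort("`a_single` must carry bootstrap resamples or be a single number")
  }
  point <- a_single$estimate
  if (point <= 0) abort("a_single must be positive")
  fs_draws <- if (is.null(f_surface_se)) {
    f_surface
  } else {
    with_seed_or_stream(seed, rtruncnorm01(length(boots), f_surface, f_surface_se))
  }
  n_boot <- transform(boots, fs_draws)
  alpha <- (1 - a_single$level) / 2
  ci <- quantile(n_boot, probs = c(alpha, 1 - alpha), names = FALSE)
  tibble(
    estimate = transform(point, f_surface),
    conf.low = ci[1],
    conf.high = ci[2],
    level = a_single$level,
    method = "bootstrap",
    a_single = point,
    f_surface = f_surface,
    p_mono = p_mono
  )
}

# normal truncated to (0, 1], by rejection
rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw > 0 & draw <= 1
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Count progenitors from mosaic cluster counts
#'
#' Fragmentation multiplies the apparent cluster count of a labeled organ
#' by the fragments-per-clone rate `m_f`, while same-color merging divides
#' it by the merging factor `m_m`; the visible cluster count of one organ
#' is therefore `n_clusters = L * m_f / m_m * f_surface` with `L` the
#' number of labeled quantified progenitors. Inverting, and dividing by
#' the quantified chimerism to go from labeled to all progenitors,
#' `N = n_clusters * (m_m / m_f) / chimerism / f_surface`
#' per organ; organs are then averaged with a percentile bootstrap. When
#' `m_f` is close to `m_m` the two rates cancel and the normalised cluster
#' count itself estimates the progenitor number. All correction factors
#' are reported so alternative compositions are auditable.
#'
#' @param hearts A tibble with one row per mosaic organ, columns
#'   `n_clusters` and `chimerism_quantified` (e.g. from
#'   [simulate_mosaic_cohort()]).
#' @param m_f Fragments per clone.
#' @param m_m Merging factor (progenitors per same-color compound); `NULL`
#'   computes it with [merging_factor()] at `p_color` from `config`.
#' @param config A [study_config()] supplying defaults.
#' @param B,level,seed Bootstrap settings (the bootstrap resamples organs).
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`, `level`,
#'   `method`, and the factors `mean_clusters`, `mean_chimerism`, `m_f`,
#'   `m_m`, `f_surface`.
#' @export
estimate_n_mosaic <- function(hearts, config = study_config(),
                              m_f = config$frag_mean, m_m = config$merge_factor,
                              B = 1000, level = 0.95, seed = NULL) {
  need <- c("n_clusters", "chimerism_quantified")
  if (!all(need %in% names(hearts))) {
    abort("`hearts` must have columns n_clusters and chimerism_quantified")
  }
  if (nrow(hearts) == 0) abort("empty heart table")
  if (any(hearts$chimerism_quantified <= 0)) {
    abort("chimerism_quantified must be positive for every organ")
  }
  if (is.null(m_m)) {
    m_m <- merging_factor(rep(config$p_color, 3), n_replicates = 60,
                          seed = seed)$estimate
  }
  assert_number(m_f, "m_f", lower = 0, strict_lower = TRUE)
  assert_number(m_m, "m_m", lower = 0, strict_lower = TRUE)
  f_surface <- config$f_surface
  per_heart <- hearts$n_clusters * (m_m / m_f) /
    hearts$chimerism_quantified / f_surface
  ci <- bootstrap_ci(per_heart, statistic = mean, B = B, level = level,
                     seed = seed)
  tibble(
    estimate = ci$estimate,
    conf.low = ci$conf.low,
    conf.high = ci$conf.high,
    level = level,
    method = "bootstrap",
    mean_clusters = mean(hearts$n_clusters),
    mean_chimerism = mean(hearts$chimerism_quantified),
    m_f = m_f,
    m_m = m_m,
    f_surface = f_surface
  )
}

#' End-to-end clonal progenitor count
#'
#' Runs the full clonal pipeline: filter organs for monoclonality,
#' aggregate fragments into clones, average the clone surface fractions
#' and invert with corrections.
#'
#' @param fragments A clonal-mode fragment table.
#' @param config A [study_config()] supplying the filter threshold and the
#'   correction factors.
#' @param max_clones Optional cap on the number of clones analysed (taken
#'   in organ order, mimicking a fixed-size experimental cohort).
#' @param B,seed Bootstrap settings.
#' @return A one-row tibble as in [estimate_n_clonal()], plus `n_clones`.
#' @export
count_progenitors_clonal <- function(fragments, config = study_config(),
                                     max_clones = NULL, B = 1000,
                                     seed = NULL) {
  clones <- fragments |>
    monoclonal_filter(threshold = config$monoclonal_threshold) |>
    aggregate_clones() |>
    filter(.data$total_sa_fraction > 0)
  if (!is.null(max_clones)) clones <- head(clones, max_clones)
  a <- mean_clone_surface_fraction(clones, B = B, seed = seed)
  estimate_n_clonal(a, f_surface = config$f_surface,
                    p_mono = config$p_mono) |>
    mutate(n_clones = nrow(clones))
}
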