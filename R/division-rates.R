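# Division-rate estimators. Under growth dominated by symmetric divisions
# the mean number of cells per clone grows as e^(rate * dt), so the rate is
# the natural logarithm of the mean clone cell count divided by the elapsed
# time. The same logic applied to surface cell counts isolates the
# "horizontal" divisions parallel to the surface, because vertical cell
# movements in and out of the surface layer balance on average in a
# continuously expanding tissue.

#' Convert clone volume to cell count
#'
#' @param volume_um3 Clone (or fragment) volume in cubic micrometers.
#' @param cell_volume_um3 Average volume of one cell (default 2,150 um^3).
#' @return Cell counts, rounded to the nearest integer.
#' @examples
#' cells_from_volume(1.2e6) # 558 cells
#' @export
cells_from_volume <- function(volume_um3, cell_volume_um3 = 2150) {
  assert_number(cell_volume_um3, "cell_volume_um3", lower = 0, strict_lower = TRUE)
  if (any(volume_um3 < 0, na.rm = TRUE)) abort("volumes must be non-negative")
  round(volume_um3 / cell_volume_um3)
}

rate_estimate <- function(mean_cells, delta_t, se_mean_cells, source) {
  assert_number(delta_t, "delta_t", lower = 0, strict_lower = TRUE)
  if (!is.numeric(mean_cells) || length(mean_cells) != 1 || mean_cells < 1) {
    abort("mean_cells must be a single number >= 1")
  }
  rate <- log(mean_cells) / delta_t
  se <- if (is.null(se_mean_cells)) NA_real_ else {
    # delta method on rate = log(m) / dt
    se_mean_cells / (mean_cells * delta_t)
  }
  tibble(
    rate = rate,
    se = se,
    delta_t = delta_t,
    mean_cells = mean_cells,
    source = source
  )
}

#' Overall division rate from mean clone cell count
#'
#' `rate = ln(mean_cells) / delta_t`, divisions per day (natural-log
#' convention: only the natural logarithm is consistent with a
#' per-division doubling read off on the same clock as the rate).
#'
#' @param mean_cells Mean number of cells per clone (>= 1).
#' @param delta_t Days between induction and analysis (decimal embryonic
#'   days difference, e.g. E6.75 to E12.5 is 5.75).
#' @param se_mean_cells Optional standard error of the mean cell count;
#'   propagated to the rate by the delta method.
#' @return A one-row tibble: `rate`, `se`, `delta_t`, `mean_cells`,
#'   `source`.
#' @examples
#' overall_division_rate(558, 5.75) # about 1.1 divisions per day
#' @export
overall_division_rate <- function(mean_cells, delta_t, se_mean_cells = NULL) {
  rate_estimate(mean_cells, delta_t, se_mean_cells, source = "volume")
}

#' Horizontal division rate from mean surface cell count
#'
#' As [overall_division_rate()] but applied to surface-touching cells per
#' clone (surface areas are converted to counts by a per-cell surface
#' footprint before calling this), isolating the divisions parallel to the
#' surface layer.
#'
#' @param mean_surface_cells Mean surface cells per clone (>= 1).
#' @inheritParams overall_division_rate
#' @return A one-row tibble as in [overall_division_rate()] with
#'   `source = "surface"`.
#' @examples
#' horizontal_division_rate(56, 5.75) # about 0.7 per day
#' @export
horizontal_division_rate <- function(mean_surface_cells, delta_t,
                                     se_mean_cells = NULL) {
  rate_estimate(mean_surface_cells, delta_t, se_mean_cells,
                source = "surface")
}

#' Overall division rate from a whole-organ cell count
#'
#' Independent cross-check of the clone-volume rate: if `n_progenitors`
#' founders grow into an organ of `n_cells` cells in `delta_t` days, the
#' per-day division rate is `ln(n_cells / n_progenitors) / delta_t`. With
#' the default constants (447,000 cells at E13.5 from 250 progenitors) this
#' gives 1.11/day for an E6.75 start; note the elapsed time is ambiguous in
#' the source material (an E7.25 start, `delta_t = 6.25`, gives 1.2/day),
#' so the caller chooses `delta_t` explicitly.
#'
#' @param n_cells Whole-organ cell count at analysis.
#' @param n_progenitors Number of founding progenitors.
#' @param delta_t Days between specification and the count.
#' @return A one-row tibble as in [overall_division_rate()] with
#'   `source = "organ_count"`.
#' @examples
#' organ_division_rate(447000, 250, 6.75)
#' @export
organ_division_rate <- function(n_cells, n_progenitors, delta_t) {
  assert_number(n_cells, "n_cells", lower = 1)
  assert_number(n_progenitors, "n_progenitors", lower = 1)
  rate_estimate(n_cells / n_progenitors, delta_t, NULL,
                source = "organ_count")
}

#' Fraction of divisions that are horizontal
#'
#' @param h_rate Horizontal division rate (>= 0).
#' @param overall_rate Overall division rate (> 0).
#' @return `h_rate / overall_rate`.
#' @examples
#' horizontal_fraction(0.7, 1.1) # about 0.64
#' @export
horizontal_fraction <- function(h_rate, overall_rate) {
  assert_number(h_rate, "h_rate", lower = 0)
  assert_number(overall_rate, "overall_rate", lower = 0, strict_lower = TRUE)
  h_rate / overall_rate
}

#' Division rates of a clone table
#'
#' Convenience wrapper computing the overall rate (from clone volumes) and
#' the horizontal rate (from clone surface cell counts) of an aggregated
#' clone table.
#'
#' @param clones A table from [aggregate_clones()] with `total_volume_um3`.
#' @param config A [study_config()] (for the cell volume).
#' @param footprint Surface fraction occupied by one surface cell, used to
#'   convert `total_sa_fraction` to surface cell counts. Synthetic cohorts
#'   record theirs in `cohort$params$footprint`.
#' @return A tibble with one row per rate (`source` = "volume",
#'   "surface").
#' @export
clone_division_rates <- function(clones, config = study_config(),
                                 footprint = NULL) {
  dt <- clones$stage_analyzed[1] - clones$stage_induced[1]
  out <- list()
  vols <- clones$total_volume_um3
  if (any(!is.na(vols))) {
    cells <- cells_from_volume(vols[!is.na(vols)], config$cell_volume_um3)
    out$volume <- overall_division_rate(
      mean(cells), dt, se_mean_cells = sd(cells) / sqrt(length(cells))
    )
  }
  if (!is.null(footprint)) {
    surf <- round(clones$total_sa_fraction / footprint)
    surf <- surf[surf > 0]
    out$surface <- horizontal_division_rate(
      mean(surf), dt, se_mean_cells = sd(surf) / sqrt(length(surf))
    )
  }
  if (length(out) == 0) {
    abort("need clone volumes and/or a surface footprint")
  }
  purrr::list_rbind(out)
}
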