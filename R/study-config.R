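#' Calibrated study constants
#'
#' Bundles every calibrated scalar the estimators rely on. The defaults are
#' the values quantified for the embryonic mouse heart: clones fragment into
#' 2.6 pieces on average; 82% of labeled fragments contact the organ surface;
#' organs passing the fragment-count filter are monoclonal with 88%
#' confidence; one cardiac cell occupies 2,150 um^3; the E13.5 heart holds
#' about 447,000 cells; each quantified confetti color labels about 17% of
#' cells at high-dose (mosaic) induction.
#'
#' @param frag_mean Mean number of spatially separate fragments per clone
#'   (must be > 1; the fragment-count law is a zero-truncated Poisson with
#'   this mean).
#' @param f_surface Fraction of labeled fragments that contact the organ
#'   surface, in (0, 1].
#' @param p_mono Confidence that an organ passing the fragment-count filter
#'   is monoclonal, in (0, 1].
#' @param monoclonal_threshold Organs are kept when every labeled color has
#'   fewer than this many fragments (default 4, i.e. "fewer than four").
#' @param cell_volume_um3 Average volume of one cell, cubic micrometers.
#' @param n_cells_e13_5 Whole-organ cell count at E13.5 (used by the
#'   organ-count division-rate check).
#' @param p_color Per-color labeling probability of each quantified confetti
#'   color in mosaic mode.
#' @param p_gfp Labeling probability of the nuclear-GFP construct, which is
#'   simulated but excluded from quantified clusters (its recombination
#'   frequency is not quantified experimentally; 0.04 is a configurable
#'   placeholder).
#' @param induction_rate Mean clonal-mode induction events per organ per
#'   color. `NULL` (default) means: calibrate with
#'   [calibrate_induction_rate()] so that the fragment-count filter has
#'   exactly `p_mono` monoclonality confidence.
#' @param merge_factor Merging factor used by the mosaic estimator. `NULL`
#'   (default) means: compute it with [merging_factor()] at `p_color`.
#' @param seed Optional integer seed stored for convenience.
#'
#' @return A list of class `study_config`.
#' @examples
#' cfg <- study_config()
#' cfg$frag_mean
#' @export
study_config <- function(frag_mean = 2.6,
                         f_surface = 0.82,
                         p_mono = 0.88,
                         monoclonal_threshold = 4,
                         cell_volume_um3 = 2150,
                         n_cells_e13_5 = 447000,
                         p_color = 0.17,
                         p_gfp = 0.04,
                         induction_rate = NULL,
                         merge_factor = NULL,
                         seed = NULL) {
  assert_number(frag_mean, "frag_mean", lower = 1, strict_lower = TRUE)
  assert_number(f_surface, "f_surface", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(p_mono, "p_mono", lower = 0, upper = 1, strict_lower = TRUE)
  assert_number(monoclonal_threshold, "monoclonal_threshold", lower = 2)
  assert_number(cell_volume_um3, "cell_volume_um3", lower = 0, strict_lower = TRUE)
  assert_number(n_cells_e13_5, "n_cells_e13_5", lower = 1)
  assert_number(p_color, "p_color", lower = 0, upper = 1)
  assert_number(p_gfp, "p_gfp", lower = 0, upper = 1)
  if (3 * p_color + p_gfp > 1) {
    abort("color probabilities exceed 1: 3 * p_color + p_gfp must be <= 1")
  }
  if (!is.null(induction_rate)) {
    assert_number(induction_rate, "induction_rate", lower = 0, strict_lower = TRUE)
  }
  if (!is.null(merge_factor)) {
    assert_number(merge_factor, "merge_factor", lower = 1)
  }
  structure(
    list(
      frag_mean = frag_mean,
      f_surface = f_surface,
      p_mono = p_mono,
      monoclonal_threshold = monoclonal_threshold,
      cell_volume_um3 = cell_volume_um3,
      n_cells_e13_5 = n_cells_e13_5,
      p_color = p_color,
      p_gfp = p_gfp,
      induction_rate = induction_rate,
      merge_factor = merge_factor,
      seed = seed
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  fragments per clone (mean): %.3g\n", x$frag_mean))
  cat(sprintf("  surface-contact fraction:   %.3g\n", x$f_surface))
  cat(sprintf("  monoclonality confidence:   %.3g (filter: < %d fragments)\n",
              x$p_mono, as.integer(x$monoclonal_threshold)))
  cat(sprintf("  cell volume:                %.4g um^3\n", x$cell_volume_um3))
  cat(sprintf("  per-color label probability: %.3g (GFP %.3g, discarded)\n",
              x$p_color, x$p_gfp))
  cat(sprintf("  induction rate per color:   %s\n",
              if (is.null(x$induction_rate)) "calibrated on demand"
              else format(x$induction_rate)))
  cat(sprintf("  merge factor:               %s\n",
              if (is.null(x$merge_factor)) "computed on demand"
              else format(x$merge_factor)))
  invisible(x)
}

#' Read a study configuration from a YAML or JSON file
#'
#' The file holds a flat mapping whose keys are the arguments of
#' [study_config()]; missing keys fall back to the defaults, unknown keys are
#' an error.
#'
#' @param path Path to a `.yaml`/`.yml` (or JSON, a YAML subset) file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) abort("config file must contain a mapping of settings")
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  do.call(study_config, vals)
}

# Induction rate to use for a config: explicit value, or calibrated so the
# fragment-count filter has exactly `p_mono` monoclonality confidence.
config_induction_rate <- function(config) {
  config$induction_rate %||%
    calibrate_induction_rate(
      target = config$p_mono,
      frag_mean = config$frag_mean,
      threshold = config$monoclonal_threshold
    )
}
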