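# Shared vocabularies for the fragment-table schema.
CLONEDYN_COLORS <- c("CFP", "YFP", "RFP", "GFP", "unlabeled")
CLONEDYN_REGIONS <- c("OFT", "RV", "LV", "RA", "LA", "IFT", "unassigned")

fragment_required_cols <- c(
  "heart_id", "stage_induced", "stage_analyzed", "clone_id", "color",
  "sa_fraction", "touches_surface"
)

#' Read a fragment table
#'
#' Reads a delimited text table with one row per labeled fragment and
#' validates it against the fragment-record schema: `heart_id`,
#' `stage_induced` and `stage_analyzed` (decimal embryonic days), `clone_id`
#' (may be missing in mosaic mode), `color` (one of CFP/YFP/RFP/GFP/
#' unlabeled), `sa_fraction` (fraction of the total organ surface, in
#' \[0, 1\]), `touches_surface` (logical), and optionally `volume_um3` and
#' `region`. Raw surface areas are accepted as a `sa_um2` column only
#' together with `total_sa_um2`, and are converted to fractions on load.
#'
#' Invariants enforced row by row: `sa_fraction` in \[0, 1\];
#' `stage_analyzed > stage_induced`; `sa_fraction == 0` exactly when
#' `touches_surface` is `FALSE`. Unknown regions become `"unassigned"`
#' (region is not used by any estimator); unknown colors are an error.
#'
#' @param path Path to a CSV or TSV file with a header.
#' @param dialect `"auto"` (by file extension, default), `"csv"` or `"tsv"`.
#' @return A tibble with one validated row per fragment, in file order.
#' @seealso [write_fragment_table()], [aggregate_clones()]
#' @export
read_fragment_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_fragment_table(raw, context = path)
}

#' Write a fragment table
#'
#' @param fragments A validated fragment tibble.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `fragments`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  fragments <- validate_fragment_table(fragments, context = "fragments")
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) {
    readr::write_tsv(fragments, path, progress = FALSE)
  } else {
    readr::write_csv(fragments, path, progress = FALSE)
  }
  invisible(fragments)
}

# Validate (and normalize) a fragment table; errors name the first offending
# rows. Used both by the reader and before writing.
validate_fragment_table <- function(x, context = "fragment table") {
  x <- as_tibble(x)
  missing_cols <- setdiff(fragment_required_cols, names(x))
  if (all(c("sa_um2", "total_sa_um2") %in% names(x)) &&
      !("sa_fraction" %in% names(x))) {
    x$sa_fraction <- x$sa_um2 / x$total_sa_um2
    x$sa_um2 <- NULL
    x$total_sa_um2 <- NULL
    missing_cols <- setdiff(missing_cols, "sa_fraction")
  } else if ("sa_um2" %in% names(x) && !("sa_fraction" %in% names(x))) {
    abort(paste0(context, ": raw `sa_um2` areas require a `total_sa_um2` column"))
  }
  if (length(missing_cols) > 0) {
    abort(paste0(
      context, ": missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!("volume_um3" %in% names(x))) x$volume_um3 <- NA_real_
  if (!("region" %in% names(x))) x$region <- "unassigned"

  x <- mutate(
    x,
    heart_id = as.character(.data$heart_id),
    clone_id = as.character(.data$clone_id),
    color = as.character(.data$color),
    region = as.character(.data$region),
    stage_induced = as.numeric(.data$stage_induced),
    stage_analyzed = as.numeric(.data$stage_analyzed),
    sa_fraction = as.numeric(.data$sa_fraction),
    volume_um3 = as.numeric(.data$volume_um3),
    touches_surface = as.logical(.data$touches_surface)
  )
  x$region[!(x$region %in% CLONEDYN_REGIONS) | is.na(x$region)] <- "unassigned"

  fail <- function(bad, what) {
    rows <- which(bad)
    abort(sprintf(
      "%s: %s in row(s) %s", context, what,
      paste(head(rows, 5), collapse = ", ")
    ))
  }
  bad_color <- !(x$color %in% CLONEDYN_COLORS)
  if (any(bad_color)) fail(bad_color, "unknown color token")
  bad_sa <- is.na(x$sa_fraction) | x$sa_fraction < 0 | x$sa_fraction > 1
  if (any(bad_sa)) fail(bad_sa, "sa_fraction outside [0, 1]")
  bad_stage <- is.na(x$stage_induced) | is.na(x$stage_analyzed) |
    x$stage_analyzed <= x$stage_induced
  if (any(bad_stage)) fail(bad_stage, "stage_analyzed must exceed stage_induced")
  bad_touch <- is.na(x$touches_surface) |
    ((x$sa_fraction == 0) != (!x$touches_surface))
  if (any(bad_touch)) {
    fail(bad_touch, "sa_fraction must be 0 exactly when touches_surface is FALSE")
  }
  select(
    x, all_of(fragment_required_cols), "volume_um3", "region",
    any_of(setdiff(names(x), c(fragment_required_cols, "volume_um3", "region")))
  )
}

#' Aggregate fragments into clone records
#'
#' Groups a clonal-mode fragment table by `(heart_id, clone_id)` and sums
#' fragment counts, surface fractions and volumes exactly. In experimental
#' data `clone_id` is the identifier the analyst assigns to each labeled
#' color of a filtered (putatively monoclonal) organ; the synthetic
#' generator mimics this by labeling fragments with their observed
#' color-group, not their ground-truth progenitor.
#'
#' @param fragments A fragment tibble (see [read_fragment_table()]).
#' @return A tibble with one row per clone: `clone_id`, `heart_id`,
#'   `n_fragments`, `n_surface_fragments`, `total_sa_fraction`,
#'   `total_volume_um3`, `stage_induced`, `stage_analyzed`.
#' @examples
#' frags <- tibble::tibble(
#'   heart_id = "H1", stage_induced = 6.75, stage_analyzed = 12.5,
#'   clone_id = "H1_RFP", color = "RFP",
#'   sa_fraction = c(0.002, 0.003, 0.0007),
#'   touches_surface = TRUE
#' )
#' aggregate_clones(frags)
#' @export
aggregate_clones <- function(fragments) {
  fragments <- validate_fragment_table(fragments, context = "fragments")
  if (any(is.na(fragments$clone_id))) {
    abort("fragment lacking clone_id: clonal-mode aggregation needs every row assigned")
  }
  if (nrow(fragments) == 0) {
    return(tibble(
      clone_id = character(), heart_id = character(),
      n_fragments = integer(), n_surface_fragments = integer(),
      total_sa_fraction = numeric(), total_volume_um3 = numeric(),
      stage_induced = numeric(), stage_analyzed = numeric()
    ))
  }
  fragments |>
    group_by(.data$heart_id, .data$clone_id) |>
    summarise(
      n_fragments = dplyr::n(),
      n_surface_fragments = sum(.data$touches_surface),
      total_sa_fraction = sum(.data$sa_fraction),
      total_volume_um3 = if (all(is.na(.data$volume_um3))) NA_real_
                         else sum(.data$volume_um3, na.rm = TRUE),
      stage_induced = .data$stage_induced[1],
      stage_analyzed = .data$stage_analyzed[1],
      .groups = "drop"
    ) |>
    relocate("clone_id", "heart_id")
}

#' Sanity-check labeled organs
#'
#' Per-organ consistency report: the summed labeled surface fraction may not
#' exceed 1 (plus a tolerance), and in strict (clonal) mode an organ with
#' fragments in more than one color is flagged for inspection. Flags are
#' reported, never raised as errors.
#'
#' @param fragments A fragment tibble.
#' @param tolerance Allowed overshoot of the summed surface fraction.
#' @param strict If `TRUE`, flag organs with more than one labeled color.
#' @return A tibble with one row per organ: `heart_id`, `total_sa_fraction`,
#'   `n_colors`, `flag_sa_excess`, `flag_multicolor`, `ok`.
#' @export
validate_heart <- function(fragments, tolerance = 0.01, strict = FALSE) {
  fragments <- validate_fragment_table(fragments, context = "fragments")
  fragments |>
    group_by(.data$heart_id) |>
    summarise(
      total_sa_fraction = sum(.data$sa_fraction),
      n_colors = dplyr::n_distinct(.data$color),
      .groups = "drop"
    ) |>
    mutate(
      flag_sa_excess = .data$total_sa_fraction > 1 + .env$tolerance,
      flag_multicolor = .env$strict & .data$n_colors > 1,
      ok = !.data$flag_sa_excess & !.data$flag_multicolor
    )
}
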