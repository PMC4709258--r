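# Synthetic cohorts with the statistical structure the estimators assume.
#
# Clonal mode emulates low-dose induction: K ~ Poisson(mu) labeled
# progenitors per organ per color, each clone fragmenting into a
# zero-truncated-Poisson number of pieces (mean frag_mean), each fragment
# contacting the surface independently with probability f_surface, and each
# surface-visible clone drawing its surface cell count from the
# negative-binomial law of the surface birth-immigration model. Clone
# surface fractions are normalised so that the mean observed by the
# filtered estimator equals 1 / (N * f_surface * p_mono): the generator is
# the exact inverse of the clonal estimator. The normalisation uses the
# exact contamination constant of [expected_visible_clones()].
#
# Mosaic mode emulates high-dose induction: the N progenitors are the sites
# of a periodic triangular lattice field, independently colored; same-color
# neighbors merge into compounds; compound fragments resolve into visible
# patches such that the expected patch count is
# L * frag_mean / merging-factor, with L the number of labeled quantified
# progenitors -- the inverse of the mosaic estimator.

#' Specification of a synthetic cohort
#'
#' @param n_hearts Number of organs to simulate (>= 1).
#' @param n_progenitors Ground-truth number of founding progenitors `N`
#'   (default 250).
#' @param mode `"clonal"` (low-dose) or `"mosaic"` (high-dose).
#' @param config A [study_config()].
#' @param gwi A [gwi_params()] describing surface clone growth; its elapsed
#'   time is taken from the stage difference below.
#' @param stage_induced,stage_analyzed Embryonic stages in decimal days.
#' @param overall_rate Overall division rate (per day) used to draw total
#'   clone cell counts, hence clone volumes.
#' @param seed Optional integer seed; a fixed seed makes the cohort
#'   bit-identical across runs.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hearts, n_progenitors = 250,
                        mode = c("clonal", "mosaic"),
                        config = study_config(), gwi = gwi_params(),
                        stage_induced = 6.75, stage_analyzed = 12.5,
                        overall_rate = 1.1, seed = NULL) {
  mode <- match.arg(mode)
  assert_number(n_hearts, "n_hearts", lower = 1)
  assert_number(n_progenitors, "n_progenitors", lower = 1)
  stopifnot(inherits(config, "study_config"), inherits(gwi, "gwi_params"))
  if (stage_analyzed <= stage_induced) {
    abort("stage_analyzed must exceed stage_induced")
  }
  assert_number(overall_rate, "overall_rate", lower = 0, strict_lower = TRUE)
  structure(
    list(
      n_hearts = as.integer(n_hearts),
      n_progenitors = as.integer(n_progenitors),
      mode = mode, config = config, gwi = gwi,
      stage_induced = stage_induced, stage_analyzed = stage_analyzed,
      overall_rate = overall_rate, seed = seed
    ),
    class = "cohort_spec"
  )
}

#' Draw fragment counts per clone
#'
#' Zero-truncated Poisson draws whose mean equals `frag_mean` (every clone
#' has at least one fragment). As `frag_mean` approaches 1 the law
#' degenerates to the constant 1.
#'
#' @param n Number of draws.
#' @param frag_mean Mean fragments per clone (> 1).
#' @return An integer vector of counts >= 1.
#' @export
sample_fragment_count <- function(n, frag_mean = 2.6) {
  assert_number(frag_mean, "frag_mean", lower = 1, strict_lower = TRUE)
  lambda <- ztp_rate(frag_mean)
  # inverse-cdf conditioning on F >= 1
  u <- runif(n, min = dpois(0, lambda), max = 1)
  as.integer(qpois(u, lambda))
}

# zero-truncated negative binomial / geometric draws by inverse cdf
rztnbinom <- function(n, size, prob) {
  p0 <- dnbinom(0, size = size, prob = prob)
  u <- runif(n, min = p0, max = 1)
  as.integer(qnbinom(u, size = size, prob = prob))
}

ztnbinom_mean <- function(size, prob) {
  mu <- size * (1 - prob) / prob
  mu / (1 - dnbinom(0, size = size, prob = prob))
}

#' Simulate a clonal-mode cohort
#'
#' @param spec A [cohort_spec()] with `mode = "clonal"`.
#' @return A list of class `clonal_cohort`:
#'   * `fragments`: an observed fragment table (clone identities are the
#'     color-groups an analyst would assign, *not* the ground truth);
#'   * `ledger`: one row per ground-truth clone (`progenitor_id`, organ,
#'     color, fragment counts, true surface fraction, total cells, and
#'     whether its color is truly monoclonal);
#'   * `fragment_map`: fragment id -> ground-truth progenitor id;
#'   * `params`: the calibration actually used (induction rate `mu`,
#'     contamination constant `c_vis`, per-clone mean visible fraction
#'     `a_single_true`, surface footprint of one cell `footprint`).
#' @examples
#' cohort <- simulate_clonal_cohort(cohort_spec(50, seed = 1))
#' head(cohort$fragments)
#' @export
simulate_clonal_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$mode != "clonal") abort("spec$mode must be 'clonal'")
  cfg <- spec$config
  mu <- config_induction_rate(cfg)
  dt <- spec$stage_analyzed - spec$stage_induced
  if (spec$gwi$beta <= 0) abort("clonal cohorts need gwi beta > 0")
  r_nb <- spec$gwi$alpha / spec$gwi$beta
  q_nb <- exp(-spec$gwi$beta * dt)
  c_vis <- expected_visible_clones(
    mu, cfg$frag_mean, cfg$monoclonal_threshold, cfg$f_surface
  )
  a_single <- 1 / (spec$n_progenitors * cfg$f_surface * cfg$p_mono * c_vis)
  footprint <- a_single / ztnbinom_mean(r_nb, q_nb)
  q_cells <- exp(-spec$overall_rate * dt)

  with_seed_or_stream(spec$seed, {
    colors <- c("CFP", "YFP", "RFP", "GFP")
    grid <- tidyr::expand_grid(
      heart_id = sprintf("H%04d", seq_len(spec$n_hearts)),
      color = colors
    )
    grid$k <- rpois(nrow(grid), mu)
    clones <- grid[rep.int(seq_len(nrow(grid)), grid$k), c("heart_id", "color")]
    n_clones <- nrow(clones)
    if (n_clones == 0) {
      return(empty_clonal_cohort(spec, mu, c_vis, a_single, footprint))
    }
    clones <- clones |>
      group_by(.data$heart_id, .data$color) |>
      mutate(clone_index = dplyr::row_number(), k_color = dplyr::n()) |>
      ungroup() |>
      mutate(
        progenitor_id = sprintf("P%06d", dplyr::row_number()),
        n_fragments = sample_fragment_count(n_clones, cfg$frag_mean),
        n_surface_fragments = rbinom(n_clones, .data$n_fragments, cfg$f_surface),
        surface_cells = ifelse(
          .data$n_surface_fragments > 0,
          rztnbinom(n_clones, r_nb, q_nb), 0L
        ),
        sa_fraction = .data$surface_cells * footprint,
        cells_total = as.integer(
          qgeom_zt(runif(n_clones), q_cells)
        ),
        volume_um3 = .data$cells_total * cfg$cell_volume_um3,
        monoclonal = .data$k_color == 1L
      )

    # one row per fragment; the first n_surface_fragments of a clone touch
    rows <- rep.int(seq_len(n_clones), clones$n_fragments)
    frag <- tibble(
      clone_row = rows,
      frag_in_clone = sequence(clones$n_fragments)
    )
    frag$touches_surface <- frag$frag_in_clone <=
      clones$n_surface_fragments[frag$clone_row]
    # surface area split among touching fragments (flat Dirichlet)
    g <- rgamma(nrow(frag), shape = 1)
    g[!frag$touches_surface] <- 0
    tot <- rowsum_by(g, frag$clone_row, n_clones)
    sa_w <- ifelse(frag$touches_surface, g / tot[frag$clone_row], 0)
    # volume split among all fragments
    gv <- rgamma(nrow(frag), shape = 1)
    totv <- rowsum_by(gv, frag$clone_row, n_clones)
    vol_w <- gv / totv[frag$clone_row]

    fragments <- tibble(
      heart_id = clones$heart_id[frag$clone_row],
      stage_induced = spec$stage_induced,
      stage_analyzed = spec$stage_analyzed,
      clone_id = paste(clones$heart_id[frag$clone_row],
                       clones$color[frag$clone_row], sep = "_"),
      color = clones$color[frag$clone_row],
      sa_fraction = sa_w * clones$sa_fraction[frag$clone_row],
      touches_surface = frag$touches_surface,
      volume_um3 = vol_w * clones$volume_um3[frag$clone_row],
      region = sample(CLONEDYN_REGIONS[1:6], nrow(frag), replace = TRUE),
      fragment_id = sprintf("F%07d", seq_len(nrow(frag)))
    )
    fragment_map <- tibble(
      fragment_id = fragments$fragment_id,
      progenitor_id = clones$progenitor_id[frag$clone_row]
    )
    ledger <- clones |>
      select("progenitor_id", "heart_id", "color", "clone_index",
             "n_fragments", "n_surface_fragments", "surface_cells",
             "sa_fraction", "cells_total", "monoclonal")
    structure(
      list(
        fragments = fragments,
        ledger = ledger,
        fragment_map = fragment_map,
        params = list(
          mu = mu, c_vis = c_vis, a_single_true = a_single,
          footprint = footprint, r_nb = r_nb, q_nb = q_nb,
          n_progenitors = spec$n_progenitors
        )
      ),
      class = "clonal_cohort"
    )
  })
}

# zero-truncated geometric quantile: success prob q, support >= 1,
# mean 1/q. Used for total clone cell counts.
qgeom_zt <- function(u, q) {
  p0 <- dgeom(0, q)
  stats::qgeom(p0 + u * (1 - p0), q) # support shifts to >= 1
}

rowsum_by <- function(x, group, n_groups) {
  as.vector(rowsum(x, factor(group, levels = seq_len(n_groups))))
}

empty_clonal_cohort <- function(spec, mu, c_vis, a_single, footprint) {
  structure(
    list(
      fragments = tibble(
        heart_id = character(), stage_induced = numeric(),
        stage_analyzed = numeric(), clone_id = character(),
        color = character(), sa_fraction = numeric(),
        touches_surface = logical(), volume_um3 = numeric(),
        region = character(), fragment_id = character()
      ),
      ledger = tibble(
        progenitor_id = character(), heart_id = character(),
        color = character(), clone_index = integer(),
        n_fragments = integer(), n_surface_fragments = integer(),
        surface_cells = integer(), sa_fraction = numeric(),
        cells_total = integer(), monoclonal = logical()
      ),
      fragment_map = tibble(fragment_id = character(),
                            progenitor_id = character()),
      params = list(mu = mu, c_vis = c_vis, a_single_true = a_single,
                    footprint = footprint,
                    n_progenitors = spec$n_progenitors)
    ),
    class = "clonal_cohort"
  )
}

# near-square factorisation for the progenitor field lattice
field_dims <- function(n) {
  for (r in seq.int(floor(sqrt(n)), 1L)) {
    if (n %% r == 0) return(c(r, n %/% r))
  }
  c(1L, n)
}

#' Simulate one mosaic-labeled organ
#'
#' The `N` progenitors form a periodic triangular-lattice field and are
#' independently colored (three quantified colors at `p_color` each, GFP at
#' `p_gfp`, otherwise unlabeled). Same-color neighbors merge into
#' compounds; each progenitor fragments into a zero-truncated-Poisson
#' number of pieces; within a compound, each fragment beyond the first
#' resolves into a separate patch with a probability calibrated so that the
#' expected total patch count equals `L * frag_mean / m_cell`, where `L` is
#' the number of labeled quantified progenitors and `m_cell` the realised
#' cell-weighted compound size -- the fragmentation/merging balance of the
#' mosaic estimator. Each patch is visible from outside with probability
#' `f_surface`. GFP compounds are simulated but excluded from the
#' quantified cluster count.
#'
#' @param spec A [cohort_spec()] with `mode = "mosaic"`.
#' @param heart_id Identifier of the simulated organ.
#' @param dims Optional lattice dimensions; default a near-square periodic
#'   field of exactly `n_progenitors` sites. The lattice may not be smaller
#'   than the progenitor number.
#' @param seed Optional integer seed.
#' @return A list: `heart` (one-row tibble with `heart_id`, `mode`,
#'   `n_clusters`, `chimerism_quantified`, ...), `clusters` (one row per
#'   quantified compound), `ledger` (one row per progenitor site).
#' @export
simulate_mosaic_heart <- function(spec, heart_id = "M0001", dims = NULL,
                                  seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$mode != "mosaic") abort("spec$mode must be 'mosaic'")
  cfg <- spec$config
  n <- spec$n_progenitors
  if (is.null(dims)) dims <- field_dims(n)
  if (prod(dims) < n) abort("lattice smaller than the number of progenitors")
  with_seed_or_stream(seed, {
    coloring <- label_lattice(
      dims, c(CFP = cfg$p_color, YFP = cfg$p_color, RFP = cfg$p_color,
              GFP = cfg$p_gfp)
    )
    cl <- same_color_clusters(coloring)
    col_vec <- as.vector(coloring$color)
    member <- as.vector(cl$membership)
    frag_n <- integer(length(col_vec))
    labeled <- col_vec != 0L
    frag_n[labeled] <- sample_fragment_count(sum(labeled), cfg$frag_mean)

    quant <- cl$clusters |> filter(.data$color %in% 1:3)
    l_quant <- sum(quant$size)
    if (l_quant == 0) {
      n_clusters <- 0L
      quant <- mutate(quant, n_fragments = integer(), n_patches = integer(),
                      n_visible = integer())
    } else {
      site_quant <- labeled & col_vec %in% 1:3
      s_per_compound <- as.vector(
        rowsum(frag_n[site_quant],
               factor(member[site_quant], levels = quant$cluster))
      )
      m_cell <- sum(quant$size^2) / l_quant
      target <- l_quant * cfg$frag_mean / m_cell
      c_n <- nrow(quant)
      s_tot <- sum(s_per_compound)
      pi_split <- if (s_tot > c_n) {
        min(1, max(0, (target - c_n) / (s_tot - c_n)))
      } else 0
      n_patches <- 1L + rbinom(c_n, s_per_compound - 1L, pi_split)
      n_visible <- rbinom(c_n, n_patches, cfg$f_surface)
      quant <- mutate(quant, n_fragments = s_per_compound,
                      n_patches = n_patches, n_visible = n_visible)
      n_clusters <- sum(n_visible)
    }
    color_names <- c("CFP", "YFP", "RFP", "GFP")
    heart <- tibble(
      heart_id = heart_id,
      mode = "mosaic",
      n_progenitors_true = n,
      chimerism_quantified = sum(col_vec %in% 1:3) / n,
      chimerism_total = mean(col_vec != 0L),
      n_clusters = as.integer(n_clusters)
    )
    ledger <- tibble(
      heart_id = heart_id,
      progenitor_id = sprintf("%s_S%04d", heart_id, seq_along(col_vec)),
      color = ifelse(col_vec == 0L, "unlabeled", color_names[pmax(col_vec, 1L)]),
      compound = member,
      n_fragments = ifelse(labeled, frag_n, NA_integer_)
    )
    list(
      heart = heart,
      clusters = quant |>
        mutate(heart_id = heart_id, color = color_names[.data$color],
               .before = 1) |>
        rename(n_progenitors = "size"),
      ledger = ledger
    )
  })
}

#' Simulate a mosaic-mode cohort
#'
#' Repeats [simulate_mosaic_heart()] over `spec$n_hearts` organs.
#'
#' @inheritParams simulate_mosaic_heart
#' @return A list of class `mosaic_cohort` with bound `hearts`, `clusters`
#'   and `ledger` tibbles.
#' @export
simulate_mosaic_cohort <- function(spec, dims = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_or_stream(spec$seed, {
    sims <- purrr::map(seq_len(spec$n_hearts), function(i) {
      simulate_mosaic_heart(spec, heart_id = sprintf("M%04d", i), dims = dims)
    })
    structure(
      list(
        hearts = purrr::list_rbind(purrr::map(sims, "heart")),
        clusters = purrr::list_rbind(purrr::map(sims, "clusters")),
        ledger = purrr::list_rbind(purrr::map(sims, "ledger"))
      ),
      class = "mosaic_cohort"
    )
  })
}
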