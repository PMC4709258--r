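test_that("fragment counts follow a zero-truncated Poisson with the right mean", {
  lambda <- clonedyn:::ztp_rate(2.6)
  # the root reproduces the mean when summed term by term
  k <- 1:300
  series_mean <- sum(k * dpois(k, lambda)) / (1 - exp(-lambda))
  expect_equal(series_mean, 2.6, tolerance = 1e-9)

  set.seed(11)
  draws <- sample_fragment_count(1e5, 2.6)
  expect_true(all(draws >= 1))
  expect_lt(abs(mean(draws) - 2.6), 0.02)

  # near the lower limit the law degenerates to the constant 1
  expect_true(all(sample_fragment_count(2000, 1 + 1e-6) == 1))
  expect_error(sample_fragment_count(10, 1), "frag_mean")
})

test_that("clonal cohorts are reproducible and internally consistent", {
  spec <- cohort_spec(60, seed = 21)
  a <- simulate_clonal_cohort(spec)
  b <- simulate_clonal_cohort(spec)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$ledger, b$ledger)

  # every fragment maps to exactly one ground-truth progenitor
  expect_equal(nrow(a$fragment_map), nrow(a$fragments))
  expect_false(any(duplicated(a$fragment_map$fragment_id)))
  expect_true(all(a$fragment_map$progenitor_id %in% a$ledger$progenitor_id))

  # per-clone totals in the ledger equal the summed fragment table
  by_prog <- a$fragments |>
    dplyr::left_join(a$fragment_map, by = "fragment_id") |>
    dplyr::group_by(progenitor_id) |>
    dplyr::summarise(sa = sum(sa_fraction), n = dplyr::n(),
                     n_surf = sum(touches_surface))
  led <- a$ledger[match(by_prog$progenitor_id, a$ledger$progenitor_id), ]
  expect_equal(by_prog$sa, led$sa_fraction, tolerance = 1e-12)
  expect_equal(by_prog$n, led$n_fragments)
  expect_equal(by_prog$n_surf, led$n_surface_fragments)

  # the validated schema accepts generated tables unchanged
  expect_silent(clonedyn:::validate_fragment_table(a$fragments))

  # clone surface area is proportional to surface cell count by construction
  expect_equal(led$sa_fraction, led$surface_cells * a$params$footprint,
               tolerance = 1e-12)
})

test_that("the labeled-organ fraction matches the four-color Poisson closed form", {
  spec <- cohort_spec(4000, seed = 31)
  cohort <- simulate_clonal_cohort(spec)
  mu <- cohort$params$mu
  p_lab <- 1 - exp(-4 * mu)
  n_lab <- dplyr::n_distinct(cohort$ledger$heart_id)
  se <- sqrt(p_lab * (1 - p_lab) * 4000)
  expect_lt(abs(n_lab - 4000 * p_lab), 3 * se + 1)
})

test_that("filtered organs are truly monoclonal at the calibrated confidence", {
  cohort <- simulate_clonal_cohort(cohort_spec(6000, seed = 41))
  kept <- monoclonal_filter(cohort$fragments)
  truth <- cohort$ledger |>
    dplyr::semi_join(dplyr::distinct(kept, heart_id), by = "heart_id") |>
    dplyr::distinct(heart_id, color, monoclonal)
  p_emp <- mean(truth$monoclonal)
  se <- sqrt(0.88 * 0.12 / nrow(truth))
  expect_lt(abs(p_emp - 0.88), 3 * se)
})

test_that("mosaic organs obey the sparse and dense labeling limits", {
  # sparse: no merging, each labeled progenitor contributes ~frag_mean patches
  cfg <- study_config(p_color = 0.003, p_gfp = 0)
  sim <- simulate_mosaic_heart(
    cohort_spec(1, n_progenitors = 2500, mode = "mosaic", config = cfg),
    seed = 51
  )
  expect_true(all(sim$clusters$n_progenitors == 1))
  mean_patches <- sum(sim$clusters$n_patches) / nrow(sim$clusters)
  expect_lt(abs(mean_patches - 2.6), 3 * 1.4 / sqrt(nrow(sim$clusters)) + 0.05)

  # chimerism converges to 3 p_color + p_gfp on a large field
  sim2 <- simulate_mosaic_heart(
    cohort_spec(1, n_progenitors = 40000, mode = "mosaic"),
    seed = 52
  )
  expect_lt(abs(sim2$heart$chimerism_total - (3 * 0.17 + 0.04)), 0.01)
  expect_lt(abs(sim2$heart$chimerism_quantified - 0.51), 0.01)

  # GFP compounds are excluded from quantified clusters
  expect_false("GFP" %in% sim2$clusters$color)
})

test_that("mosaic cluster counts balance fragmentation against merging", {
  mc <- simulate_mosaic_cohort(cohort_spec(40, mode = "mosaic", seed = 61))
  m_m <- merging_factor(rep(0.17, 3), dims = c(10, 25), n_replicates = 300,
                        seed = 62)$estimate
  ratio <- mc$hearts$n_clusters /
    (250 * mc$hearts$chimerism_quantified * 0.82)
  se <- sd(ratio) / sqrt(nrow(mc$hearts))
  expect_lt(abs(mean(ratio) - 2.6 / m_m), 3 * se + 0.02)

  # reproducibility
  mc2 <- simulate_mosaic_cohort(cohort_spec(40, mode = "mosaic", seed = 61))
  expect_identical(mc$hearts, mc2$hearts)

  # a lattice smaller than the progenitor field is refused
  expect_error(
    simulate_mosaic_heart(cohort_spec(1, n_progenitors = 100, mode = "mosaic"),
                          dims = c(5, 5)),
    "smaller"
  )
})
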