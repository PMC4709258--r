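test_that("bootstrap intervals are deterministic, degenerate on constants, and near-nominal", {
  x <- rep(0.004, 30)
  ci <- bootstrap_ci(x, B = 200, seed = 1)
  expect_equal(ci$estimate, 0.004)
  expect_equal(ci$conf.low, 0.004)
  expect_equal(ci$conf.high, 0.004)

  y <- rexp(40)
  expect_identical(bootstrap_ci(y, B = 200, seed = 9),
                   bootstrap_ci(y, B = 200, seed = 9))
  expect_error(bootstrap_ci(numeric(0)), "empty")
  expect_error(bootstrap_ci(y, B = 50), "B")
})

test_that("percentile bootstrap covers the exponential mean near nominally", {
  set.seed(17)
  trials <- 400
  covered <- vapply(seq_len(trials), function(i) {
    x <- rexp(50)
    ci <- bootstrap_ci(x, B = 500)
    ci$conf.low <= 1 && 1 <= ci$conf.high
  }, logical(1))
  # percentile intervals on skewed small samples run slightly below nominal
  expect_gt(mean(covered), 0.91)
  expect_lt(mean(covered), 0.98)
})

test_that("bootstrap CI width agrees with the analytic SEM for normal data", {
  set.seed(23)
  clones <- tibble::tibble(total_sa_fraction = rnorm(500, 0.005, 0.001))
  est <- mean_clone_surface_fraction(clones, B = 2000, seed = 3)
  half <- (est$conf.high - est$conf.low) / 2
  analytic <- 1.96 * sd(clones$total_sa_fraction) / sqrt(500)
  expect_lt(abs(half - analytic) / analytic, 0.1)
})

test_that("mean clone surface fraction drops invisible clones and needs two observations", {
  clones <- tibble::tibble(total_sa_fraction = c(0.004, 0.004, 0))
  est <- mean_clone_surface_fraction(clones, B = 100, seed = 2)
  expect_equal(est$estimate, 0.004)
  expect_equal(est$n, 2)
  expect_error(
    mean_clone_surface_fraction(tibble::tibble(total_sa_fraction = 0.004)),
    "at least 2"
  )
})

test_that("the clonal estimator is the corrected reciprocal of the mean fraction", {
  expect_equal(estimate_n_clonal(0.004, 1, 1)$estimate, 250)
  expect_equal(estimate_n_clonal(0.01, 0.5, 1)$estimate, 200)
  est <- estimate_n_clonal(0.0057, 0.82, 0.88)
  expect_equal(est$estimate, 1 / (0.0057 * 0.82 * 0.88), tolerance = 1e-12)
  expect_equal(round(est$estimate), 243)

  # strictly decreasing in every input
  base <- estimate_n_clonal(0.0057, 0.82, 0.88)$estimate
  expect_lt(estimate_n_clonal(0.006, 0.82, 0.88)$estimate, base)
  expect_lt(estimate_n_clonal(0.0057, 0.9, 0.88)$estimate, base)
  expect_lt(estimate_n_clonal(0.0057, 0.82, 0.95)$estimate, base)
})

test_that("clonal CI propagates through the reciprocal transform", {
  set.seed(5)
  clones <- tibble::tibble(total_sa_fraction = rgamma(89, 2, 400))
  a <- mean_clone_surface_fraction(clones, B = 1000, seed = 7)
  n <- estimate_n_clonal(a, f_surface = 0.82, p_mono = 0.88)
  expect_lt(n$conf.low, n$estimate)
  expect_gt(n$conf.high, n$estimate)
  # endpoints are the transformed percentile endpoints of the mean
  expect_equal(n$conf.low, 1 / (a$conf.high * 0.82 * 0.88), tolerance = 0.02)
  expect_equal(n$conf.high, 1 / (a$conf.low * 0.82 * 0.88), tolerance = 0.02)
})

test_that("the mosaic estimator reduces to the cluster count under identity corrections", {
  hearts <- tibble::tibble(n_clusters = rep(100L, 5), chimerism_quantified = 1)
  cfg <- study_config(f_surface = 1)
  est <- estimate_n_mosaic(hearts, config = cfg, m_f = 2, m_m = 2,
                           B = 200, seed = 1)
  expect_equal(est$estimate, 100)
  expect_error(
    estimate_n_mosaic(
      tibble::tibble(n_clusters = 10L, chimerism_quantified = 0),
      config = cfg, m_f = 2, m_m = 2
    ),
    "positive"
  )
})

test_that("the clonal pipeline recovers the ground-truth progenitor number", {
  n_cover <- 0
  for (i in 1:20) {
    cohort <- simulate_clonal_cohort(cohort_spec(300, seed = 500 + i))
    est <- count_progenitors_clonal(cohort$fragments, max_clones = 89,
                                    B = 400, seed = 700 + i)
    expect_lt(abs(est$estimate - 250) / 250, 0.35)
    if (est$conf.low <= 250 && 250 <= est$conf.high) n_cover <- n_cover + 1
  }
  expect_gte(n_cover, 15)
})

test_that("the mosaic pipeline recovers the ground-truth progenitor number", {
  mc <- simulate_mosaic_cohort(cohort_spec(50, mode = "mosaic", seed = 77))
  est <- estimate_n_mosaic(mc$hearts, B = 500, seed = 78)
  expect_lt(abs(est$estimate - 250) / 250, 0.1)
})

test_that("clonal and mosaic estimates from one ground truth agree within their CIs", {
  cohort <- simulate_clonal_cohort(cohort_spec(400, seed = 91))
  clonal <- count_progenitors_clonal(cohort$fragments, B = 500, seed = 92)
  mc <- simulate_mosaic_cohort(cohort_spec(50, mode = "mosaic", seed = 93))
  mosaic <- estimate_n_mosaic(mc$hearts, B = 500, seed = 94)
  expect_lt(max(clonal$conf.low, mosaic$conf.low),
            min(clonal$conf.high, mosaic$conf.high))
})
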