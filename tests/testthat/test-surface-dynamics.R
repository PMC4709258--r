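test_that("with no immigration or exchange the process is a pure Yule process", {
  # starting from one cell, sizes are geometric with mean e^(beta t)
  beta <- 0.7
  t <- 2
  sizes <- simulate_gwi(gwi_params(alpha = 0, beta = beta, t = t, rho = 0),
                        n_clones = 4000, init_size = 1, seed = 1)
  expect_true(all(sizes >= 1))
  q <- exp(-beta * t)
  bins <- c(1:9, Inf)
  obs <- table(cut(sizes, breaks = c(0, bins)))
  probs <- diff(c(0, pgeom(bins - 1, q)))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = probs))
  expect_gt(chi$p.value, 0.001)
  expect_lt(abs(mean(sizes) - exp(beta * t)), 4 * sd(sizes) / sqrt(4000))
})

test_that("with no division the process is pure Poisson immigration", {
  sizes <- simulate_gwi(gwi_params(alpha = 2, beta = 0, t = 1.5, rho = 0),
                        n_clones = 4000, seed = 2)
  lambda <- 2 * 1.5
  expect_lt(abs(mean(sizes) - lambda), 4 * sqrt(lambda / 4000))
  expect_lt(abs(var(sizes) / mean(sizes) - 1), 0.15)
})

test_that("birth plus immigration from empty start is negative binomial", {
  params <- gwi_params(alpha = 1.4, beta = 0.7, t = 3, rho = 0)
  law <- gwi_nb_law(params)
  expect_equal(law$r, 2)
  expect_equal(law$q, exp(-2.1))
  sizes <- simulate_gwi(params, n_clones = 5000, seed = 3)
  known <- clonedyn:::new_nbfit(r = law$r, q = law$q,
                                mu = law$r * (1 - law$q) / law$q,
                                logLik = NA, converged = TRUE,
                                boundary = FALSE, n = 5000)
  gof <- gof_nb(sizes, fit = known, B = 99, refit = FALSE, seed = 4)
  expect_gt(gof$p.value, 0.01)
})

test_that("balanced vertical exchange preserves the immigration-birth mean trajectory", {
  params <- gwi_params(alpha = 0.7, beta = 0.7, t = 3, rho = 0.5)
  expect_equal(params$delta, params$rho)
  sizes <- simulate_gwi(params, n_clones = 5000, seed = 5)
  expected <- (0.7 / 0.7) * (exp(0.7 * 3) - 1)
  se <- sd(sizes) / sqrt(5000)
  expect_lt(abs(mean(sizes) - expected), 3.5 * se)
})

test_that("negative binomial fitting recovers known parameters and matches MASS", {
  set.seed(6)
  sizes <- rnbinom(1e4, size = 2, prob = 0.3)
  fit <- fit_nb(sizes)
  expect_true(fit$converged)
  expect_gt(fit$r, 1.8)
  expect_lt(fit$r, 2.2)
  expect_gt(fit$q, 0.28)
  expect_lt(fit$q, 0.32)

  ref <- MASS::fitdistr(sizes, "negative binomial")
  expect_equal(fit$r, unname(ref$estimate["size"]), tolerance = 0.01)
  expect_equal(fit$r * (1 - fit$q) / fit$q, unname(ref$estimate["mu"]),
               tolerance = 0.01)

  # r = 1 data are indistinguishable from geometric
  set.seed(7)
  geo <- rnbinom(1e4, size = 1, prob = 0.25)
  fit_geo <- fit_nb(geo)
  expect_gt(fit_geo$r, 0.9)
  expect_lt(fit_geo$r, 1.1)
})

test_that("fit_nb recovers the immigration/division ratio from simulated clones", {
  params <- gwi_params(alpha = 1.4, beta = 0.7, t = 3, rho = 0)
  sizes <- simulate_gwi(params, n_clones = 1e4, seed = 8)
  fit <- fit_nb(sizes)
  expect_lt(abs(fit$r - 2) / 2, 0.15)
})

test_that("underdispersed samples fall back to the Poisson boundary with a warning", {
  expect_warning(fit <- fit_nb(rep(5L, 50)), "Poisson boundary")
  expect_true(fit$boundary)
  expect_equal(fit$mu, 5)
  expect_error(fit_nb(1:10), "at least 20")
})

test_that("tidy and glance methods expose the fit", {
  set.seed(9)
  fit <- fit_nb(rnbinom(500, size = 2, mu = 10))
  td <- tidy(fit)
  expect_equal(td$term, c("r", "q"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 500)
})

test_that("the empirical CDF with bands is a proper CDF", {
  set.seed(10)
  sizes <- rnbinom(200, size = 2, mu = 8)
  ec <- ecdf_with_bands(sizes, B = 300, seed = 11)
  expect_true(all(diff(ec$ecdf) > 0)) # strictly increasing on unique sizes
  expect_true(all(ec$ecdf >= 0 & ec$ecdf <= 1))
  expect_true(all(ec$lower <= ec$ecdf & ec$ecdf <= ec$upper))
  expect_equal(ec$ecdf[nrow(ec)], 1)

  single <- ecdf_with_bands(rep(4L, 10), B = 100, seed = 12)
  expect_equal(nrow(single), 1)
  expect_equal(single$lower, single$upper)
})

test_that("one-sigma bands cover the true CDF at roughly the nominal rate", {
  q_true <- 0.25
  grid_pt <- 5 # interior point of the size distribution
  set.seed(13)
  hits <- vapply(1:150, function(i) {
    s <- rnbinom(80, size = 2, prob = q_true)
    ec <- ecdf_with_bands(s, B = 200)
    row <- ec[ec$size == max(ec$size[ec$size <= grid_pt]), ]
    truth <- pnbinom(row$size, size = 2, prob = q_true)
    row$lower <= truth && truth <= row$upper
  }, logical(1))
  expect_gt(mean(hits), 0.55)
  expect_lt(mean(hits), 0.82)
})

test_that("the goodness-of-fit p-value is calibrated under the null and rejects mixtures", {
  set.seed(14)
  pvals <- vapply(1:100, function(i) {
    s <- rnbinom(150, size = 2, mu = 10)
    gof_nb(s, B = 60)$p.value
  }, numeric(1))
  expect_lt(abs(mean(pvals) - 0.5), 0.1)

  set.seed(15)
  rejections <- vapply(1:5, function(i) {
    mix <- c(rnbinom(150, size = 5, mu = 3), rnbinom(150, size = 5, mu = 60))
    gof_nb(mix, B = 99)$p.value < 0.05
  }, logical(1))
  expect_gte(sum(rejections), 4)

  expect_error(gof_nb(rnbinom(10, size = 2, mu = 5)), "at least 20")
})

test_that("the bimodality test has size and power on mixture alternatives", {
  set.seed(16)
  # size: single negative binomial should rarely be called bimodal
  null_calls <- vapply(1:10, function(i) {
    s <- rnbinom(150, size = 2, mu = 12)
    bt <- bimodality_test(s, B = 19, n_restarts = 6)
    c(bt$p.value > 0.05, !bt$bimodal)
  }, logical(2))
  expect_gte(sum(null_calls[1, ]), 8)

  # power: a separated mixture is detected nearly always, by the BIC
  # verdict or by the bootstrap LRT (BIC is the more conservative of the
  # two on marginal draws)
  alt_calls <- vapply(1:10, function(i) {
    s <- c(rnbinom(50, size = 3, mu = 5), rnbinom(50, size = 3, mu = 50))
    bt <- bimodality_test(s, B = 39, n_restarts = 10)
    bt$bimodal || bt$p.value < 0.05
  }, logical(1))
  expect_gte(sum(alt_calls), 9)

  # internal consistency of the default decision rule
  s <- c(rnbinom(60, size = 3, mu = 5), rnbinom(60, size = 3, mu = 50))
  bt <- bimodality_test(s, B = 19, seed = 17)
  expect_identical(bt$bimodal, bt$bic2 < bt$bic1)
  expect_equal(nrow(tidy(bt)), 2)
})
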