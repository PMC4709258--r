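# Bimodality of the clone-size distribution: one- versus two-component
# negative binomial mixture. A second, more proliferative subpopulation of
# progenitors shows up as a heavy second mode that a single negative
# binomial cannot accommodate.

# Weighted NB maximum likelihood (responsibility-weighted M-step): the
# success parameter is profiled out with the weighted mean.
fit_nb_weighted <- function(x, w) {
  m <- sum(w * x) / sum(w)
  if (m == 0) return(list(r = Inf, q = NA_real_, mu = 0))
  nll <- function(log_r) {
    r <- exp(log_r)
    q <- r / (r + m)
    -sum(w * dnbinom(x, size = r, prob = q, log = TRUE))
  }
  opt <- optimize(nll, interval = c(log(1e-4), log(1e6)), tol = 1e-6)
  r <- exp(opt$minimum)
  list(r = r, q = r / (r + m), mu = m)
}

dnbinom_safe <- function(x, r, q, mu) {
  if (is.infinite(r)) dpois(x, mu, log = TRUE)
  else dnbinom(x, size = r, prob = q, log = TRUE)
}

logsumexp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

# One EM run from given responsibilities.
em_nb_mixture <- function(x, resp, max_iter = 200, tol = 1e-7) {
  ll_old <- -Inf
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- colMeans(resp)
    w <- pmax(w, 1e-8)
    w <- w / sum(w)
    comps <- lapply(1:2, function(j) fit_nb_weighted(x, resp[, j]))
    fit <- list(
      weight = w,
      r = vapply(comps, `[[`, numeric(1), "r"),
      q = vapply(comps, `[[`, numeric(1), "q"),
      mu = vapply(comps, `[[`, numeric(1), "mu")
    )
    lcomp <- vapply(1:2, function(j) {
      log(w[j]) + dnbinom_safe(x, fit$r[j], fit$q[j], fit$mu[j])
    }, numeric(length(x)))
    lse <- apply(lcomp, 1, logsumexp)
    ll <- sum(lse)
    resp <- exp(lcomp - lse)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(fit = fit, logLik = ll, converged = converged, iterations = it)
}

# Best of several EM starts: a size-split start plus random perturbations.
fit_nb_mixture <- function(x, n_restarts = 10, max_iter = 200, seed = NULL) {
  with_seed_or_stream(seed, {
    n <- length(x)
    starts <- vector("list", n_restarts)
    # split on log size (k-means-style single split)
    lx <- log(x + 1)
    cut <- mean(range(lx))
    hard <- cbind(lx <= cut, lx > cut) * 1
    if (all(hard[, 2] == 0) || all(hard[, 1] == 0)) {
      hard <- cbind(rep(0.5, n), rep(0.5, n))
    }
    starts[[1]] <- 0.9 * hard + 0.05
    for (i in seq_len(n_restarts - 1)) {
      p <- runif(n)
      starts[[i + 1]] <- cbind(p, 1 - p)
    }
    runs <- lapply(starts, function(s) em_nb_mixture(x, s, max_iter = max_iter))
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "logLik"))]]
    best
  })
}

#' Test the clone-size distribution for bimodality
#'
#' Compares a single negative binomial against a two-component negative
#' binomial mixture fitted by EM (ties between restarts broken by best
#' likelihood): a likelihood-ratio test calibrated by parametric bootstrap
#' under the single-component null (the classic mixture LRT has no chi-square
#' reference distribution), plus a BIC comparison. The default verdict is
#' `BIC2 < BIC1`.
#'
#' @param sizes Non-negative integer clone sizes (at least 30).
#' @param B Parametric-bootstrap replicates for the LRT p-value; `B = 0`
#'   skips the bootstrap (the BIC verdict needs none) and reports a
#'   degenerate `p.value` of 1.
#' @param n_restarts EM restarts for the observed fit (bootstrap refits use
#'   fewer).
#' @param seed Optional integer seed.
#' @return An object of class `bimodality_test`: list with `lrt`,
#'   `p.value`, `bic1`, `bic2`, `bimodal` (the BIC verdict), `fit1`
#'   (`nbfit`), `fit2` (mixture parameters), `em_converged`, `n`, `B`.
#' @examples
#' sizes <- c(rnbinom(60, mu = 5, size = 2), rnbinom(60, mu = 50, size = 2))
#' bimodality_test(sizes, B = 39, seed = 1)
#' @export
bimodality_test <- function(sizes, B = 100, n_restarts = 20, seed = NULL) {
  sizes <- check_sizes(sizes, min_n = 30)
  n <- length(sizes)
  with_seed_or_stream(seed, {
    fit1 <- suppressWarnings(fit_nb(sizes))
    ll1 <- fit1$logLik
    mix <- fit_nb_mixture(sizes, n_restarts = n_restarts)
    ll2 <- mix$logLik
    lrt <- 2 * max(0, ll2 - ll1)
    bic1 <- -2 * ll1 + 2 * log(n)
    bic2 <- -2 * ll2 + 5 * log(n)
    lrt_boot <- vapply(seq_len(B), function(b) {
      s <- rnb_rq(n, fit1$r, fit1$q, fit1$mu)
      f1 <- suppressWarnings(fit_nb(s))
      f2 <- fit_nb_mixture(s, n_restarts = 2, max_iter = 100)
      2 * max(0, f2$logLik - f1$logLik)
    }, numeric(1))
    structure(
      list(
        lrt = lrt,
        p.value = (1 + sum(lrt_boot >= lrt)) / (B + 1),
        bic1 = bic1,
        bic2 = bic2,
        bimodal = bic2 < bic1,
        fit1 = fit1,
        fit2 = mix$fit,
        em_converged = mix$converged,
        n = n,
        B = B
      ),
      class = "bimodality_test"
    )
  })
}

#' @export
print.bimodality_test <- function(x, ...) {
  cat("<bimodality_test>\n")
  cat(sprintf("  LRT = %.3f, parametric-bootstrap p = %.4f (B = %d)\n",
              x$lrt, x$p.value, x$B))
  cat(sprintf("  BIC (1 component) = %.1f, BIC (2 components) = %.1f\n",
              x$bic1, x$bic2))
  cat(sprintf("  verdict: %s\n",
              if (x$bimodal) "bimodal" else "consistent with one component"))
  if (!x$em_converged) cat("  note: EM did not converge\n")
  invisible(x)
}

#' @rdname bimodality_test
#' @param x An object returned by `bimodality_test()`.
#' @param ... Unused.
#' @export
tidy.bimodality_test <- function(x, ...) {
  tibble(
    component = 1:2,
    weight = x$fit2$weight,
    r = x$fit2$r,
    q = x$fit2$q,
    mean = x$fit2$mu
  )
}

#' @rdname bimodality_test
#' @export
glance.bimodality_test <- function(x, ...) {
  tibble(
    lrt = x$lrt, p.value = x$p.value, bic1 = x$bic1, bic2 = x$bic2,
    bimodal = x$bimodal, em_converged = x$em_converged, nobs = x$n
  )
}
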