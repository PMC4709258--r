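# Negative binomial clone-size fitting and goodness of fit.

#' Maximum-likelihood negative binomial fit
#'
#' Fits the clone-size law predicted by the surface birth-immigration
#' model, a negative binomial with pmf
#' `P(k) = choose(k + r - 1, k) q^r (1 - q)^k` on `k >= 0`, by maximum
#' likelihood. The success parameter is profiled out (`q(r) = r / (r + m)`
#' with `m` the sample mean solves the score equation for `q`), leaving a
#' one-dimensional optimisation in `log r`.
#'
#' When the sample variance does not exceed the mean there is no interior
#' optimum; the fit falls back to the Poisson boundary (`r = Inf`) with a
#' warning.
#'
#' @param sizes Non-negative integer clone sizes (at least 20).
#' @return An object of class `nbfit`: list with `r`, `q`, `mu` (mean),
#'   `logLik`, `converged`, `boundary`, `n`.
#' @examples
#' sizes <- rnbinom(500, size = 2, prob = 0.3)
#' fit <- fit_nb(sizes)
#' tidy(fit)
#' @export
fit_nb <- function(sizes) {
  sizes <- check_sizes(sizes, min_n = 20)
  m <- mean(sizes)
  if (m == 0) abort("all sizes are zero; nothing to fit")
  if (var(sizes) <= m) {
    warn("sample variance does not exceed the mean; falling back to a Poisson boundary fit")
    ll <- sum(dpois(sizes, m, log = TRUE))
    return(new_nbfit(r = Inf, q = NA_real_, mu = m, logLik = ll,
                     converged = TRUE, boundary = TRUE, n = length(sizes)))
  }
  nll <- function(log_r) {
    r <- exp(log_r)
    q <- r / (r + m)
    -sum(dnbinom(sizes, size = r, prob = q, log = TRUE))
  }
  opt <- optimize(nll, interval = c(log(1e-4), log(1e6)), tol = 1e-10)
  r <- exp(opt$minimum)
  converged <- opt$minimum < log(1e6) - 1e-3 # interior optimum
  new_nbfit(r = r, q = r / (r + m), mu = m, logLik = -opt$objective,
            converged = converged, boundary = !converged, n = length(sizes))
}

new_nbfit <- function(r, q, mu, logLik, converged, boundary, n) {
  structure(
    list(r = r, q = q, mu = mu, logLik = logLik, converged = converged,
         boundary = boundary, n = n),
    class = "nbfit"
  )
}

check_sizes <- function(sizes, min_n = 2) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) < min_n) {
    abort(sprintf("need at least %d observations, got %d", min_n, length(sizes)))
  }
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    abort("sizes must be non-negative integers")
  }
  as.integer(round(sizes))
}

#' @export
print.nbfit <- function(x, ...) {
  cat(sprintf(
    "<nbfit> r = %.4g, q = %.4g (mean %.4g), logLik = %.2f, n = %d%s\n",
    x$r, x$q, x$mu, x$logLik, x$n,
    if (x$boundary) " [Poisson boundary]" else ""
  ))
  invisible(x)
}

#' @rdname fit_nb
#' @param x,object An `nbfit` object.
#' @param ... Unused.
#' @export
tidy.nbfit <- function(x, ...) {
  tibble(term = c("r", "q"), estimate = c(x$r, x$q))
}

#' @rdname fit_nb
#' @export
glance.nbfit <- function(x, ...) {
  tibble(r = x$r, q = x$q, mean = x$mu, logLik = x$logLik,
         converged = x$converged, boundary = x$boundary, nobs = x$n)
}

#' Empirical CDF with bootstrap bands
#'
#' Empirical cumulative distribution of clone sizes with pointwise
#' one-sigma bootstrap bands (percentile method), the standard display of
#' cumulative clone-size data.
#'
#' @param sizes Non-negative integer clone sizes (at least 2).
#' @param B Number of bootstrap resamples.
#' @param level Band level; the default 0.6827 corresponds to one sigma.
#' @param seed Optional integer seed.
#' @return A tibble of class `clonedyn_ecdf`: `size`, `ecdf`, `lower`,
#'   `upper`, evaluated at every observed size.
#' @export
ecdf_with_bands <- function(sizes, B = 1000, level = 0.6827, seed = NULL) {
  sizes <- check_sizes(sizes, min_n = 2)
  grid <- sort(unique(sizes))
  n <- length(sizes)
  bands <- with_seed_or_stream(seed, {
    boots <- matrix(sample(sizes, n * B, replace = TRUE), nrow = n)
    # ECDF of each resample on the observed grid
    apply(boots, 2, function(b) ecdf(b)(grid))
  })
  if (length(grid) == 1) bands <- matrix(bands, nrow = 1)
  alpha <- (1 - level) / 2
  qs <- apply(bands, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  out <- tibble(
    size = grid,
    ecdf = ecdf(sizes)(grid),
    lower = qs[1, ],
    upper = qs[2, ]
  )
  class(out) <- c("clonedyn_ecdf", class(out))
  attr(out, "level") <- level
  attr(out, "n") <- n
  out
}

# Kolmogorov-Smirnov-type discrepancy between the ECDF of integer sizes and
# a reference CDF evaluated on 0..max(sizes).
ks_discrepancy <- function(sizes, cdf_fun) {
  grid <- 0:max(sizes)
  max(abs(ecdf(sizes)(grid) - cdf_fun(grid)))
}

#' Parametric-bootstrap goodness of fit for the negative binomial
#'
#' Measures the Kolmogorov-Smirnov-type discrepancy between the empirical
#' CDF of the sizes and the fitted negative binomial, and calibrates it by
#' parametric bootstrap: `B` samples are drawn from the fitted law, each is
#' refitted (so the statistic's null distribution accounts for estimation),
#' and the p-value is the usual `(1 + #{D_b >= D}) / (B + 1)`.
#'
#' @param sizes Non-negative integer clone sizes (at least 20).
#' @param fit An [fit_nb()] result; `NULL` fits `sizes` first.
#' @param B Number of parametric-bootstrap replicates.
#' @param refit Refit each bootstrap sample (default). `refit = FALSE`
#'   tests against the *fixed* law in `fit`, appropriate when the reference
#'   parameters are known rather than estimated.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `statistic`, `p.value`, `B`, `refit`.
#' @export
gof_nb <- function(sizes, fit = NULL, B = 200, refit = TRUE, seed = NULL) {
  sizes <- check_sizes(sizes, min_n = 20)
  if (is.null(fit)) fit <- fit_nb(sizes)
  stopifnot(inherits(fit, "nbfit"))
  if (!fit$converged) abort("fit did not converge; refusing goodness-of-fit test")
  n <- length(sizes)
  cdf0 <- function(k) pnb_rq(k, fit$r, fit$q, fit$mu)
  d_obs <- ks_discrepancy(sizes, cdf0)
  d_boot <- with_seed_or_stream(seed, {
    vapply(seq_len(B), function(b) {
      s <- rnb_rq(n, fit$r, fit$q, fit$mu)
      if (refit) {
        fb <- suppressWarnings(fit_nb(s))
        ks_discrepancy(s, function(k) pnb_rq(k, fb$r, fb$q, fb$mu))
      } else {
        ks_discrepancy(s, cdf0)
      }
    }, numeric(1))
  })
  tibble(
    statistic = d_obs,
    p.value = (1 + sum(d_boot >= d_obs)) / (B + 1),
    B = B,
    refit = refit
  )
}
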