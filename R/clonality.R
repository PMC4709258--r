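# Monoclonality: the fragment-count filter and its confidence under a
# Poisson-induction + clone-fragmentation model.
#
# A low induction dose labels K ~ Poisson(mu) progenitors per organ per
# color; each labeled progenitor fragments into F pieces with F drawn from a
# zero-truncated Poisson of mean `frag_mean`. An organ color showing S =
# F_1 + ... + F_K fragments with 1 <= S <= threshold - 1 is called
# (putatively) monoclonal; the confidence of that call is
# P(K = 1 | 1 <= S <= threshold - 1), computed by exact convolution. Because
# every clone contributes at least one fragment, only K <= threshold - 1
# terms can contribute, so the computation is finite and exact.

#' Rate of the zero-truncated Poisson fragment-count law
#'
#' Solves `lambda / (1 - exp(-lambda)) = frag_mean` for the underlying
#' Poisson rate, so that the zero-truncated law has mean `frag_mean`.
#'
#' @param frag_mean Target mean number of fragments per clone (> 1).
#' @return The Poisson rate `lambda`.
#' @export
ztp_rate <- function(frag_mean) {
  assert_number(frag_mean, "frag_mean", lower = 1, strict_lower = TRUE)
  uniroot(
    function(l) l / (-expm1(-l)) - frag_mean, # expm1 keeps the limit l -> 0 stable
    interval = c(1e-12, frag_mean + 10),
    tol = 1e-12
  )$root
}

#' Fragment-count probability mass function
#'
#' Zero-truncated Poisson pmf with mean `frag_mean`, evaluated on
#' `1:max_count`.
#'
#' @inheritParams ztp_rate
#' @param max_count Largest count to tabulate.
#' @return A numeric vector `p` with `p[k] = P(F = k)`.
#' @export
fragment_count_pmf <- function(frag_mean, max_count = 50) {
  lambda <- ztp_rate(frag_mean)
  k <- seq_len(max_count)
  dpois(k, lambda) / (1 - exp(-lambda))
}

# All fragment-count compositions compatible with passing the filter:
# integer vectors (f_1, ..., f_K), each part >= 1, sum <= s_max.
filter_compositions <- function(s_max) {
  out <- list()
  recurse <- function(prefix, remaining) {
    if (length(prefix) > 0) out[[length(out) + 1]] <<- prefix
    for (f in seq_len(remaining)) recurse(c(prefix, f), remaining - f)
  }
  recurse(integer(), s_max)
  out
}

resolve_fragment_pmf <- function(pmf, frag_mean, s_max) {
  if (is.null(pmf)) {
    pmf <- fragment_count_pmf(frag_mean, max_count = s_max)
  }
  if (any(pmf < 0) || sum(pmf) > 1 + 1e-9) {
    abort("fragment pmf must be non-negative and sum to at most 1")
  }
  # pad so pmf[f] is defined for every part of a composition
  c(pmf, rep(0, max(0, s_max - length(pmf))))
}

#' Monoclonality confidence of the fragment-count filter
#'
#' Probability that an organ color passing the filter (1 to `threshold - 1`
#' fragments) arose from a single induction event:
#' `P(K = 1 | 1 <= S <= threshold - 1)` with `K ~ Poisson(mu)` inductions
#' and `S` the total fragment count. Exact finite convolution; no
#' truncation error is incurred because compositions with more than
#' `threshold - 1` clones cannot pass.
#'
#' @param mu Mean induction events per organ per color (> 0).
#' @param frag_mean Mean fragments per clone (ignored when `pmf` is given).
#' @param threshold Filter threshold: organs with fewer than `threshold`
#'   fragments in a color pass.
#' @param pmf Optional explicit fragment-count pmf, a numeric vector with
#'   `pmf[k] = P(F = k)` on support `k >= 1`.
#' @return The confidence, a probability in (0, 1].
#' @examples
#' monoclonal_confidence(0.3, frag_mean = 2.6)
#' # point mass at 2 fragments: two inductions already exceed 3 fragments
#' monoclonal_confidence(0.3, pmf = c(0, 1))
#' @export
monoclonal_confidence <- function(mu, frag_mean = 2.6, threshold = 4,
                                  pmf = NULL) {
  assert_number(mu, "mu", lower = 0, strict_lower = TRUE)
  assert_number(threshold, "threshold", lower = 2)
  s_max <- as.integer(threshold) - 1L
  p <- resolve_fragment_pmf(pmf, frag_mean, s_max)
  # P(S_k <= s_max) for k clones, by truncated convolution
  pass_prob <- numeric(s_max)
  conv <- c(1, rep(0, s_max)) # distribution of S over 0..s_max
  for (k in seq_len(s_max)) {
    nxt <- numeric(s_max + 1)
    for (s in 0:s_max) {
      if (conv[s + 1] == 0) next
      f_max <- s_max - s
      if (f_max >= 1) {
        idx <- seq_len(f_max)
        nxt[s + 1 + idx] <- nxt[s + 1 + idx] + conv[s + 1] * p[idx]
      }
    }
    conv <- nxt
    pass_prob[k] <- sum(conv)
  }
  k <- seq_len(s_max)
  joint <- dpois(k, mu) * pass_prob
  joint[1] / sum(joint)
}

#' Calibrate the induction rate to a target monoclonality confidence
#'
#' Finds the induction rate `mu*` at which the fragment-count filter has
#' exactly the target confidence, by root finding on
#' [monoclonal_confidence()], which is monotone decreasing in `mu`.
#'
#' @param target Target confidence in (0, 1) (default 0.88, the calibrated
#'   study value).
#' @inheritParams monoclonal_confidence
#' @param interval Search bracket for `mu`.
#' @return The calibrated rate `mu*`, with
#'   `|monoclonal_confidence(mu*) - target| < 1e-6`.
#' @export
calibrate_induction_rate <- function(target = 0.88, frag_mean = 2.6,
                                     threshold = 4, pmf = NULL,
                                     interval = c(1e-9, 50)) {
  assert_number(target, "target", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  f <- function(mu) monoclonal_confidence(mu, frag_mean, threshold, pmf) - target
  lo <- f(interval[1])
  hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    abort("target confidence unattainable inside the search bracket")
  }
  uniroot(f, interval = interval, tol = 1e-12)$root
}

#' Expected number of surface-visible clones per passing organ color
#'
#' Among organ colors that pass the fragment-count filter *and* show at
#' least one surface-visible clone, the expected number of distinct clones
#' that contribute visible surface area. A clone with `f` fragments is
#' visible when at least one fragment contacts the surface, i.e. with
#' probability `1 - (1 - f_surface)^f`. This is the exact contamination
#' constant linking the mean surface fraction measured on filtered organs
#' to the per-clone mean: the synthetic generator uses it to make the
#' clonal estimator its exact inverse.
#'
#' @inheritParams monoclonal_confidence
#' @param f_surface Per-fragment probability of contacting the surface.
#' @return The expectation, a number >= 1.
#' @export
expected_visible_clones <- function(mu, frag_mean = 2.6, threshold = 4,
                                    f_surface = 0.82, pmf = NULL) {
  assert_number(mu, "mu", lower = 0, strict_lower = TRUE)
  assert_number(f_surface, "f_surface", lower = 0, upper = 1, strict_lower = TRUE)
  s_max <- as.integer(threshold) - 1L
  p <- resolve_fragment_pmf(pmf, frag_mean, s_max)
  num <- 0
  denom <- 0
  for (f in filter_compositions(s_max)) {
    w <- dpois(length(f), mu) * prod(p[f])
    vis <- 1 - (1 - f_surface)^f
    num <- num + w * sum(vis)
    denom <- denom + w * (1 - prod(1 - vis))
  }
  if (denom <= 0) abort("no composition is ever visible; check f_surface and pmf")
  num / denom
}

#' Filter organs for monoclonality by fragment count
#'
#' Keeps organs in which every labeled color has fewer than `threshold`
#' fragments. Each labeled color of a kept organ is treated as an
#' independent putative clone (colors recombine independently). Organs with
#' no fragments never appear in a fragment table and are therefore excluded
#' by construction.
#'
#' @param fragments A clonal-mode fragment tibble.
#' @param threshold Maximum-plus-one fragment count per color (default 4:
#'   "fewer than four fragments"). Must be at least 2.
#' @return The subset of `fragments` belonging to kept organs.
#' @export
monoclonal_filter <- function(fragments, threshold = 4) {
  assert_number(threshold, "threshold", lower = 2)
  fragments <- validate_fragment_table(fragments, context = "fragments")
  kept <- fragments |>
    dplyr::count(.data$heart_id, .data$color) |>
    group_by(.data$heart_id) |>
    summarise(keep = max(.data$n) < .env$threshold, .groups = "drop") |>
    filter(.data$keep)
  semi_join(fragments, kept, by = "heart_id")
}
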