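# clonedyn

Quantitative analysis of multicolor (confetti-style) lineage tracing for
counting the progenitors that found an organ and describing their clonal
dynamics. The package was built around the embryonic mouse heart — where a
few hundred progenitors specified at gastrulation build the myocardium —
but every estimator works on plain tables and calibrated constants, so the
machinery applies to any organ traced the same way.

Two complementary estimators give the progenitor number *N*:

- **Clonal (low dose).** Organs with fewer than four labeled fragments per
  color are monoclonal with known confidence `p_mono`. Surface-visible
  clones tile the organ surface, so the mean fraction of the surface
  covered by one clone, `A_single`, gives

  `N = (1 / A_single) / f_surface / p_mono`,

  correcting for clones that never contact the surface (`f_surface`) and
  for residual polyclonal contamination of the filter (`p_mono`).

- **Mosaic (high dose).** With >50% chimerism, the visible cluster count
  per organ reflects two opposing processes: fragmentation multiplies it
  by `m_f` (fragments per clone) and same-color neighbor co-labeling
  divides it by the merging factor `m_m`, quantified by Monte Carlo
  labeling of a triangular lattice. Then

  `N = n_clusters * (m_m / m_f) / chimerism / f_surface`.

A Galton–Watson-with-immigration model describes clone sizes on the organ
surface (negative binomial with `r = alpha/beta`, `q = exp(-beta t)`),
with maximum-likelihood fitting, bootstrap ECDF bands, parametric-bootstrap
goodness of fit and a mixture-based bimodality test; division rates follow
from `ln(mean cells) / Δt`. A synthetic cohort generator reproduces the
statistical structure the estimators assume, so the whole pipeline is
testable end to end without animal data.

## Worked example

```r
library(clonedyn)

# a synthetic low-dose cohort with ground truth N = 250
cohort <- simulate_clonal_cohort(cohort_spec(n_hearts = 300, seed = 42))

count_progenitors_clonal(cohort$fragments, B = 1000, seed = 7)
#> # A tibble: 1 × 9
#>   estimate conf.low conf.high level method    a_single f_surface p_mono n_clones
#>      <dbl>    <dbl>     <dbl> <dbl> <chr>        <dbl>     <dbl>  <dbl>    <int>
#> 1     255.     214.      308.  0.95 bootstrap  0.00544      0.82   0.88      110
```

The cohort's 300 organs yield 110 putatively monoclonal clones; their mean
surface fraction (0.544%) inverts, after the surface-contact and
monoclonality corrections, to an estimate of 255 founding progenitors with
a 95% bootstrap CI of [214, 308] — covering the ground truth of 250.

With the study's own quantified inputs (mean clone fraction 0.57%,
surface contact 82%, filter confidence 88%):

```r
estimate_n_clonal(0.0057, f_surface = 0.82, p_mono = 0.88)$estimate
#> [1] 243.1244
```

The independent mosaic route, on 50 simulated high-dose organs:

```r
mosaic <- simulate_mosaic_cohort(cohort_spec(50, mode = "mosaic", seed = 5))
estimate_n_mosaic(mosaic$hearts, B = 1000, seed = 9)
#> # A tibble: 1 × 10
#>   estimate conf.low conf.high level method    mean_clusters mean_chimerism   m_f
#>      <dbl>    <dbl>     <dbl> <dbl> <chr>             <dbl>          <dbl> <dbl>
#> 1     252.     241.      264.  0.95 bootstrap          93.9          0.518   2.6
#> # ℹ 2 more variables: m_m <dbl>, f_surface <dbl>
```

The estimate of 252 uses the computed merging factor `m_m = 2.95` and the
surface-visibility correction `f_surface = 0.82`.

and the merging factor it relies on, at the experimental chimerism
(three colors at 0.17 each):

```r
merging_factor(rep(0.17, 3), n_replicates = 200, seed = 3)
#> # A tibble: 1 × 8
#>   estimate conf.low conf.high level method     mean_cluster_size n_replicates     n
#>      <dbl>    <dbl>     <dbl> <dbl> <chr>                  <dbl>        <int> <dbl>
#> 1     2.95     2.95      2.96  0.95 simulation              1.82          200 65536
```

about 2.95 progenitors fuse into the compound containing a typical labeled
progenitor, close to the observed compound size of ~2.75 and nearly
cancelling the fragmentation rate of 2.6 — which is why the normalized
cluster count is itself a good progenitor count.

Clone-size dynamics and division rates:

```r
sizes <- simulate_gwi(gwi_params(alpha = 1.4, beta = 0.7, t = 3, rho = 0),
                      n_clones = 1e4, seed = 1)
glance(fit_nb(sizes))
#> # A tibble: 1 × 7
#>       r     q  mean  logLik converged boundary  nobs
#>   <dbl> <dbl> <dbl>   <dbl> <lgl>     <lgl>    <int>
#> 1  2.01 0.122  14.4 -36137. TRUE      FALSE    10000

overall_division_rate(558, 5.75)$rate    # clone volumes -> ~1.1 divisions/day
#> [1] 1.099889
horizontal_division_rate(56, 5.75)$rate  # surface areas -> ~0.7/day
#> [1] 0.7000612
horizontal_fraction(0.7, 1.1)            # ~64% of divisions are horizontal
#> [1] 0.6363636
```

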