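# fireweek

Bayesian detection and testing of **weekly cycles in regional fire counts**.

Vegetation burning in sub-Saharan Africa is almost entirely anthropogenic —
fires are set for pasture management, hunting, pest control and cropland
preparation. Because there is no natural forcing with a seven-day period, a
weekly cycle in fire activity is a human fingerprint, and the day of minimum
activity should track the regionally dominant religion's day of rest: Sunday
in Christian regions, Friday in Muslim regions. `fireweek` is for
spatial-epidemiology-style analyses of that question: it classifies
administrative regions by dominant religion and land use (anthrome), fits
Bayesian spatial count models to per-weekday fire counts, selects among
candidate model structures, and tests the weekday contrasts of interest.

## The model

For region *i* and weekday *W* (1 = Monday … 7 = Sunday), yearly counts are
negative binomial with shape θ and mean μ_iW,

    ln(μ_iW) = ln(area_i) + α₀ + α_1A + α_2R + α_3W
               + α_1RW + α_2RA + α_3WA + α_RWA + z_i

with log region area as an offset, corner-constrained factor effects for
anthrome *A*, religion *R* and weekday *W* plus their interactions, and an
intrinsic conditional autoregressive (ICAR) random effect *z* on the region
contiguity graph, with improper density ∝ τ^((n−k)/2) exp{−(τ/2) Σ_{i~j}
(z_i − z_j)²}. Fitting is by an adaptive Metropolis-within-Gibbs sampler
(compiled C++ core; conjugate gamma updates for τ; bit-reproducible given a
seed). Candidate models are ranked by DIC = D̄ + p_D, and the 15 contrasts
of interest (Sunday vs other weekdays in Christian regions, Friday vs other
weekdays in Muslim regions, three cross-group comparisons) are tested by
posterior contour probabilities of zero — one minus the content of the
highest-posterior-density interval just covering zero — with
Benjamini–Hochberg adjustment across the family.

A synthetic-data module generates lattice region systems (spatially
clustered religion labels, Dirichlet anthrome compositions, exact ICAR field
draws, gamma–Poisson counts) with the same statistical structure, so every
stage is testable without the original satellite/demographic data.

## Worked example

Simulate a 10 × 10 lattice with a −0.21 log-scale Sunday deficit in
Christian regions and Friday deficit in Muslim regions, fit the
religion × weekday interaction model with the spatial term, and test the
contrasts:

```r
library(fireweek)

cfg <- simulation_config(n_rows = 10, n_cols = 10, n_years = 3, seed = 11)
sys <- generate_regions(cfg)
sim <- simulate_counts(sys$regions, sys$graph, cfg)
fit <- fit_mcmc(sim$panel, sim$regions, sys$graph,
                model_spec("R + W + R:W + ICAR"),
                config = mcmc_config(seed = 5))
head(run_contrast_suite(fit), 3)
#>          contrast   mean     sd ci_low ci_high     p  p_bh
#> 1 Chr:Sun-Chr:Mon -0.400 0.0774 -0.547 -0.2414 0.000 0.000
#> 2 Chr:Sun-Chr:Tue -0.290 0.0820 -0.460 -0.1318 0.000 0.000
#> 3 Chr:Sun-Chr:Wed -0.111 0.0826 -0.269  0.0522 0.162 0.203
compute_dic(fit)$dic
#> [1] 22400.4
```

Each row is a log-scale difference of cell means: Christian-region Sunday
counts are estimated ~33% lower than Monday (e^−0.400 ≈ 0.67) with a 95%
credible interval excluding zero, while the Wednesday contrast — whose true
simulated value is the same −0.21 — happens to be noisier at this lattice
size; the contour probability `p` is a Bayesian analogue of a two-sided
p-value and `p_bh` its BH adjustment over the 15-contrast family. `select_model()` compares candidate structures by DIC, and
`run_full_analysis()` chains classification → global selection →
per-anthrome selection → contrasts, writing stamped CSVs (a thin CLI lives
in `inst/cli/fireweek`).

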