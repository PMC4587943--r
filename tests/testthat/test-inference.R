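test_that("sampler is deterministic given a seed and respects fixed parameters", {
  regions <- label_regions(as_region_table(tiny_region_df(3)))
  g <- build_adjacency(rbind(c("r01", "r02"), c("r02", "r03")),
                       regions$region_id)
  set.seed(1)
  long <- expand.grid(region_id = regions$region_id, year = 2003:2004,
                      weekday = 1:7, stringsAsFactors = FALSE)
  long$count <- rpois(nrow(long), 40)
  panel <- make_fire_panel(long, regions$region_id, 2003:2004)
  cfg <- mcmc_config(n_chains = 2, n_iter = 600, n_burn = 200, seed = 77)
  f1 <- suppressWarnings(fit_mcmc(panel, regions, g, model_spec("W + ICAR"),
                                  config = cfg))
  f2 <- suppressWarnings(fit_mcmc(panel, regions, g, model_spec("W + ICAR"),
                                  config = cfg))
  expect_identical(f1$chains[[1]]$alpha, f2$chains[[1]]$alpha)
  expect_identical(f1$chains[[2]]$z, f2$chains[[2]]$z)
  # non-ICAR fit carries no spatial draws and no tau
  f0 <- suppressWarnings(fit_mcmc(panel, regions, g, model_spec("W"),
                                  config = cfg))
  expect_true(all(is.na(f0$chains[[1]]$tau)))
  expect_equal(ncol(f0$chains[[1]]$z), 0)
  # spatial draws are recentered: every retained z sums to zero per component
  expect_equal(max(abs(rowSums(f1$chains[[1]]$z))), 0, tolerance = 1e-10)
})

test_that("intercept-only posterior matches the MLE on large counts", {
  regions <- label_regions(as_region_table(tiny_region_df(1, area = 50)))
  set.seed(6)
  long <- expand.grid(region_id = "r01", year = 2003:2005, weekday = 1:7,
                      stringsAsFactors = FALSE)
  long$count <- rpois(nrow(long), 5000)
  panel <- make_fire_panel(long, "r01", 2003:2005)
  fit <- suppressWarnings(fit_mcmc(panel, regions, NULL, model_spec("1"),
                                   config = mcmc_config(n_chains = 2,
                                                        n_iter = 2000,
                                                        n_burn = 500,
                                                        seed = 2)))
  ps <- posterior_summary(fit)
  a0 <- ps[ps$parameter == "(Intercept)", ]
  mle <- log(mean(panel$count) / 50)
  expect_lt(abs(a0$mean - mle), 2 * a0$sd)
})

test_that("posterior mean and sd match a 1-D quadrature oracle with theta fixed", {
  regions <- label_regions(as_region_table(tiny_region_df(3, area = c(40, 80, 120))))
  set.seed(12)
  long <- expand.grid(region_id = regions$region_id, year = 2003:2004,
                      weekday = 1:7, stringsAsFactors = FALSE)
  long$count <- rpois(nrow(long), 30)
  panel <- make_fire_panel(long, regions$region_id, 2003:2004)
  theta0 <- 2
  pr <- prior_spec()
  fit <- suppressWarnings(fit_mcmc(panel, regions, NULL, model_spec("1"),
                                   priors = pr,
                                   config = mcmc_config(n_chains = 2,
                                                        n_iter = 4000,
                                                        n_burn = 1000,
                                                        thin = 1,
                                                        seed = 9,
                                                        fix_theta = theta0)))
  d <- build_design(regions, model_spec("1"))
  # dense grid integration over the single free coefficient
  grid <- seq(-1.5, 1.5, length.out = 4001)
  logpost <- vapply(grid, function(a) {
    log_likelihood(panel, d, a, theta0) + dnorm(a, 0, pr$alpha_sd, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  q_mean <- sum(w * grid)
  q_sd <- sqrt(sum(w * (grid - q_mean)^2))
  draws <- as.vector(chain_draws <- alpha_draws(fit))
  expect_lt(abs(mean(draws) - q_mean), 0.01)
  expect_lt(abs(sd(draws) - q_sd), 0.01)
})

test_that("the tau draws follow the conjugate gamma full conditional", {
  out <- small_cropland_fit(seed = 31, n_iter = 2000, n_burn = 500)
  fit <- out$fit
  g <- fit$graph
  pr <- fit$priors
  shape <- pr$tau_shape + (length(g$ids) - g$n_components) / 2
  u <- unlist(lapply(fit$chains, function(ch) {
    vapply(seq_along(ch$tau), function(t) {
      quad <- icar_quadratic(ch$z[t, ], g)
      pgamma(ch$tau[t], shape = shape, rate = pr$tau_rate + quad / 2)
    }, numeric(1))
  }))
  # probability integral transform of the conditional: uniform on [0, 1]
  expect_lt(abs(mean(u) - 0.5), 0.03)
  expect_lt(abs(mean(u < 0.25) - 0.25), 0.05)
  expect_lt(abs(mean(u < 0.75) - 0.75), 0.05)
})

test_that("DIC decomposes exactly and is zero-complexity on a degenerate posterior", {
  regions <- label_regions(as_region_table(tiny_region_df(1)))
  panel <- uniform_panel("r01", count = 12L)
  spec <- model_spec("1")
  design <- build_design(regions, spec)
  a <- log(12 / 100)
  ll <- log_likelihood(panel, design, a, 2)
  degenerate <- structure(list(
    spec = spec,
    chains = list(list(alpha = matrix(a, 200, 1,
                                      dimnames = list(NULL, "(Intercept)")),
                       log_theta = rep(log(2), 200),
                       tau = rep(NA_real_, 200), z = matrix(0, 0, 0),
                       log_lik = rep(ll, 200))),
    design = design, panel = panel, regions = regions,
    config = mcmc_config(seed = 1)), class = "fireweek_fit")
  d <- compute_dic(degenerate)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, -2 * ll)
  expect_equal(d$dic, d$dbar + d$p_d)

  # two-draw arithmetic oracle
  a2 <- c(a - 0.1, a + 0.3)
  lt2 <- c(log(2), log(3))
  ll2 <- vapply(1:2, function(i) {
    log_likelihood(panel, design, a2[i], exp(lt2[i]))
  }, numeric(1))
  two <- degenerate
  two$chains <- list(list(alpha = matrix(a2, 2, 1,
                                         dimnames = list(NULL, "(Intercept)")),
                          log_theta = lt2, tau = rep(NA_real_, 2),
                          z = matrix(0, 0, 0), log_lik = ll2))
  d2 <- suppressWarnings(compute_dic(two))
  dbar_hand <- mean(-2 * ll2)
  dhat_hand <- -2 * log_likelihood(panel, design, mean(a2), exp(mean(lt2)))
  expect_equal(d2$dbar, dbar_hand)
  expect_equal(d2$p_d, dbar_hand - dhat_hand)
  expect_equal(d2$dic, 2 * dbar_hand - dhat_hand)
})

test_that("the DIC identity holds for every real fit", {
  out <- small_cropland_fit(seed = 41, n_iter = 800, n_burn = 300)
  d <- compute_dic(out$fit)
  expect_equal(d$dic, d$dbar + d$p_d, tolerance = 1e-9)
})

test_that("posterior summaries are quantile-exact and diagnose divergent chains", {
  # all-equal draws
  cfit <- fake_fit(list(matrix(2.5, 500, 21)))
  ps <- posterior_summary(cfit)
  expect_equal(ps$mean[1], 2.5)
  expect_equal(ps$sd[1], 0)
  expect_equal(ps$ci_low[1], 2.5)
  expect_equal(ps$ci_high[1], 2.5)
  # large normal sample: equal-tailed CI ~ +/- 1.96
  set.seed(10)
  m <- matrix(rnorm(1e6), ncol = 2)
  nfit <- fake_fit(list(matrix(m[, 1], ncol = 21, nrow = nrow(m)),
                        matrix(m[, 2], ncol = 21, nrow = nrow(m))))
  ps2 <- posterior_summary(nfit)
  expect_equal(ps2$ci_low[1], -1.96, tolerance = 0.01)
  expect_equal(ps2$ci_high[1], 1.96, tolerance = 0.01)
  # two chains with shifted means: R-hat far above 1
  sfit <- fake_fit(list(matrix(rnorm(500), 500, 21),
                        matrix(rnorm(500, 5), 500, 21)))
  expect_gt(posterior_summary(sfit)$rhat[1], 2)
})

test_that("model selection returns a DIC-ascending table and survives failures", {
  out <- small_cropland_fit(seed = 51, n_iter = 600, n_burn = 200)
  sel <- suppressWarnings(select_model(
    out$sim$panel, out$sim$regions, out$graph,
    list("R + W", "R + W + ICAR"),
    config = mcmc_config(n_chains = 2, n_iter = 600, n_burn = 200, seed = 5)))
  expect_equal(nrow(sel$table), 2)
  expect_false(is.unsorted(sel$table$dic))
  expect_equal(format(sel$best), sel$table$model[1])
  # single candidate trivially wins
  sel1 <- suppressWarnings(select_model(
    out$sim$panel, out$sim$regions, out$graph, list("R + W"),
    config = mcmc_config(n_chains = 2, n_iter = 600, n_burn = 200, seed = 5)))
  expect_equal(format(sel1$best), "R + W")
  # an unfittable candidate is excluded with a warning, not fatal
  expect_warning(
    selbad <- select_model(
      out$sim$panel, out$sim$regions, out$graph,
      list("R + W", "R + W + A + R:A"),  # anthrome has one level here
      config = mcmc_config(n_chains = 2, n_iter = 600, n_burn = 200, seed = 5)),
    "failed")
  expect_equal(nrow(selbad$table), 1)
})
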