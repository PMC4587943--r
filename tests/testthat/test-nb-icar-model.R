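test_that("NB log-pmf matches closed forms, normalises, and has the Poisson limit", {
  expect_equal(nb_log_pmf(0, 3.7, 2.2), 2.2 * log(2.2 / (3.7 + 2.2)))
  expect_equal(nb_log_pmf(1, 1, 1), log(1 / 4))
  # independent oracle: R's own NB density
  set.seed(8)
  y <- rpois(50, 20)
  mu <- runif(50, 0.5, 80)
  th <- runif(50, 0.3, 15)
  expect_equal(nb_log_pmf(y, mu, th[1]),
               dnbinom(y, size = th[1], mu = mu, log = TRUE))
  # normalisation by direct summation, random (mu, theta) pairs
  for (rep in 1:20) {
    m <- runif(1, 0.5, 12); t0 <- runif(1, 0.3, 8)
    expect_equal(sum(exp(nb_log_pmf(0:5000, m, t0))), 1, tolerance = 1e-8)
  }
  # theta -> infinity: Poisson
  expect_equal(nb_log_pmf(0:100, 5, 1e9), dpois(0:100, 5, log = TRUE),
               tolerance = 1e-5)
  # no overflow at large counts
  expect_true(is.finite(nb_log_pmf(1e7, 1e7, 2)))
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_log_pmf(1.5, 1, 1), "integer")
})

test_that("model strings parse, canonicalise, and enforce term hierarchy", {
  s <- model_spec("W + R + R:W + ICAR")
  expect_true(s$icar)
  expect_equal(s$terms, c("R", "W", "R:W"))
  expect_equal(format(model_spec("R + W + A + W:A")), "R + W + A + W:A")
  expect_equal(format(model_spec("1")), "1")
  expect_error(model_spec("R + R:W"), "main effects")
  expect_error(model_spec("R + W + Q"), "unknown")
})

test_that("design matrices have the corner-constrained column counts and span the cell means", {
  # one region per religion x anthrome combination (15 in all)
  combos <- expand.grid(rel = c("Christian", "Muslim", "Mixed"),
                        ant = c("Cropland", "Natural", "Rangeland",
                                "Settled", "Mixed"),
                        stringsAsFactors = FALSE)
  regions <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    d <- tiny_region_df(1, combos$rel[i], combos$ant[i])
    d$region_id <- sprintf("c%02d", i)
    d
  }))
  regions <- label_regions(as_region_table(regions))
  expect_equal(ncol(build_design(regions, model_spec("R + W + A"))$X), 13)
  expect_equal(ncol(build_design(regions, model_spec("R + W + R:W"))$X), 21)
  full <- build_design(regions,
                       model_spec("R + W + A + R:W + R:A + W:A + R:W:A"))
  expect_equal(ncol(full$X), 105)
  expect_equal(qr(full$X)$rank, 105)
  # full factorial design spans every religion x weekday x anthrome cell mean
  cells <- full$cells
  cell_id <- interaction(cells$religion, cells$weekday, cells$anthrome,
                         drop = TRUE)
  mm <- model.matrix(~ 0 + cell_id)
  expect_equal(qr(cbind(full$X, mm))$rank, qr(full$X)$rank)
})

test_that("the linear predictor applies offsets, coefficients and spatial effects", {
  regions <- label_regions(as_region_table(tiny_region_df(2, area = c(100, 50))))
  d <- build_design(regions, model_spec("1"))
  expect_equal(unique(linear_predictor(d, 0, as_mu = TRUE)[1:7]), 100)
  expect_equal(linear_predictor(d, log(2), as_mu = TRUE)[8:14],
               rep(100, 7))
  # loop oracle on a random small case
  d2 <- build_design(regions, model_spec("W"))
  alpha <- rnorm(ncol(d2$X)); z <- rnorm(2)
  eta <- linear_predictor(d2, alpha, z)
  for (i in sample(nrow(d2$X), 5)) {
    expect_equal(eta[i],
                 d2$log_offset[i] + sum(d2$X[i, ] * alpha) + z[d2$region_index[i]])
  }
  expect_error(linear_predictor(d2, alpha[-1]), "length")
})

test_that("ICAR quadratic equals the explicit Laplacian form and is component-shift invariant", {
  ids <- letters[1:5]
  g <- build_adjacency(cbind(ids[-5], ids[-1]), ids)  # 5-node path
  expect_equal(icar_quadratic(rep(1, 5), g), 0)
  g2 <- build_adjacency(rbind(c("a", "b")), c("a", "b"))
  expect_equal(icar_quadratic(c(1, -1), g2), 4)
  # precision-matrix oracle Q = D - W
  set.seed(3)
  W <- matrix(0, 5, 5)
  for (e in seq_len(nrow(g$edges))) {
    i <- match(g$edges[e, 1], ids); j <- match(g$edges[e, 2], ids)
    W[i, j] <- W[j, i] <- 1
  }
  Q <- diag(rowSums(W)) - W
  for (rep in 1:10) {
    z <- rnorm(5)
    expect_equal(icar_quadratic(z, g), drop(z %*% Q %*% z))
  }
  # adding a constant per component leaves the quadratic unchanged
  ids2 <- letters[1:6]
  g3 <- build_adjacency(rbind(c("a", "b"), c("b", "c"), c("d", "e")), ids2)
  z <- rnorm(6)
  shift <- c(2, 2, 2, -3, -3, 7)  # one constant per component {abc},{de},{f}
  expect_equal(icar_quadratic(z + shift, g3), icar_quadratic(z, g3))
  # rank correction in the log-density: doubling tau on constant z changes
  # the density only through ((n - k)/2) log tau
  z0 <- rep(0, 6)
  expect_equal(icar_log_density(z0, 2, g3) - icar_log_density(z0, 1, g3),
               ((6 - 3) / 2) * log(2))
})

test_that("log-likelihood sums the NB pmf over all cells and doubles with duplicated years", {
  regions <- label_regions(as_region_table(tiny_region_df(2)))
  spec <- model_spec("W")
  d <- build_design(regions, spec)
  set.seed(9)
  long <- expand.grid(region_id = regions$region_id, year = 2003:2004,
                      weekday = 1:7, stringsAsFactors = FALSE)
  long$count <- rpois(nrow(long), 15)
  panel <- make_fire_panel(long, regions$region_id, 2003:2004)
  alpha <- rnorm(ncol(d$X), sd = 0.1); theta <- 2.5; z <- rnorm(2, sd = 0.2)
  # naive loop oracle
  eta <- linear_predictor(d, alpha, z)
  ll0 <- 0
  for (r in seq_len(nrow(panel))) {
    i <- which(d$cells$region_id == panel$region_id[r] &
                 d$cells$weekday == panel$weekday[r])
    ll0 <- ll0 + dnbinom(panel$count[r], size = theta, mu = exp(eta[i]),
                         log = TRUE)
  }
  expect_equal(log_likelihood(panel, d, alpha, theta, z), ll0,
               tolerance = 1e-10)
  # replicate additivity: appending the same years doubles the likelihood
  long2 <- long; long2$year <- long2$year + 10L
  panel2 <- make_fire_panel(rbind(long, long2), regions$region_id,
                            c(2003:2004, 2013:2014))
  expect_equal(log_likelihood(panel2, d, alpha, theta, z),
               2 * log_likelihood(panel, d, alpha, theta, z))
})

test_that("log-posterior composes likelihood, ICAR density and priors", {
  regions <- label_regions(as_region_table(tiny_region_df(3)))
  g <- build_adjacency(rbind(c("r01", "r02"), c("r02", "r03")),
                       regions$region_id)
  spec <- model_spec("W + ICAR")
  d <- build_design(regions, spec)
  panel <- uniform_panel(regions$region_id)
  alpha <- rnorm(ncol(d$X), sd = 0.1)
  z <- c(0.1, -0.2, 0.1)
  params <- list(alpha = alpha, theta = 2, z = z, tau = 3)
  pr <- prior_spec()
  lp <- log_posterior(panel, d, spec, params, pr, g)
  ll <- log_likelihood(panel, d, alpha, 2, z)
  expect_equal(lp - ll,
               sum(dnorm(alpha, 0, pr$alpha_sd, log = TRUE)) +
                 dnorm(log(2), 0, pr$log_theta_sd, log = TRUE) +
                 icar_log_density(z, 3, g) +
                 dgamma(3, pr$tau_shape, rate = pr$tau_rate, log = TRUE))
  # tau delta on constant z acts only through rank and prior terms
  paramsc <- params; paramsc$z <- rep(0, 3)
  delta <- log_posterior(panel, d, spec,
                         within(paramsc, tau <- 6), pr, g) -
    log_posterior(panel, d, spec, paramsc, pr, g)
  expect_equal(delta,
               ((3 - 1) / 2) * log(2) +
                 dgamma(6, pr$tau_shape, rate = pr$tau_rate, log = TRUE) -
                 dgamma(3, pr$tau_shape, rate = pr$tau_rate, log = TRUE))
  # without ICAR the posterior ignores z and tau
  spec0 <- model_spec("W")
  p1 <- log_posterior(panel, d, spec0, params, pr)
  p2 <- log_posterior(panel, d, spec0,
                      within(params, {z <- rnorm(3); tau <- 99}), pr)
  expect_equal(p1, p2)
  # positivity violations flag as -Inf
  expect_equal(log_posterior(panel, d, spec, within(params, theta <- -1),
                             pr, g), -Inf)
})

test_that("NB moments from the gamma-Poisson generator match mean and variance", {
  set.seed(14)
  n <- 1e6; mu <- 7; theta <- 3
  y <- rpois(n, rgamma(n, shape = theta, scale = mu / theta))
  expect_equal(mean(y), mu, tolerance = 0.01)
  expect_equal(var(y), mu + mu^2 / theta, tolerance = 0.01)
})
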