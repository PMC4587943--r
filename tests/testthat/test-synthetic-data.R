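test_that("lattice adjacency has the expected grid combinatorics", {
  cfg <- simulation_config(n_rows = 2, n_cols = 2, seed = 1)
  sys <- generate_regions(cfg)
  expect_equal(nrow(sys$regions), 4)
  expect_equal(nrow(sys$graph$edges), 4)  # 2x2 rook
  cfgq <- simulation_config(n_rows = 2, n_cols = 2, contiguity = "queen",
                            seed = 1)
  expect_equal(nrow(generate_regions(cfgq)$graph$edges), 6)
})

test_that("generation is deterministic per seed and valid as a region table", {
  cfg <- simulation_config(n_rows = 4, n_cols = 4, seed = 13)
  a <- generate_regions(cfg)
  b <- generate_regions(cfg)
  expect_identical(a$regions, b$regions)
  expect_identical(a$graph$edges, b$graph$edges)
  expect_s3_class(a$regions, "region_table")
  sim1 <- simulate_counts(a$regions, a$graph, cfg)
  sim2 <- simulate_counts(b$regions, b$graph, cfg)
  expect_identical(sim1$panel$count, sim2$panel$count)
})

test_that("religion labels are spatially clustered under the default config", {
  cfg <- simulation_config(n_rows = 10, n_cols = 10, seed = 17)
  sys <- generate_regions(cfg)
  lab <- label_regions(sys$regions)$religion_label
  # join-count statistic: same-label adjacent pairs vs its permutation null
  ei <- match(sys$graph$edges[, 1], sys$graph$ids)
  ej <- match(sys$graph$edges[, 2], sys$graph$ids)
  jc <- sum(lab[ei] == lab[ej])
  set.seed(99)
  null <- replicate(99, {
    perm <- sample(lab)
    sum(perm[ei] == perm[ej])
  })
  expect_gt(jc, quantile(null, 0.99))
})

test_that("zero clustering strength gives spatially unstructured labels", {
  cfg <- simulation_config(n_rows = 10, n_cols = 10,
                           religion_clustering = 0, seed = 19)
  sys <- generate_regions(cfg)
  lab <- label_regions(sys$regions)$religion_label
  ei <- match(sys$graph$edges[, 1], sys$graph$ids)
  ej <- match(sys$graph$edges[, 2], sys$graph$ids)
  jc <- sum(lab[ei] == lab[ej])
  set.seed(98)
  null <- replicate(199, {
    perm <- sample(lab)
    sum(perm[ei] == perm[ej])
  })
  expect_lte(jc, quantile(null, 0.995))
  expect_gte(jc, quantile(null, 0.005))
})

test_that("ICAR field draws are centred, tau-scaled, and match the Laplacian pseudo-inverse", {
  ids <- letters[1:5]
  g <- build_adjacency(cbind(ids[-5], ids[-1]), ids)  # 5-node path
  z <- sample_icar_field(g, tau = 1, seed = 5)
  expect_equal(sum(z), 0, tolerance = 1e-12)
  # tau scaling: fields shrink as tau^(-1/2)
  set.seed(7)
  big <- sample_icar_field(g, tau = 1e6, n = 50)
  expect_lt(max(abs(big)), 0.05)
  # empirical covariance vs pseudo-inverse oracle
  draws <- sample_icar_field(g, tau = 1, seed = 8, n = 1e5)
  emp <- crossprod(draws) / nrow(draws)
  W <- matrix(0, 5, 5)
  W[cbind(1:4, 2:5)] <- 1; W <- W + t(W)
  Sigma <- MASS::ginv(diag(rowSums(W)) - W)
  expect_lt(max(abs(emp - Sigma)), 0.05 * max(abs(Sigma)))
  # disconnected graphs: per-component centring, singletons exactly zero
  g2 <- build_adjacency(rbind(c("a", "b")), c("a", "b", "c"))
  z2 <- sample_icar_field(g2, tau = 1, seed = 9)
  expect_equal(z2[1] + z2[2], 0, tolerance = 1e-12)
  expect_equal(z2[3], 0)
})

test_that("simulated counts carry the configured weekday deficit and NB dispersion", {
  # isolated regions (empty graph) so z = 0 and the ratio is exact in expectation
  n <- 1500
  df <- tiny_region_df(n, area = 100)
  df$region_id <- sprintf("c%04d", seq_len(n))
  regions <- label_regions(as_region_table(df))
  g <- build_adjacency(matrix(character(), ncol = 2), regions$region_id)
  cfg <- simulation_config(n_years = 9, seed = 23, theta = 4)
  sim <- simulate_counts(regions, g, cfg)
  tot <- panel_weekday_totals(sim$panel)
  ratio <- sum(tot[, 7]) / sum(tot[, 1])  # Sunday / Monday in Christian regions
  expect_equal(ratio, exp(-0.21), tolerance = 0.02)
  # Monday-Saturday carry no cycle
  expect_equal(sum(tot[, 6]) / sum(tot[, 1]), 1, tolerance = 0.02)

  # dispersion oracle at mu = 100, theta = 2: var/mean = 1 + mu/theta = 51
  cfg2 <- simulation_config(n_years = 1, seed = 29, theta = 2,
                            christian_sunday_deficit = 0,
                            muslim_friday_deficit = 0)
  df2 <- tiny_region_df(3000, area = 100)
  df2$region_id <- sprintf("d%04d", 1:3000)
  regions2 <- label_regions(as_region_table(df2))
  g2 <- build_adjacency(matrix(character(), ncol = 2), regions2$region_id)
  sim2 <- simulate_counts(regions2, g2, cfg2)
  y <- sim2$panel$count
  expect_equal(mean(y), 100, tolerance = 0.05)
  expect_equal(var(y) / mean(y), 51, tolerance = 0.1 * 51)

  # overflow guard
  cfg3 <- simulation_config(intercept = 40, seed = 1, n_rows = 2, n_cols = 2)
  sys3 <- generate_regions(cfg3)
  expect_error(simulate_counts(sys3$regions, sys3$graph, cfg3), "1e12")
})

test_that("truth coefficients reproduce the simulated cell structure exactly", {
  cfg <- simulation_config(n_rows = 5, n_cols = 5, n_years = 2, seed = 37)
  sys <- generate_regions(cfg)
  sim <- simulate_counts(sys$regions, sys$graph, cfg)
  d <- build_design(sim$regions, model_spec("R + W + R:W"))
  tr <- truth_coefficients(sim$truth, d)
  # the projected coefficients rebuild the per-cell log-means minus offset/z
  rebuilt <- unname(drop(d$X %*% tr))
  direct <- sim$truth$log_mu - log(sim$regions$area_km2)[d$region_index] -
    sim$truth$z[d$region_index]
  expect_equal(rebuilt, unname(direct), tolerance = 1e-10)
})

test_that("fixtures are deterministic and match their documented shapes", {
  p <- make_fixture("table4-pvalues")
  expect_length(p, 15)
  expect_equal(unname(p[c(3, 5, 15)]), c(0.00036, 0.00319, 0.57856))
  t1 <- make_fixture("table1-regions")
  expect_equal(nrow(t1), 372)
  ex <- make_fixture("exclusions-554")
  expect_equal(nrow(ex$regions), 554)
  tiny <- make_fixture("tiny-fit")
  expect_equal(nrow(tiny$regions), 9)
  expect_equal(length(attr(tiny$panel, "years")), 2)
  expect_error(make_fixture("nope"), "table4-pvalues")
})

test_that("the tiny fixture fits end-to-end quickly", {
  tiny <- make_fixture("tiny-fit")
  t0 <- Sys.time()
  fit <- suppressWarnings(fit_mcmc(
    tiny$panel, tiny$regions, tiny$graph, model_spec("R + W + ICAR"),
    config = mcmc_config(n_chains = 2, n_iter = 800, n_burn = 300, seed = 3)))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_s3_class(fit, "fireweek_fit")
  expect_true(is.finite(compute_dic(fit)$dic))
})
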