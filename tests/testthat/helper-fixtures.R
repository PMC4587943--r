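# Small in-code fixtures shared across test files.

tiny_region_df <- function(n = 3, religion = "Christian", anthrome = "Cropland",
                           area = 100) {
  rel <- switch(religion,
                Christian = c(0.8, 0.1), Muslim = c(0.1, 0.8),
                Mixed = c(0.4, 0.4))
  ant <- stats::setNames(rep(0.1, 4),
                         c("frac_cropland", "frac_natural", "frac_rangeland",
                           "frac_settled"))
  if (anthrome == "Mixed") ant[] <- 0.25 else
    ant[paste0("frac_", tolower(anthrome))] <- 0.7
  df <- data.frame(region_id = sprintf("r%02d", seq_len(n)),
                   area_km2 = area,
                   frac_christian = rel[1], frac_muslim = rel[2],
                   frac_other = 0.05,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(as.list(ant)))
}

uniform_panel <- function(region_ids, years = 2003L, count = 10L) {
  long <- expand.grid(region_id = region_ids, year = years, weekday = 1:7,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$count <- count
  make_fire_panel(long, region_ids, years)
}

# a small fitted model on simulated cropland data, reused by contrast tests
small_cropland_fit <- function(seed = 21L, n_years = 3L, dim = 5L,
                               n_chains = 2L, n_iter = 1500L, n_burn = 500L) {
  cfg <- simulation_config(n_rows = dim, n_cols = dim, n_years = n_years,
                           seed = seed)
  sys <- generate_regions(cfg)
  sim <- simulate_counts(sys$regions, sys$graph, cfg)
  fit <- suppressWarnings(fit_mcmc(
    sim$panel, sim$regions, sys$graph, model_spec("R + W + R:W + ICAR"),
    config = mcmc_config(n_chains = n_chains, n_iter = n_iter,
                         n_burn = n_burn, seed = seed)))
  list(fit = fit, sim = sim, graph = sys$graph)
}

three_religion_regions <- function() {
  label_regions(as_region_table(rbind(
    tiny_region_df(2, "Christian"),
    local({d <- tiny_region_df(2, "Muslim"); d$region_id <- c("m01", "m02"); d}),
    local({d <- tiny_region_df(2, "Mixed"); d$region_id <- c("x01", "x02"); d}))))
}

# hand-built fit object with known draws, for arithmetic oracles
fake_fit <- function(alpha_chains, regions = three_religion_regions(),
                     spec = model_spec(c("R", "W", "R:W"))) {
  design <- build_design(regions, spec)
  chains <- lapply(alpha_chains, function(a) {
    colnames(a) <- colnames(design$X)
    list(alpha = a, log_theta = rep(0, nrow(a)),
         tau = rep(NA_real_, nrow(a)), z = matrix(0, 0, 0),
         log_lik = rep(0, nrow(a)))
  })
  structure(list(spec = spec, chains = chains, design = design,
                 regions = regions,
                 config = mcmc_config(n_chains = length(chains), seed = 1)),
            class = "fireweek_fit")
}
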