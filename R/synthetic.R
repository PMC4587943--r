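# Synthetic region systems and fire-count panels with the statistical
# structure the analysis assumes: lattice contiguity, spatially clustered
# religion/anthrome labels, log-normal areas, ICAR-distributed spatial
# effects, and negative binomial counts whose log-means carry
# religion-specific weekday deficits.

#' Simulation configuration
#'
#' Defaults mirror the study design at a desk scale: a 10 x 10 rook lattice
#' standing in for the contiguous administrative regions, nine annual
#' replicates of the 7 weekday counts, a Christian-region Sunday deficit and
#' a Muslim-region Friday deficit of -0.21 on the log scale (the order of the
#' largest fitted within-religion contrast), shape theta = 4 (moderate
#' conditional overdispersion once labels and the spatial field are
#' accounted for), ICAR precision tau = 10, and log-normal areas with median
#' 100 km2 so a typical region-weekday-year cell sees counts of order 100.
#'
#' @param n_rows,n_cols lattice dimensions (>= 2 each).
#' @param contiguity `"rook"` or `"queen"` lattice adjacency.
#' @param n_years number of annual replicates (study value 9).
#' @param religion_clustering probability in \[0, 1\] that a region keeps the
#'   label of its spatial cluster; 0 gives spatially independent labels.
#' @param anthrome_mode `"cropland"` (every region cropland-dominated) or
#'   `"mixed"` (four quadrant clusters, each favouring one class).
#' @param intercept baseline log fire rate per km2 per weekday-year.
#' @param religion_effects named log-scale main effects (reference Christian).
#' @param anthrome_effects named log-scale main effects (reference Cropland).
#' @param christian_sunday_deficit,muslim_friday_deficit log-scale deficits
#'   applied to the (Christian, Sunday) and (Muslim, Friday) cells.
#' @param theta true NB shape.
#' @param tau true ICAR precision of the spatial field.
#' @param area_median_km2,area_sdlog log-normal area distribution.
#' @param seed integer seed; all outputs are deterministic given it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_rows = 10L, n_cols = 10L,
                              contiguity = c("rook", "queen"),
                              n_years = 9L,
                              religion_clustering = 0.9,
                              anthrome_mode = c("cropland", "mixed"),
                              intercept = 0,
                              religion_effects = c(Christian = 0,
                                                   Muslim = 0.15,
                                                   Mixed = -0.1),
                              anthrome_effects = c(Cropland = 0,
                                                   Natural = -0.5,
                                                   Rangeland = -0.3,
                                                   Settled = 0.2,
                                                   Mixed = -0.1),
                              christian_sunday_deficit = -0.21,
                              muslim_friday_deficit = -0.21,
                              theta = 4, tau = 10,
                              area_median_km2 = 100, area_sdlog = 0.5,
                              seed = 1L) {
  stopifnot(n_rows >= 2L, n_cols >= 2L, n_years >= 1L,
            religion_clustering >= 0, religion_clustering <= 1,
            theta > 0, tau > 0, area_median_km2 > 0, area_sdlog >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 contiguity = match.arg(contiguity),
                 n_years = as.integer(n_years),
                 religion_clustering = religion_clustering,
                 anthrome_mode = match.arg(anthrome_mode),
                 intercept = intercept,
                 religion_effects = religion_effects,
                 anthrome_effects = anthrome_effects,
                 christian_sunday_deficit = christian_sunday_deficit,
                 muslim_friday_deficit = muslim_friday_deficit,
                 theta = theta, tau = tau,
                 area_median_km2 = area_median_km2, area_sdlog = area_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

lattice_edges <- function(n_rows, n_cols, contiguity) {
  id <- function(r, c) sprintf("r%03d", (r - 1L) * n_cols + c)
  out <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) out[[length(out) + 1L]] <- c(id(r, c), id(r, c + 1L))
      if (r < n_rows) out[[length(out) + 1L]] <- c(id(r, c), id(r + 1L, c))
      if (contiguity == "queen" && r < n_rows) {
        if (c < n_cols) out[[length(out) + 1L]] <- c(id(r, c), id(r + 1L, c + 1L))
        if (c > 1L) out[[length(out) + 1L]] <- c(id(r, c), id(r + 1L, c - 1L))
      }
    }
  }
  do.call(rbind, out)
}

# two-seed region growing: a Muslim seed on the north edge and a Christian
# seed on the south edge grow over the lattice (multi-source BFS with random
# tie-breaks); regions on the frontier between the two blocks become Mixed
grow_religion_clusters <- function(graph, n_rows, n_cols) {
  n <- length(graph$ids)
  lab <- rep(NA_character_, n)
  seed_m <- ceiling(n_cols / 2)                     # north
  seed_c <- (n_rows - 1L) * n_cols + ceiling(n_cols / 2)  # south
  lab[seed_m] <- "Muslim"
  lab[seed_c] <- "Christian"
  frontier <- c(seed_m, seed_c)
  shuffle <- function(x) if (length(x) > 1L) x[sample.int(length(x))] else x
  while (any(is.na(lab))) {
    nxt <- integer()
    for (v in shuffle(frontier)) {
      for (u in shuffle(graph$neighbours[[v]])) {
        if (is.na(lab[u])) {
          lab[u] <- lab[v]
          nxt <- c(nxt, u)
        }
      }
    }
    if (length(nxt) == 0L) {  # disconnected leftovers: assign at random
      rest <- which(is.na(lab))
      lab[rest] <- sample(c("Christian", "Muslim"), length(rest), replace = TRUE)
      break
    }
    frontier <- nxt
  }
  for (v in seq_len(n)) {
    nb <- graph$neighbours[[v]]
    if (length(nb) > 0L && any(lab[nb] != lab[v]) && stats::runif(1) < 0.5) {
      lab[v] <- "Mixed"
    }
  }
  lab
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic region system
#'
#' Builds the lattice adjacency graph, draws log-normal areas, assigns
#' spatially clustered religion labels (north Muslim belt, south Christian
#' block, Mixed frontier) and cluster-specific Dirichlet anthrome fractions,
#' then backfills religion/anthrome fractions consistent with the intended
#' labels.
#'
#' @param config a `simulation_config`.
#' @return list with `regions` (a `region_table`) and `graph` (an
#'   `adjacency_graph`).
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_rows * config$n_cols
  ids <- sprintf("r%03d", seq_len(n))
  graph <- build_adjacency(lattice_edges(config$n_rows, config$n_cols,
                                         config$contiguity), ids)
  cluster_lab <- grow_religion_clusters(graph, config$n_rows, config$n_cols)
  keep <- stats::runif(n) < config$religion_clustering
  lab <- ifelse(keep, cluster_lab,
                sample(RELIGION_LEVELS, n, replace = TRUE))
  frac_c <- frac_m <- numeric(n)
  for (i in seq_len(n)) {
    if (lab[i] == "Christian") {
      frac_c[i] <- stats::runif(1, 0.70, 0.90)
      frac_m[i] <- stats::runif(1, 0.00,
                                min(frac_c[i] / 3, 1 - frac_c[i]) - 1e-9)
    } else if (lab[i] == "Muslim") {
      frac_m[i] <- stats::runif(1, 0.70, 0.90)
      frac_c[i] <- stats::runif(1, 0.00,
                                min(frac_m[i] / 3, 1 - frac_m[i]) - 1e-9)
    } else {
      frac_c[i] <- stats::runif(1, 0.30, 0.45)
      frac_m[i] <- stats::runif(1, max(0.30, frac_c[i] / 3 + 1e-9),
                                min(0.45, frac_c[i] * 3 - 1e-9))
    }
  }
  frac_other <- pmax(0, 1 - frac_c - frac_m) * stats::runif(n, 0.5, 1)

  if (config$anthrome_mode == "cropland") {
    # cropland-only stratum: every region is guaranteed cropland-dominated
    crop <- stats::runif(n, 0.55, 0.9)
    rest <- t(vapply(seq_len(n), function(i) rdirichlet1(c(0.5, 0.5, 1)),
                     numeric(3))) * (1 - crop)
    ant <- cbind(crop, rest)
    colnames(ant) <- c("frac_cropland", "frac_natural", "frac_rangeland",
                       "frac_settled")
    conc <- NULL
  } else {
    row_i <- (seq_len(n) - 1L) %/% config$n_cols + 1L
    col_i <- (seq_len(n) - 1L) %% config$n_cols + 1L
    quadrant <- 1L + (row_i > config$n_rows / 2) * 2L + (col_i > config$n_cols / 2)
    conc <- t(vapply(quadrant, function(q) {
      base <- rep(0.8, 4)
      base[q] <- 6
      base
    }, numeric(4)))
    ant <- t(apply(conc, 1, rdirichlet1))
    colnames(ant) <- c("frac_cropland", "frac_natural", "frac_rangeland",
                       "frac_settled")
  }
  regions <- data.frame(
    region_id = ids,
    area_km2 = stats::rlnorm(n, log(config$area_median_km2), config$area_sdlog),
    frac_christian = frac_c, frac_muslim = frac_m, frac_other = frac_other,
    stringsAsFactors = FALSE)
  regions <- cbind(regions, as.data.frame(ant))
  list(regions = as_region_table(regions), graph = graph)
}

#' Draw one realisation of the ICAR spatial field
#'
#' Samples from the intrinsic Gaussian Markov random field with precision
#' tau (D - W), via the eigendecomposition of each component's Laplacian
#' restricted to its non-null eigenspace, so component sums are exactly zero.
#' Single-node components get z = 0.
#'
#' @param graph an `adjacency_graph`.
#' @param tau positive precision.
#' @param seed optional integer seed.
#' @param n number of independent realisations; the default 1 returns a
#'   vector, larger values an `n` x regions matrix.
#' @return numeric vector over `graph$ids` (or matrix of `n` such rows),
#'   summing to zero per component.
#' @export
sample_icar_field <- function(graph, tau, seed = NULL, n = 1L) {
  stopifnot(tau > 0, n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nn <- length(graph$ids)
  z <- matrix(0, n, nn)
  ei <- match(graph$edges[, 1], graph$ids)
  ej <- match(graph$edges[, 2], graph$ids)
  for (k in seq_len(graph$n_components)) {
    members <- which(graph$component == k)
    m <- length(members)
    if (m == 1L) next
    L <- matrix(0, m, m)
    sel <- which(ei %in% members)  # both endpoints share a component
    li <- match(ei[sel], members)
    lj <- match(ej[sel], members)
    for (q in seq_along(li)) {
      L[li[q], lj[q]] <- L[li[q], lj[q]] - 1
      L[lj[q], li[q]] <- L[lj[q], li[q]] - 1
      L[li[q], li[q]] <- L[li[q], li[q]] + 1
      L[lj[q], lj[q]] <- L[lj[q], lj[q]] + 1
    }
    e <- eigen(L, symmetric = TRUE)
    pos <- e$values > max(e$values) * 1e-10
    eps <- matrix(stats::rnorm(n * sum(pos)), n, sum(pos))
    zc <- tcrossprod(sweep(eps, 2, sqrt(tau * e$values[pos]), "/"),
                     e$vectors[, pos, drop = FALSE])
    z[, members] <- zc - rowMeans(zc)
  }
  if (n == 1L) drop(z) else z
}

# log-scale religion x weekday cell effect matrix implied by a config
config_cell_effects <- function(config) {
  delta <- matrix(0, 3, 7, dimnames = list(RELIGION_LEVELS, NULL))
  delta["Christian", 7] <- config$christian_sunday_deficit
  delta["Muslim", 5] <- config$muslim_friday_deficit
  delta + config$religion_effects[RELIGION_LEVELS]
}

#' Simulate a fire-count panel from the generative model
#'
#' Computes each region-weekday log-mean from the true effects, the log-area
#' offset and a fresh ICAR field draw, then draws `n_years` independent
#' negative binomial counts per cell via a gamma-Poisson mixture (an
#' NB sampler independent of the pmf code the fits use).
#'
#' @param regions labelled `region_table` (labels are computed if absent).
#' @param graph the matching `adjacency_graph`.
#' @param config a `simulation_config`.
#' @return list with `panel` (a `fire_panel`), `truth` (true alpha structure,
#'   z, theta, tau, per-cell log-means) and `regions` (labelled).
#' @export
simulate_counts <- function(regions, graph, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(regions$religion_label)) regions <- label_regions(regions)
  set.seed(config$seed + 1L)
  n <- nrow(regions)
  z <- sample_icar_field(graph, config$tau)
  delta <- config_cell_effects(config)
  cells <- expand.grid(weekday = 1:7, idx = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  rel <- regions$religion_label[cells$idx]
  bad <- !rel %in% RELIGION_LEVELS
  if (any(bad)) stop("simulate_counts needs Christian/Muslim/Mixed labels for all regions")
  log_mu <- log(regions$area_km2[cells$idx]) + config$intercept +
    delta[cbind(match(rel, RELIGION_LEVELS), cells$weekday)] +
    config$anthrome_effects[regions$anthrome_label[cells$idx]] +
    z[cells$idx]
  mu <- exp(log_mu)
  if (any(mu > 1e12)) {
    stop("simulated mean exceeds 1e12; use a smaller intercept or areas")
  }
  n_cells <- nrow(cells)
  counts <- matrix(0L, n_cells, config$n_years)
  for (t in seq_len(config$n_years)) {
    lambda <- stats::rgamma(n_cells, shape = config$theta,
                            scale = mu / config$theta)
    counts[, t] <- stats::rpois(n_cells, lambda)
  }
  long <- data.frame(
    region_id = rep(regions$region_id[cells$idx], times = config$n_years),
    year = rep(2000L + seq_len(config$n_years), each = n_cells),
    weekday = rep(cells$weekday, times = config$n_years),
    count = as.vector(counts), stringsAsFactors = FALSE)
  panel <- make_fire_panel(long, regions$region_id,
                           2000L + seq_len(config$n_years))
  truth <- list(config = config, z = z, theta = config$theta, tau = config$tau,
                cell_effects = delta,
                anthrome_effects = config$anthrome_effects,
                intercept = config$intercept, log_mu = log_mu)
  list(panel = panel, truth = truth, regions = regions)
}

#' True coefficient values under a fitted design
#'
#' Projects the generator's cell-level log-mean structure onto the
#' corner-constrained coefficient basis of a fitted design, so posterior
#' draws can be compared against ground truth coefficient by coefficient.
#' Exact whenever the fitted terms span the structure actually simulated
#' (e.g. R + W + R:W on cropland-only data).
#'
#' @param truth the `truth` record from [simulate_counts()].
#' @param design the fitted design (from [build_design()] or a
#'   `fireweek_fit$design`).
#' @return named numeric vector over the design's columns.
#' @export
truth_coefficients <- function(truth, design) {
  cells <- design$cells
  target <- truth$intercept +
    truth$cell_effects[cbind(match(cells$religion, RELIGION_LEVELS),
                             cells$weekday)] +
    truth$anthrome_effects[cells$anthrome]
  fit <- stats::lm.fit(design$X, target)
  resid <- max(abs(fit$residuals))
  if (resid > 1e-8) {
    warning(sprintf(
      "fitted terms do not span the simulated structure (max residual %.2e); coefficients are a least-squares projection", resid))
  }
  stats::setNames(fit$coefficients, colnames(design$X))
}

#' Built-in deterministic fixtures
#'
#' * `"table4-pvalues"` - the 15 raw contour probabilities of the published
#'   cropland contrast table, in reporting order.
#' * `"table1-regions"` - 372 labelled regions whose religion x anthrome
#'   cross-tabulation reproduces the published region counts (e.g. 216
#'   Christian, 164 Cropland of 372).
#' * `"exclusions-554"` - a 554-region system (the 372 above plus 161
#'   low-fire-density regions, 19 regions with a sub-50% Christian + Muslim
#'   share, and 2 with missing religion data) together with a one-year count
#'   panel; running [apply_exclusions()] on it retains exactly the 372.
#' * `"tiny-fit"` - a 3 x 3 lattice, 2-year simulated system for end-to-end
#'   smoke tests (list with `regions`, `graph`, `panel`, `truth`).
#'
#' @param name fixture name.
#' @return the fixture (type depends on the name; see above).
#' @export
make_fixture <- function(name) {
  fixtures <- c("table4-pvalues", "table1-regions", "exclusions-554",
                "tiny-fit")
  if (!name %in% fixtures) {
    stop("unknown fixture; available: ", paste(fixtures, collapse = ", "))
  }
  switch(name,
    "table4-pvalues" = {
      labels <- c(sprintf("Chr:Sun-Chr:%s", WEEKDAY_ABBR[1:6]),
                  sprintf("Mus:Fri-Mus:%s", WEEKDAY_ABBR[c(1:4, 6:7)]),
                  "Chr:Sun-Mus:Fri", "Chr:Sun-Mix:Sun", "Mus:Fri-Mix:Fri")
      stats::setNames(c(0, 0, 0.00036, 0, 0.00319, 0,
                        rep(0, 6), 0, 0, 0.57856), labels)
    },
    "table1-regions" = fixture_table1_regions(),
    "exclusions-554" = fixture_exclusions_554(),
    "tiny-fit" = {
      cfg <- simulation_config(n_rows = 3, n_cols = 3, n_years = 2,
                               seed = 42L)
      sys <- generate_regions(cfg)
      sim <- simulate_counts(sys$regions, sys$graph, cfg)
      list(regions = sim$regions, graph = sys$graph, panel = sim$panel,
           truth = sim$truth)
    })
}

# published region counts by (anthrome x religion)
TABLE1_CELLS <- matrix(
  c(69, 47, 48,
    27,  0,  5,
    30, 14, 12,
    48,  4,  5,
    42,  7, 14),
  nrow = 5, byrow = TRUE,
  dimnames = list(ANTHROME_LEVELS, RELIGION_LEVELS))

region_row <- function(id, religion, anthrome) {
  rel <- switch(religion,
                Christian = c(0.80, 0.10),
                Muslim = c(0.10, 0.80),
                Mixed = c(0.40, 0.40),
                Excluded = c(0.25, 0.20),
                MissingData = c(NA_real_, NA_real_))
  ant <- stats::setNames(rep(0.1, 4),
                         c("Cropland", "Natural", "Rangeland", "Settled"))
  if (anthrome == "Mixed") {
    ant[] <- 0.25
  } else {
    ant[anthrome] <- 0.7
  }
  data.frame(region_id = id, area_km2 = 100,
             frac_christian = rel[1], frac_muslim = rel[2],
             frac_other = if (is.na(rel[1])) NA_real_ else
               round(1 - rel[1] - rel[2], 10) / 2,
             frac_cropland = ant[["Cropland"]],
             frac_natural = ant[["Natural"]],
             frac_rangeland = ant[["Rangeland"]],
             frac_settled = ant[["Settled"]],
             stringsAsFactors = FALSE)
}

fixture_table1_regions <- function() {
  rows <- list()
  i <- 0L
  for (a in ANTHROME_LEVELS) {
    for (r in RELIGION_LEVELS) {
      n <- TABLE1_CELLS[a, r]
      for (q in seq_len(n)) {
        i <- i + 1L
        rows[[i]] <- region_row(sprintf("kept%03d", i), r, a)
      }
    }
  }
  label_regions(as_region_table(do.call(rbind, rows)))
}

fixture_exclusions_554 <- function() {
  kept <- fixture_table1_regions()
  extra <- list()
  for (q in seq_len(161)) {  # cumulative density 9/100 = 0.09 < 0.1
    extra[[length(extra) + 1L]] <- region_row(sprintf("lowd%03d", q),
                                              "Christian", "Cropland")
  }
  for (q in seq_len(19)) {   # Christian + Muslim share 0.45 < 0.5
    extra[[length(extra) + 1L]] <- region_row(sprintf("othr%03d", q),
                                              "Excluded", "Cropland")
  }
  for (q in seq_len(2)) {    # religion data missing
    extra[[length(extra) + 1L]] <- region_row(sprintf("miss%03d", q),
                                              "MissingData", "Cropland")
  }
  regions <- as_region_table(rbind(as.data.frame(kept)[REGION_COLUMNS],
                                   do.call(rbind, extra)))
  low <- grepl("^lowd", regions$region_id)
  counts <- data.frame(region_id = rep(regions$region_id, each = 7L),
                       year = 2003L,
                       weekday = rep(1:7, times = nrow(regions)),
                       count = ifelse(rep(low, each = 7L),
                                      rep(c(2, 2, 1, 1, 1, 1, 1), nrow(regions)),
                                      10L),
                       stringsAsFactors = FALSE)
  panel <- make_fire_panel(counts, regions$region_id, 2003L)
  list(regions = label_regions(regions), panel = panel)
}
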