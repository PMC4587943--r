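# Posterior sampling (driver for the compiled sampler), convergence
# diagnostics, DIC and model selection over an enumerated candidate space.

#' MCMC configuration
#'
#' Defaults (4 chains x 5,000 iterations, 2,000 burn-in, thinning 2) are sized
#' so a full synthetic-lattice pipeline runs in minutes on one CPU.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations (adaptation happens only here).
#' @param thin retain every `thin`-th post-burn-in draw.
#' @param seed integer seed; the whole fit is deterministic given it.
#' @param fix_theta optional positive value at which to fix the NB shape
#'   (mainly for validation against low-dimensional oracles).
#' @param fix_tau optional positive value at which to fix the ICAR precision.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 5000L, n_burn = 2000L,
                        thin = 2L, seed = 1L, fix_theta = NULL,
                        fix_tau = NULL) {
  stopifnot(n_iter > n_burn, n_chains >= 1L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed), fix_theta = fix_theta,
                 fix_tau = fix_tau),
            class = "mcmc_config")
}

# induce the subgraph on `ids` (in that order), keeping only edges whose
# endpoints are both retained; components are recomputed
subset_graph <- function(graph, ids) {
  if (identical(graph$ids, ids)) return(graph)
  missing_ids <- setdiff(ids, graph$ids)
  if (length(missing_ids) > 0L) {
    stop("graph lacks regions: ", paste(missing_ids, collapse = ", "))
  }
  keep <- graph$edges[, 1] %in% ids & graph$edges[, 2] %in% ids
  build_adjacency(graph$edges[keep, , drop = FALSE], ids)
}

# cells x years count matrix aligned with a design's cell order
panel_cell_matrix <- function(panel, design) {
  years <- attr(panel, "years")
  key <- paste(design$cells$region_id, design$cells$weekday, sep = "\r")
  y <- matrix(NA_integer_, nrow = length(key), ncol = length(years))
  idx_cell <- match(paste(panel$region_id, panel$weekday, sep = "\r"), key)
  idx_year <- match(panel$year, years)
  keep <- !is.na(idx_cell)
  y[cbind(idx_cell[keep], idx_year[keep])] <- panel$count[keep]
  if (anyNA(y)) stop("panel does not cover every design cell and year")
  y
}

#' Fit the NB-ICAR model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler: single-site random-walk
#' updates for each fixed effect and spatial effect, a random-walk update for
#' log(theta), sum-to-zero recentering of the spatial field per graph
#' component after every sweep, and a conjugate gamma update for the ICAR
#' precision tau. Proposal scales adapt during burn-in only. Chains start
#' from jittered initial values and the whole run is deterministic given
#' `config$seed`.
#'
#' @param panel a `fire_panel` over the regions being fitted.
#' @param regions labelled region table (the fit's region universe and order).
#' @param graph an `adjacency_graph` covering the regions (only needed for
#'   ICAR specs).
#' @param spec a `model_spec`.
#' @param priors a `prior_spec`.
#' @param config an `mcmc_config`.
#' @return an object of class `fireweek_fit` holding per-chain draws of
#'   `alpha` (fixed effects), `log_theta`, `tau`, `z`, per-draw log-likelihood,
#'   acceptance rates, and the design/panel needed downstream.
#' @export
fit_mcmc <- function(panel, regions, graph = NULL, spec, priors = prior_spec(),
                     config = mcmc_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "mcmc_config"))
  design <- build_design(regions, spec)
  y <- panel_cell_matrix(panel, design)
  n_regions <- nrow(regions)
  n_cells <- nrow(y)

  if (spec$icar) {
    if (is.null(graph)) stop("ICAR models need an adjacency graph")
    graph <- subset_graph(graph, regions$region_id)
    nb <- graph$neighbours
    comp <- graph$component
    n_comp <- graph$n_components
    edges <- cbind(match(graph$edges[, 1], graph$ids),
                   match(graph$edges[, 2], graph$ids))
    if (nrow(graph$edges) == 0L) edges <- matrix(0L, 0, 2)
  } else {
    nb <- rep(list(integer()), n_regions)
    comp <- rep(1L, n_regions)
    n_comp <- 1L
    edges <- matrix(0L, 0, 2)
  }
  region_cells <- split(seq_len(n_cells), design$region_index)
  region_cells <- region_cells[as.character(seq_len(n_regions))]

  # moment-matched intercept start; everything else starts at zero
  a0 <- log((sum(y) + 0.5) / (ncol(y) * sum(exp(design$log_offset))))
  p <- ncol(design$X)

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    alpha_init <- c(a0, rep(0, p - 1L)) + stats::rnorm(p, 0, 0.05)
    lt_init <- if (is.null(config$fix_theta)) stats::rnorm(1, 0, 0.2) else
      log(config$fix_theta)
    tau_init <- if (is.null(config$fix_tau)) 1 else config$fix_tau
    z_init <- rep(0, n_regions)
    lp0 <- sum(nb_log_pmf(as.vector(y),
                          rep(exp(design$log_offset + drop(design$X %*% alpha_init)),
                              ncol(y)),
                          exp(lt_init)))
    if (!is.finite(lp0)) stop("non-finite posterior at initial values")
    chains[[ch]] <- .nbicar_chain(
      y, design$X, design$log_offset, design$region_index,
      n_regions, region_cells, nb, comp, n_comp, edges,
      spec$icar,
      priors$alpha_sd, priors$log_theta_mean, priors$log_theta_sd,
      priors$tau_shape, priors$tau_rate,
      alpha_init, lt_init, z_init, tau_init,
      config$n_iter, config$n_burn, config$thin,
      !is.null(config$fix_theta), !is.null(config$fix_tau))
    colnames(chains[[ch]]$alpha) <- colnames(design$X)
    if (spec$icar) colnames(chains[[ch]]$z) <- regions$region_id
  }

  fit <- structure(list(spec = spec, chains = chains, design = design,
                        panel = panel, regions = regions, priors = priors,
                        config = config,
                        graph = if (spec$icar) graph else NULL),
                   class = "fireweek_fit")
  diag <- posterior_summary(fit)
  worst <- max(diag$rhat, na.rm = TRUE)
  if (is.finite(worst) && worst > 1.1) {
    warning(sprintf("largest split R-hat is %.3f (> 1.1); chains may not have converged",
                    worst))
  }
  fit$diagnostics <- diag
  fit
}

#' @export
print.fireweek_fit <- function(x, ...) {
  cat(sprintf("fireweek_fit: %s\n%d chains x %d retained draws, %d regions\n",
              format(x$spec), length(x$chains),
              length(x$chains[[1]]$log_theta), nrow(x$regions)))
  invisible(x)
}

# draws of one scalar/vector parameter as a (draw x chain) matrix or
# (draw x chain x column) array collapsed by column name
chain_matrix <- function(fit, what, column = NULL) {
  do.call(cbind, lapply(fit$chains, function(ch) {
    if (is.null(column)) ch[[what]] else ch[[what]][, column]
  }))
}

#' Pooled posterior draws of the fixed effects
#' @param fit a `fireweek_fit`.
#' @return matrix (all chains stacked) with one column per coefficient.
#' @export
alpha_draws <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "alpha"))
}

# split R-hat (Gelman-Rubin on half-chains)
split_rhat <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(half), j], m[seq.int(n - half + 1L, n), j])
  }))
  w <- mean(apply(sub, 2, stats::var))
  if (w == 0) return(1)
  b <- half * stats::var(colMeans(sub))
  sqrt(((half - 1) / half * w + b / half) / w)
}

# effective sample size via Geyer's initial positive sequence, per chain
ess_basic <- function(m) {
  total <- 0
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    n <- length(x)
    if (stats::var(x) == 0) { total <- total + n; next }
    rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                      demean = TRUE)$acf[-1]
    s <- 0
    k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair < 0) break
      s <- s + pair
      k <- k + 2
    }
    total <- total + n / (1 + 2 * s)
  }
  total
}

#' Posterior summary table
#'
#' Mean, sd, equal-tailed 95% credible interval, split R-hat and effective
#' sample size for every fixed effect, log(theta), and (for ICAR models) tau.
#'
#' @param fit a `fireweek_fit`.
#' @param transform optional function applied to draws before summarising.
#' @return data frame, one row per parameter.
#' @export
posterior_summary <- function(fit, transform = NULL) {
  params <- list()
  for (cn in colnames(fit$chains[[1]]$alpha)) {
    params[[cn]] <- chain_matrix(fit, "alpha", cn)
  }
  if (is.null(fit$config$fix_theta)) {
    params[["log_theta"]] <- chain_matrix(fit, "log_theta")
  }
  if (fit$spec$icar && is.null(fit$config$fix_tau)) {
    params[["tau"]] <- chain_matrix(fit, "tau")
  }
  rows <- lapply(names(params), function(nm) {
    m <- params[[nm]]
    if (!is.null(transform)) m <- transform(m)
    x <- as.vector(m)
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = nm, mean = mean(x), sd = stats::sd(x),
               ci_low = q[1], ci_high = q[2],
               rhat = if (ncol(m) >= 2) split_rhat(m) else NA_real_,
               ess = ess_basic(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior point estimates used for the DIC plug-in
#'
#' alpha and z by posterior (per-node) means; theta via the mean of
#' log(theta).
#'
#' @param fit a `fireweek_fit`.
#' @return list with `alpha`, `theta`, `z` (NULL for non-ICAR specs).
#' @export
posterior_point <- function(fit) {
  alpha_hat <- colMeans(alpha_draws(fit))
  theta_hat <- exp(mean(unlist(lapply(fit$chains, `[[`, "log_theta"))))
  z_hat <- if (fit$spec$icar) {
    colMeans(do.call(rbind, lapply(fit$chains, `[[`, "z")))
  } else NULL
  list(alpha = alpha_hat, theta = theta_hat, z = z_hat)
}

#' Deviance information criterion
#'
#' DIC = Dbar + pD with D = -2 log-likelihood, Dbar the posterior mean
#' deviance over the retained draws, and pD = Dbar - D(point estimate), the
#' point estimate being the posterior means (theta plugged in via the mean of
#' log theta, z via per-node means). The spatial effects are treated as
#' parameters, i.e. this is the conditional DIC commonly reported for random
#' effect models.
#'
#' @param fit a `fireweek_fit` with at least 100 retained draws.
#' @return list with `dic`, `p_d`, `dbar`.
#' @export
compute_dic <- function(fit) {
  ll <- unlist(lapply(fit$chains, `[[`, "log_lik"))
  if (length(ll) < 100L) {
    warning("fewer than 100 retained draws; DIC will be noisy")
  }
  dbar <- mean(-2 * ll)
  pt <- posterior_point(fit)
  d_hat <- -2 * log_likelihood(fit$panel, fit$design, pt$alpha, pt$theta, pt$z)
  p_d <- dbar - d_hat
  list(dic = dbar + p_d, p_d = p_d, dbar = dbar)
}

#' Fit and rank a set of candidate models by DIC
#'
#' @param panel a `fire_panel`.
#' @param regions labelled region table.
#' @param graph an `adjacency_graph`.
#' @param specs list of `model_spec`s (or model strings).
#' @param priors a `prior_spec`.
#' @param config an `mcmc_config`; each candidate is fitted with the same
#'   seed so ranks are reproducible.
#' @return list with `table` (data frame model/dic/p_d/dbar, DIC ascending),
#'   `best` (the winning `model_spec`), and `fits` (named list of
#'   `fireweek_fit`s; failed candidates are recorded as NULL with a warning).
#' @export
select_model <- function(panel, regions, graph, specs, priors = prior_spec(),
                         config = mcmc_config()) {
  if (length(specs) < 1L) stop("need at least one candidate model")
  specs <- lapply(specs, function(s) if (inherits(s, "model_spec")) s else
    model_spec(s))
  labels <- vapply(specs, format, character(1))
  fits <- stats::setNames(vector("list", length(specs)), labels)
  rows <- list()
  for (i in seq_along(specs)) {
    res <- tryCatch(
      fit_mcmc(panel, regions, graph, specs[[i]], priors, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("candidate ", labels[i], " failed: ", conditionMessage(res))
      next
    }
    fits[[i]] <- res
    d <- compute_dic(res)
    rows[[length(rows) + 1L]] <- data.frame(
      model = labels[i], dic = d$dic, p_d = d$p_d, dbar = d$dbar,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("every candidate model failed to fit")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dic), ]
  rownames(tab) <- NULL
  list(table = tab, best = specs[[match(tab$model[1], labels)]], fits = fits)
}
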