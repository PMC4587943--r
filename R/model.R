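# The probability model: negative binomial observation density, factor design
# matrices under corner (treatment) constraints, the ICAR improper Gaussian
# prior on the region adjacency graph, and the resulting log-likelihood and
# log-posterior.

MODEL_TERMS <- c("R", "W", "A", "R:W", "R:A", "W:A", "R:W:A")

#' Define a candidate model
#'
#' A model is a subset of the fixed-effect terms {R, W, A, R:W, R:A, W:A,
#' R:W:A} (R = religion, W = weekday, A = anthrome) plus an optional ICAR
#' spatial random effect. Interaction terms require their main effects.
#'
#' @param terms character vector of terms, or a single string such as
#'   `"R + W + R:W + ICAR"`.
#' @param icar logical; include the ICAR spatial effect. May also be given via
#'   an `"ICAR"` element of `terms`.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(terms, icar = FALSE) {
  if (length(terms) == 1L && grepl("\\+", terms)) {
    terms <- trimws(strsplit(terms, "+", fixed = TRUE)[[1]])
  }
  terms <- setdiff(trimws(terms), c("", "1"))  # "1" = intercept-only
  if ("ICAR" %in% terms) {
    icar <- TRUE
    terms <- setdiff(terms, "ICAR")
  }
  # canonicalise interaction order, e.g. "W:R" -> "R:W"
  terms <- vapply(terms, function(t) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    paste(parts[order(match(parts, c("R", "W", "A")))], collapse = ":")
  }, character(1), USE.NAMES = FALSE)
  bad <- setdiff(terms, MODEL_TERMS)
  if (length(bad) > 0L) stop("unknown model terms: ", paste(bad, collapse = ", "))
  terms <- MODEL_TERMS[MODEL_TERMS %in% terms]
  for (t in terms) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (length(parts) > 1L && !all(parts %in% terms)) {
      stop("interaction ", t, " requires its main effects in the model")
    }
  }
  structure(list(terms = terms, icar = icar), class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  if (length(x$terms) == 0L && !x$icar) return("1")
  paste(c(x$terms, if (x$icar) "ICAR"), collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec:", format(x), "\n")
  invisible(x)
}

#' Build the cell grid and design matrix for a model
#'
#' Expands labelled regions over the 7 weekdays into the (region, weekday)
#' cell grid and constructs the corner-constrained (treatment-coded) design
#' matrix for the requested terms. Reference levels are the first levels of
#' the fixed orders: religion Christian < Muslim < Mixed; weekday 1 (Monday)
#' ... 7 (Sunday); anthrome Cropland < Natural < Rangeland < Settled < Mixed.
#' Factors with a single observed level (e.g. anthrome within a per-anthrome
#' fit) contribute no columns for their main effect; the spec must then not
#' request interactions with that factor.
#'
#' @param regions labelled region table (needs `region_id`, `area_km2`,
#'   `religion_label`, `anthrome_label`).
#' @param spec a `model_spec`.
#' @return list with `X` (design matrix, one row per region-weekday cell),
#'   `cells` (data frame region_id/weekday/religion/anthrome),
#'   `log_offset` (per-cell log area), `region_index` (1-based region index
#'   per cell).
#' @export
build_design <- function(regions, spec) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(regions)
  cells <- data.frame(
    region_id = rep(regions$region_id, each = 7L),
    weekday = rep(1:7, times = n),
    stringsAsFactors = FALSE)
  rlv <- RELIGION_LEVELS[RELIGION_LEVELS %in% unique(regions$religion_label)]
  alv <- ANTHROME_LEVELS[ANTHROME_LEVELS %in% unique(regions$anthrome_label)]
  dat <- data.frame(
    R = factor(rep(regions$religion_label, each = 7L), levels = rlv),
    W = factor(cells$weekday, levels = 1:7),
    A = factor(rep(regions$anthrome_label, each = 7L), levels = alv))
  single <- c(R = length(rlv), W = 7L, A = length(alv)) < 2L
  for (t in spec$terms) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (any(single[parts]) && length(parts) > 1L) {
      stop("term ", t, " involves a factor with a single observed level")
    }
  }
  use <- spec$terms[vapply(spec$terms, function(t) {
    !(t %in% names(single)) || !single[[t]]
  }, logical(1))]
  fml <- if (length(use) == 0L) ~1 else
    stats::as.formula(paste("~", paste(use, collapse = " + ")))
  X <- stats::model.matrix(fml, dat)
  colnames(X)[1] <- "(Intercept)"
  list(X = X, cells = cbind(cells,
                            religion = as.character(dat$R),
                            anthrome = as.character(dat$A),
                            stringsAsFactors = FALSE),
       log_offset = rep(log(regions$area_km2), each = 7L),
       region_index = rep(seq_len(n), each = 7L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative binomial log-pmf (mean/shape parameterisation)
#'
#' log P(Y = y) for the negative binomial with mean `mu` and shape `theta`
#' (variance mu + mu^2/theta), computed on the log scale via `lgamma` so large
#' counts do not overflow.
#'
#' @param y non-negative integer count(s).
#' @param mu positive mean(s).
#' @param theta positive shape.
#' @return numeric vector of log-probabilities.
#' @export
nb_log_pmf <- function(y, mu, theta) {
  if (any(y < 0 | y != round(y))) stop("y must be a non-negative integer")
  stopifnot(all(mu > 0), all(theta > 0))
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    y * (log(mu) - log(mu + theta)) + theta * (log(theta) - log(mu + theta))
}

#' Per-cell log-mean of the count model
#'
#' ln mu = log area (offset) + X alpha + z, with the spatial effect expanded
#' from regions to cells.
#'
#' @param design output of [build_design()].
#' @param alpha coefficient vector matching `ncol(design$X)`.
#' @param z per-region spatial effects (0 if the model has no ICAR term).
#' @param as_mu return exp(log mu) instead of log mu.
#' @return numeric vector over cells.
#' @export
linear_predictor <- function(design, alpha, z = NULL, as_mu = FALSE) {
  if (length(alpha) != ncol(design$X)) {
    stop(sprintf("alpha has length %d, design has %d columns",
                 length(alpha), ncol(design$X)))
  }
  eta <- design$log_offset + unname(drop(design$X %*% alpha))
  if (!is.null(z)) {
    if (length(z) != max(design$region_index)) {
      stop("z must have one element per region")
    }
    eta <- eta + z[design$region_index]
  }
  if (as_mu) exp(eta) else eta
}

#' ICAR pairwise-difference quadratic form
#'
#' sum over graph edges (i, j) of (z_i - z_j)^2, i.e. z' (D - W) z with D the
#' degree matrix and W the adjacency matrix.
#'
#' @param z numeric vector indexed like `graph$ids`.
#' @param graph an `adjacency_graph`.
#' @return scalar quadratic form (0 when z is constant per component).
#' @export
icar_quadratic <- function(z, graph) {
  if (length(z) != length(graph$ids)) stop("z must match the graph's regions")
  if (nrow(graph$edges) == 0L) return(0)
  i <- match(graph$edges[, 1], graph$ids)
  j <- match(graph$edges[, 2], graph$ids)
  sum((z[i] - z[j])^2)
}

#' ICAR log-density
#'
#' Improper intrinsic Gaussian Markov random field log-density, up to an
#' additive constant: ((n - k) / 2) log tau - (tau / 2) z'(D - W)z, where k is
#' the number of connected components (the rank deficiency of the graph
#' Laplacian). Identification requires z to sum to zero within each component.
#'
#' @param z spatial effect vector.
#' @param tau positive precision.
#' @param graph an `adjacency_graph`.
#' @return scalar log-density (up to a constant).
#' @export
icar_log_density <- function(z, tau, graph) {
  stopifnot(tau > 0)
  n <- length(graph$ids)
  k <- graph$n_components
  ((n - k) / 2) * log(tau) - (tau / 2) * icar_quadratic(z, graph)
}

#' Model log-likelihood over a fire panel
#'
#' Sums the NB log-pmf over every (region, weekday, year) observation; the
#' mean mu is shared across years within a region-weekday cell.
#'
#' @param panel a `fire_panel` covering the regions in `design`.
#' @param design output of [build_design()].
#' @param alpha,theta,z model parameters (`z` optional).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(panel, design, alpha, theta, z = NULL) {
  eta <- linear_predictor(design, alpha, z)
  key <- paste(design$cells$region_id, design$cells$weekday, sep = "\r")
  idx <- match(paste(panel$region_id, panel$weekday, sep = "\r"), key)
  if (anyNA(idx)) stop("panel contains cells missing from the design")
  if (length(unique(panel$year)) * length(key) != nrow(panel)) {
    stop("panel is not a complete region x weekday x year grid for the design")
  }
  sum(nb_log_pmf(panel$count, exp(eta[idx]), theta))
}

#' Prior specification
#'
#' Weakly informative defaults in the style of the common Bayesian GLMM
#' engines: independent Normal(0, sd 31.6) on each fixed effect (precision
#' 0.001), Normal(0, sd 10) on log theta, Gamma(shape 1, rate 5e-5) on the
#' ICAR precision tau.
#'
#' @param alpha_sd normal prior sd per fixed-effect coefficient.
#' @param log_theta_mean,log_theta_sd normal prior on log theta.
#' @param tau_shape,tau_rate gamma prior on tau.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(alpha_sd = 31.6, log_theta_mean = 0, log_theta_sd = 10,
                       tau_shape = 1, tau_rate = 5e-5) {
  stopifnot(alpha_sd > 0, log_theta_sd > 0, tau_shape > 0, tau_rate > 0)
  structure(list(alpha_sd = alpha_sd, log_theta_mean = log_theta_mean,
                 log_theta_sd = log_theta_sd, tau_shape = tau_shape,
                 tau_rate = tau_rate),
            class = "prior_spec")
}

#' Joint log-posterior (up to a constant)
#'
#' log-likelihood + ICAR log-density (if the spec has the spatial term) +
#' log prior densities for alpha, log theta and tau.
#'
#' @param panel a `fire_panel`.
#' @param design output of [build_design()].
#' @param spec the `model_spec` (controls whether the ICAR term enters).
#' @param params list with `alpha`, `theta`, and (for ICAR models) `z`, `tau`.
#' @param priors a `prior_spec`.
#' @param graph an `adjacency_graph` (required for ICAR models).
#' @return scalar log-posterior; `-Inf` if `theta` or `tau` violate
#'   positivity.
#' @export
log_posterior <- function(panel, design, spec, params, priors, graph = NULL) {
  if (params$theta <= 0) return(-Inf)
  lp <- log_likelihood(panel, design, params$alpha, params$theta,
                       if (spec$icar) params$z else NULL)
  lp <- lp + sum(stats::dnorm(params$alpha, 0, priors$alpha_sd, log = TRUE))
  lp <- lp + stats::dnorm(log(params$theta), priors$log_theta_mean,
                          priors$log_theta_sd, log = TRUE)
  if (spec$icar) {
    if (is.null(graph)) stop("ICAR models need an adjacency graph")
    if (params$tau <= 0) return(-Inf)
    lp <- lp + icar_log_density(params$z, params$tau, graph)
    lp <- lp + stats::dgamma(params$tau, shape = priors$tau_shape,
                             rate = priors$tau_rate, log = TRUE)
  }
  lp
}
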