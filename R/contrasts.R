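# Religion x weekday contrasts: per-draw cell-mean differences, posterior
# contour probabilities of zero, credible intervals, and Benjamini-Hochberg
# adjustment over the contrast family.

WEEKDAY_ABBR <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
RELIGION_ABBR <- c(Christian = "Chr", Muslim = "Mus", Mixed = "Mix")

#' Define one religion-weekday contrast
#'
#' The contrast is the difference of log-scale cell means
#' (left religion, left weekday) minus (right religion, right weekday),
#' weekdays coded 1 = Monday ... 7 = Sunday.
#'
#' @param left_religion,right_religion religion labels
#'   (`Christian`/`Muslim`/`Mixed`).
#' @param left_weekday,right_weekday integers in 1..7.
#' @return an object of class `contrast_spec` with an auto-generated label
#'   such as `"Chr:Sun-Chr:Fri"`.
#' @export
contrast_spec <- function(left_religion, left_weekday,
                          right_religion, right_weekday) {
  stopifnot(left_religion %in% RELIGION_LEVELS,
            right_religion %in% RELIGION_LEVELS,
            left_weekday %in% 1:7, right_weekday %in% 1:7)
  if (left_religion == right_religion && left_weekday == right_weekday) {
    stop("contrast cells must differ")
  }
  label <- sprintf("%s:%s-%s:%s",
                   RELIGION_ABBR[[left_religion]], WEEKDAY_ABBR[left_weekday],
                   RELIGION_ABBR[[right_religion]], WEEKDAY_ABBR[right_weekday])
  structure(list(left = list(religion = left_religion,
                             weekday = as.integer(left_weekday)),
                 right = list(religion = right_religion,
                              weekday = as.integer(right_weekday)),
                 label = label),
            class = "contrast_spec")
}

# row of fixed-effect dummies for a (religion, weekday) cell, at the
# reference level of any anthrome terms; offset and spatial effect excluded
cell_design_row <- function(fit, religion, weekday) {
  cells <- fit$design$cells
  hit <- which(cells$religion == religion & cells$weekday == weekday)
  if (length(hit) == 0L) {
    stop("no fitted cell for religion ", religion, ", weekday ", weekday)
  }
  X <- fit$design$X[hit, , drop = FALSE]
  # anthrome main/interaction columns vary across regions; zero them so the
  # cell mean refers to the reference anthrome (for per-anthrome fits there
  # are none and every row is identical)
  acols <- grepl("^A|:A|A:", colnames(X))
  X[, acols] <- 0
  unique_rows <- unique(X)
  if (nrow(unique_rows) != 1L) {
    stop("cell mean is not unique for religion ", religion,
         ", weekday ", weekday)
  }
  drop(unique_rows[1, ])
}

#' Per-draw posterior samples of a cell-mean difference
#'
#' For each retained draw, evaluates the difference of log-scale cell means
#' between the contrast's two (religion, weekday) cells from the fixed
#' effects alone. The log-area offset and the spatial effects do not enter:
#' they are region-level quantities that cancel within a region and are
#' excluded across cells, so the contrast isolates the religion/weekday
#' structure.
#'
#' @param fit a `fireweek_fit` whose model contains R and W (and any
#'   interactions actually fitted).
#' @param contrast a `contrast_spec`.
#' @return numeric vector, one difference per retained draw (chains pooled).
#' @export
cell_mean_difference_samples <- function(fit, contrast) {
  stopifnot(inherits(contrast, "contrast_spec"))
  if (!all(c("R", "W") %in% fit$spec$terms)) {
    stop("contrasts need a model containing R and W")
  }
  for (side in c("left", "right")) {
    if (!contrast[[side]]$religion %in% fit$design$cells$religion) {
      stop("religion level ", contrast[[side]]$religion,
           " is absent from the fitted data")
    }
  }
  d <- cell_design_row(fit, contrast$left$religion, contrast$left$weekday) -
    cell_design_row(fit, contrast$right$religion, contrast$right$weekday)
  drop(alpha_draws(fit) %*% d)
}

#' Posterior contour probability of zero
#'
#' One minus the content of the highest-posterior-density interval that just
#' covers zero: the posterior probability that the density is at or below its
#' value at zero. Estimated from the draws by a Gaussian kernel density
#' estimate (Silverman's rule, FFT grid) as
#' mean over draws of 1\[f(x_s) <= f(0)\]. A normal-approximation variant
#' 2 Phi(-|mean| / sd) is returned alongside for transparency.
#'
#' @param diff_samples numeric vector of posterior draws (>= 1000 advised).
#' @return list with `p` (KDE estimate), `p_normal` (normal approximation).
#' @export
contour_probability <- function(diff_samples) {
  x <- diff_samples[is.finite(diff_samples)]
  if (length(x) < 2L || stats::sd(x) == 0) {
    warning("zero-variance contrast samples")
    p <- if (all(x == 0)) 1 else 0
    return(list(p = p, p_normal = p))
  }
  if (length(x) < 1000L) {
    warning("fewer than 1000 draws; contour probability will be noisy")
  }
  dens <- stats::density(x, bw = "nrd0", n = 4096,
                         from = min(c(x, 0)) - 3 * stats::bw.nrd0(x),
                         to = max(c(x, 0)) + 3 * stats::bw.nrd0(x))
  f <- stats::approxfun(dens$x, dens$y, rule = 2)
  p <- mean(f(x) <= f(0))
  z <- abs(mean(x)) / stats::sd(x)
  list(p = p, p_normal = 2 * stats::pnorm(-z))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment over one family of contour
#' probabilities: sorted ascending, the i-th smallest becomes
#' min over j >= i of p_(j) * m / j, capped at 1 and mapped back to input
#' order. Adjusted values are never smaller than raw values.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted vector, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p_values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' The study's 15-contrast suite
#'
#' Runs, in the fixed reporting order: Sunday minus every other weekday
#' within Christian regions (6 contrasts), Friday minus every other weekday
#' within Muslim regions (6), then Chr:Sun-Mus:Fri, Chr:Sun-Mix:Sun and
#' Mus:Fri-Mix:Fri. Contour probabilities are BH-adjusted jointly across all
#' contrasts actually run. Families whose religion level is absent from the
#' fitted data are skipped with a warning.
#'
#' @param fit a `fireweek_fit` of a model containing R and W (typically the
#'   best cropland-anthrome model, R + W + R:W + ICAR).
#' @param ci_level credible-interval level (default 0.95, equal-tailed).
#' @return data frame with one row per contrast: `contrast`, `mean`, `sd`,
#'   `ci_low`, `ci_high`, `p` (KDE contour probability), `p_normal`, `p_bh`.
#' @export
run_contrast_suite <- function(fit, ci_level = 0.95) {
  present <- unique(fit$design$cells$religion)
  suite <- list()
  add <- function(lr, lw, rr, rw) {
    if (!lr %in% present || !rr %in% present) {
      warning("skipping contrasts involving absent religion level: ",
              if (!lr %in% present) lr else rr)
      return()
    }
    suite[[length(suite) + 1L]] <<- contrast_spec(lr, lw, rr, rw)
  }
  for (w in 1:6) add("Christian", 7L, "Christian", w)
  for (w in c(1:4, 6:7)) add("Muslim", 5L, "Muslim", w)
  add("Christian", 7L, "Muslim", 5L)
  add("Christian", 7L, "Mixed", 7L)
  add("Muslim", 5L, "Mixed", 5L)
  if (length(suite) == 0L) stop("no contrast family can be run on this fit")
  a <- (1 - ci_level) / 2
  rows <- lapply(suite, function(cs) {
    s <- cell_mean_difference_samples(fit, cs)
    cp <- contour_probability(s)
    q <- stats::quantile(s, c(a, 1 - a), names = FALSE)
    data.frame(contrast = cs$label, mean = mean(s), sd = stats::sd(s),
               ci_low = q[1], ci_high = q[2], p = cp$p,
               p_normal = cp$p_normal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
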