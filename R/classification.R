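# Region labelling by dominant religion and dominant anthrome, exclusion
# rules, weekday minima and the religion x anthrome cross-tabulation.

RELIGION_LEVELS <- c("Christian", "Muslim", "Mixed")
ANTHROME_LEVELS <- c("Cropland", "Natural", "Rangeland", "Settled", "Mixed")

#' Classify a region's dominant religion
#'
#' A region is Christian (Muslim) when that faith exceeds 75% of the combined
#' Christian + Muslim share; Mixed otherwise. Regions where Christians and
#' Muslims together are less than 50% of the total population are flagged
#' `Excluded` (a weekly rest day is specific to these faiths, so the weekly
#' cycle hypothesis does not apply there), and regions with missing religion
#' data are flagged `MissingData`.
#'
#' @param frac_christian,frac_muslim shares of the *total* population, in
#'   \[0, 1\]; `NA` means the data are missing. Vectorised.
#' @return character vector over
#'   `{"Christian","Muslim","Mixed","Excluded","MissingData"}`.
#' @export
classify_religion <- function(frac_christian, frac_muslim) {
  n <- max(length(frac_christian), length(frac_muslim))
  frac_christian <- rep_len(frac_christian, n)
  frac_muslim <- rep_len(frac_muslim, n)
  if (any(frac_christian < 0 | frac_muslim < 0, na.rm = TRUE)) {
    stop("religion fractions must be non-negative")
  }
  if (any(frac_christian > 1 | frac_muslim > 1, na.rm = TRUE)) {
    stop("religion fractions must not exceed 1")
  }
  out <- rep(NA_character_, n)
  miss <- is.na(frac_christian) | is.na(frac_muslim)
  out[miss] <- "MissingData"
  tot <- frac_christian + frac_muslim
  low <- !miss & tot < 0.5
  out[low] <- "Excluded"
  rest <- !miss & !low
  share_chr <- frac_christian[rest] / tot[rest]
  out[rest] <- ifelse(share_chr > 0.75, "Christian",
                      ifelse(1 - share_chr > 0.75, "Muslim", "Mixed"))
  out
}

#' Classify a region's dominant anthrome
#'
#' The label is the aggregated anthrome class covering at least 50% of the
#' region's area; if no class reaches 50% the region is `Mixed`. The single
#' possible two-way tie (two classes at exactly 0.5) is broken by the fixed
#' preference order Cropland > Natural > Rangeland > Settled, with a warning.
#'
#' @param fracs named numeric vector (or single-row data frame) of area
#'   fractions over `Cropland`, `Natural`, `Rangeland`, `Settled`, summing
#'   to 1 within `tol`.
#' @param tol tolerance on the fraction sum.
#' @return one of `"Cropland"`, `"Natural"`, `"Rangeland"`, `"Settled"`,
#'   `"Mixed"`.
#' @export
classify_anthrome <- function(fracs, tol = 1e-6) {
  fracs <- unlist(fracs)[ANTHROME_CLASSES]
  if (anyNA(fracs)) stop("fracs must cover all of: ",
                         paste(ANTHROME_CLASSES, collapse = ", "))
  if (any(fracs < 0)) stop("anthrome fractions must be non-negative")
  if (abs(sum(fracs) - 1) > tol) {
    stop(sprintf("anthrome fractions sum to %.6f, expected 1", sum(fracs)))
  }
  qualifying <- which(fracs >= 0.5)
  if (length(qualifying) == 0L) return("Mixed")
  if (length(qualifying) > 1L) {
    warning("two anthrome classes tie at exactly 0.5; preferring ",
            ANTHROME_CLASSES[qualifying[1L]])
  }
  ANTHROME_CLASSES[qualifying[1L]]
}

#' Label every region by religion and anthrome
#'
#' Adds `religion_label` and `anthrome_label` columns to a region table.
#'
#' @param regions a `region_table`.
#' @return the region table with the two label columns appended.
#' @export
label_regions <- function(regions) {
  regions$religion_label <- classify_religion(regions$frac_christian,
                                              regions$frac_muslim)
  regions$anthrome_label <- vapply(seq_len(nrow(regions)), function(i) {
    classify_anthrome(c(Cropland  = regions$frac_cropland[i],
                        Natural   = regions$frac_natural[i],
                        Rangeland = regions$frac_rangeland[i],
                        Settled   = regions$frac_settled[i]))
  }, character(1))
  regions
}

#' Apply the study's region exclusion rules
#'
#' Removes regions in three ordered passes, attributing each excluded region
#' to the first rule it fails: (1) cumulative fire density below 0.1 counts
#' per square km over the whole study period; (2) Christian + Muslim share of
#' the population below 50% (`religion_label == "Excluded"`); (3) missing
#' religion data.
#'
#' @param regions a labelled region table (see [label_regions()]; labels are
#'   computed on the fly if absent).
#' @param panel a `fire_panel` covering all regions.
#' @param density_threshold minimum cumulative fire count density (counts per
#'   square km, all years and weekdays pooled); default 0.1.
#' @return list with `retained` (the surviving region table), `excluded`
#'   (region_id + rule), and `report` (named counts per rule).
#' @export
apply_exclusions <- function(regions, panel, density_threshold = 0.1) {
  if (is.null(regions$religion_label)) regions <- label_regions(regions)
  totals <- rowSums(panel_weekday_totals(panel))
  totals <- totals[regions$region_id]
  if (anyNA(totals)) stop("panel does not cover all regions")
  density <- totals / regions$area_km2
  rule <- rep(NA_character_, nrow(regions))
  rule[density < density_threshold] <- "low_fire_density"
  rule[is.na(rule) & regions$religion_label == "Excluded"] <- "low_christian_muslim_share"
  rule[is.na(rule) & regions$religion_label == "MissingData"] <- "missing_religion_data"
  excluded <- data.frame(region_id = regions$region_id[!is.na(rule)],
                         rule = rule[!is.na(rule)],
                         stringsAsFactors = FALSE)
  report <- c(low_fire_density = sum(rule == "low_fire_density", na.rm = TRUE),
              low_christian_muslim_share =
                sum(rule == "low_christian_muslim_share", na.rm = TRUE),
              missing_religion_data =
                sum(rule == "missing_religion_data", na.rm = TRUE))
  retained <- regions[is.na(rule), ]
  rownames(retained) <- NULL
  list(retained = retained, excluded = excluded, report = report)
}

#' Weekday with the fewest fires in a region
#'
#' Sums counts across years and returns the weekday (1 = Monday ... 7 =
#' Sunday) with the minimum total; ties resolve to the smallest index and set
#' the tie flag.
#'
#' @param panel a `fire_panel`.
#' @param region_id a single region id present in the panel.
#' @return list with `weekday` (integer in 1..7) and `tie` (logical).
#' @export
weekday_minimum <- function(panel, region_id) {
  totals <- panel_weekday_totals(panel)
  if (!region_id %in% rownames(totals)) stop("unknown region: ", region_id)
  x <- totals[region_id, ]
  w <- which.min(x)
  list(weekday = as.integer(w), tie = sum(x == x[w]) > 1L)
}

#' Cross-tabulate regions by religion and anthrome
#'
#' Builds the (anthrome x religion) table of region counts with row and column
#' margins, as used to summarise the analysed region set.
#'
#' @param regions a labelled region table whose `religion_label` values are
#'   all in `{Christian, Muslim, Mixed}`.
#' @return integer matrix with anthrome rows (plus `Total`) and religion
#'   columns (plus `Total`).
#' @export
crosstab_regions <- function(regions) {
  if (is.null(regions$religion_label) || is.null(regions$anthrome_label) ||
      anyNA(regions$religion_label) || anyNA(regions$anthrome_label)) {
    stop("all regions must carry religion and anthrome labels")
  }
  bad <- setdiff(unique(regions$religion_label), RELIGION_LEVELS)
  if (length(bad) > 0L) {
    stop("regions with non-analysis religion labels present: ",
         paste(bad, collapse = ", "), " (run apply_exclusions first)")
  }
  tab <- table(factor(regions$anthrome_label, levels = ANTHROME_LEVELS),
               factor(regions$religion_label, levels = RELIGION_LEVELS))
  m <- as.matrix(unclass(tab))
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Anthrome shares of the analysed regions
#'
#' @param crosstab output of [crosstab_regions()].
#' @return named numeric vector of each anthrome's share (in percent) of the
#'   total region count.
#' @export
anthrome_shares <- function(crosstab) {
  totals <- crosstab[ANTHROME_LEVELS, "Total"]
  100 * totals / crosstab["Total", "Total"]
}
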