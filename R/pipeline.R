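# End-to-end orchestration: classification -> global model selection ->
# per-anthrome model selection -> contrast suite on the best cropland model,
# with seeded, hash-stamped CSV outputs.

#' The enumerated global model space
#'
#' The twelve candidate fixed-effect structures over religion (R), weekday
#' (W) and anthrome (A): all main effects plus every reported combination of
#' the two- and three-way interactions, each with and without the ICAR term.
#' @return character vector of model strings.
#' @export
global_model_space <- function() {
  c("R + W + A + R:W + R:A + W:A + R:W:A + ICAR",
    "R + W + A + R:W + R:A + W:A + R:W:A",
    "R + W + A + R:W + R:A + W:A + ICAR",
    "R + W + A + R:W + R:A + W:A",
    "R + W + A + R:W + R:A + ICAR",
    "R + W + A + R:W + R:A",
    "R + W + A + R:W + W:A + ICAR",
    "R + W + A + R:W + W:A",
    "R + W + A + R:W + ICAR",
    "R + W + A + R:W",
    "R + W + A + ICAR",
    "R + W + A")
}

#' The per-anthrome model space
#'
#' The four candidates fitted within each anthrome stratum: religion and
#' weekday main effects, with and without their interaction, each with and
#' without the ICAR term.
#' @return character vector of model strings.
#' @export
anthrome_model_space <- function() {
  c("R + W + R:W + ICAR", "R + W + R:W", "R + W + ICAR", "R + W")
}

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param simulate optional `simulation_config`; when given, inputs are
#'   simulated instead of read from files.
#' @param regions_csv,counts_csv,adjacency_csv input paths (ignored when
#'   `simulate` is given).
#' @param global_models,anthrome_models candidate model strings.
#' @param priors a `prior_spec`.
#' @param mcmc an `mcmc_config` (its seed is the pipeline seed).
#' @param per_anthrome run the per-anthrome stratified selection.
#' @param run_contrasts run the contrast suite on the best cropland model.
#' @param min_stratum_regions smallest stratum worth fitting.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, regions_csv = NULL,
                            counts_csv = NULL, adjacency_csv = NULL,
                            global_models = global_model_space(),
                            anthrome_models = anthrome_model_space(),
                            priors = prior_spec(), mcmc = mcmc_config(),
                            per_anthrome = TRUE, run_contrasts = TRUE,
                            min_stratum_regions = 20L) {
  if (is.null(simulate) &&
      (is.null(regions_csv) || is.null(counts_csv) || is.null(adjacency_csv))) {
    stop("provide either `simulate` or all three input CSV paths")
  }
  if (length(global_models) == 0L && length(anthrome_models) == 0L) {
    stop("candidate model list must be non-empty")
  }
  structure(list(out_dir = out_dir, simulate = simulate,
                 regions_csv = regions_csv, counts_csv = counts_csv,
                 adjacency_csv = adjacency_csv,
                 global_models = global_models,
                 anthrome_models = anthrome_models,
                 priors = priors, mcmc = mcmc,
                 per_anthrome = isTRUE(per_anthrome),
                 run_contrasts = isTRUE(run_contrasts),
                 min_stratum_regions = as.integer(min_stratum_regions)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # stable short fingerprint of the analysis configuration (for output
  # provenance); the output directory itself does not affect the analysis
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
             collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

write_stamped_csv <- function(df, path, seed, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# seed=%d config_hash=%s", seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full weekly-cycle analysis
#'
#' Executes the stages in dependency order: load or simulate inputs; label
#' regions and apply the exclusion rules; write the religion x anthrome
#' cross-tabulation and per-region weekday minima; rank the global candidate
#' models by DIC; rank the per-anthrome candidates within each sufficiently
#' large stratum; and, when the best cropland model contains the
#' religion x weekday interaction, run the 15-contrast suite on it. Every
#' output CSV is stamped with the seed and a configuration hash.
#'
#' @param config a `pipeline_config`.
#' @return list with `retained` regions, `exclusions` report, `crosstab`,
#'   `global` selection, `per_anthrome` selections, `contrasts` (NULL when
#'   not run), and `out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$mcmc$seed
  hash <- config_hash(config)
  stage <- "load_inputs"
  on_fail <- function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s)",
                 stage, conditionMessage(e), config$out_dir), call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$simulate)) {
      sys <- generate_regions(config$simulate)
      sim <- simulate_counts(sys$regions, sys$graph, config$simulate)
      regions <- sim$regions
      panel <- sim$panel
      graph <- sys$graph
    } else {
      regions <- label_regions(read_region_table(config$regions_csv))
      panel <- read_fire_counts(config$counts_csv, regions)
      graph <- build_adjacency(config$adjacency_csv, regions$region_id)
    }

    stage <- "classify"
    excl <- apply_exclusions(regions, panel)
    retained <- excl$retained
    write_stamped_csv(retained, file.path(config$out_dir, "labelled_regions.csv"),
                      seed, hash)
    write_stamped_csv(excl$excluded, file.path(config$out_dir, "exclusions.csv"),
                      seed, hash)
    ct <- crosstab_regions(retained)
    write_stamped_csv(data.frame(anthrome = rownames(ct), ct,
                                 check.names = FALSE),
                      file.path(config$out_dir, "crosstab.csv"), seed, hash)
    minima <- do.call(rbind, lapply(retained$region_id, function(id) {
      wm <- weekday_minimum(panel, id)
      data.frame(region_id = id, weekday = wm$weekday, tie = wm$tie)
    }))
    write_stamped_csv(minima, file.path(config$out_dir, "weekday_minima.csv"),
                      seed, hash)
    panel_kept <- make_fire_panel(
      panel[panel$region_id %in% retained$region_id, , drop = FALSE],
      retained$region_id, attr(panel, "years"))

    stage <- "global_model_selection"
    global <- NULL
    if (length(config$global_models) > 0L) {
      global <- select_model(panel_kept, retained, graph,
                             as.list(config$global_models),
                             config$priors, config$mcmc)
      write_stamped_csv(global$table,
                        file.path(config$out_dir, "model_table_global.csv"),
                        seed, hash)
    }

    stage <- "per_anthrome_model_selection"
    per_anthrome <- list()
    if (config$per_anthrome) {
      for (a in ANTHROME_LEVELS) {
        sub <- retained[retained$anthrome_label == a, , drop = FALSE]
        if (nrow(sub) < config$min_stratum_regions ||
            length(unique(sub$religion_label)) < 2L) next
        sub_panel <- make_fire_panel(
          panel[panel$region_id %in% sub$region_id, , drop = FALSE],
          sub$region_id, attr(panel, "years"))
        per_anthrome[[a]] <- select_model(sub_panel, sub, graph,
                                          as.list(config$anthrome_models),
                                          config$priors, config$mcmc)
        write_stamped_csv(per_anthrome[[a]]$table,
                          file.path(config$out_dir,
                                    sprintf("model_table_%s.csv", tolower(a))),
                          seed, hash)
      }
    }

    stage <- "contrasts"
    contrasts <- NULL
    cpath <- file.path(config$out_dir, "contrasts.csv")
    if (config$run_contrasts && !is.null(per_anthrome$Cropland)) {
      best <- per_anthrome$Cropland$best
      if ("R:W" %in% best$terms) {
        fit <- per_anthrome$Cropland$fits[[format(best)]]
        contrasts <- run_contrast_suite(fit)
        write_stamped_csv(contrasts, cpath, seed, hash)
      } else {
        empty <- data.frame(contrast = character(), mean = numeric(),
                            sd = numeric(), ci_low = numeric(),
                            ci_high = numeric(), p = numeric(),
                            p_normal = numeric(), p_bh = numeric())
        write_stamped_csv(empty, cpath, seed, hash)
        cat(sprintf("# best cropland model (%s) lacks R:W; contrast suite not run\n",
                    format(best)),
            file = cpath, append = TRUE)
      }
    }

    stage <- "run_log"
    log <- list(seed = seed, config_hash = hash,
                r_version = as.character(getRversion()),
                package_version = as.character(utils::packageVersion("fireweek")),
                timestamp = format(Sys.time(), tz = "UTC"),
                n_regions_retained = nrow(retained),
                exclusion_report = as.list(excl$report))
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(retained = retained, exclusions = excl, crosstab = ct,
         global = global, per_anthrome = per_anthrome,
         contrasts = contrasts, out_dir = config$out_dir)
  }, error = on_fail)
}
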