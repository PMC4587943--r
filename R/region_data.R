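# Data model and I/O for regions, adjacency and fire-count panels.

ANTHROME_CLASSES <- c("Cropland", "Natural", "Rangeland", "Settled")

REGION_COLUMNS <- c("region_id", "area_km2",
                    "frac_christian", "frac_muslim", "frac_other",
                    "frac_cropland", "frac_natural", "frac_rangeland",
                    "frac_settled")

#' Read a region table
#'
#' Reads a CSV of administrative regions with area, religion shares and
#' aggregated anthrome (anthropogenic biome) area fractions. Expected columns:
#' `region_id`, `area_km2`, `frac_christian`, `frac_muslim`, `frac_other`,
#' `frac_cropland`, `frac_natural`, `frac_rangeland`, `frac_settled`.
#' Religion fractions are shares of total population; empty cells are read as
#' `NA` and mean the religion data are missing for that region (a value of 0 is
#' a legitimate share, so missing and zero are distinct).
#'
#' @param path path to a CSV file with the columns above.
#' @return a `data.frame` of class `region_table`, one row per region.
#' @export
read_region_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "character"))
  missing_cols <- setdiff(REGION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("region table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  as_region_table(df[REGION_COLUMNS])
}

#' Validate a region table
#'
#' Checks the invariants of a region table data frame (unique ids, positive
#' areas, fractions in \[0, 1\], anthrome fractions summing to one) and stamps
#' the `region_table` class.
#'
#' @param df a data frame with the region-table columns.
#' @param tol tolerance on the anthrome fraction sum.
#' @return `df`, validated, with class `region_table`.
#' @export
as_region_table <- function(df, tol = 1e-6) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REGION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("region table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$region_id <- as.character(df$region_id)
  dup <- duplicated(df$region_id)
  if (any(dup)) {
    stop("duplicate region_id: ", paste(unique(df$region_id[dup]), collapse = ", "))
  }
  check_col <- function(col, test, what) {
    x <- df[[col]]
    bad <- which(!is.na(x) & !test(x))
    if (length(bad) > 0L) {
      stop(sprintf("row %d, column %s: %s (value %s)",
                   bad[1L], col, what, format(x[bad[1L]])))
    }
  }
  bad_area <- which(is.na(df$area_km2) | df$area_km2 <= 0)
  if (length(bad_area) > 0L) {
    stop(sprintf("row %d, column area_km2: area must be a positive number",
                 bad_area[1L]))
  }
  frac_cols <- setdiff(REGION_COLUMNS, c("region_id", "area_km2"))
  for (col in frac_cols) {
    check_col(col, function(x) x >= 0 & x <= 1, "fraction outside [0, 1]")
  }
  # religion fractions: either all present or treated as missing together
  rel <- df[, c("frac_christian", "frac_muslim", "frac_other")]
  known <- stats::complete.cases(rel)
  over <- which(known & rowSums(rel) > 1 + tol)
  if (length(over) > 0L) {
    stop(sprintf("row %d: religion fractions sum to %.6f > 1", over[1L],
                 rowSums(rel)[over[1L]]))
  }
  ant <- df[, c("frac_cropland", "frac_natural", "frac_rangeland", "frac_settled")]
  if (anyNA(ant)) stop("anthrome fractions may not be missing")
  bad_sum <- which(abs(rowSums(ant) - 1) > tol)
  if (length(bad_sum) > 0L) {
    stop(sprintf("row %d: anthrome fractions sum to %.6f, expected 1",
                 bad_sum[1L], rowSums(ant)[bad_sum[1L]]))
  }
  class(df) <- c("region_table", "data.frame")
  df
}

#' Write a region table to CSV
#'
#' Inverse of [read_region_table()]; missing religion data are written as empty
#' cells so a read-write-read cycle is the identity.
#'
#' @param regions a `region_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  utils::write.csv(as.data.frame(regions)[REGION_COLUMNS], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-form fire-count file into a dense panel
#'
#' Reads `region_id, year, weekday, count` records and densifies them into a
#' complete (region x weekday x year) panel; combinations absent from the file
#' become explicit zeros (reported via a message). Weekdays are coded
#' 1 = Monday ... 7 = Sunday.
#'
#' @param path path to a CSV with columns `region_id`, `year`, `weekday`, `count`.
#' @param regions a `region_table` (or character vector of region ids) defining
#'   the region universe; ids in the file must belong to it.
#' @param years integer vector of years the panel must cover; defaults to the
#'   years present in the file.
#' @return a `fire_panel`: a complete long data frame with attributes
#'   `region_ids` and `years`.
#' @export
read_fire_counts <- function(path, regions, years = NULL) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "character"))
  need <- c("region_id", "year", "weekday", "count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("count file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  region_ids <- if (is.data.frame(regions)) regions$region_id else as.character(regions)
  if (is.null(years)) years <- sort(unique(df$year))
  make_fire_panel(df[need], region_ids, years)
}

#' Build a dense fire-count panel from long records
#'
#' @param df data frame with `region_id`, `year`, `weekday`, `count`.
#' @param region_ids character vector of all region ids.
#' @param years integer vector of all years.
#' @return a `fire_panel` data frame (complete index, zeros explicit).
#' @export
make_fire_panel <- function(df, region_ids, years) {
  region_ids <- as.character(region_ids)
  years <- sort(as.integer(years))
  unknown <- setdiff(unique(df$region_id), region_ids)
  if (length(unknown) > 0L) {
    stop("unknown region_id in counts: ", paste(unknown, collapse = ", "))
  }
  if (nrow(df) > 0L) {
    if (any(df$weekday < 1L | df$weekday > 7L | df$weekday != round(df$weekday))) {
      stop("weekday must be an integer in 1..7 (1 = Monday ... 7 = Sunday)")
    }
    if (any(is.na(df$count) | df$count < 0 | df$count != round(df$count))) {
      stop("count must be a non-negative integer")
    }
    if (any(!df$year %in% years)) {
      stop("year outside panel years: ",
           paste(setdiff(unique(df$year), years), collapse = ", "))
    }
    key <- paste(df$region_id, df$year, df$weekday, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (region_id, year, weekday) record: ",
           gsub("\r", "/", key[duplicated(key)][1L]))
    }
  }
  full <- expand.grid(region_id = region_ids, weekday = 1:7, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full_key <- paste(full$region_id, full$year, full$weekday, sep = "\r")
  full$count <- 0L
  if (nrow(df) > 0L) {
    idx <- match(paste(df$region_id, df$year, df$weekday, sep = "\r"), full_key)
    full$count[idx] <- as.integer(df$count)
    n_filled <- nrow(full) - nrow(df)
    if (n_filled > 0L) {
      message(sprintf("filled %d absent (region, weekday, year) cells with 0", n_filled))
    }
  }
  full <- full[order(full$region_id, full$year, full$weekday), ]
  rownames(full) <- NULL
  structure(full, region_ids = region_ids, years = years,
            class = c("fire_panel", "data.frame"))
}

#' Cast a fire panel to a region x weekday matrix of totals across years
#' @param panel a `fire_panel`.
#' @return integer matrix with region ids as rows and weekdays 1..7 as columns.
#' @export
panel_weekday_totals <- function(panel) {
  region_ids <- attr(panel, "region_ids")
  m <- tapply(panel$count, list(factor(panel$region_id, levels = region_ids),
                                factor(panel$weekday, levels = 1:7)), sum)
  m[is.na(m)] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Build a region adjacency graph
#'
#' Constructs the symmetric neighbourhood graph used by the ICAR spatial
#' random effect. Input is either a two-column edge list (data frame, matrix,
#' or CSV path with columns `region_id_a`, `region_id_b`) or, for polygon
#' input, a named list of coordinate matrices / a GeoJSON file, from which
#' queen contiguity (sharing at least one boundary point) is derived.
#'
#' @param x edge list / edge CSV path / named list of polygon coordinate
#'   matrices / GeoJSON path.
#' @param region_ids character vector of all region ids (isolated regions are
#'   kept as singleton components).
#' @return an `adjacency_graph`: list with `ids`, `edges` (2-column character
#'   matrix, each undirected edge once), `neighbours` (list of integer index
#'   vectors), `component` (integer component label per region) and
#'   `n_components`.
#' @export
build_adjacency <- function(x, region_ids) {
  region_ids <- as.character(region_ids)
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.(geojson|json)$", x, ignore.case = TRUE)) {
      x <- read_geojson_polygons(x)
    } else {
      x <- utils::read.csv(x, stringsAsFactors = FALSE,
                           colClasses = "character")
    }
  }
  if (is.list(x) && !is.data.frame(x) && (is.null(dim(x[[1]])) || is.matrix(x[[1]]))) {
    edges <- polygon_queen_edges(x)
  } else if (is.data.frame(x) || is.matrix(x)) {
    edges <- as.matrix(x)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
  } else {
    stop("unsupported adjacency input")
  }
  if (nrow(edges) > 0L) {
    unknown <- setdiff(unique(c(edges)), region_ids)
    if (length(unknown) > 0L) {
      stop("edge references unknown region_id: ", paste(unknown, collapse = ", "))
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edges are not allowed")
    # canonical undirected form, deduplicated
    lo <- pmin(edges[, 1], edges[, 2])
    hi <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(lo, hi, sep = "\r"))
    edges <- cbind(lo[keep], hi[keep])
  }
  g <- igraph::make_empty_graph(n = length(region_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = region_ids)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  nb <- lapply(igraph::adjacent_vertices(g, seq_along(region_ids)), as.integer)
  names(nb) <- region_ids
  structure(list(ids = region_ids, edges = edges, neighbours = nb,
                 component = as.integer(comp$membership),
                 n_components = comp$no),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency_graph: %d regions, %d edges, %d components\n",
              length(x$ids), nrow(x$edges), x$n_components))
  invisible(x)
}

# queen contiguity on coordinate-ring polygons: adjacency = sharing at least
# one boundary vertex (exact for lattice/fixture polygons with conforming rings)
polygon_queen_edges <- function(polys) {
  ids <- names(polys)
  if (is.null(ids)) stop("polygon list must be named by region_id")
  vkey <- lapply(polys, function(p) {
    p <- as.matrix(p)
    unique(paste(format(p[, 1], digits = 12), format(p[, 2], digits = 12)))
  })
  n <- length(polys)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (any(vkey[[i]] %in% vkey[[j]])) out[[length(out) + 1L]] <- c(ids[i], ids[j])
    }
  }
  if (length(out) == 0L) return(matrix(character(), ncol = 2))
  do.call(rbind, out)
}

read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  polys <- list()
  for (f in feats) {
    id <- f$properties$region_id
    if (is.null(id)) stop("GeoJSON feature lacks a region_id property")
    geom <- f$geometry
    ring <- if (geom$type == "Polygon") geom$coordinates[[1]] else
      stop("only Polygon geometries are supported")
    polys[[id]] <- do.call(rbind, lapply(ring, function(pt) unlist(pt)))
  }
  polys
}

#' Aggregate fine Anthromes classes into the four analysis classes
#'
#' Collapses the top-level Anthromes legend into the four classes used for
#' region labelling: Dense Settlements + Villages -> Settled, Forested +
#' Wildlands -> Natural; Croplands and Rangelands pass through unchanged.
#' The result is renormalised to sum to exactly 1.
#'
#' @param raw_fracs named numeric vector of area fractions over the fine
#'   classes `DenseSettlements`, `Villages`, `Croplands`, `Rangelands`,
#'   `Forested`, `Wildlands` (absent classes count as 0).
#' @param tol tolerance on the input sum's deviation from 1.
#' @return named numeric vector over `Cropland`, `Natural`, `Rangeland`,
#'   `Settled`, summing to 1.
#' @export
aggregate_anthromes <- function(raw_fracs, tol = 0.01) {
  fine <- c("DenseSettlements", "Villages", "Croplands", "Rangelands",
            "Forested", "Wildlands")
  if (is.null(names(raw_fracs)) || any(!names(raw_fracs) %in% fine)) {
    stop("raw_fracs must be named with classes: ", paste(fine, collapse = ", "))
  }
  if (any(raw_fracs < 0)) stop("anthrome fractions must be non-negative")
  x <- stats::setNames(numeric(length(fine)), fine)
  x[names(raw_fracs)] <- raw_fracs
  total <- sum(x)
  if (abs(total - 1) > tol) {
    stop(sprintf("anthrome fractions sum to %.4f, outside 1 +/- %.3g", total, tol))
  }
  out <- c(Cropland  = unname(x["Croplands"]),
           Natural   = unname(x["Forested"] + x["Wildlands"]),
           Rangeland = unname(x["Rangelands"]),
           Settled   = unname(x["DenseSettlements"] + x["Villages"]))
  out / total
}
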