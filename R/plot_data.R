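#' Construct a forest plot data object
#'
#' A `plot_data` object is the unit of all dynamics computations: plot-level
#' metadata together with a stem table (one row per tree, taxonomy and wood
#' density) and a long measurement table (one row per tree per census where
#' the tree was recorded).
#'
#' @param plot_id Plot identifier (character).
#' @param area_ha Plot area in hectares, corrected for topography.
#' @param edge_distance_m Distance from plot centre to the nearest
#'   anthropogenic forest edge, in metres.
#' @param min_diameter_cm Minimum diameter threshold of the census protocol
#'   (10 cm for most plots; 15 cm where small stems were never measured).
#' @param stems data.frame with columns `tag`, `family`, `genus`, `species`,
#'   `monocot` and optionally `wood_density`, `wd_level`.
#' @param measurements data.frame with columns `tag`, `census_date` (decimal
#'   years), `diameter` (cm at POM), `pom` (m), `status` (one of `"alive"`,
#'   `"recruit"`, `"dead"`, `"unobserved"`), `flag` (one of `"accepted"`,
#'   `"corrected"`, `"estimated"`), and `diameter_new`/`pom_new` holding the
#'   dual measurement recorded when the point of measurement was moved.
#' @param census_dates Optional numeric vector of plot census dates; derived
#'   from the measurements when omitted.
#' @param forest_type Optional forest-type label (e.g. `"moist_dipterocarp"`).
#'
#' @return An object of class `plot_data`.
#' @export
plot_data <- function(plot_id, area_ha, edge_distance_m, min_diameter_cm = 10,
                      stems = empty_stem_table(),
                      measurements = empty_measurement_table(),
                      census_dates = NULL, forest_type = NA_character_) {
  stems <- as.data.frame(stems, stringsAsFactors = FALSE)
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  for (col in c("wood_density", "wd_level")) {
    if (is.null(stems[[col]])) {
      stems[[col]] <- if (col == "wd_level") NA_character_ else NA_real_
    }
  }
  for (col in c("flag")) {
    if (is.null(measurements[[col]])) measurements[[col]] <- "accepted"
  }
  for (col in c("diameter_new", "pom_new")) {
    if (is.null(measurements[[col]])) measurements[[col]] <- NA_real_
  }
  if (nrow(measurements)) {
    measurements <- measurements[order(measurements$tag,
                                       measurements$census_date), ,
                                 drop = FALSE]
    rownames(measurements) <- NULL
  }
  if (is.null(census_dates)) {
    census_dates <- sort(unique(measurements$census_date))
  }
  x <- structure(list(
    plot_id = as.character(plot_id),
    area = as.numeric(area_ha),
    edge_distance = as.numeric(edge_distance_m),
    min_diameter = as.numeric(min_diameter_cm),
    forest_type = forest_type,
    census_dates = as.numeric(census_dates),
    stems = stems,
    measurements = measurements
  ), class = "plot_data")
  problems <- validate_plot_data(x)
  if (length(problems)) {
    stop("invalid plot_data for plot '", plot_id, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  x
}

empty_stem_table <- function() {
  data.frame(tag = character(), family = character(), genus = character(),
             species = character(), monocot = logical(),
             wood_density = numeric(), wd_level = character(),
             stringsAsFactors = FALSE)
}

empty_measurement_table <- function() {
  data.frame(tag = character(), census_date = numeric(), diameter = numeric(),
             pom = numeric(), status = character(), flag = character(),
             diameter_new = numeric(), pom_new = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate a plot_data object
#'
#' Checks the structural invariants of a plot: positive area, at least two
#' censuses (when the plot has any trees), measurement dates drawn from the
#' plot census dates, positive diameters for live records, strictly
#' increasing dates within a tree, at most one alive-to-dead transition per
#' tree, and first-record diameters at or above the plot minimum diameter.
#'
#' @param x A `plot_data` object.
#' @return Character vector of problems (empty when valid). Measurement-level
#'   problems name the offending row numbers of `x$measurements`.
#' @export
validate_plot_data <- function(x) {
  problems <- character()
  m <- x$measurements
  if (!is.finite(x$area) || x$area <= 0) {
    problems <- c(problems, "area must be > 0")
  }
  if (nrow(m) && length(x$census_dates) < 2) {
    problems <- c(problems, "plot must have at least 2 census dates")
  }
  if (!nrow(m)) return(problems)
  bad <- which(!(m$census_date %in% x$census_dates))
  if (length(bad)) {
    problems <- c(problems, paste0("measurement dates not in census dates: rows ",
                                   paste(bad, collapse = ", ")))
  }
  live <- m$status %in% c("alive", "recruit")
  bad <- which(live & (!is.finite(m$diameter) | m$diameter <= 0))
  if (length(bad)) {
    problems <- c(problems, paste0("non-positive diameter on live record: rows ",
                                   paste(bad, collapse = ", ")))
  }
  unknown <- which(!m$status %in% c("alive", "recruit", "dead", "unobserved"))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown status: rows ",
                                   paste(unknown, collapse = ", ")))
  }
  by_tree <- split(seq_len(nrow(m)), m$tag)
  for (idx in by_tree) {
    dates <- m$census_date[idx]
    if (any(diff(dates) <= 0)) {
      problems <- c(problems, paste0("census dates not strictly increasing within tree: rows ",
                                     paste(idx, collapse = ", ")))
    }
    dead <- m$status[idx] == "dead"
    if (sum(dead) > 1 || (any(dead) && which.max(dead) < length(idx))) {
      problems <- c(problems, paste0("more than one alive->dead transition: rows ",
                                     paste(idx, collapse = ", ")))
    }
    first_live <- idx[m$status[idx] %in% c("alive", "recruit")][1]
    if (!is.na(first_live) && is.finite(m$diameter[first_live]) &&
        m$diameter[first_live] < x$min_diameter - 1e-9) {
      problems <- c(problems, paste0("first-record diameter below plot minimum: row ",
                                     first_live))
    }
  }
  problems
}

#' @export
print.plot_data <- function(x, ...) {
  cat("<plot_data> ", x$plot_id, ": ", format(x$area, digits = 3), " ha, ",
      length(unique(x$stems$tag)), " stems, ",
      length(x$census_dates), " censuses (",
      if (length(x$census_dates)) paste(round(range(x$census_dates), 1), collapse = "-") else "none",
      "), edge distance ", round(x$edge_distance), " m\n", sep = "")
  invisible(x)
}

# live (alive/recruit) measurement rows of one census
live_rows <- function(plot, census_date) {
  m <- plot$measurements
  which(abs(m$census_date - census_date) < 1e-9 &
          m$status %in% c("alive", "recruit"))
}
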