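TREE_COLS <- c("plot_id", "tag", "family", "genus", "species", "monocot",
               "census_date", "diameter_cm", "pom_m", "status")
PLOT_COLS <- c("plot_id", "area_ha", "edge_distance_m", "min_diameter_cm")

#' Read long-format census tables
#'
#' Reads a tree-by-tree census table and a plot metadata table and assembles
#' validated [plot_data] objects. A point-of-measurement (POM) change is
#' represented in the tree table by two rows for the same tree and census
#' date with different `pom_m`: the row at the lower POM is taken as the old
#' POM measurement and the row at the higher POM as the new one.
#'
#' @param tree_csv_path CSV with columns `plot_id, tag, family, genus,
#'   species, monocot, census_date, diameter_cm, pom_m, status`.
#' @param plot_csv_path CSV with columns `plot_id, area_ha, edge_distance_m,
#'   min_diameter_cm`.
#' @return Named list of [plot_data] objects, one per plot row.
#' @export
read_census_table <- function(tree_csv_path, plot_csv_path) {
  for (p in c(tree_csv_path, plot_csv_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  trees <- utils::read.csv(tree_csv_path, stringsAsFactors = FALSE)
  plots <- utils::read.csv(plot_csv_path, stringsAsFactors = FALSE)
  miss <- setdiff(TREE_COLS, names(trees))
  if (length(miss)) {
    stop("tree table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(PLOT_COLS, names(plots))
  if (length(miss)) {
    stop("plot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(trees$plot_id), plots$plot_id)
  if (length(unknown)) {
    stop("tree rows reference unknown plot(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- which(trees$status %in% c("alive", "recruit") &
                 (!is.finite(trees$diameter_cm) | trees$diameter_cm <= 0))
  if (length(bad)) {
    stop("non-positive diameter on live record(s) in tree table, row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!nrow(trees)) {
    warning("tree table is empty; returning plots with zero trees")
  }
  out <- list()
  for (i in seq_len(nrow(plots))) {
    pid <- plots$plot_id[i]
    tr <- trees[trees$plot_id == pid, , drop = FALSE]
    if (!nrow(tr)) {
      out[[as.character(pid)]] <- plot_data(
        pid, plots$area_ha[i], plots$edge_distance_m[i],
        plots$min_diameter_cm[i])
      next
    }
    tr <- tr[order(tr$tag, tr$census_date, tr$pom_m), , drop = FALSE]
    key <- paste(tr$tag, format(tr$census_date, nsmall = 6))
    dup <- duplicated(key)           # second row of a dual POM measurement
    first <- tr[!dup, , drop = FALSE]
    meas <- data.frame(
      tag = as.character(first$tag), census_date = first$census_date,
      diameter = first$diameter_cm, pom = first$pom_m,
      status = first$status, flag = "accepted",
      diameter_new = NA_real_, pom_new = NA_real_,
      stringsAsFactors = FALSE)
    if (any(dup)) {
      second <- tr[dup, , drop = FALSE]
      j <- match(paste(second$tag, format(second$census_date, nsmall = 6)),
                 key[!dup])
      meas$diameter_new[j] <- second$diameter_cm
      meas$pom_new[j] <- second$pom_m
    }
    stem_first <- first[!duplicated(first$tag), , drop = FALSE]
    stems <- data.frame(
      tag = as.character(stem_first$tag), family = as.character(stem_first$family),
      genus = as.character(stem_first$genus),
      species = as.character(stem_first$species),
      monocot = as.logical(stem_first$monocot),
      stringsAsFactors = FALSE)
    out[[as.character(pid)]] <- plot_data(
      pid, plots$area_ha[i], plots$edge_distance_m[i],
      plots$min_diameter_cm[i], stems = stems, measurements = meas)
  }
  out
}

#' Write plot_data objects back to long-format census tables
#'
#' Inverse of [read_census_table]: POM-change records are expanded back to
#' two rows (old and new POM). Rows are written in a canonical order
#' (plot, tag, census date, POM) so that read-write-read round trips are
#' exact.
#'
#' @param plots List of [plot_data] objects.
#' @param tree_csv_path,plot_csv_path Output CSV paths.
#' @export
write_census_table <- function(plots, tree_csv_path, plot_csv_path) {
  plot_tab <- data.frame(
    plot_id = vapply(plots, function(p) p$plot_id, ""),
    area_ha = vapply(plots, function(p) p$area, 0),
    edge_distance_m = vapply(plots, function(p) p$edge_distance, 0),
    min_diameter_cm = vapply(plots, function(p) p$min_diameter, 0),
    stringsAsFactors = FALSE)
  tree_tabs <- lapply(plots, function(p) {
    m <- p$measurements
    if (!nrow(m)) return(NULL)
    s <- p$stems[match(m$tag, p$stems$tag), , drop = FALSE]
    base <- data.frame(
      plot_id = p$plot_id, tag = m$tag, family = s$family, genus = s$genus,
      species = s$species, monocot = s$monocot, census_date = m$census_date,
      diameter_cm = m$diameter, pom_m = m$pom, status = m$status,
      stringsAsFactors = FALSE)
    dual <- which(!is.na(m$diameter_new))
    if (length(dual)) {
      extra <- base[dual, , drop = FALSE]
      extra$diameter_cm <- m$diameter_new[dual]
      extra$pom_m <- m$pom_new[dual]
      base <- rbind(base, extra)
    }
    base
  })
  tree_tab <- do.call(rbind, c(tree_tabs, list(make.row.names = FALSE)))
  if (is.null(tree_tab)) {
    tree_tab <- data.frame(matrix(nrow = 0, ncol = length(TREE_COLS),
                                  dimnames = list(NULL, TREE_COLS)))
  } else {
    tree_tab <- tree_tab[order(tree_tab$plot_id, tree_tab$tag,
                               tree_tab$census_date, tree_tab$pom_m), ,
                         drop = FALSE]
  }
  utils::write.csv(tree_tab, tree_csv_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(plot_tab, plot_csv_path, row.names = FALSE, quote = FALSE)
  invisible(list(trees = tree_tab, plots = plot_tab))
}

#' Merge small nearby plots with synchronous censuses
#'
#' Plots smaller than `area_threshold` that lie within `distance_threshold`
#' of one another and share an identical census-date set (dates rounded to
#' 0.1 yr) are merged into a single sampling unit. The merged unit has the
#' summed area, the union of trees (tags prefixed by the source plot id),
#' and an area-weighted mean edge distance.
#'
#' @param plots List of [plot_data] objects.
#' @param coordinates data.frame with columns `plot_id`, `x`, `y` (metres,
#'   planar approximation).
#' @param area_threshold Area below which plots are merge candidates (ha).
#' @param distance_threshold Maximum pairwise distance for merging (m).
#' @return List with `plots` (merged list) and `merge_map` (data.frame
#'   mapping original `plot_id` to `merged_id`).
#' @export
merge_small_plots <- function(plots, coordinates, area_threshold = 0.4,
                              distance_threshold = 1000) {
  ids <- vapply(plots, function(p) p$plot_id, "")
  names(plots) <- ids
  co <- coordinates[match(ids, coordinates$plot_id), , drop = FALSE]
  if (any(is.na(co$x))) {
    stop("coordinates missing for plot(s): ",
         paste(ids[is.na(co$x)], collapse = ", "), call. = FALSE)
  }
  small <- vapply(plots, function(p) p$area < area_threshold, TRUE)
  dates_key <- vapply(plots, function(p)
    paste(sprintf("%.1f", sort(p$census_dates)), collapse = "|"), "")
  n <- length(plots)
  comp <- seq_len(n)   # union-find over merge-qualifying pairs
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (!(small[i] && small[j])) next
    d <- sqrt((co$x[i] - co$x[j])^2 + (co$y[i] - co$y[j])^2)
    if (d > distance_threshold) next
    if (dates_key[i] != dates_key[j]) next
    if (plots[[i]]$min_diameter != plots[[j]]$min_diameter) {
      stop("refusing to merge plots '", ids[i], "' and '", ids[j],
           "': different minimum diameters (", plots[[i]]$min_diameter,
           " vs ", plots[[j]]$min_diameter, " cm)", call. = FALSE)
    }
    comp[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- list()
  map <- data.frame(plot_id = ids, merged_id = ids, stringsAsFactors = FALSE)
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (length(members) == 1) {
      p <- plots[[members]]
      out[[p$plot_id]] <- p
      next
    }
    ms <- plots[members]
    new_id <- paste(vapply(ms, function(p) p$plot_id, ""), collapse = "+")
    map$merged_id[members] <- new_id
    areas <- vapply(ms, function(p) p$area, 0)
    stems <- do.call(rbind, lapply(ms, function(p) {
      s <- p$stems; s$tag <- paste0(p$plot_id, ":", s$tag); s
    }))
    meas <- do.call(rbind, lapply(ms, function(p) {
      m <- p$measurements; m$tag <- paste0(p$plot_id, ":", m$tag); m
    }))
    rownames(stems) <- rownames(meas) <- NULL
    out[[new_id]] <- plot_data(
      new_id, sum(areas),
      stats::weighted.mean(vapply(ms, function(p) p$edge_distance, 0), areas),
      ms[[1]]$min_diameter, stems = stems, measurements = meas,
      forest_type = ms[[1]]$forest_type)
  }
  list(plots = out, merge_map = map)
}
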