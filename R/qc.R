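#' Standardize a tree's diameter series across POM changes
#'
#' When buttress growth forces the point of measurement (POM) upward, the
#' change census records the diameter at both the old and the new POM; their
#' ratio (new/old) is the taper ratio. The full series is standardized to
#' the old POM (dividing post-change measurements by the taper ratio) and to
#' the new POM (multiplying pre-change measurements by it); the returned
#' working diameter is the elementwise mean of the two standardized series,
#' which corresponds to an invariant POM between the old and new ones.
#' With several POM changes the taper ratios compound.
#'
#' If a POM change is recorded (a `pom_new` without a usable old-POM
#' diameter, or a jump in `pom` between censuses), the old-POM diameter at
#' the change is estimated by projecting the previous measurement forward at
#' `fallback_growth` and the affected records are flagged `"estimated"`.
#'
#' @param tree data.frame of one tree's measurement rows (as stored in
#'   `plot_data$measurements`), ordered by census date.
#' @param fallback_growth Annual diameter growth (cm/yr) used to estimate a
#'   missing old-POM diameter at a POM change.
#' @return The measurement data.frame with `diameter` replaced by the mean
#'   standardized series, the original values preserved in `diameter_raw`,
#'   and `flag` set to `"corrected"` (or `"estimated"`) on affected rows.
#' @export
standardize_pom_series <- function(tree, fallback_growth = 0.2) {
  m <- tree
  if (is.null(m$diameter_raw)) m$diameter_raw <- m$diameter
  live <- which(m$status %in% c("alive", "recruit"))
  changes <- intersect(which(!is.na(m$pom_new)), live)
  if (!length(changes)) return(m)
  n_changes <- length(changes)
  # regime k applies strictly after the k-th change census; the change
  # census itself records `diameter` at the old POM (regime k-1) and
  # `diameter_new` at the new POM
  regime <- rep(0L, nrow(m))
  for (k in seq_len(n_changes)) {
    regime[seq_len(nrow(m)) > changes[k]] <- k
  }
  taper <- numeric(n_changes)
  estimated <- logical(n_changes)
  for (k in seq_len(n_changes)) {
    i <- changes[k]
    old_d <- m$diameter[i]
    if (!is.finite(old_d) || old_d <= 0) {
      # old POM unusable at the change census: estimate it by projecting
      # the previous accepted measurement forward
      prev <- live[live < i]
      if (length(prev)) {
        j <- max(prev)
        old_d <- m$diameter[j] + fallback_growth * (m$census_date[i] - m$census_date[j])
      } else {
        old_d <- m$diameter_new[i]  # no earlier record: taper ratio 1
      }
      m$diameter[i] <- old_d
      estimated[k] <- TRUE
    }
    taper[k] <- m$diameter_new[i] / old_d
  }
  cum_taper <- c(1, cumprod(taper))     # T_0..T_K
  t_final <- cum_taper[n_changes + 1]
  for (i in live) {
    d <- m$diameter[i]
    old_std <- d / cum_taper[regime[i] + 1]
    new_std <- old_std * t_final
    m$diameter[i] <- (old_std + new_std) / 2
  }
  affected <- live[abs(m$diameter[live] - m$diameter_raw[live]) > 1e-12]
  m$flag[affected] <- "corrected"
  if (any(estimated)) m$flag[live] <- "estimated"
  m
}

GROWTH_CLASS_BREAKS <- c(0, 20, 40, Inf)
GROWTH_CLASS_LABELS <- c("10-19.9", "20-39.9", ">=40")

growth_class <- function(d) {
  cut(d, GROWTH_CLASS_BREAKS, labels = GROWTH_CLASS_LABELS, right = FALSE)
}

# annualized growth records of a plot: one row per consecutive live pair
growth_records <- function(plot) {
  m <- plot$measurements
  live <- m[m$status %in% c("alive", "recruit"), , drop = FALSE]
  if (nrow(live) < 2) {
    return(data.frame(tag = character(), d0 = numeric(), growth = numeric(),
                      accepted = logical(), class = factor(character(),
                      levels = GROWTH_CLASS_LABELS)))
  }
  same <- live$tag[-1] == live$tag[-nrow(live)]
  i <- which(same)
  dt <- live$census_date[i + 1] - live$census_date[i]
  g <- (live$diameter[i + 1] - live$diameter[i]) / dt
  data.frame(tag = live$tag[i], d0 = live$diameter[i], growth = g,
             accepted = live$flag[i] == "accepted" & live$flag[i + 1] == "accepted",
             class = growth_class(live$diameter[i]),
             stringsAsFactors = FALSE)
}

#' Per-size-class growth statistics of a plot
#'
#' Mean and median annualized diameter growth (cm/yr) of accepted growth
#' records in the size classes 10-19.9, 20-39.9 and >=40 cm (classes defined
#' on the diameter at the start of each interval). A class without accepted
#' records falls back to the plot-level statistic with a warning; if the
#' plot has no accepted records at all, statistics are computed over all
#' (corrected) records with a warning.
#'
#' @param plot A [plot_data] object with at least two censuses.
#' @param thresholds Length-2 numeric `(min, max)` plausible annualized
#'   growth (cm/yr) used to define accepted records.
#' @return data.frame with columns `class`, `n`, `mean`, `median`.
#' @export
plot_growth_stats <- function(plot, thresholds = c(-0.5, 4)) {
  if (length(plot$census_dates) < 2) {
    stop("plot '", plot$plot_id, "' has fewer than two censuses: no growth intervals",
         call. = FALSE)
  }
  gr <- growth_records(plot)
  gr$accepted <- gr$accepted & gr$growth >= thresholds[1] & gr$growth <= thresholds[2]
  use <- gr[gr$accepted, , drop = FALSE]
  if (!nrow(use) && nrow(gr)) {
    warning("plot '", plot$plot_id,
            "' has no accepted growth records; statistics use corrected records")
    use <- gr
  }
  out <- data.frame(class = GROWTH_CLASS_LABELS, n = 0L,
                    mean = NA_real_, median = NA_real_,
                    stringsAsFactors = FALSE)
  plot_mean <- mean(use$growth)
  plot_median <- stats::median(use$growth)
  for (k in seq_along(GROWTH_CLASS_LABELS)) {
    gk <- use$growth[use$class == GROWTH_CLASS_LABELS[k]]
    out$n[k] <- length(gk)
    if (length(gk)) {
      out$mean[k] <- mean(gk)
      out$median[k] <- stats::median(gk)
    } else {
      warning("plot '", plot$plot_id, "': no accepted growth records in class ",
              GROWTH_CLASS_LABELS[k], "; using plot-level statistic")
      out$mean[k] <- plot_mean
      out$median[k] <- plot_median
    }
  }
  out
}

# statistic used to fill an implausible growth record: mean for the
# 10-19.9 cm class, median for the larger classes
class_fill_growth <- function(stats, d) {
  k <- as.integer(growth_class(d))
  if (k == 1L) stats$mean[1] else stats$median[k]
}

#' Flag and correct implausible diameter growth records
#'
#' Annualized growth outside `[min_growth, max_growth]` is treated as a
#' measurement error. The offending measurement is replaced by
#' extrapolation from the previous (corrected) measurement at (a) the
#' tree's own mean growth over its accepted intervals when at least one
#' exists, else (b) the plot size-class statistic (mean for the 10-19.9 cm
#' class, median for larger classes). Corrections cascade: a corrected value
#' is the baseline for the next interval.
#'
#' @param tree data.frame of one tree's measurement rows, ordered by date.
#' @param plot_stats Output of [plot_growth_stats] for the tree's plot.
#' @param max_growth,min_growth Plausibility thresholds (cm/yr).
#' @return The measurement data.frame with corrected `diameter` values and
#'   `flag = "corrected"` on replaced rows; `NULL` when the tree has two or
#'   more growth intervals and every one of them is implausible (excluded).
#' @export
flag_and_correct_growth <- function(tree, plot_stats, max_growth = 4,
                                    min_growth = -0.5) {
  m <- tree
  if (is.null(m$diameter_raw)) m$diameter_raw <- m$diameter
  live <- which(m$status %in% c("alive", "recruit"))
  if (length(live) < 2) return(m)
  d <- m$diameter[live]
  dates <- m$census_date[live]
  g_raw <- diff(d) / diff(dates)
  ok <- g_raw >= min_growth & g_raw <= max_growth
  if (all(ok)) return(m)
  if (!any(ok) && length(g_raw) >= 2) {
    return(NULL)                        # all intervals implausible: exclude
  }
  g_tree <- if (any(ok)) mean(g_raw[ok]) else NA_real_
  for (i in seq_along(g_raw)) {
    dt <- dates[i + 1] - dates[i]
    g <- (d[i + 1] - d[i]) / dt         # growth against (possibly corrected) baseline
    if (g >= min_growth && g <= max_growth) next
    fill <- if (is.finite(g_tree)) g_tree else class_fill_growth(plot_stats, d[i])
    d[i + 1] <- d[i] + fill * dt
    m$flag[live[i + 1]] <- "corrected"
  }
  m$diameter[live] <- d
  m
}

#' Quality-control a plot's diameter series
#'
#' Applies the full per-tree QC pipeline: POM-change standardization, plot
#' growth statistics, and detection/correction of implausible growth
#' records. Trees whose growth intervals are all implausible are excluded.
#'
#' @param plot A [plot_data] object.
#' @param max_growth,min_growth Plausibility thresholds for annualized
#'   diameter growth (cm/yr).
#' @return The QC'd [plot_data]; the attribute `"qc_report"` holds counts of
#'   flagged/corrected records, the corrected fraction of measurements, and
#'   excluded tags.
#' @export
qc_plot <- function(plot, max_growth = 4, min_growth = -0.5) {
  m <- plot$measurements
  if (is.null(m$diameter_raw)) m$diameter_raw <- m$diameter
  # 1. POM standardization, only for trees with recorded POM changes
  pom_tags <- unique(m$tag[!is.na(m$pom_new)])
  if (length(pom_tags)) {
    rows <- m$tag %in% pom_tags
    fixed <- lapply(split(m[rows, , drop = FALSE], m$tag[rows]),
                    standardize_pom_series)
    m <- rbind(m[!rows, , drop = FALSE], do.call(rbind, fixed))
    m <- m[order(m$tag, m$census_date), , drop = FALSE]
    rownames(m) <- NULL
  }
  plot$measurements <- m
  # 2. plot growth statistics over accepted records
  stats <- plot_growth_stats(plot, thresholds = c(min_growth, max_growth))
  # 3. growth corrections, only for trees with an implausible record
  gr <- growth_records(plot)
  bad <- gr$growth < min_growth | gr$growth > max_growth
  bad_tags <- unique(gr$tag[bad])
  excluded <- character()
  if (length(bad_tags)) {
    rows <- m$tag %in% bad_tags
    fixed <- lapply(split(m[rows, , drop = FALSE], m$tag[rows]),
                    flag_and_correct_growth, plot_stats = stats,
                    max_growth = max_growth, min_growth = min_growth)
    excluded <- names(fixed)[vapply(fixed, is.null, TRUE)]
    fixed <- fixed[!vapply(fixed, is.null, TRUE)]
    m <- rbind(m[!rows, , drop = FALSE], do.call(rbind, fixed))
    m <- m[order(m$tag, m$census_date), , drop = FALSE]
    rownames(m) <- NULL
    plot$measurements <- m
    plot$stems <- plot$stems[!plot$stems$tag %in% excluded, , drop = FALSE]
  }
  n_changed <- sum(m$flag != "accepted")
  attr(plot, "qc_report") <- list(
    n_measurements = nrow(m),
    n_pom_standardized = sum(m$tag %in% pom_tags),
    n_growth_corrected = sum(m$flag == "corrected" & !m$tag %in% pom_tags),
    corrected_fraction = if (nrow(m)) n_changed / nrow(m) else 0,
    excluded_tags = excluded,
    growth_stats = stats)
  plot
}
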