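#' Define a drought event
#'
#' @param name Event label, e.g. `"elnino_1997_1998"`.
#' @param start,end Event window in decimal years (e.g. 1997.5 and 1998.5).
#' @return Object of class `drought_event`.
#' @export
drought_event <- function(name, start, end) {
  if (!(start < end)) stop("event start must precede end", call. = FALSE)
  structure(list(name = name, start = start, end = end),
            class = "drought_event")
}

#' Assign census intervals to drought windows
#'
#' For each plot, the unique census interval spanning the drought episode
#' becomes the `during` window; earlier intervals are `before`, later ones
#' `after`. A plot qualifies only if it has intervals in all three windows
#' (it was monitored before, during and after the event). If a census date
#' falls inside the event so that two intervals overlap it, the interval
#' containing the event midpoint is taken as `during` and the assignment is
#' flagged.
#'
#' @param dynamics Interval-level dynamics table ([network_dynamics]):
#'   columns `plot_id`, `start`, `end` at minimum.
#' @param event A [drought_event].
#' @return The dynamics table with added columns `window` (`"before"`,
#'   `"during"`, `"after"`, or `NA` for non-qualifying plots), `qualifies`,
#'   `exclusion_reason`, and `multi_overlap` (flag).
#' @export
assign_drought_windows <- function(dynamics, event) {
  stopifnot(inherits(event, "drought_event"))
  mid <- (event$start + event$end) / 2
  out <- dynamics
  out$window <- NA_character_
  out$qualifies <- FALSE
  out$exclusion_reason <- NA_character_
  out$multi_overlap <- FALSE
  for (pid in unique(out$plot_id)) {
    idx <- which(out$plot_id == pid)
    s <- out$start[idx]; e <- out$end[idx]
    overlap <- which(s < event$end & e > event$start)
    reason <- NULL
    if (!length(overlap)) {
      reason <- "no interval spans the event"
    } else {
      during <- if (length(overlap) == 1) overlap else {
        has_mid <- overlap[s[overlap] <= mid & e[overlap] >= mid]
        if (length(has_mid)) has_mid[1] else overlap[1]
      }
      win <- rep(NA_character_, length(idx))
      win[during] <- "during"
      win[e <= s[during] + 1e-9 & seq_along(idx) != during] <- "before"
      win[s >= e[during] - 1e-9 & seq_along(idx) != during] <- "after"
      if (!any(win == "before", na.rm = TRUE)) {
        reason <- "not monitored before the event"
      } else if (!any(win == "after", na.rm = TRUE)) {
        reason <- "not monitored after the event"
      }
    }
    if (is.null(reason)) {
      out$window[idx] <- win
      out$qualifies[idx] <- TRUE
      out$multi_overlap[idx] <- length(overlap) > 1
    } else {
      out$exclusion_reason[idx] <- reason
    }
  }
  out
}

# intercept-only mixed model mean of an interval-level response, with
# interval-length weights (longer intervals carry more information);
# falls back to the weighted mean when the plot variance is inestimable
window_mean <- function(d, response, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  dat <- data.frame(y = d[[response]], plot_id = factor(d$plot_id),
                    w_inv = 1 / d$t)
  fit <- tryCatch(
    nlme::lme(y ~ 1, random = ~1 | plot_id, data = dat, method = "REML",
              weights = nlme::varFixed(~w_inv),
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- unname(nlme::fixef(fit)[1])
    se <- sqrt(fit$varFix[1, 1])
  } else {
    est <- stats::weighted.mean(dat$y, d$t)
    se <- sqrt(sum((d$t / sum(d$t))^2 *
                     (dat$y - est)^2) * nrow(dat) / max(1, nrow(dat) - 1))
  }
  c(estimate = est, lower = est - z * se, upper = est + z * se)
}

#' Window-specific biomass dynamics around a drought event
#'
#' Partitions each qualifying plot's census intervals into before/during/
#' after windows around the event ([assign_drought_windows]) and estimates
#' the mean AGWP, AGB mortality and annualized AGB change in each window
#' with an intercept-only mixed model (plot random intercept, interval
#' responses weighted by interval length).
#'
#' @param dynamics Interval-level dynamics table with columns `plot_id`,
#'   `start`, `end`, `t`, `agwp`, `agb_mortality`, `agb_change`.
#' @param event A [drought_event].
#' @param conf Confidence level.
#' @return data.frame with one row per window and response: `window`,
#'   `response`, `estimate`, `lower`, `upper`, `n_plots`, `n_intervals`,
#'   `span_start`, `span_end` (mean window span over plots). The attribute
#'   `"n_qualifying"` gives the number of qualifying plots.
#' @export
window_estimates <- function(dynamics, event, conf = 0.95) {
  lab <- assign_drought_windows(dynamics, event)
  q <- lab[lab$qualifies, , drop = FALSE]
  n_q <- length(unique(q$plot_id))
  if (n_q < 5) {
    stop("only ", n_q, " plot(s) qualify (monitored before, during and after ",
         event$name, "); need at least 5", call. = FALSE)
  }
  responses <- c("agwp", "agb_mortality", "agb_change")
  rows <- list()
  for (win in c("before", "during", "after")) {
    d <- q[q$window == win & !is.na(q$window), , drop = FALSE]
    spans <- do.call(rbind, lapply(split(d, d$plot_id), function(p) {
      c(min(p$start), max(p$end))
    }))
    for (resp in responses) {
      if (nrow(d) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          window = win, response = resp, estimate = NA_real_,
          lower = NA_real_, upper = NA_real_,
          n_plots = length(unique(d$plot_id)), n_intervals = nrow(d),
          span_start = NA_real_, span_end = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      est <- window_mean(d, resp, conf)
      rows[[length(rows) + 1]] <- data.frame(
        window = win, response = resp, estimate = est[["estimate"]],
        lower = est[["lower"]], upper = est[["upper"]],
        n_plots = length(unique(d$plot_id)), n_intervals = nrow(d),
        span_start = mean(spans[, 1]), span_end = mean(spans[, 2]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_qualifying") <- n_q
  out
}
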