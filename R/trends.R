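#' Per-plot AGB trends
#'
#' Ordinary least-squares slope of AGB against time for each plot, with the
#' cube root of monitoring length as the analysis weight (longer-monitored
#' plots average away more short-term demographic noise) and an edge
#' classification at a given distance threshold.
#'
#' @param observations Census-level AGB table ([network_observations]):
#'   columns `plot_id`, `census_date`, `agb`, `area`, `edge_distance`.
#' @param edge_threshold Edge distance (m) below which a plot is classed as
#'   an edge plot.
#' @return data.frame with one row per plot: `plot_id`, `slope`
#'   (Mg/ha/yr), `monitoring_length` (yr), `weight`, `area`,
#'   `edge_distance`, `is_edge`.
#' @export
plot_trends <- function(observations, edge_threshold = 448) {
  sp <- split(observations, observations$plot_id)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < 2) {
      stop("plot '", d$plot_id[1], "' has fewer than 2 censuses", call. = FALSE)
    }
    len <- max(d$census_date) - min(d$census_date)
    data.frame(
      plot_id = d$plot_id[1],
      slope = unname(stats::coef(stats::lm(agb ~ census_date, data = d))[2]),
      monitoring_length = len, weight = len^(1 / 3),
      area = d$area[1], edge_distance = d$edge_distance[1],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$is_edge <- out$edge_distance < edge_threshold
  out
}

#' Diagnostic for the sampling-effort weighting
#'
#' Regresses the absolute deviation of each plot's AGB change from the
#' weighted population mean on plot area and on monitoring length, both for
#' the raw deviations and after scaling by the cube-root weights. An
#' effective weighting removes the monitoring-length relationship.
#'
#' @param trends Output of [plot_trends] (at least 5 plots).
#' @return data.frame with one row per (predictor, weighting) combination:
#'   `predictor`, `weighted`, `slope`, `p_value`.
#' @export
weighting_diagnostic <- function(trends) {
  if (nrow(trends) < 5) stop("need at least 5 plots", call. = FALSE)
  mu <- stats::weighted.mean(trends$slope, trends$weight)
  dev_raw <- abs(trends$slope - mu)
  dev_w <- dev_raw * trends$weight / mean(trends$weight)
  out <- rbind(
    data.frame(predictor = "area", weighted = FALSE,
               slope = NA_real_, p_value = NA_real_),
    data.frame(predictor = "monitoring_length", weighted = FALSE,
               slope = NA_real_, p_value = NA_real_),
    data.frame(predictor = "area", weighted = TRUE,
               slope = NA_real_, p_value = NA_real_),
    data.frame(predictor = "monitoring_length", weighted = TRUE,
               slope = NA_real_, p_value = NA_real_))
  fill <- function(k, y, x) {
    if (stats::sd(y) < 1e-12 || stats::sd(x) < 1e-12) {
      out$slope[k] <<- 0; out$p_value[k] <<- 1
    } else {
      fit <- summary(stats::lm(y ~ x))
      out$slope[k] <<- fit$coefficients[2, 1]
      out$p_value[k] <<- fit$coefficients[2, 4]
    }
  }
  fill(1, dev_raw, trends$area)
  fill(2, dev_raw, trends$monitoring_length)
  fill(3, dev_w, trends$area)
  fill(4, dev_w, trends$monitoring_length)
  out
}

# bootstrap quantile with normal-scale interpolation between order
# statistics (the convention used for BCa percentile endpoints)
norm_inter <- function(tstar, alpha) {
  ts <- sort(tstar)
  B <- length(ts)
  vapply(alpha, function(a) {
    k <- (B + 1) * a
    if (k <= 1) return(ts[1])
    if (k >= B) return(ts[B])
    k1 <- floor(k); k2 <- k1 + 1
    if (ts[k1] == ts[k2]) return(ts[k1])
    # interpolate on the normal quantile scale
    g <- (stats::qnorm(a) - stats::qnorm(k1 / (B + 1))) /
      (stats::qnorm(k2 / (B + 1)) - stats::qnorm(k1 / (B + 1)))
    ts[k1] + g * (ts[k2] - ts[k1])
  }, 0)
}

#' Weighted mean AGB change with BCa bootstrap interval
#'
#' Weighted mean of individual plot AGB slopes (cube-root-of-monitoring-
#' length weights) with a non-parametric bias-corrected and accelerated
#' (BCa) bootstrap confidence interval obtained by resampling plots with
#' replacement.
#'
#' @param trends Output of [plot_trends] (at least 3 plots).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return List with `mean`, `ci` (length-2), `n_boot`, `n`.
#' @export
weighted_mean_change <- function(trends, n_boot = 999, seed = 20171219,
                                 conf = 0.95) {
  n <- nrow(trends)
  if (n < 3) stop("need at least 3 plots", call. = FALSE)
  s <- trends$slope; w <- trends$weight
  stat <- function(idx) stats::weighted.mean(s[idx], w[idx])
  t0 <- stat(seq_len(n))
  if (stats::sd(s) < 1e-12) {
    return(list(mean = t0, ci = c(t0, t0), n_boot = n_boot, n = n))
  }
  set.seed(seed)
  tstar <- vapply(seq_len(n_boot),
                  function(b) stat(sample.int(n, n, replace = TRUE)), 0)
  z0 <- stats::qnorm((sum(tstar < t0) + 0.5 * sum(tstar == t0)) / n_boot)
  jack <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)), 0)
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zal <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  list(mean = t0, ci = norm_inter(tstar, adj), n_boot = n_boot, n = n)
}
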