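#' Mixed-effects model of AGB change for interior and edge forests
#'
#' Fits the linear mixed-effects model
#' AGB_ij = b0 + b1 time_ij + b2 edge_i + b3 time_ij:edge_i + u0i + u1i time_ij + e_ij
#' with a random intercept and random time slope per plot, by (restricted)
#' maximum likelihood. The residual variance follows a power function of
#' plot area and fitted value, variance = (area)^delta_a (fitted)^delta_f,
#' with the exponents estimated during model fitting (nlme variance
#' functions). The fixed effect `time` is the interior AGB trend and
#' `time + time:edge` the edge trend. 95% CIs use a normal approximation to
#' the (RE)ML estimator distribution.
#'
#' When every observation is in a single edge class the edge terms are
#' dropped and `b1` is the overall trend.
#'
#' @param observations data.frame with columns `plot_id`, `census_date`,
#'   `agb` (Mg/ha), `area` (ha), and either `is_edge` (logical) or
#'   `edge_distance` (m, classified at `edge_threshold`).
#' @param edge_threshold Edge distance threshold (m) used when `is_edge` is
#'   absent.
#' @param center_time Centre the time covariate at the network mean census
#'   date? (The trend estimates are invariant to centring.)
#' @param reml Use REML (default) or ML.
#' @param var_power Estimate the power variance function? `FALSE` fits a
#'   homoscedastic model.
#' @return Object of class `lme_fit`: fixed effects `beta` with `se`, `ci`
#'   and `vcov`; `random` (sd of intercept and slope, their correlation,
#'   residual sigma); `var_exponents` (variance-scale exponents
#'   `delta_area`, `delta_fitted`); `marginal_r2`; `interior` and `edge`
#'   trend estimates with CIs; `n_obs`, `n_plots`, `fallback`, and the
#'   underlying `nlme::lme` model.
#' @export
fit_lme <- function(observations, edge_threshold = 448, center_time = TRUE,
                    reml = TRUE, var_power = TRUE) {
  dat <- as.data.frame(observations)
  if (is.null(dat$is_edge)) {
    if (is.null(dat$edge_distance)) {
      stop("observations need an is_edge or edge_distance column", call. = FALSE)
    }
    dat$is_edge <- dat$edge_distance < edge_threshold
  }
  center <- if (center_time) mean(dat$census_date) else 0
  dat$time <- dat$census_date - center
  dat$edge <- as.numeric(dat$is_edge)
  dat$plot_id <- factor(dat$plot_id)
  tab <- table(dat$plot_id)
  if (any(tab < 2)) {
    stop("every plot needs at least 2 observations; offending plot(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  has_edge_term <- length(unique(dat$edge)) > 1
  fixed <- if (has_edge_term) agb ~ time * edge else agb ~ time
  method <- if (reml) "REML" else "ML"
  ctrl <- nlme::lmeControl(maxIter = 100, msMaxIter = 200, niterEM = 50,
                           msMaxEval = 500)
  weights_obj <- if (var_power) {
    nlme::varComb(nlme::varPower(form = ~area),
                  nlme::varPower(form = ~fitted(.)))
  } else NULL
  attempt <- function(random, w) {
    fit <- tryCatch(nlme::lme(fixed, random = random, data = dat,
                              method = method, weights = w, control = ctrl),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      ctrl2 <- ctrl; ctrl2$opt <- "optim"
      fit <- tryCatch(nlme::lme(fixed, random = random, data = dat,
                                method = method, weights = w,
                                control = ctrl2),
                      error = function(e) e)
    }
    fit
  }
  fallback <- "none"
  fit <- attempt(~time | plot_id, weights_obj)
  if (inherits(fit, "error") && var_power) {
    fit <- attempt(~time | plot_id, NULL)
    fallback <- "homoscedastic"
  }
  if (inherits(fit, "error")) {
    fit <- attempt(~1 | plot_id, weights_obj)
    fallback <- "intercept_only"
  }
  if (inherits(fit, "error")) {
    fit <- attempt(~1 | plot_id, NULL)
    fallback <- "intercept_only_homoscedastic"
  }
  if (inherits(fit, "error")) {
    stop("mixed model failed to converge: ", conditionMessage(fit),
         call. = FALSE)
  }
  beta <- nlme::fixef(fit)
  vc <- fit$varFix
  se <- sqrt(diag(vc))
  z <- stats::qnorm(0.975)
  ci <- cbind(lower = beta - z * se, upper = beta + z * se)
  # variance-function exponents: nlme's varPower works on the sd scale,
  # variance exponents are twice the fitted powers
  var_exponents <- c(delta_area = 0, delta_fitted = 0)
  vs <- fit$modelStruct$varStruct
  if (!is.null(vs)) {
    pw <- stats::coef(vs, unconstrained = FALSE)
    var_exponents <- c(delta_area = 2 * unname(pw["A.power"]),
                       delta_fitted = 2 * unname(pw["B.power"]))
  }
  # random-effect structure
  re <- nlme::getVarCov(fit)
  sd_u0 <- sqrt(re[1, 1])
  sd_u1 <- if (nrow(re) > 1) sqrt(re[2, 2]) else NA_real_
  cor_u <- if (nrow(re) > 1) re[1, 2] / (sd_u0 * sd_u1) else NA_real_
  # marginal R2: variance of fixed-effect predictions over total variance,
  # with heteroscedastic residual variance averaged over observations
  mu_fix <- stats::predict(fit, level = 0)
  var_f <- stats::var(mu_fix)
  t_obs <- dat$time
  var_r <- if (nrow(re) > 1) {
    mean(re[1, 1] + 2 * re[1, 2] * t_obs + re[2, 2] * t_obs^2)
  } else re[1, 1]
  vw <- if (!is.null(vs)) nlme::varWeights(vs) else rep(1, nrow(dat))
  var_e <- mean((fit$sigma / vw)^2)
  marginal_r2 <- var_f / (var_f + var_r + var_e)

  interior <- list(estimate = unname(beta["time"]),
                   ci = unname(ci["time", ]))
  edge <- NULL
  if (has_edge_term) {
    est <- unname(beta["time"] + beta["time:edge"])
    v <- vc["time", "time"] + vc["time:edge", "time:edge"] +
      2 * vc["time", "time:edge"]
    edge <- list(estimate = est, ci = c(est - z * sqrt(v), est + z * sqrt(v)))
  }
  structure(list(
    beta = beta, se = se, ci = ci, vcov = vc,
    random = list(sd_intercept = sd_u0, sd_slope = sd_u1,
                  correlation = cor_u, sigma = fit$sigma),
    var_exponents = var_exponents, marginal_r2 = marginal_r2,
    interior = interior, edge = edge,
    n_obs = nrow(dat), n_plots = nlevels(dat$plot_id),
    time_center = center, reml = reml, fallback = fallback,
    model = fit), class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit> n_obs=", x$n_obs, ", n_plots=", x$n_plots,
      if (x$fallback != "none") paste0(" [fallback: ", x$fallback, "]"),
      "\n", sep = "")
  cat("  interior trend: ", signif(x$interior$estimate, 4), " (",
      paste(signif(x$interior$ci, 4), collapse = ", "), ") Mg/ha/yr\n",
      sep = "")
  if (!is.null(x$edge)) {
    cat("  edge trend:     ", signif(x$edge$estimate, 4), " (",
        paste(signif(x$edge$ci, 4), collapse = ", "), ") Mg/ha/yr\n", sep = "")
  }
  cat("  variance exponents: area ", signif(x$var_exponents[1], 3),
      ", fitted ", signif(x$var_exponents[2], 3),
      "; marginal R2 = ", signif(x$marginal_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Interior/edge trend estimates over a range of edge thresholds
#'
#' Re-classifies plots as edge or interior at each candidate threshold and
#' refits the mixed model, tabulating interior and edge trend estimates.
#' Thresholds leaving fewer than 3 plots in either class are flagged and
#' not fitted.
#'
#' @param observations As for [fit_lme]; must contain `edge_distance`.
#' @param thresholds Candidate thresholds (m).
#' @param ... Passed to [fit_lme].
#' @return data.frame with one row per threshold: `threshold`,
#'   `n_interior`, `n_edge`, `fitted` (logical), interior and edge
#'   estimates with CI bounds.
#' @export
threshold_scan <- function(observations, thresholds = seq(100, 1000, by = 100),
                           ...) {
  plots <- observations[!duplicated(observations$plot_id), , drop = FALSE]
  rows <- lapply(thresholds, function(thr) {
    is_edge <- plots$edge_distance < thr
    n_edge <- sum(is_edge); n_int <- sum(!is_edge)
    row <- data.frame(threshold = thr, n_interior = n_int, n_edge = n_edge,
                      fitted = FALSE, interior = NA_real_,
                      interior_lo = NA_real_, interior_hi = NA_real_,
                      edge = NA_real_, edge_lo = NA_real_, edge_hi = NA_real_)
    if (n_edge < 3 || n_int < 3) return(row)
    obs <- observations
    obs$is_edge <- obs$edge_distance < thr
    fit <- tryCatch(fit_lme(obs, ...), error = function(e) NULL)
    if (is.null(fit)) return(row)
    row$fitted <- TRUE
    row$interior <- fit$interior$estimate
    row$interior_lo <- fit$interior$ci[1]
    row$interior_hi <- fit$interior$ci[2]
    row$edge <- fit$edge$estimate
    row$edge_lo <- fit$edge$ci[1]
    row$edge_hi <- fit$edge$ci[2]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out spectrum of the interior trend
#'
#' Refits the mixed model omitting one unit (plot or site) at a time and
#' collects the spectrum of interior-trend estimates.
#'
#' @param observations As for [fit_lme]. For `unit = "site"` a `site`
#'   column must be present.
#' @param unit `"plot"` or `"site"`.
#' @param ... Passed to [fit_lme].
#' @return data.frame with one row per omitted unit: `unit`, `estimate`,
#'   `lower`, `upper`, `skipped`. The attribute `"summary"` gives the full
#'   estimate and the min/max of the spectrum and whether all estimates
#'   share its sign.
#' @export
leave_one_out <- function(observations, unit = c("plot", "site"), ...) {
  unit <- match.arg(unit)
  key <- if (unit == "plot") observations$plot_id else observations$site
  if (is.null(key)) stop("observations lack a '", unit, "' column", call. = FALSE)
  full <- fit_lme(observations, ...)
  units <- unique(key)
  rows <- lapply(units, function(u) {
    obs <- observations[key != u, , drop = FALSE]
    if (length(unique(obs$plot_id)) < 3) {
      return(data.frame(unit = u, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, skipped = TRUE))
    }
    fit <- tryCatch(fit_lme(obs, ...), error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(unit = u, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, skipped = TRUE))
    }
    data.frame(unit = u, estimate = fit$interior$estimate,
               lower = fit$interior$ci[1], upper = fit$interior$ci[2],
               skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  est <- out$estimate[!out$skipped]
  attr(out, "summary") <- list(
    full_estimate = full$interior$estimate,
    min = min(est), max = max(est),
    sign_consistent = all(sign(est) == sign(full$interior$estimate)))
  out
}

#' Simulate census-level AGB observations from the mixed model
#'
#' Observation-level counterpart of the stand simulator: draws plot random
#' effects and residuals directly from the mixed-model data-generating
#' process, with an optional power variance function
#' variance = area^delta_area * mu^delta_fitted. Used to validate the
#' estimator (parameter recovery, exponent recovery, coverage).
#'
#' @param n_plots Number of plots.
#' @param prop_edge Proportion of edge plots.
#' @param beta Named-free numeric of length 4: intercept, time slope, edge
#'   offset, time-by-edge interaction (time is centred in the generator).
#' @param sd_u0,sd_u1,cor_u Random intercept/slope sds and correlation.
#' @param sigma Baseline residual sd (at area = 1, mu = 1 scaling centre).
#' @param delta_area,delta_fitted Variance-scale exponents.
#' @param censuses Range (length-2 integer) of censuses per plot, sampled
#'   uniformly (unbalanced designs).
#' @param time_range Calendar range of census dates.
#' @param area_range Plot area range (ha), sampled log-uniformly.
#' @param seed RNG seed.
#' @return data.frame of observations (`plot_id`, `census_date`, `agb`,
#'   `area`, `edge_distance`, `is_edge`) with the generating parameters in
#'   the attribute `"truth"`.
#' @export
simulate_agb_observations <- function(n_plots = 71, prop_edge = 22 / 71,
                                      beta = c(400, 1.0, -40, -1.2),
                                      sd_u0 = 80, sd_u1 = 1.2, cor_u = 0,
                                      sigma = 15,
                                      delta_area = 0, delta_fitted = 0,
                                      censuses = c(2, 10),
                                      time_range = c(1970, 2012),
                                      area_range = c(0.25, 4.4), seed = 1) {
  set.seed(seed)
  mid <- mean(time_range)
  rows <- lapply(seq_len(n_plots), function(i) {
    is_edge <- i <= round(n_plots * prop_edge)
    area <- exp(stats::runif(1, log(area_range[1]), log(area_range[2])))
    nc <- sample(seq(censuses[1], censuses[2]), 1)
    dates <- sort(stats::runif(nc, time_range[1], time_range[2]))
    t <- dates - mid
    u <- c(stats::rnorm(1, 0, sd_u0), stats::rnorm(1, 0, sd_u1))
    if (abs(cor_u) > 0) {
      # bivariate draw via conditional normal
      u[2] <- cor_u * sd_u1 / sd_u0 * u[1] +
        stats::rnorm(1, 0, sd_u1 * sqrt(1 - cor_u^2))
    }
    mu <- beta[1] + beta[2] * t + (beta[3] + beta[4] * t) * is_edge +
      u[1] + u[2] * t
    sd_e <- sigma * area^(delta_area / 2) * (abs(mu) / beta[1])^(delta_fitted / 2)
    data.frame(plot_id = sprintf("P%03d", i), census_date = dates,
               agb = mu + stats::rnorm(nc, 0, sd_e), area = area,
               edge_distance = if (is_edge) 100 else 1000,
               is_edge = is_edge, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(beta = beta, sd_u0 = sd_u0, sd_u1 = sd_u1,
                             cor_u = cor_u, sigma = sigma,
                             delta_area = delta_area,
                             delta_fitted = delta_fitted, time_center = mid)
  out
}
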