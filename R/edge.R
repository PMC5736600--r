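#' Fit a model of AGB change against edge distance
#'
#' Fits one of four forms to per-plot AGB slopes as a function of distance
#' to the nearest anthropogenic forest edge:
#' \itemize{
#'   \item `"hockey"`: two linear segments joined continuously, the second
#'     with zero slope (the break-point is the edge-effect penetration
#'     distance). Fitted by profiling the break over a deterministic grid of
#'     observed distances plus their midpoints and minimizing the weighted
#'     SSE; ties go to the smaller break.
#'   \item `"asymptotic"`: y = a - b exp(-c x), weighted nonlinear least
#'     squares.
#'   \item `"linear"`: weighted simple regression.
#'   \item `"null"`: weighted mean (no edge relationship).
#' }
#' AIC is computed as n log(SSE_w / n) + 2k with the residual variance
#' counted as a parameter: k = 4 (hockey, asymptotic), 3 (linear),
#' 2 (null).
#'
#' @param trends Output of [plot_trends].
#' @param form Model form.
#' @param max_distance Restrict to plots with edge distance below this (m);
#'   `NULL` uses all plots.
#' @param weighted Use the cube-root monitoring-length weights in the SSE?
#' @param break_grid Optional candidate break-point grid for the hockey
#'   form (defaults to the observed distances plus midpoints); used by the
#'   bootstrap so every refit profiles over the full-data grid.
#' @return Object of class `edge_model_fit`: `form`, `params`, `aic`,
#'   `sse_w`, `n`, `k`, `fitted`, and the `(x, y, w)` data used.
#' @export
fit_edge_model <- function(trends, form = c("hockey", "asymptotic", "linear", "null"),
                           max_distance = 2000, weighted = TRUE,
                           break_grid = NULL) {
  form <- match.arg(form)
  d <- trends
  if (!is.null(max_distance)) {
    d <- d[d$edge_distance < max_distance, , drop = FALSE]
  }
  x <- d$edge_distance; y <- d$slope
  w <- if (weighted) d$weight else rep(1, nrow(d))
  n <- length(x)
  min_n <- switch(form, hockey = 4L, asymptotic = 4L, linear = 3L, null = 2L)
  if (n < min_n) {
    stop("need at least ", min_n, " plots to fit a ", form, " model; got ",
         n, call. = FALSE)
  }
  if (form == "null") {
    mu <- stats::weighted.mean(y, w)
    fitted <- rep(mu, n)
    params <- c(mean = mu)
    k <- 2L
  } else if (form == "linear") {
    fit <- stats::lm(y ~ x, weights = w)
    params <- c(intercept = unname(stats::coef(fit)[1]),
                slope = unname(stats::coef(fit)[2]))
    fitted <- unname(stats::fitted(fit))
    k <- 3L
  } else if (form == "hockey") {
    xs <- sort(unique(x))
    cand <- if (is.null(break_grid)) {
      sort(unique(c(xs, (xs[-1] + xs[-length(xs)]) / 2)))
    } else sort(unique(break_grid))
    eps <- 1e-9 * max(1, diff(range(xs)))
    cand <- cand[cand > min(xs) + eps & cand < max(xs) - eps]
    best <- NULL
    for (brk in cand) {
      z <- pmin(x, brk)
      fit <- stats::lm.wfit(cbind(1, z), y, w)
      sse <- sum(w * fit$residuals^2)
      if (is.null(best) || sse < best$sse - 1e-12) {
        best <- list(brk = brk, coef = fit$coefficients, sse = sse)
      }
    }
    params <- c(breakpoint = best$brk,
                intercept = unname(best$coef[1]),
                pre_slope = unname(best$coef[2]),
                plateau = unname(best$coef[1] + best$coef[2] * best$brk))
    fitted <- params["intercept"] + params["pre_slope"] * pmin(x, params["breakpoint"])
    fitted <- unname(fitted)
    k <- 4L
  } else {  # asymptotic
    a0 <- stats::weighted.mean(y[x > stats::median(x)], w[x > stats::median(x)])
    if (!is.finite(a0)) a0 <- mean(y)
    b0 <- a0 - y[which.min(x)]
    if (!is.finite(b0) || abs(b0) < 1e-8) b0 <- max(stats::sd(y), 0.1)
    dat <- data.frame(x = x, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - b * exp(-c * x), data = dat, weights = w,
                        start = list(a = a0, b = b0, c = 2 / stats::median(x)),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (stats::sd(y) < 1e-8 * max(1, abs(mean(y)))) {
        # constant response: degenerate asymptote with no edge component
        params <- c(a = stats::weighted.mean(y, w), b = 0, c = 1e-3)
        fitted <- rep(unname(params["a"]), n)
        k <- 4L
      } else {
        stop("asymptotic edge model failed to converge: ",
             conditionMessage(fit), call. = FALSE)
      }
    } else {
      params <- stats::coef(fit)[c("a", "b", "c")]
      fitted <- unname(stats::fitted(fit))
      k <- 4L
    }
  }
  sse_w <- sum(w * (y - fitted)^2)
  # floor the SSE so degenerate perfect fits rank by parameter count
  sse_eff <- max(sse_w, 1e-10 * max(1, sum(w * y^2)))
  structure(list(form = form, params = params,
                 aic = n * log(sse_eff / n) + 2 * k,
                 sse_w = sse_w, n = n, k = k, fitted = fitted,
                 x = x, y = y, w = w, weighted = weighted),
            class = "edge_model_fit")
}

#' @export
print.edge_model_fit <- function(x, ...) {
  cat("<edge_model_fit> ", x$form, ": ",
      paste(names(x$params), signif(x$params, 4), sep = "=", collapse = ", "),
      "; AIC=", round(x$aic, 1), ", n=", x$n, "\n", sep = "")
  invisible(x)
}

#' Rank edge-distance models by AIC
#'
#' @param fits List of `edge_model_fit` objects fitted to the same data.
#' @return data.frame sorted by AIC with `form`, `k`, `sse_w`, `aic`,
#'   `delta_aic`.
#' @export
compare_edge_models <- function(fits) {
  n <- vapply(fits, function(f) f$n, 0L)
  if (length(unique(n)) > 1) {
    stop("edge model fits use different numbers of plots: ",
         paste(n, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(
    form = vapply(fits, function(f) f$form, ""),
    k = vapply(fits, function(f) f$k, 0L),
    sse_w = vapply(fits, function(f) f$sse_w, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Bootstrap confidence interval for the hockey-stick break-point
#'
#' Resamples plots with replacement, refits the hockey-stick model on each
#' resample, and returns the percentile interval of the break-point.
#'
#' @param trends Output of [plot_trends].
#' @param n_boot Number of resamples.
#' @param seed RNG seed.
#' @param max_distance,weighted Passed to [fit_edge_model].
#' @param conf Confidence level.
#' @return List with `breakpoint` (full-data fit), `ci`, `boot_breaks`,
#'   `n_failed`. Errors if more than 20% of refits fail.
#' @export
bootstrap_breakpoint <- function(trends, n_boot = 999, seed = 20171219,
                                 max_distance = 2000, weighted = TRUE,
                                 conf = 0.95) {
  full <- fit_edge_model(trends, "hockey", max_distance = max_distance,
                         weighted = weighted)
  d <- trends
  if (!is.null(max_distance)) {
    d <- d[d$edge_distance < max_distance, , drop = FALSE]
  }
  xs <- sort(unique(d$edge_distance))
  grid <- sort(unique(c(xs, (xs[-1] + xs[-length(xs)]) / 2)))
  set.seed(seed)
  breaks <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
    res <- d[idx, , drop = FALSE]
    if (length(unique(res$edge_distance)) < 3) next
    fit <- tryCatch(fit_edge_model(res, "hockey", max_distance = NULL,
                                   weighted = weighted, break_grid = grid),
                    error = function(e) NULL)
    if (!is.null(fit)) breaks[b] <- fit$params[["breakpoint"]]
  }
  n_failed <- sum(is.na(breaks))
  if (n_failed > 0.2 * n_boot) {
    stop("hockey-stick refit failed in ", n_failed, "/", n_boot,
         " bootstrap resamples", call. = FALSE)
  }
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(breakpoint = full$params[["breakpoint"]],
       ci = unname(stats::quantile(breaks, alpha, na.rm = TRUE)),
       boot_breaks = breaks[!is.na(breaks)], n_failed = n_failed)
}
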