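#' Fit a height-diameter model
#'
#' Fits one of three height-diameter (H-D) forms to a sample of measured
#' heights: a three-parameter Weibull curve H = a(1 - exp(-b D^c)) by
#' ordinary least squares, the same curve weighted by stem basal area
#' (weights proportional to D^2, giving more influence to large trees), or
#' a log-log model ln(H) = a + b ln(D).
#'
#' @param heights data.frame with columns `diameter` (cm) and `height` (m).
#' @param form One of `"weibull"`, `"weibull_ba_weighted"`, `"loglog"`.
#' @param forest_type Optional label (e.g. `"moist_dipterocarp"`) carried in
#'   the fitted object.
#' @return An object of class `hd_model`: list with `form`, `params` (named
#'   numeric: `a`, `b`, `c` for Weibull forms; `a`, `b` for log-log),
#'   `forest_type`, `fit_n`, and `convergence` diagnostics.
#' @export
fit_hd_model <- function(heights,
                         form = c("weibull", "weibull_ba_weighted", "loglog"),
                         forest_type = NA_character_) {
  form <- match.arg(form)
  d <- heights$diameter
  h <- heights$height
  keep <- is.finite(d) & is.finite(h) & d > 0 & h > 0
  d <- d[keep]; h <- h[keep]
  if (length(d) < 10) {
    stop("need at least 10 positive (D, H) pairs; got ", length(d),
         call. = FALSE)
  }
  if (form == "loglog") {
    fit <- stats::lm(log(h) ~ log(d))
    params <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
    conv <- list(converged = TRUE, iterations = 0L,
                 deviance = sum(stats::resid(fit)^2))
  } else {
    w <- if (form == "weibull_ba_weighted") pi * (d / 200)^2 else rep(1, length(d))
    dat <- data.frame(d = d, h = h)
    start <- list(a = max(h) * 1.05, b = 0.05, c = 0.9)
    fit <- tryCatch(
      minpack.lm::nlsLM(h ~ a * (1 - exp(-b * d^c)), data = dat,
                        start = start, weights = w,
                        lower = c(a = 1, b = 1e-6, c = 0.05),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      stop("Weibull H-D fit failed to converge: ", conditionMessage(fit),
           call. = FALSE)
    }
    params <- stats::coef(fit)[c("a", "b", "c")]
    info <- fit$convInfo
    conv <- list(converged = isTRUE(info$isConv),
                 iterations = info$finIter,
                 deviance = stats::deviance(fit))
    if (!conv$converged) {
      stop("Weibull H-D fit did not converge after ", conv$iterations,
           " iterations; best iterate: a=", signif(params["a"], 6),
           " b=", signif(params["b"], 6), " c=", signif(params["c"], 6),
           ", deviance=", signif(conv$deviance, 6), call. = FALSE)
    }
  }
  structure(list(form = form, params = params, forest_type = forest_type,
                 fit_n = length(d), convergence = conv),
            class = "hd_model")
}

#' Predict tree height from diameter
#'
#' @param object An `hd_model`.
#' @param diameter Diameter(s) at POM, cm.
#' @param ... Unused.
#' @return Predicted total height(s), m.
#' @export
predict.hd_model <- function(object, diameter, ...) {
  p <- object$params
  if (object$form == "loglog") {
    exp(p[["a"]] + p[["b"]] * log(diameter))
  } else {
    p[["a"]] * (1 - exp(-p[["b"]] * diameter^p[["c"]]))
  }
}

#' @export
print.hd_model <- function(x, ...) {
  cat("<hd_model> ", x$form,
      if (!is.na(x$forest_type)) paste0(" (", x$forest_type, ")"), ": ",
      paste(names(x$params), signif(x$params, 5), sep = "=", collapse = ", "),
      "; n=", x$fit_n, "\n", sep = "")
  invisible(x)
}

#' Select the H-D model minimizing AGB prediction error
#'
#' Candidates are ranked by the summed absolute difference between stem AGB
#' computed from measured heights and stem AGB computed from model-predicted
#' heights, over the height sample. Ties are broken by the deterministic
#' preference order weibull > weibull_ba_weighted > loglog.
#'
#' @param candidates List of `hd_model` objects fitted on the same sample.
#' @param heights data.frame with columns `diameter`, `height` and
#'   optionally `wd` (wood density, g/cm3; defaults to 0.6).
#' @return The selected `hd_model`; attribute `"selection"` holds the
#'   per-candidate AGB errors (kg).
#' @export
select_hd_model <- function(candidates, heights) {
  wd <- if (!is.null(heights$wd)) heights$wd else rep(0.6, nrow(heights))
  agb_meas <- stem_agb(heights$diameter, heights$height, wd)
  errs <- vapply(candidates, function(mod) {
    sum(abs(agb_meas - stem_agb(heights$diameter,
                                predict(mod, heights$diameter), wd)))
  }, 0)
  pref <- match(vapply(candidates, function(m) m$form, ""),
                c("weibull", "weibull_ba_weighted", "loglog"))
  best <- order(errs, pref)[1]
  out <- candidates[[best]]
  attr(out, "selection") <- data.frame(
    form = vapply(candidates, function(m) m$form, ""),
    agb_error = errs, selected = seq_along(candidates) == best,
    stringsAsFactors = FALSE)
  out
}

#' Read a wood-density lookup table
#'
#' @param path CSV with columns `family`, `genus`, `species`, `wd_g_cm3`;
#'   genus-level rows leave `species` empty and family-level rows leave both
#'   `genus` and `species` empty.
#' @return The validated lookup data.frame.
#' @export
read_wood_density <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  miss <- setdiff(c("family", "genus", "species", "wd_g_cm3"), names(tab))
  if (length(miss)) {
    stop("wood-density table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$wd_g_cm3) | tab$wd_g_cm3 <= 0)) {
    stop("wood-density values must be positive", call. = FALSE)
  }
  tab
}

#' Assign wood density to every stem of a plot
#'
#' Wood density is looked up by taxonomic hierarchy: the species-level value
#' when the stem's genus + species match a table row, else the genus mean,
#' else the family mean, else the mean wood density of all identified stems
#' in the plot (provenance `"plot_mean"`).
#'
#' @param plot A [plot_data] object.
#' @param wd_table Lookup table as returned by [read_wood_density].
#' @return The plot with `stems$wood_density` and `stems$wd_level` filled.
#' @export
assign_wood_density <- function(plot, wd_table) {
  s <- plot$stems
  if (!nrow(s)) return(plot)
  blank <- function(x) is.na(x) | x == ""
  sp_rows <- !blank(wd_table$species)
  gn_rows <- blank(wd_table$species) & !blank(wd_table$genus)
  fa_rows <- blank(wd_table$species) & blank(wd_table$genus) & !blank(wd_table$family)
  wd <- rep(NA_real_, nrow(s))
  lvl <- rep(NA_character_, nrow(s))
  i <- match(paste(s$genus, s$species),
             paste(wd_table$genus, wd_table$species)[sp_rows])
  hit <- !is.na(i) & !blank(s$species) & !blank(s$genus)
  wd[hit] <- wd_table$wd_g_cm3[sp_rows][i[hit]]
  lvl[hit] <- "species"
  todo <- is.na(wd)
  i <- match(s$genus[todo], wd_table$genus[gn_rows])
  hit <- !is.na(i) & !blank(s$genus[todo])
  wd[todo][hit] <- wd_table$wd_g_cm3[gn_rows][i[hit]]
  lvl[todo][hit] <- "genus"
  todo <- is.na(wd)
  i <- match(s$family[todo], wd_table$family[fa_rows])
  hit <- !is.na(i) & !blank(s$family[todo])
  wd[todo][hit] <- wd_table$wd_g_cm3[fa_rows][i[hit]]
  lvl[todo][hit] <- "family"
  todo <- is.na(wd)
  if (any(todo)) {
    if (all(todo)) {
      stop("plot '", plot$plot_id,
           "' has no taxonomically identified stems: cannot form plot-mean wood density",
           call. = FALSE)
    }
    wd[todo] <- mean(wd[!todo])
    lvl[todo] <- "plot_mean"
  }
  s$wood_density <- wd
  s$wd_level <- lvl
  plot$stems <- s
  plot
}

#' Stem above-ground biomass
#'
#' AGB (kg, dry mass) of a single stem from diameter, height and wood
#' density: 0.0673 (rho D^2 H)^0.976 for non-monocots, and the
#' diameter-only form exp(-3.3488 + 2.7483 ln D) for monocot families
#' (height and wood density are ignored for monocots). Vectorized over all
#' arguments.
#'
#' @param diameter Diameter at POM, cm.
#' @param height Total height, m (ignored for monocots).
#' @param wd Wood density, g/cm3 (ignored for monocots).
#' @param monocot Logical; monocot allometry?
#' @return AGB in kg.
#' @export
stem_agb <- function(diameter, height = NULL, wd = NULL, monocot = FALSE) {
  n <- max(length(diameter), length(height), length(wd), length(monocot))
  diameter <- rep_len(diameter, n)
  monocot <- rep_len(monocot, n)
  if (any(!is.finite(diameter) | diameter <= 0)) {
    stop("diameter must be positive and finite", call. = FALSE)
  }
  out <- numeric(n)
  if (any(monocot)) {
    out[monocot] <- exp(-3.3488 + 2.7483 * log(diameter[monocot]))
  }
  if (any(!monocot)) {
    if (is.null(height) || is.null(wd)) {
      stop("height and wood density are required for non-monocot stems",
           call. = FALSE)
    }
    height <- rep_len(height, n)
    wd <- rep_len(wd, n)
    i <- !monocot
    if (any(!is.finite(height[i]) | height[i] <= 0 |
            !is.finite(wd[i]) | wd[i] <= 0)) {
      stop("height and wood density must be positive and finite for non-monocots",
           call. = FALSE)
    }
    out[i] <- 0.0673 * (wd[i] * diameter[i]^2 * height[i])^0.976
  }
  out
}
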