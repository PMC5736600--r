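#' Run the full biomass-dynamics pipeline on a plot network
#'
#' Convenience wrapper chaining the module steps: per-plot quality control
#' ([qc_plot]), wood-density assignment ([assign_wood_density]), fitting
#' and selection of the height-diameter model ([fit_hd_model],
#' [select_hd_model]), census-level observations and interval dynamics
#' ([network_observations], [network_dynamics]), per-plot trends
#' ([plot_trends]), the edge-distance model comparison with bootstrap
#' break-point CI ([fit_edge_model], [compare_edge_models],
#' [bootstrap_breakpoint]), and the mixed-effects trend model ([fit_lme])
#' at the hockey-stick break-point (or a fixed threshold).
#'
#' @param plots List of [plot_data] objects.
#' @param heights Height sample data.frame (`plot_id`, `tag`, `diameter`,
#'   `height`) pooled over plots.
#' @param wd_table Wood-density lookup ([read_wood_density] format).
#' @param edge_threshold `"auto"` (use the fitted hockey-stick break) or a
#'   fixed distance in m.
#' @param max_distance Edge-model fitting restricted to plots nearer than
#'   this (m).
#' @param n_boot Bootstrap resamples for the break-point CI.
#' @param seed RNG seed for the bootstrap.
#' @param var_power Estimate the LME power variance function?
#' @return List with `plots` (QC'd), `hd_model`, `observations`,
#'   `dynamics`, `trends`, `edge_fits`, `edge_comparison`, `breakpoint`
#'   (bootstrap result), `edge_threshold` (the one used), `lme`, and
#'   `qc_summary`.
#' @export
run_pipeline <- function(plots, heights, wd_table, edge_threshold = "auto",
                         max_distance = 2000, n_boot = 999,
                         seed = 20171219, var_power = TRUE) {
  plots <- lapply(plots, qc_plot)
  qc_summary <- list(
    corrected_fraction = stats::weighted.mean(
      vapply(plots, function(p) attr(p, "qc_report")$corrected_fraction, 0),
      vapply(plots, function(p) attr(p, "qc_report")$n_measurements, 0)))
  plots <- lapply(plots, assign_wood_density, wd_table = wd_table)
  forms <- c("weibull", "weibull_ba_weighted", "loglog")
  cand <- lapply(forms, function(f) fit_hd_model(heights, f))
  hd <- select_hd_model(cand, heights)
  obs <- network_observations(plots, hd)
  dyn <- network_dynamics(plots, hd)
  trends <- plot_trends(obs, edge_threshold = if (identical(edge_threshold, "auto")) 448 else edge_threshold)
  edge_fits <- lapply(c("hockey", "asymptotic", "linear", "null"),
                      function(f) fit_edge_model(trends, f,
                                                 max_distance = max_distance))
  names(edge_fits) <- c("hockey", "asymptotic", "linear", "null")
  comparison <- compare_edge_models(edge_fits)
  bp <- bootstrap_breakpoint(trends, n_boot = n_boot, seed = seed,
                             max_distance = max_distance)
  thr <- if (identical(edge_threshold, "auto")) bp$breakpoint else edge_threshold
  trends$is_edge <- trends$edge_distance < thr
  obs$is_edge <- obs$edge_distance < thr
  lme <- fit_lme(obs, edge_threshold = thr, var_power = var_power)
  list(plots = plots, hd_model = hd, observations = obs, dynamics = dyn,
       trends = trends, edge_fits = edge_fits, edge_comparison = comparison,
       breakpoint = bp, edge_threshold = thr, lme = lme,
       qc_summary = qc_summary)
}
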