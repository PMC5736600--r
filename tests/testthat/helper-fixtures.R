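# Shared fixtures built in code. The default simulated network (the study
# design the package emulates) is expensive, so it is computed once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# a fixed Weibull H-D model for hand computations
fixed_hd_model <- function(a = 60, b = 0.03, c = 0.9) {
  structure(list(form = "weibull", params = c(a = a, b = b, c = c),
                 forest_type = NA_character_, fit_n = 0L,
                 convergence = list(converged = TRUE)),
            class = "hd_model")
}

# three-tree toy plot: one survivor (20 -> 22 cm), one recruit (10.5 cm at
# the second census), one death (30 cm at the first census); t = 5 yr, 1 ha
toy_interval_plot <- function() {
  stems <- data.frame(
    tag = c("T1", "T2", "T3"), family = "family01", genus = "genus001",
    species = c("sp001", "sp002", "sp003"), monocot = FALSE,
    wood_density = c(0.6, 0.62, 0.58), wd_level = "species",
    stringsAsFactors = FALSE)
  meas <- data.frame(
    tag = c("T1", "T1", "T2", "T3", "T3"),
    census_date = c(2000, 2005, 2005, 2000, 2005),
    diameter = c(20, 22, 10.5, 30, NA),
    pom = c(1.3, 1.3, 1.3, 1.3, NA),
    status = c("alive", "alive", "recruit", "alive", "dead"),
    stringsAsFactors = FALSE)
  plot_data("TOY", 1, 1000, 10, stems = stems, measurements = meas)
}

default_network <- function() {
  if (is.null(.fixture_cache$net)) {
    .fixture_cache$net <- simulate_network(sim_config(seed = 20171219))
  }
  .fixture_cache$net
}

# QC'd plots, wood density, selected H-D model, observations, dynamics and
# trends for the default network
default_analysis <- function() {
  if (is.null(.fixture_cache$analysis)) {
    net <- default_network()
    plots <- suppressWarnings(lapply(net$plots, qc_plot))
    plots <- lapply(plots, assign_wood_density, wd_table = net$wd_table)
    cand <- lapply(c("weibull", "weibull_ba_weighted", "loglog"),
                   function(f) fit_hd_model(net$heights, f))
    hd <- select_hd_model(cand, net$heights)
    obs <- suppressWarnings(network_observations(plots, hd))
    dyn <- suppressWarnings(network_dynamics(plots, hd))
    .fixture_cache$analysis <- list(
      net = net, plots = plots, hd = hd, obs = obs, dyn = dyn,
      trends = plot_trends(obs))
  }
  .fixture_cache$analysis
}

# heteroscedastic observation-level generator used for the variance-function
# recovery checks: wide fitted-value span, 15 censuses per plot
gen_het_obs <- function(seed, delta_area, delta_fitted, n_plots = 150,
                        sigma = 12) {
  set.seed(seed)
  out <- lapply(seq_len(n_plots), function(i) {
    is_edge <- i <= n_plots / 2
    area <- exp(stats::runif(1, log(0.25), log(4.4)))
    dates <- sort(stats::runif(15, 1970, 2012))
    t <- dates - 1991
    u0 <- stats::rnorm(1, 0, 180); u1 <- stats::rnorm(1, 0, 0.3)
    mu <- pmax(500 + 1.0 * t + (-150 - 1.2 * t) * is_edge + u0 + u1 * t, 60)
    sd <- sigma * area^(delta_area / 2) * (mu / 500)^(delta_fitted / 2)
    data.frame(plot_id = sprintf("P%03d", i), census_date = dates,
               agb = mu + stats::rnorm(15, 0, sd), area = area,
               edge_distance = if (is_edge) 100 else 1000,
               is_edge = is_edge, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
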