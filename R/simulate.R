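#' Configuration for the stand-demography simulator
#'
#' Builds the parameter set controlling [simulate_stand] and
#' [simulate_network]. Defaults emulate a lowland Bornean plot network:
#' 71 plots (22 edge, 49 interior; 7 with a 15 cm minimum diameter),
#' 0.25-4.4 ha, censused every 2-6 years between the early 1970s and
#' mid-2010s, stems >= 10 cm at about 530/ha, interior stem mortality
#' 1.8%/yr against 2.3%/yr near edges, recruitment balancing mortality,
#' and a drought year in 1997-1998 that multiplies the mortality hazard and
#' is followed by a growth stimulus.
#'
#' @param seed RNG seed (mandatory; every quantity is reproducible from
#'   it).
#' @param n_plots,n_edge,n_min15 Network design: total plots, edge plots
#'   (simulated with edge distance below `edge_threshold`), plots with a
#'   15 cm minimum diameter.
#' @param edge_threshold Depth (m) of the edge-effect step: plots nearer
#'   than this get the edge demography.
#' @param stem_density Initial live stems per ha above the minimum
#'   diameter.
#' @param init_size_scale Exponential scale (cm) of initial diameters above
#'   the minimum.
#' @param growth_means Mean annual diameter increment (cm/yr) in the size
#'   classes 10-19.9, 20-39.9, >=40 cm.
#' @param growth_sdlog Lognormal sd (log scale) of annual increments.
#' @param mortality_rate Baseline stem mortality, %/yr.
#' @param mortality_size_exp Exponent of the size bias of the mortality
#'   hazard (hazard proportional to (D/20)^-exp, renormalized so the mean
#'   hazard equals `mortality_rate`); positive values concentrate death in
#'   small stems, which lowers biomass mortality below mortality_rate x AGB
#'   and produces a net biomass sink.
#' @param edge_mort_mult Multiplier on the mortality hazard in edge plots.
#' @param edge_growth_mult Multiplier on mean diameter growth in edge
#'   plots (elevated turnover opens the canopy).
#' @param recruit_rate,edge_recruit_rate Recruitment intensity, %/yr of the
#'   live stem count, interior and edge.
#' @param edge_recruit_wd_tilt Strength of the low-wood-density bias of
#'   edge recruitment (species sampling weight proportional to
#'   exp(-tilt x WD); 0 = no compositional shift).
#' @param drought List of events, each a list with `start`, `end` (decimal
#'   years), `mort_mult` (event-year hazard multiplier), `post_growth_mult`
#'   and `post_years` (growth stimulus after the event).
#' @param drift Linear trend in the growth multiplier per year (0 =
#'   stationary growth).
#' @param hd_params True Weibull height-diameter parameters (a, b, c).
#' @param height_noise_sd Lognormal sd of measured heights around the true
#'   curve.
#' @param wd_mean,wd_sd Species wood-density distribution (g/cm3).
#' @param n_species,n_genera,n_families Size of the synthetic species pool.
#' @param monocot_frac Fraction of species that are monocots.
#' @param p_unident_species,p_unident_genus,p_unident_family Probability
#'   that a stem lacks species / genus / family identification.
#' @param dbh_noise_sd Diameter measurement error sd (cm).
#' @param pom_change_prob Per-census probability that a stem >=
#'   `pom_min_diameter` gets a new POM.
#' @param pom_min_diameter Diameter above which POM changes can occur (cm).
#' @param taper_range Range of the per-change taper ratio (new/old).
#' @param first_census_range,n_intervals_range,interval_range,last_census
#'   Census schedule: first census date range, number of intervals,
#'   interval length (whole years), and latest possible census.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_plots = 71, n_edge = 22, n_min15 = 7,
                       edge_threshold = 448,
                       stem_density = 530, init_size_scale = 13,
                       growth_means = c(0.17, 0.24, 0.20),
                       growth_sdlog = 0.7,
                       mortality_rate = 1.8, mortality_size_exp = 0.4,
                       edge_mort_mult = 2.3 / 1.8, edge_growth_mult = 1.05,
                       recruit_rate = 1.6, edge_recruit_rate = 2.3,
                       edge_recruit_wd_tilt = 3,
                       drought = list(list(start = 1997.5, end = 1998.5,
                                           mort_mult = 4.0,
                                           post_growth_mult = 1.30,
                                           post_years = 12)),
                       drift = 0,
                       hd_params = c(a = 61.8, b = 0.035, c = 0.93),
                       height_noise_sd = 0.06,
                       wd_mean = 0.60, wd_sd = 0.09,
                       n_species = 150, n_genera = 45, n_families = 16,
                       monocot_frac = 0.02,
                       p_unident_species = 0.08, p_unident_genus = 0.03,
                       p_unident_family = 0.01,
                       dbh_noise_sd = 0.1,
                       pom_change_prob = 0.02, pom_min_diameter = 30,
                       taper_range = c(0.85, 0.97),
                       first_census_range = c(1972, 1994),
                       n_intervals_range = c(2, 9),
                       interval_range = c(2, 6),
                       last_census = 2014) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(cfg$n_plots >= 1, cfg$n_edge >= 0, cfg$n_edge <= cfg$n_plots,
            cfg$mortality_rate >= 0, cfg$recruit_rate >= 0,
            cfg$stem_density > 0, all(cfg$growth_means >= 0),
            cfg$monocot_frac >= 0, cfg$monocot_frac <= 1,
            cfg$dbh_noise_sd >= 0, cfg$pom_change_prob >= 0,
            cfg$pom_change_prob <= 1)
  structure(cfg, class = "sim_config")
}

# integer draw from an inclusive range (safe for degenerate ranges)
sample_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1, n, replace = TRUE) - 1
}

# deterministic per-plot RNG substream
plot_seed <- function(seed, plot_index) {
  as.integer((as.numeric(seed) + 104729 * plot_index) %% 2147483629)
}

# synthetic species pool: taxonomy + species wood densities (one monocot
# block of species); deterministic given config$seed
species_pool <- function(config) {
  set.seed(plot_seed(config$seed, 0))
  fam_of_gen <- sort(sample.int(config$n_families, config$n_genera,
                                replace = TRUE))
  gen_of_sp <- sort(sample.int(config$n_genera, config$n_species,
                               replace = TRUE))
  wd <- pmin(0.95, pmax(0.25, stats::rnorm(config$n_species,
                                           config$wd_mean, config$wd_sd)))
  n_mono <- round(config$monocot_frac * config$n_species)
  monocot <- seq_len(config$n_species) <= n_mono
  # monocots get their own family so the flag is taxonomically coherent
  fam <- sprintf("family%02d", fam_of_gen[gen_of_sp])
  gen <- sprintf("genus%03d", gen_of_sp)
  fam[monocot] <- "familyMC"
  gen[monocot] <- "genusMC1"
  data.frame(species_id = seq_len(config$n_species),
             family = fam, genus = gen,
             species = sprintf("sp%03d", seq_len(config$n_species)),
             wd = wd, monocot = monocot, stringsAsFactors = FALSE)
}

#' Wood-density lookup table of the simulated species pool
#'
#' Species-level rows plus genus and family means, in the format read by
#' [read_wood_density].
#'
#' @param config A [sim_config].
#' @return data.frame with columns `family`, `genus`, `species`,
#'   `wd_g_cm3`.
#' @export
sim_wood_density_table <- function(config) {
  pool <- species_pool(config)
  sp <- data.frame(family = pool$family, genus = pool$genus,
                   species = pool$species, wd_g_cm3 = pool$wd,
                   stringsAsFactors = FALSE)
  gn <- do.call(rbind, lapply(split(pool, pool$genus), function(g) {
    data.frame(family = g$family[1], genus = g$genus[1],
               species = NA_character_, wd_g_cm3 = mean(g$wd),
               stringsAsFactors = FALSE)
  }))
  fa <- do.call(rbind, lapply(split(pool, pool$family), function(f) {
    data.frame(family = f$family[1], genus = NA_character_,
               species = NA_character_, wd_g_cm3 = mean(f$wd),
               stringsAsFactors = FALSE)
  }))
  out <- rbind(sp, gn, fa)
  rownames(out) <- NULL
  out
}

true_height <- function(d, hd_params) {
  hd_params[["a"]] * (1 - exp(-hd_params[["b"]] * d^hd_params[["c"]]))
}

true_agb <- function(d, wd, monocot, hd_params) {
  stem_agb(d, true_height(d, hd_params), wd, monocot)
}

sim_growth_class <- function(d) {
  findInterval(d, c(0, 20, 40))
}

#' Simulate one forest plot through its census history
#'
#' Annual-time-step stand demography: each live stem grows by a lognormal
#' diameter increment with a size-class mean, dies with a size-biased
#' Bernoulli hazard (renormalized to the configured stem mortality rate,
#' multiplied up in edge plots and in drought years), and recruits enter at
#' the minimum diameter with Poisson intensity. Censuses observe diameters
#' with measurement error; large stems occasionally receive a new POM, in
#' which case the census records the diameter at both the old and new POM.
#' Output is deterministic given `(config$seed, plot_index)`.
#'
#' @param config A [sim_config].
#' @param plot_index Plot number in 1..n_plots; indices up to
#'   `config$n_edge` are edge plots, the last `config$n_min15` use a 15 cm
#'   minimum diameter.
#' @return List with `plot` (a [plot_data]; stems carry the simulated
#'   taxonomy, with a fraction left unidentified), `truth` (true annual AGB
#'   trajectory, per-interval true AGWP and biomass mortality and per-year
#'   live/death counts computed from the complete event stream, true trend
#'   slope, design attributes), and
#'   `heights` (a measured height sample from the final census).
#' @export
simulate_stand <- function(config, plot_index) {
  stopifnot(inherits(config, "sim_config"))
  pool <- species_pool(config)
  set.seed(plot_seed(config$seed, plot_index))
  is_edge <- plot_index <= config$n_edge
  min_d <- if (plot_index > config$n_plots - config$n_min15) 15 else 10
  area <- min(4.4, max(0.25, stats::rlnorm(1, log(0.95), 0.55)))
  edge_distance <- if (is_edge) {
    stats::runif(1, 30, 0.98 * config$edge_threshold)
  } else {
    exp(stats::runif(1, log(1.1 * config$edge_threshold), log(8000)))
  }
  first <- round(stats::runif(1, config$first_census_range[1],
                              config$first_census_range[2]), 1)
  n_int <- sample_range(config$n_intervals_range[1],
                        config$n_intervals_range[2])
  gaps <- sample_range(config$interval_range[1], config$interval_range[2],
                       n_int)
  dates <- first + cumsum(c(0, gaps))
  dates <- dates[dates <= config$last_census]
  if (length(dates) < 2) dates <- first + c(0, gaps[1])

  # stem state
  n0 <- stats::rpois(1, config$stem_density * area)
  D <- min_d + pmin(170, stats::rexp(n0, 1 / config$init_size_scale))
  sp <- sample.int(nrow(pool), n0, replace = TRUE)
  alive <- rep(TRUE, n0)
  taper <- rep(1, n0)
  pom <- rep(1.3, n0)
  recorded <- rep(FALSE, n0)
  dead_recorded <- rep(FALSE, n0)

  base_mort <- config$mortality_rate / 100 *
    (if (is_edge) config$edge_mort_mult else 1)
  rec_rate <- (if (is_edge) config$edge_recruit_rate else config$recruit_rate) / 100

  obs <- list()
  truth_times <- numeric()
  truth_agb <- numeric()
  ann_year <- numeric(); ann_live <- integer(); ann_die <- integer()
  int_gain <- 0; int_loss <- 0
  truth_int <- list()
  cur_interval <- 1L

  record_census <- function(t_now) {
    meas_d <- D * taper + stats::rnorm(length(D), 0, config$dbh_noise_sd)
    new_rec <- alive & !recorded & meas_d >= min_d
    recordable <- alive & (recorded | new_rec)
    rows <- which(recordable)
    first_census <- abs(t_now - dates[1]) < 1e-9
    status <- if (first_census) rep("alive", length(rows)) else
      ifelse(recorded[rows], "alive", "recruit")
    d_new <- rep(NA_real_, length(rows))
    pom_new <- rep(NA_real_, length(rows))
    # POM changes among previously recorded large stems
    big <- recorded[rows] & D[rows] >= config$pom_min_diameter
    chg <- big & stats::runif(length(rows)) < config$pom_change_prob
    if (any(chg)) {
      u <- stats::runif(sum(chg), config$taper_range[1], config$taper_range[2])
      idx <- rows[chg]
      taper_new <- taper[idx] * u
      d_new[chg] <- D[idx] * taper_new +
        stats::rnorm(sum(chg), 0, config$dbh_noise_sd)
      pom_new[chg] <- pom[idx] + stats::runif(sum(chg), 0.4, 1.2)
      taper[idx] <<- taper_new
      pom[idx] <<- pom_new[chg]
    }
    dying <- which(!alive & recorded & !dead_recorded)
    recorded[rows] <<- TRUE
    dead_recorded[dying] <<- TRUE
    obs[[length(obs) + 1]] <<- data.frame(
      tag = sprintf("P%03dT%05d", plot_index, c(rows, dying)),
      census_date = t_now,
      diameter = c(meas_d[rows], rep(NA_real_, length(dying))),
      pom = c(pom[rows], rep(NA_real_, length(dying))),
      status = c(status, rep("dead", length(dying))),
      flag = "accepted",
      diameter_new = c(d_new, rep(NA_real_, length(dying))),
      pom_new = c(pom_new, rep(NA_real_, length(dying))),
      stringsAsFactors = FALSE)
  }

  t_now <- dates[1]
  repeat {
    at_census <- any(abs(dates - t_now) < 1e-9)
    if (at_census) {
      record_census(t_now)
      truth_times <- c(truth_times, t_now)
      truth_agb <- c(truth_agb,
                     sum(true_agb(D[alive], pool$wd[sp[alive]],
                                  pool$monocot[sp[alive]], config$hd_params)) /
                       1000 / area)
      if (t_now > dates[cur_interval] + 1e-9) {
        truth_int[[cur_interval]] <- data.frame(
          start = dates[cur_interval], end = t_now,
          t = t_now - dates[cur_interval],
          agwp_true = int_gain / 1000 / area / (t_now - dates[cur_interval]),
          mort_true = int_loss / 1000 / area / (t_now - dates[cur_interval]))
        cur_interval <- cur_interval + 1L
        int_gain <- 0; int_loss <- 0
      }
    } else {
      truth_times <- c(truth_times, t_now)
      truth_agb <- c(truth_agb,
                     sum(true_agb(D[alive], pool$wd[sp[alive]],
                                  pool$monocot[sp[alive]], config$hd_params)) /
                       1000 / area)
    }
    if (t_now >= dates[length(dates)] - 1e-9) break

    # ---- advance demography one year ----
    live <- which(alive)
    g_mult <- (1 + config$drift * (t_now - dates[1])) *
      (if (is_edge) config$edge_growth_mult else 1)
    mort_mult <- 1
    for (ev in config$drought) {
      frac <- max(0, min(t_now + 1, ev$end) - max(t_now, ev$start))
      mort_mult <- mort_mult * (1 + (ev$mort_mult - 1) * frac)
      if (t_now + 0.5 >= ev$end && t_now + 0.5 < ev$end + ev$post_years) {
        g_mult <- g_mult * ev$post_growth_mult
      }
    }
    cls <- sim_growth_class(D[live])
    g_mean <- config$growth_means[cls] * g_mult
    agb_before <- true_agb(D[live], pool$wd[sp[live]], pool$monocot[sp[live]],
                           config$hd_params)
    D[live] <- D[live] + stats::rlnorm(length(live),
                                       log(g_mean) - config$growth_sdlog^2 / 2,
                                       config$growth_sdlog)
    agb_after <- true_agb(D[live], pool$wd[sp[live]], pool$monocot[sp[live]],
                          config$hd_params)
    int_gain <- int_gain + sum(agb_after - agb_before)
    hazard <- (D[live] / 20)^(-config$mortality_size_exp)
    p_die <- pmin(0.9, hazard / mean(hazard) * base_mort * mort_mult)
    dies <- stats::runif(length(live)) < p_die
    ann_year <- c(ann_year, t_now)
    ann_live <- c(ann_live, length(live))
    ann_die <- c(ann_die, sum(dies))
    if (any(dies)) {
      alive[live[dies]] <- FALSE
      int_loss <- int_loss + sum(agb_after[dies])
    }
    n_new <- stats::rpois(1, rec_rate * sum(alive))
    if (n_new > 10 * config$stem_density * area ||
        sum(alive) > 1e5) {
      stop("demographic explosion in plot ", plot_index,
           ": check the configuration", call. = FALSE)
    }
    if (n_new > 0) {
      w_sp <- if (is_edge && config$edge_recruit_wd_tilt > 0) {
        exp(-config$edge_recruit_wd_tilt * pool$wd)
      } else rep(1, nrow(pool))
      new_sp <- sample.int(nrow(pool), n_new, replace = TRUE, prob = w_sp)
      new_d <- min_d + stats::runif(n_new, 0, 0.3)
      int_gain <- int_gain + sum(true_agb(new_d, pool$wd[new_sp],
                                          pool$monocot[new_sp],
                                          config$hd_params))
      D <- c(D, new_d); sp <- c(sp, new_sp)
      alive <- c(alive, rep(TRUE, n_new))
      taper <- c(taper, rep(1, n_new))
      pom <- c(pom, rep(1.3, n_new))
      recorded <- c(recorded, rep(FALSE, n_new))
      dead_recorded <- c(dead_recorded, rep(FALSE, n_new))
    }
    t_now <- t_now + 1
  }

  meas <- do.call(rbind, obs)
  rec_tags <- unique(meas$tag)
  stem_idx <- as.integer(sub("^P\\d+T", "", rec_tags))
  s_pool <- pool[sp[stem_idx], , drop = FALSE]
  # a fraction of stems lacks identification at each taxonomic level
  u <- stats::runif(length(rec_tags))
  no_fam <- u < config$p_unident_family
  no_gen <- u < config$p_unident_family + config$p_unident_genus
  no_sp <- u < config$p_unident_family + config$p_unident_genus +
    config$p_unident_species
  stems <- data.frame(
    tag = rec_tags,
    family = ifelse(no_fam, NA_character_, s_pool$family),
    genus = ifelse(no_gen, NA_character_, s_pool$genus),
    species = ifelse(no_sp, NA_character_, s_pool$species),
    monocot = s_pool$monocot, stringsAsFactors = FALSE)
  plot <- plot_data(sprintf("P%03d", plot_index), area, edge_distance, min_d,
                    stems = stems, measurements = meas,
                    census_dates = dates,
                    forest_type = "moist_dipterocarp")

  # measured height sample at the final census: the 10 largest stems plus a
  # random subsample, heights around the true curve with lognormal noise
  live <- which(alive & recorded & !pool$monocot[sp])
  n_h <- min(100, length(live))
  ord <- live[order(-D[live])]
  pick <- unique(c(ord[seq_len(min(10, length(ord)))],
                   live[sample.int(length(live), n_h)]))[seq_len(n_h)]
  heights <- data.frame(
    plot_id = plot$plot_id, tag = sprintf("P%03dT%05d", plot_index, pick),
    diameter = D[pick] * taper[pick],
    height = true_height(D[pick] * taper[pick], config$hd_params) *
      exp(stats::rnorm(n_h, 0, config$height_noise_sd)),
    stringsAsFactors = FALSE)

  keep <- truth_times >= dates[1] & truth_times <= dates[length(dates)]
  slope_true <- unname(stats::coef(stats::lm(truth_agb ~ truth_times))[2])
  truth <- list(plot_id = plot$plot_id, is_edge = is_edge, area = area,
                edge_distance = edge_distance, min_diameter = min_d,
                times = truth_times, agb = truth_agb,
                intervals = do.call(rbind, truth_int),
                annual = data.frame(year = ann_year, n_live = ann_live,
                                    n_die = ann_die),
                slope = slope_true)
  list(plot = plot, truth = truth, heights = heights)
}

#' Simulate a plot network with exportable ground truth
#'
#' Runs [simulate_stand] for every plot index and assembles the network:
#' the list of [plot_data] objects, the measured-height samples, the
#' wood-density lookup table, and the truth bundle (per-plot true AGB
#' trajectories, per-interval true fluxes, realized interior and edge mean
#' trend slopes).
#'
#' @param config A [sim_config].
#' @return Object of class `forest_network_sim`: list with `plots`,
#'   `heights`, `wd_table`, `truth` (per-plot truths plus
#'   `interior_trend`, `edge_trend`), and `config`.
#' @export
simulate_network <- function(config) {
  sims <- lapply(seq_len(config$n_plots),
                 function(i) simulate_stand(config, i))
  plots <- lapply(sims, function(s) s$plot)
  names(plots) <- vapply(plots, function(p) p$plot_id, "")
  truths <- lapply(sims, function(s) s$truth)
  slopes <- vapply(truths, function(t) t$slope, 0)
  is_edge <- vapply(truths, function(t) t$is_edge, TRUE)
  heights <- do.call(rbind, lapply(sims, function(s) s$heights))
  rownames(heights) <- NULL
  structure(list(
    plots = plots, heights = heights,
    wd_table = sim_wood_density_table(config),
    truth = list(plots = truths,
                 interior_trend = mean(slopes[!is_edge]),
                 edge_trend = mean(slopes[is_edge]),
                 edge_threshold = config$edge_threshold),
    config = config), class = "forest_network_sim")
}

#' Write a simulated network to plain-text files
#'
#' Writes `trees.csv` and `plots.csv` (the [read_census_table] format),
#' `heights.csv`, `wood_density.csv`, and — when the jsonlite package is
#' available — `truth.json` with the ground-truth bundle.
#'
#' @param network A `forest_network_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_census_table(network$plots, file.path(dir, "trees.csv"),
                     file.path(dir, "plots.csv"))
  utils::write.csv(network$heights, file.path(dir, "heights.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(network$wd_table, file.path(dir, "wood_density.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- file.path(dir, c("trees.csv", "plots.csv", "heights.csv",
                            "wood_density.csv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(network$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(dir, "truth.json"))
  }
  invisible(files)
}
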