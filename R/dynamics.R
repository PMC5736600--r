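# AGB (kg) of given measurement rows, using assigned wood density and
# heights predicted from the H-D model
agb_of_rows <- function(plot, rows, hd_model, diameter = NULL) {
  m <- plot$measurements
  s <- plot$stems[match(m$tag[rows], plot$stems$tag), , drop = FALSE]
  if (any(is.na(s$wood_density) & !s$monocot)) {
    stop("wood density not assigned for plot '", plot$plot_id,
         "'; call assign_wood_density() first", call. = FALSE)
  }
  d <- if (is.null(diameter)) m$diameter[rows] else diameter
  stem_agb(d, predict(hd_model, d), s$wood_density, s$monocot)
}

#' Plot-level summary of one census
#'
#' Live-stem totals for a single census: AGB (Mg/ha), stand basal area
#' (m2/ha), basal-area-weighted mean wood density (g/cm3) and stem count.
#'
#' @param plot A [plot_data] object with wood density assigned.
#' @param census_date One of `plot$census_dates`.
#' @param hd_model `hd_model` used to predict heights.
#' @return One-row data.frame: `plot_id`, `census_date`, `agb`, `ba`,
#'   `wd_ba`, `n_stems`.
#' @export
plot_census_summary <- function(plot, census_date, hd_model) {
  if (!any(abs(plot$census_dates - census_date) < 1e-9)) {
    stop("census date ", census_date, " is not a census of plot '",
         plot$plot_id, "'", call. = FALSE)
  }
  rows <- live_rows(plot, census_date)
  if (!length(rows)) {
    warning("plot '", plot$plot_id, "' has no live stems at census ",
            census_date)
    return(data.frame(plot_id = plot$plot_id, census_date = census_date,
                      agb = 0, ba = 0, wd_ba = NA_real_, n_stems = 0L,
                      stringsAsFactors = FALSE))
  }
  d <- plot$measurements$diameter[rows]
  s <- plot$stems[match(plot$measurements$tag[rows], plot$stems$tag), ,
                  drop = FALSE]
  agb_kg <- agb_of_rows(plot, rows, hd_model)
  ba_stem <- pi * (d / 200)^2          # m2
  data.frame(plot_id = plot$plot_id, census_date = census_date,
             agb = sum(agb_kg) / 1000 / plot$area,
             ba = sum(ba_stem) / plot$area,
             wd_ba = sum(s$wood_density * ba_stem, na.rm = TRUE) /
               sum(ba_stem[!is.na(s$wood_density)]),
             n_stems = length(rows), stringsAsFactors = FALSE)
}

#' Observed and census-corrected stem turnover rates
#'
#' Observed recruitment and mortality rates (percent per year) over a
#' census interval, r = 100 (ln(Ns + Nr) - ln(Ns)) / t and
#' m = 100 (ln(Ns + Nm) - ln(Ns)) / t, and the census-interval-corrected
#' rates r t^0.0759 and m t^0.0759 that account for stems entering and
#' dying unobserved within longer intervals.
#'
#' @param Ns Number of stems surviving the interval (> 0).
#' @param Nr,Nm Observed numbers of recruits and deaths.
#' @param t Interval length, years.
#' @return data.frame with `r_obs`, `m_obs`, `r_corr`, `m_corr` (percent
#'   per year). Vectorized.
#' @export
stem_rates <- function(Ns, Nr, Nm, t) {
  if (any(Ns <= 0)) {
    stop("Ns must be positive: rates are undefined with no survivors",
         call. = FALSE)
  }
  if (any(t <= 0)) stop("interval length t must be positive", call. = FALSE)
  r <- 100 * (log(Ns + Nr) - log(Ns)) / t
  m <- 100 * (log(Ns + Nm) - log(Ns)) / t
  k <- t^0.0759
  data.frame(r_obs = r, m_obs = m, r_corr = r * k, m_corr = m * k)
}

#' Biomass and stem dynamics of one census interval
#'
#' Computes above-ground wood productivity (AGWP) and AGB mortality for a
#' census interval, including the two small unobserved components relating
#' to trees that die within the interval:
#' (1) the cohort of unobserved recruits that both enter and die between
#' the two censuses (count derived from the census-corrected recruitment
#' rate with the survivors as base population; each assigned a diameter of
#' the plot minimum plus one third of the interval's growth at the small
#' size-class mean rate, the plot mean wood density and a predicted
#' height), and (2) the unobserved growth of known dying trees, assumed to
#' die at mid-interval having grown at the size-class median rate. Both
#' components add equally to biomass gain and loss, so the identity
#' AGWP - AGB mortality = annualized AGB change is preserved exactly.
#'
#' Survivor biomass gains count positive AGB increments; survivors with net
#' negative corrected growth contribute their decline to the loss side
#' (reported as `survivor_loss`, included in `agb_mortality`).
#'
#' @param plot A QC'd [plot_data] with wood density assigned.
#' @param interval Index of the interval (1 = first to second census).
#' @param hd_model `hd_model` for height prediction.
#' @param stats Plot growth statistics from [plot_growth_stats]; computed
#'   when omitted.
#' @return One-row data.frame with interval dates, `t`, `agb_start`,
#'   `agb_end`, annualized `agwp`, `agb_mortality`, `agb_change` (all in
#'   Mg/ha/yr), stem counts `Ns`, `Nr`, `Nm`, observed and corrected stem
#'   rates, and the correction components `unobs_recruit_gain`,
#'   `unobs_recruit_loss`, `dead_growth_gain`, `dead_growth_loss`,
#'   `survivor_loss` (Mg/ha/yr), plus `n_unobs_recruits`.
#' @export
interval_dynamics <- function(plot, interval, hd_model, stats = NULL) {
  dates <- plot$census_dates
  if (interval < 1 || interval > length(dates) - 1) {
    stop("plot '", plot$plot_id, "' has no census interval ", interval,
         call. = FALSE)
  }
  if (is.null(stats)) stats <- plot_growth_stats(plot)
  c1 <- dates[interval]; c2 <- dates[interval + 1]
  t <- c2 - c1
  m <- plot$measurements
  r1 <- live_rows(plot, c1)
  r2 <- live_rows(plot, c2)
  dead2 <- which(abs(m$census_date - c2) < 1e-9 & m$status == "dead")
  tags1 <- m$tag[r1]; tags2 <- m$tag[r2]
  surv1 <- r1[tags1 %in% tags2]
  surv2 <- r2[match(m$tag[surv1], tags2)]
  recr2 <- r2[!tags2 %in% tags1]
  died1 <- r1[tags1 %in% m$tag[dead2]]
  # trees live at c1 with no later record of any kind are treated as deaths
  later <- m$census_date > c1 + 1e-9
  seen_later <- unique(m$tag[later])
  lost <- r1[!tags1 %in% tags2 & !tags1 %in% m$tag[dead2] &
               !tags1 %in% seen_later]
  died1 <- c(died1, lost)

  area_mg <- 1000 * plot$area           # kg -> Mg/ha divisor
  agb_s1 <- agb_of_rows(plot, surv1, hd_model)
  agb_s2 <- agb_of_rows(plot, surv2, hd_model)
  d_agb <- agb_s2 - agb_s1
  survivor_gain <- sum(pmax(0, d_agb)) / area_mg / t
  survivor_loss <- sum(pmax(0, -d_agb)) / area_mg / t
  recruit_gain <- sum(agb_of_rows(plot, recr2, hd_model)) / area_mg / t
  agb_died <- agb_of_rows(plot, died1, hd_model)
  death_loss <- sum(agb_died) / area_mg / t

  Ns <- length(surv1); Nr <- length(recr2); Nm <- length(died1)
  if (Ns > 0) {
    rates <- stem_rates(Ns, Nr, Nm, t)
    # invert the corrected recruitment rate with survivors as base to get
    # the 'true' (real-valued) recruit count, hence the unobserved cohort
    n_true <- Ns * (((Ns + Nr) / Ns)^(t^0.0759) - 1)
    n_unobs <- max(0, n_true - Nr)
  } else {
    rates <- data.frame(r_obs = NA_real_, m_obs = NA_real_,
                        r_corr = NA_real_, m_corr = NA_real_)
    n_unobs <- 0
  }
  g_small <- stats$mean[1]
  if (n_unobs > 0 && is.finite(g_small)) {
    d_u <- plot$min_diameter + (t / 3) * g_small
    wd_u <- mean(plot$stems$wood_density, na.rm = TRUE)
    agb_u <- stem_agb(d_u, predict(hd_model, d_u), wd_u)
    unobs_flux <- n_unobs * agb_u / area_mg / t
  } else {
    unobs_flux <- 0
  }
  # unobserved growth of known dying trees: grown to mid-interval at the
  # size-class median growth rate
  if (Nm > 0) {
    d1 <- m$diameter[died1]
    g_cls <- stats$median[as.integer(growth_class(d1))]
    d_mid <- pmax(d1, d1 + g_cls * t / 2)
    dead_growth <- sum(agb_of_rows(plot, died1, hd_model, diameter = d_mid) -
                         agb_died) / area_mg / t
  } else {
    dead_growth <- 0
  }
  agb_start <- (sum(agb_s1) + sum(agb_died)) / area_mg
  agb_end <- sum(agb_s2) / area_mg + recruit_gain * t
  agwp <- survivor_gain + recruit_gain + unobs_flux + dead_growth
  agb_mortality <- death_loss + survivor_loss + unobs_flux + dead_growth
  data.frame(
    plot_id = plot$plot_id, start = c1, end = c2, t = t,
    agb_start = agb_start, agb_end = agb_end,
    agwp = agwp, agb_mortality = agb_mortality,
    agb_change = (agb_end - agb_start) / t,
    Ns = Ns, Nr = Nr, Nm = Nm,
    r_obs = rates$r_obs, m_obs = rates$m_obs,
    r_corr = rates$r_corr, m_corr = rates$m_corr,
    unobs_recruit_gain = unobs_flux, unobs_recruit_loss = unobs_flux,
    dead_growth_gain = dead_growth, dead_growth_loss = dead_growth,
    survivor_loss = survivor_loss, n_unobs_recruits = n_unobs,
    stringsAsFactors = FALSE)
}

#' All census-interval dynamics of a plot
#'
#' @param plot A QC'd [plot_data] with wood density assigned.
#' @param hd_model `hd_model` for height prediction.
#' @return data.frame with one row per census interval (see
#'   [interval_dynamics]).
#' @export
plot_dynamics <- function(plot, hd_model) {
  stats <- plot_growth_stats(plot)
  do.call(rbind, lapply(seq_len(length(plot$census_dates) - 1),
                        function(i) interval_dynamics(plot, i, hd_model, stats)))
}

#' Per-census summaries of a plot
#'
#' @inheritParams plot_dynamics
#' @return data.frame with one row per census (see [plot_census_summary]).
#' @export
plot_summaries <- function(plot, hd_model) {
  do.call(rbind, lapply(plot$census_dates,
                        function(d) plot_census_summary(plot, d, hd_model)))
}

#' Census-level AGB observations for a plot network
#'
#' Assembles the observation table consumed by the trend models: one row
#' per plot per census with AGB (Mg/ha), plot area and edge distance.
#'
#' @param plots List of QC'd [plot_data] objects with wood density assigned.
#' @param hd_model `hd_model` for height prediction.
#' @return data.frame with columns `plot_id`, `census_date`, `agb`, `ba`,
#'   `wd_ba`, `n_stems`, `area`, `edge_distance`.
#' @export
network_observations <- function(plots, hd_model) {
  out <- lapply(plots, function(p) {
    s <- plot_summaries(p, hd_model)
    s$area <- p$area
    s$edge_distance <- p$edge_distance
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All census-interval dynamics of a plot network
#'
#' @inheritParams network_observations
#' @return data.frame stacking [plot_dynamics] over plots, with `area` and
#'   `edge_distance` columns appended.
#' @export
network_dynamics <- function(plots, hd_model) {
  out <- lapply(plots, function(p) {
    d <- plot_dynamics(p, hd_model)
    d$area <- p$area
    d$edge_distance <- p$edge_distance
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert biomass to carbon
#'
#' Applies the mean carbon fraction of tropical angiosperm wood, 47.1%.
#'
#' @param x Biomass (any Mg-based unit).
#' @return Carbon in the same unit basis.
#' @export
carbon_from_agb <- function(x) x * 0.471
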