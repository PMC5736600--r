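test_that("census summaries compute AGB, basal area and BA-weighted WD", {
  hd <- fixed_hd_model()
  p <- toy_interval_plot()
  s <- plot_census_summary(p, 2000, hd)
  # two live stems at the first census (20 and 30 cm)
  expect_identical(s$n_stems, 2L)
  expect_equal(s$ba, pi * ((0.1)^2 + (0.15)^2))
  agb_kg <- stem_agb(c(20, 30), predict(hd, c(20, 30)), c(0.6, 0.58))
  expect_equal(s$agb, sum(agb_kg) / 1000)
  ba <- pi * (c(20, 30) / 200)^2
  expect_equal(s$wd_ba, sum(c(0.6, 0.58) * ba) / sum(ba))

  # single tree: BA of a 20 cm stem in 1 ha is pi * 0.1^2, wd_ba is its WD
  p1 <- p
  p1$measurements <- p1$measurements[p1$measurements$tag == "T1", ]
  p1$census_dates <- c(2000, 2005)
  s1 <- plot_census_summary(p1, 2000, hd)
  expect_equal(s1$ba, 0.0314159, tolerance = 1e-5)
  expect_equal(s1$wd_ba, 0.6)

  # empty census: zeros with a warning
  p0 <- p
  p0$measurements <- p0$measurements[p0$measurements$tag == "T2", ]
  p0$census_dates <- c(2000, 2005)
  expect_warning(s0 <- plot_census_summary(p0, 2000, hd), "no live stems")
  expect_equal(s0$agb, 0)
  expect_identical(s0$n_stems, 0L)

  expect_error(plot_census_summary(p, 1999, hd), "not a census")
})

test_that("stem turnover rates follow the log-ratio formulas with t^0.0759 correction", {
  r <- stem_rates(95, 5, 0, 5)
  expect_equal(r$r_obs, 100 * (log(100) - log(95)) / 5)
  expect_equal(r$r_obs, 1.026, tolerance = 1e-3)
  expect_equal(r$r_corr, 1.159, tolerance = 1e-3)
  expect_equal(r$m_obs, 0)

  # no recruits: zero rate regardless of t
  expect_equal(stem_rates(100, 0, 3, 7)$r_obs, 0)
  expect_equal(stem_rates(100, 0, 3, 7)$r_corr, 0)

  # t = 1: correction is the identity
  r1 <- stem_rates(80, 6, 4, 1)
  expect_equal(r1$r_corr, r1$r_obs)
  expect_equal(r1$m_corr, r1$m_obs)

  # m_corr / m_obs = t^0.0759 exactly, over a grid of t
  for (t in c(0.5, 1, 2, 5, 10, 20)) {
    r <- stem_rates(90, 7, 12, t)
    expect_equal(r$m_corr / r$m_obs, t^0.0759)
    expect_equal(r$r_corr / r$r_obs, t^0.0759)
  }
  expect_error(stem_rates(0, 5, 5, 5), "Ns")
})

test_that("interval dynamics match a by-hand computation on the toy plot", {
  hd <- fixed_hd_model()
  p <- toy_interval_plot()
  stats <- data.frame(class = c("10-19.9", "20-39.9", ">=40"), n = 1,
                      mean = c(0.4, 0.4, 0.4), median = c(0.4, 0.4, 0.4),
                      stringsAsFactors = FALSE)
  dyn <- interval_dynamics(p, 1, hd, stats = stats)

  # hand computation with the stated rules (area 1 ha, t = 5)
  H <- function(d) 60 * (1 - exp(-0.03 * d^0.9))
  surv_gain <- (stem_agb(22, H(22), 0.6) - stem_agb(20, H(20), 0.6)) / 1000 / 5
  recr_gain <- stem_agb(10.5, H(10.5), 0.62) / 1000 / 5
  death_loss <- stem_agb(30, H(30), 0.58) / 1000 / 5
  # unobserved recruits: N_true inverts the corrected recruitment rate with
  # the survivor count (1) as base population
  n_true <- 1 * ((2 / 1)^(5^0.0759) - 1)
  n_unobs <- n_true - 1
  d_u <- 10 + (5 / 3) * 0.4
  wd_u <- mean(c(0.6, 0.62, 0.58))
  unobs <- n_unobs * stem_agb(d_u, H(d_u), wd_u) / 1000 / 5
  # known dead tree grown at the class median to mid-interval
  d_mid <- 30 + 0.4 * 2.5
  deadg <- (stem_agb(d_mid, H(d_mid), 0.58) -
              stem_agb(30, H(30), 0.58)) / 1000 / 5

  expect_identical(c(dyn$Ns, dyn$Nr, dyn$Nm), c(1L, 1L, 1L))
  expect_equal(dyn$n_unobs_recruits, n_unobs)
  expect_equal(dyn$unobs_recruit_gain, unobs)
  expect_equal(dyn$unobs_recruit_loss, unobs)
  expect_equal(dyn$dead_growth_gain, deadg)
  expect_equal(dyn$dead_growth_loss, deadg)
  expect_equal(dyn$agwp, surv_gain + recr_gain + unobs + deadg)
  expect_equal(dyn$agb_mortality, death_loss + unobs + deadg)
  expect_equal(dyn$survivor_loss, 0)
  expect_equal(dyn$agwp - dyn$agb_mortality, dyn$agb_change)
  expect_equal(dyn$r_obs, 100 * (log(2) - log(1)) / 5)
})

test_that("without mortality or recruitment the corrections vanish", {
  hd <- fixed_hd_model()
  stems <- data.frame(tag = c("a", "b"), family = "familyA",
                      genus = "genusX", species = "sp1", monocot = FALSE,
                      wood_density = 0.6, wd_level = "species",
                      stringsAsFactors = FALSE)
  meas <- data.frame(tag = rep(c("a", "b"), each = 2),
                     census_date = rep(c(2000, 2006), 2),
                     diameter = c(20, 22, 35, 36.5), pom = 1.3,
                     status = "alive", stringsAsFactors = FALSE)
  p <- plot_data("NC", 0.5, 900, 10, stems = stems, measurements = meas)
  dyn <- suppressWarnings(plot_dynamics(p, hd))
  expect_equal(dyn$unobs_recruit_gain, 0)
  expect_equal(dyn$dead_growth_gain, 0)
  expect_equal(dyn$agb_mortality, 0)
  # with no losses, AGWP times t equals the AGB change exactly
  expect_equal(dyn$agwp * dyn$t, dyn$agb_end - dyn$agb_start)
})

test_that("net-change identity holds on simulated stands", {
  cfg <- sim_config(seed = 5, n_plots = 6, n_edge = 2, n_min15 = 1)
  net <- simulate_network(cfg)
  plots <- suppressWarnings(lapply(net$plots, qc_plot))
  plots <- lapply(plots, assign_wood_density, wd_table = net$wd_table)
  hd <- fit_hd_model(net$heights, "weibull")
  dyn <- suppressWarnings(network_dynamics(plots, hd))
  expect_gt(nrow(dyn), 10)
  expect_lt(max(abs(dyn$agwp - dyn$agb_mortality - dyn$agb_change)), 1e-9)
  # corrected rates exceed observed ones on multi-year intervals
  multi <- dyn$t >= 1
  expect_true(all(dyn$r_corr[multi] >= dyn$r_obs[multi] - 1e-12))
  expect_true(all(dyn$m_corr[multi] >= dyn$m_obs[multi] - 1e-12))
})

test_that("biomass converts to carbon at the angiosperm fraction", {
  expect_equal(carbon_from_agb(1), 0.471)
  expect_equal(carbon_from_agb(0), 0)
  expect_equal(round(carbon_from_agb(0.91), 2), 0.43)
})
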