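test_that("simulation is deterministic given seed and plot index", {
  cfg <- sim_config(seed = 13, n_plots = 3, n_edge = 1, n_min15 = 0,
                    stem_density = 150)
  a <- simulate_stand(cfg, 2)
  b <- simulate_stand(cfg, 2)
  expect_identical(a$plot$measurements, b$plot$measurements)
  expect_identical(a$plot$stems, b$plot$stems)
  expect_identical(a$truth$agb, b$truth$agb)
  expect_identical(a$heights, b$heights)
  # different plot indices give different data
  c_ <- simulate_stand(cfg, 3)
  expect_false(identical(a$plot$measurements, c_$plot$measurements))
})

test_that("a frozen stand has exactly constant AGB", {
  cfg <- sim_config(seed = 4, n_plots = 1, n_edge = 0, n_min15 = 0,
                    stem_density = 120, growth_means = c(0, 0, 0),
                    mortality_rate = 0, recruit_rate = 0,
                    edge_recruit_rate = 0, dbh_noise_sd = 0,
                    pom_change_prob = 0, drought = list(), drift = 0)
  sim <- simulate_stand(cfg, 1)
  expect_lt(diff(range(sim$truth$agb)), 1e-9)
  # observed AGB is constant too: no measurement noise, no demography
  p <- sim$plot
  d_by_census <- tapply(p$measurements$diameter, p$measurements$census_date,
                        sum)
  expect_lt(diff(range(d_by_census)), 1e-9)
  # observed stem counts equal the truth at every census
  n_by_census <- tapply(p$measurements$tag, p$measurements$census_date,
                        length)
  expect_true(all(n_by_census == n_by_census[1]))
})

test_that("the default network reproduces the study design", {
  net <- default_network()
  expect_length(net$plots, 71)
  ed <- vapply(net$plots, function(p) p$edge_distance, 0)
  expect_identical(sum(ed >= 448), 49L)
  expect_identical(sum(ed < 448), 22L)
  areas <- vapply(net$plots, function(p) p$area, 0)
  expect_true(all(areas >= 0.25 & areas <= 4.4))
  expect_identical(sum(vapply(net$plots, function(p) p$min_diameter, 0) == 15),
                   7L)
  nc <- vapply(net$plots, function(p) length(p$census_dates), 0L)
  expect_true(all(nc >= 2 & nc <= 15))
  # 15-cm plots only contain stems recorded at or above 15 cm
  p15 <- net$plots[[71]]
  first <- !duplicated(p15$measurements$tag)
  expect_true(all(p15$measurements$diameter[first] >= 15, na.rm = TRUE))
})

test_that("a drought-year hazard multiplier is realized in stem deaths", {
  # annual alignment so the event covers whole simulation years
  cfg <- sim_config(seed = 27, n_plots = 40, n_edge = 0, n_min15 = 0,
                    stem_density = 350,
                    first_census_range = c(1990, 1990),
                    n_intervals_range = c(6, 6), interval_range = c(4, 4),
                    drought = list(list(start = 1997, end = 1998,
                                        mort_mult = 1.65,
                                        post_growth_mult = 1,
                                        post_years = 0)))
  sims <- lapply(seq_len(40), function(i) simulate_stand(cfg, i))
  ann <- do.call(rbind, lapply(sims, function(s) s$truth$annual))
  ev <- ann$year >= 1997 - 1e-9 & ann$year < 1998 - 1e-9
  rate_ev <- sum(ann$n_die[ev]) / sum(ann$n_live[ev])
  rate_base <- sum(ann$n_die[!ev]) / sum(ann$n_live[!ev])
  ratio <- rate_ev / rate_base
  # binomial sampling error on ~25k event-year stem-years is a few percent
  expect_gt(ratio, 1.65 - 0.25)
  expect_lt(ratio, 1.65 + 0.25)
})

test_that("observed recruitment declines with interval length while corrected rates hold", {
  # high-turnover stand censused annually; rates are then recomputed over
  # aggregated intervals of increasing length from the same event stream
  cfg <- sim_config(seed = 6, n_plots = 1, n_edge = 0, n_min15 = 0,
                    stem_density = 2000, mortality_rate = 3,
                    recruit_rate = 3, dbh_noise_sd = 0,
                    first_census_range = c(1990, 1990),
                    n_intervals_range = c(12, 12), interval_range = c(1, 1),
                    drought = list())
  sim <- simulate_stand(cfg, 1)
  m <- sim$plot$measurements
  dates <- sim$plot$census_dates
  live_at <- function(d) m$tag[abs(m$census_date - d) < 1e-9 &
                                 m$status %in% c("alive", "recruit")]
  rate_span <- function(a, t) {
    tags0 <- live_at(a); tags1 <- live_at(a + t)
    stem_rates(sum(tags0 %in% tags1), sum(!tags1 %in% tags0),
               sum(!tags0 %in% tags1), t)
  }
  avg_rate <- function(t) {
    starts <- dates[1] + seq(0, 12 - t, by = t)
    colMeans(do.call(rbind, lapply(starts, rate_span, t = t)))
  }
  rates <- as.data.frame(t(vapply(c(1, 3, 6, 12), avg_rate,
                                  numeric(4))))
  # observed recruitment falls as stems entering and dying unobserved
  # accumulate over longer intervals
  expect_lt(rates$r_obs[4], rates$r_obs[1])
  # the corrected rate does not decline: the interval-length correction
  # compensates (erring toward over- rather than under-correction at this
  # demography) and stays in the neighbourhood of the annual-census value
  expect_gte(rates$r_corr[4], rates$r_corr[1] * 0.95)
  expect_lt(abs(rates$r_corr[4] / rates$r_corr[1] - 1), 0.35)
})

test_that("exported files round-trip into the analysis pipeline", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 19, n_plots = 3, n_edge = 1, n_min15 = 1,
                    stem_density = 150)
  net <- simulate_network(cfg)
  files <- export_network(net, dir)
  expect_true(all(file.exists(file.path(dir, c("trees.csv", "plots.csv",
                                               "heights.csv",
                                               "wood_density.csv")))))
  plots <- read_census_table(file.path(dir, "trees.csv"),
                             file.path(dir, "plots.csv"))
  expect_length(plots, 3)
  wd <- read_wood_density(file.path(dir, "wood_density.csv"))
  p <- assign_wood_density(suppressWarnings(qc_plot(plots[[1]])), wd)
  expect_true(all(is.finite(p$stems$wood_density)))
  expect_true(all(p$stems$wood_density > 0))
})
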