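pom_tree <- function(dates, d, d_new = NA, pom_new = NA, status = "alive") {
  data.frame(tag = "T1", census_date = dates, diameter = d, pom = 1.3,
             status = status, flag = "accepted",
             diameter_new = d_new, pom_new = pom_new,
             stringsAsFactors = FALSE)
}

test_that("POM standardization averages the old- and new-POM series", {
  # dual measurement at census 2: 52 cm at the old POM, 46.8 at the new
  # (taper ratio 0.9); the mean standardized series is [47.5, 49.4]
  tr <- pom_tree(c(2000, 2005), c(50, 52), d_new = c(NA, 46.8),
                 pom_new = c(NA, 2.5))
  out <- standardize_pom_series(tr)
  expect_equal(out$diameter, c(47.5, 49.4))
  expect_identical(out$flag, c("corrected", "corrected"))
  expect_equal(out$diameter_raw, c(50, 52))

  # measurements after the change are taken at the new POM and standardized
  # back through the same taper ratio
  tr3 <- pom_tree(c(2000, 2005, 2010), c(50, 52, 47.7),
                  d_new = c(NA, 46.8, NA), pom_new = c(NA, 2.5, NA))
  out3 <- standardize_pom_series(tr3)
  expect_equal(out3$diameter[3], (47.7 / 0.9 + 47.7) / 2)

  # no POM change: identity
  tr0 <- pom_tree(c(2000, 2005), c(50, 52))
  expect_equal(standardize_pom_series(tr0)$diameter, c(50, 52))

  # taper ratio exactly 1: the mean series equals the original
  tr1 <- pom_tree(c(2000, 2005), c(50, 52), d_new = c(NA, 52),
                  pom_new = c(NA, 2.5))
  expect_equal(standardize_pom_series(tr1)$diameter, c(50, 52))
})

test_that("a POM change without a usable old-POM diameter is estimated", {
  tr <- pom_tree(c(2000, 2005, 2010), c(30, 30.9, NA))
  tr$status[3] <- "alive"
  # at census 3 the old POM is unusable: only the new-POM diameter exists
  tr$diameter[3] <- NA
  tr$diameter_new[3] <- 28.5
  tr$pom_new[3] <- 2.6
  out <- standardize_pom_series(tr, fallback_growth = 0.18)
  expect_identical(unique(out$flag), "estimated")
  # old-POM diameter projected at the tree's growth: 30.9 + 0.18 * 5 = 31.8
  expect_equal(out$diameter_raw[2], 30.9)
  expect_true(all(is.finite(out$diameter)))
  # taper ratio 28.5/31.8; the mean series stays between both series
  expect_true(out$diameter[3] > 28.5 && out$diameter[3] < 31.8)
})

growth_plot <- function(tags, dates, diam, flags = "accepted") {
  n <- length(tags)
  stems <- data.frame(tag = unique(tags), family = "family01",
                      genus = "genus001", species = "sp001",
                      monocot = FALSE, stringsAsFactors = FALSE)
  meas <- data.frame(tag = tags, census_date = dates, diameter = diam,
                     pom = 1.3, status = "alive", flag = flags,
                     stringsAsFactors = FALSE)
  plot_data("G", 1, 1000, 10, stems = stems, measurements = meas)
}

test_that("per-size-class growth statistics use mean and median as stated", {
  # three trees in class 10-19.9 with growth 0.1, 0.2, 0.9 cm/yr
  p <- growth_plot(rep(c("a", "b", "c"), each = 2),
                   rep(c(2000, 2010), 3),
                   c(15, 16, 15, 17, 15, 24))
  st <- suppressWarnings(plot_growth_stats(p))
  expect_equal(st$mean[st$class == "10-19.9"], 0.4)
  expect_equal(st$median[st$class == "10-19.9"], 0.2)

  # the same growths in class 20-39.9
  p2 <- growth_plot(rep(c("a", "b", "c"), each = 2),
                    rep(c(2000, 2010), 3),
                    c(25, 26, 25, 27, 25, 34))
  st2 <- suppressWarnings(plot_growth_stats(p2))
  expect_equal(st2$median[st2$class == "20-39.9"], 0.2)
  expect_equal(st2$mean[st2$class == "20-39.9"], 0.4)

  # empty classes fall back to the plot-level statistic with a warning
  w <- capture_warnings(plot_growth_stats(p))
  expect_match(w, ">=40", all = FALSE)

  # all records corrected: statistics over corrected values, with warning
  p3 <- growth_plot(rep(c("a", "b"), each = 2), rep(c(2000, 2010), 2),
                    c(15, 16, 15, 17), flags = "corrected")
  w3 <- capture_warnings(st3 <- plot_growth_stats(p3))
  expect_match(w3, "no accepted", all = FALSE)
  expect_equal(st3$mean[1], 0.15)

  # single census: no intervals
  p1 <- growth_plot(rep("a", 2), c(2000, 2010), c(15, 16))
  p1$census_dates <- 2000
  expect_error(plot_growth_stats(p1), "fewer than two censuses")
})

test_that("implausible growth is corrected by extrapolation and cascades", {
  stats <- data.frame(class = c("10-19.9", "20-39.9", ">=40"), n = 5,
                      mean = c(0.25, 0.35, 0.30),
                      median = c(0.2, 0.3, 0.25), stringsAsFactors = FALSE)
  # tree mean growth over accepted intervals is 0.3 cm/yr; the +4.5 cm/yr
  # interval is replaced by extrapolation at that rate
  tr <- pom_tree(c(2000, 2002, 2004, 2006), c(15, 15.6, 24.6, 25.2))
  out <- flag_and_correct_growth(tr, stats)
  expect_equal(out$diameter[3], 15.6 + 0.3 * 2)
  expect_identical(out$flag[3], "corrected")
  # correction cascades: the next interval is measured against the
  # corrected baseline, 25.2 is implausible against 16.2? (25.2-16.2)/2 =
  # 4.5 -> also corrected
  expect_equal(out$diameter[4], out$diameter[3] + 0.3 * 2)

  # shrinkage below -0.5 cm/yr is corrected the same way
  tr2 <- pom_tree(c(2000, 2002, 2004), c(20, 20.6, 19.0))
  out2 <- flag_and_correct_growth(tr2, stats)
  expect_equal(out2$diameter[3], 20.6 + 0.3 * 2)

  # plausible series untouched
  tr3 <- pom_tree(c(2000, 2002), c(20, 20.5))
  out3 <- flag_and_correct_growth(tr3, stats)
  expect_equal(out3$diameter, tr3$diameter)
  expect_identical(out3$flag, c("accepted", "accepted"))

  # no accepted interval: the plot size-class statistic fills in (the
  # median for the 20-39.9 cm class)
  tr4 <- pom_tree(c(2000, 2002), c(25, 35))
  out4 <- flag_and_correct_growth(tr4, stats)
  expect_equal(out4$diameter[2], 25 + 0.3 * 2)

  # a tree whose intervals are all implausible is excluded
  tr5 <- pom_tree(c(2000, 2002, 2004), c(15, 25, 35))
  expect_null(flag_and_correct_growth(tr5, stats))
})

test_that("after QC no interval's growth lies outside the thresholds", {
  net <- default_network()
  for (p in net$plots[c(3, 25, 60)]) {
    q <- suppressWarnings(qc_plot(p))
    gr <- forestsink:::growth_records(q)
    expect_true(all(gr$growth >= -0.5 - 1e-9 & gr$growth <= 4 + 1e-9))
  }
})

test_that("the QC pipeline reports a small corrected fraction on realistic data", {
  net <- default_network()
  q <- suppressWarnings(qc_plot(net$plots[[10]]))
  rep <- attr(q, "qc_report")
  expect_lt(rep$corrected_fraction, 0.15)
  expect_identical(rep$n_measurements, nrow(q$measurements))
})
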