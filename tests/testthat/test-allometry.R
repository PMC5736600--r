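test_that("H-D models recover noise-free generating parameters", {
  d <- seq(10, 150, length.out = 60)
  h <- 60 * (1 - exp(-0.03 * d^0.9))
  fit <- fit_hd_model(data.frame(diameter = d, height = h), "weibull")
  expect_equal(unname(fit$params), c(60, 0.03, 0.9), tolerance = 1e-4)
  expect_true(fit$convergence$converged)

  h2 <- exp(0.5 + 0.6 * log(d))
  fit2 <- fit_hd_model(data.frame(diameter = d, height = h2), "loglog")
  expect_equal(unname(fit2$params), c(0.5, 0.6), tolerance = 1e-10)

  expect_error(fit_hd_model(data.frame(diameter = d[1:5], height = h[1:5]),
                            "weibull"), "at least 10")
})

test_that("basal-area weighting minimizes the BA-weighted residual sum", {
  set.seed(42)
  d <- runif(200, 10, 120)
  h <- 60 * (1 - exp(-0.03 * d^0.9)) * exp(rnorm(200, 0, 0.1 * (d / 60)))
  dat <- data.frame(diameter = d, height = h)
  plain <- fit_hd_model(dat, "weibull")
  weighted <- fit_hd_model(dat, "weibull_ba_weighted")
  ba <- pi * (d / 200)^2
  sse_w <- function(m) sum(ba * (h - predict(m, d))^2)
  expect_lt(sse_w(weighted), sse_w(plain))
})

test_that("model selection minimizes AGB prediction error with a stable tie-break", {
  set.seed(7)
  d <- runif(150, 10, 120)
  h <- 58 * (1 - exp(-0.035 * d^0.92)) * exp(rnorm(150, 0, 0.07))
  sample_df <- data.frame(diameter = d, height = h, wd = runif(150, 0.4, 0.8))
  cand <- lapply(c("weibull", "weibull_ba_weighted", "loglog"),
                 function(f) fit_hd_model(sample_df, f))
  sel <- select_hd_model(cand, sample_df)
  # brute-force oracle: rank candidates by directly accumulated AGB error
  errs <- vapply(cand, function(m) {
    s <- 0
    for (i in seq_along(d)) {
      s <- s + abs(stem_agb(d[i], h[i], sample_df$wd[i]) -
                     stem_agb(d[i], predict(m, d[i]), sample_df$wd[i]))
    }
    s
  }, 0)
  expect_identical(sel$form, cand[[which.min(errs)]]$form)
  expect_equal(attr(sel, "selection")$agb_error, errs)
  # selection invariant to candidate order
  sel_rev <- select_hd_model(rev(cand), sample_df)
  expect_identical(sel_rev$form, sel$form)

  # the true generating model has zero error and is selected
  h0 <- 58 * (1 - exp(-0.035 * d^0.92))
  perfect <- data.frame(diameter = d, height = h0)
  true_mod <- fit_hd_model(perfect, "weibull")
  sel0 <- select_hd_model(list(true_mod, cand[[3]]), perfect)
  expect_identical(sel0$form, "weibull")
  expect_lt(attr(sel0, "selection")$agb_error[1], 1e-4)

  # two identical candidates: first by the preference order
  sel_tie <- select_hd_model(list(cand[[2]], cand[[2]]), sample_df)
  expect_identical(sel_tie$form, "weibull_ba_weighted")
  tie2 <- cand[[2]]; tie2$form <- "weibull"
  sel_tie2 <- select_hd_model(list(cand[[2]], tie2), sample_df)
  expect_identical(sel_tie2$form, "weibull")
})

test_that("Weibull predictions are bounded by the asymptote", {
  m <- fixed_hd_model(a = 55, b = 0.04, c = 0.8)
  expect_true(all(predict(m, seq(1, 500, by = 7)) < 55))
})

test_that("wood density is assigned by taxonomic hierarchy with plot-mean fallback", {
  wd_tab <- data.frame(
    family = c("familyA", "familyA", "familyA", "familyB"),
    genus = c("genusX", "genusX", NA, NA),
    species = c("sp1", NA, NA, NA),
    wd_g_cm3 = c(0.71, 0.65, 0.55, 0.45), stringsAsFactors = FALSE)
  stems <- data.frame(
    tag = c("t1", "t2", "t3", "t4"),
    family = c("familyA", "familyA", "familyB", NA),
    genus = c("genusX", "genusX", "genusZ", NA),
    species = c("sp1", "sp9", NA, NA),
    monocot = FALSE, stringsAsFactors = FALSE)
  meas <- data.frame(tag = rep(c("t1", "t2", "t3", "t4"), each = 2),
                     census_date = rep(c(2000, 2005), 4),
                     diameter = rep(c(20, 21), 4), pom = 1.3,
                     status = "alive", stringsAsFactors = FALSE)
  p <- plot_data("W", 1, 600, 10, stems = stems, measurements = meas)
  out <- assign_wood_density(p, wd_tab)
  expect_equal(out$stems$wood_density, c(0.71, 0.65, 0.45,
                                         mean(c(0.71, 0.65, 0.45))))
  expect_identical(out$stems$wd_level,
                   c("species", "genus", "family", "plot_mean"))

  # unidentified plot with two identified stems at 0.5 and 0.7 -> 0.6
  stems2 <- stems
  stems2$species <- c("sp1", NA, NA, NA)
  stems2$genus <- c("genusX", NA, NA, NA)
  stems2$family <- c("familyA", "familyB", NA, NA)
  wd2 <- data.frame(family = c("familyA", "familyB"),
                    genus = c("genusX", NA), species = c("sp1", NA),
                    wd_g_cm3 = c(0.5, 0.7), stringsAsFactors = FALSE)
  p2 <- plot_data("W2", 1, 600, 10, stems = stems2, measurements = meas)
  out2 <- assign_wood_density(p2, wd2)
  expect_equal(out2$stems$wood_density[3:4], c(0.6, 0.6))

  # no identified stem at all: cannot form the plot mean
  stems3 <- stems2
  stems3[, c("family", "genus", "species")] <- NA_character_
  p3 <- plot_data("W3", 1, 600, 10, stems = stems3, measurements = meas)
  expect_error(assign_wood_density(p3, wd2), "plot-mean")
})

test_that("stem AGB follows the printed allometries and is monotone", {
  expect_equal(stem_agb(20, 18, 0.6), 0.0673 * (0.6 * 400 * 18)^0.976)
  expect_equal(stem_agb(20, 18, 0.6), 237.8, tolerance = 1e-3)
  expect_equal(stem_agb(15, monocot = TRUE),
               exp(-3.3488 + 2.7483 * log(15)))
  expect_equal(stem_agb(15, monocot = TRUE), 60.0, tolerance = 1e-3)

  # strictly increasing in each argument; vanishes towards zero size
  d <- seq(10, 150, by = 10)
  expect_true(all(diff(stem_agb(d, 20, 0.6)) > 0))
  expect_true(all(diff(stem_agb(30, d, 0.6)) > 0))
  expect_true(all(diff(stem_agb(30, 20, seq(0.3, 0.9, 0.1))) > 0))
  expect_true(all(diff(stem_agb(d, monocot = TRUE)) > 0))
  expect_lt(stem_agb(0.5, 0.5, 0.6), 0.1)
  expect_error(stem_agb(-5, 10, 0.6), "positive")
})
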