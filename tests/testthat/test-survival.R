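ctrl_unit <- tibble::tibble(i_c = 50, od_c = 1, i_d = 1050, od_d = 1)

test_that("PI survival hits its definitional fixed points", {
  # boiled-control ratio -> 0% survival; unstained ratio -> 100%
  expect_equal(picls_survival(1050, 1, ctrl_unit)$survival_pct, 0)
  expect_equal(picls_survival(50, 1, ctrl_unit)$survival_pct, 100)
  # midway between the two controls -> 50%
  expect_equal(picls_survival(550, 1, ctrl_unit)$survival_pct, 50)
  # the controls' own means reproduce 0 and 100 exactly
  plate <- make_plate(n_samples = 0)
  ctrl <- summarize_controls(plate)
  expect_identical(picls_survival(ctrl$i_d, ctrl$od_d, ctrl)$survival_raw, 0)
  expect_identical(picls_survival(ctrl$i_c, ctrl$od_c, ctrl)$survival_raw, 100)
})

test_that("PI survival is scale invariant and monotone in fluorescence", {
  set.seed(21)
  for (i in 1:10) {
    fl <- runif(5, 100, 2000)
    od <- runif(5, 0.5, 3)
    ctrl <- tibble::tibble(i_c = 60, od_c = 1.1, i_d = 1200, od_d = 0.9)
    base <- picls_survival(fl, od, ctrl)$survival_raw
    c_fl <- runif(1, 0.1, 10)
    c_od <- runif(1, 0.1, 10)
    scaled_ctrl <- dplyr::mutate(ctrl, i_c = i_c * c_fl, i_d = i_d * c_fl,
                                 od_c = od_c * c_od, od_d = od_d * c_od)
    scaled <- picls_survival(fl * c_fl, od * c_od, scaled_ctrl)$survival_raw
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  fl_grid <- seq(60, 1200, length.out = 25)
  s <- picls_survival(fl_grid, rep(1, 25), ctrl_unit)$survival_raw
  expect_true(all(diff(s) < 0))
})

test_that("PI survival validates OD floor, controls, and records clamping", {
  expect_error(picls_survival(500, 0.01, ctrl_unit),
               class = "picls_below_range_error")
  inverted <- tibble::tibble(i_c = 900, od_c = 1, i_d = 100, od_d = 1)
  expect_error(picls_survival(500, 1, inverted),
               class = "picls_invalid_plate_error")
  over <- picls_survival(20, 1, ctrl_unit)  # brighter than 100% live
  expect_gt(over$survival_raw, 100)
  expect_equal(over$survival_pct, 100)
  expect_true(over$clamped)
})

test_that("outgrowth survival is anchored at day 1 and clamped above it", {
  expect_equal(outgrowth_survival(0.8, 0.8)$survival_pct, 100)
  expect_equal(outgrowth_survival(0.4, 0.8)$survival_pct, 50)
  over <- outgrowth_survival(0.96, 0.8)
  expect_equal(over$survival_pct, 100)
  expect_true(over$clamped)
  expect_equal(outgrowth_survival(0.5, 0.9, blank = 0.1)$survival_pct, 50)
  expect_error(outgrowth_survival(0.5, 0.05, blank = 0.1),
               class = "picls_invalid_anchor_error")
})

test_that("survival curves aggregate wells with per-plate/day controls", {
  # six identical wells -> zero dispersion, mean equals the per-well value
  plate <- make_plate(n_samples = 6)
  cur <- build_survival_curve(plate)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$survival_pct, 50)
  expect_equal(cur$sd_pct, 0)
  expect_equal(cur$n_wells, 6)

  # controls must be present on every plate/day
  no_ctrl <- dplyr::filter(plate, role == "sample")
  expect_error(build_survival_curve(no_ctrl),
               class = "picls_assay_design_error")

  # law of large numbers: the unclamped per-well mean tracks closed-form
  # viability at every day (the clamped mean is biased where V ~ 0).
  # Precision must grow in both sample wells and control anchors: the
  # per-plate control means enter every well's score, so their error does
  # not average out over sample wells alone.
  design <- screen_design(
    tibble::tibble(compound = "control", concentration = 0,
                   conc_unit = NA, k = 1.3, lam = 4),
    age_days = c(1, 4, 7, 14, 21), n_replicates = 200, n_controls = 24)
  sim <- simulate_plate(design, seed = 314)
  raw_means <- survival_by_well(sim$records) |>
    dplyr::group_by(age_day) |>
    dplyr::summarise(mean_raw = mean(survival_raw))
  joined <- dplyr::inner_join(raw_means, sim$truth, by = "age_day")
  expect_true(all(abs(joined$mean_raw - 100 * joined$viability) < 2))
})

test_that("outgrowth curves require the day-1 anchor", {
  days <- c(1, 4, 7)
  rec <- purrr::map_dfr(days, function(d) {
    r <- make_plate(n_samples = 3, fl = 0, od = 0.8 * exp(-(d - 1) / 5),
                    age_day = as.integer(d))
    r$fluorescence <- 1  # unused by the outgrowth method
    r
  })
  cur <- build_survival_curve(rec, method = "outgrowth")
  expect_equal(cur$survival_pct[cur$age_day == 1], 100)
  expect_equal(cur$survival_pct[cur$age_day == 4],
               100 * exp(-3 / 5), tolerance = 1e-9)
  expect_error(
    build_survival_curve(dplyr::filter(rec, age_day != 1),
                         method = "outgrowth"),
    class = "picls_invalid_anchor_error")
})

test_that("mortality fit recovers noiseless Weibull parameters exactly", {
  days <- c(4, 7, 14, 21)
  cur <- tibble::tibble(age_day = days,
                        survival_pct = 100 * exp(-((days - 1) / 4)^1.3))
  fit <- fit_mortality_model(cur)
  expect_equal(fit$k, 1.3, tolerance = 1e-6)
  expect_equal(fit$lam, 4, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_equal(predict(fit, 1), 100)

  flat <- tibble::tibble(age_day = days, survival_pct = 100)
  expect_error(fit_mortality_model(flat),
               class = "picls_unidentifiable_error")
  expect_error(fit_mortality_model(cur[1:2, ]),
               class = "picls_unidentifiable_error")
})

test_that("mortality fit is consistent as noise vanishes", {
  days <- c(1, 4, 7, 14, 21)
  true_v <- exp(-((days - 1) / 9)^1.3)
  set.seed(77)
  errs <- sapply(c(0.05, 0.01, 0.002), function(cv) {
    est <- replicate(20, {
      noisy <- pmin(100, pmax(0, 100 * true_v * (1 + rnorm(5, 0, cv))))
      fit_mortality_model(tibble::tibble(age_day = days,
                                         survival_pct = noisy))$lam
    })
    median(abs(est - 9) / 9)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("curve summaries compute trapezoidal AUC and interpolated t50", {
  const <- tibble::tibble(compound = "x", concentration = 1,
                          age_day = c(1, 21), survival_pct = 100)
  s <- curve_summaries(const)
  expect_equal(s$auc, 2000)
  expect_true(s$t50_censored)
  expect_equal(s$t50, 21)

  drop <- tibble::tibble(compound = "x", concentration = 1,
                         age_day = c(1, 3), survival_pct = c(100, 0))
  expect_equal(curve_summaries(drop)$t50, 2.0)

  days <- c(1, 4, 7, 14, 21)
  weib <- tibble::tibble(compound = "x", concentration = 1, age_day = days,
                         survival_pct = 100 * exp(-((days - 1) / 4)^1.3))
  t50_closed <- 1 + 4 * log(2)^(1 / 1.3)
  expect_equal(curve_summaries(weib)$t50, t50_closed, tolerance = 0.1)

  single <- tibble::tibble(compound = "x", concentration = 1,
                           age_day = 1, survival_pct = 100)
  expect_error(curve_summaries(single), class = "picls_insufficient_data_error")
})
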