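test_that("calibration fitting recovers exact lines", {
  x <- six_levels
  f1 <- fit_calibration(x, line_ratio(x))
  expect_equal(f1$slope, 8.5133, tolerance = 1e-12)
  expect_equal(f1$intercept, 1.7962, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1)
  expect_equal(f1$calibrators$back_calc, x, tolerance = 1e-9)

  f2 <- fit_calibration(x, 2 * x)
  expect_equal(unname(coef(f2)), c(0, 2), tolerance = 1e-12)
  expect_equal(predict(f2, 3), 6)
  expect_error(fit_calibration(c(1, 2, 3), c(1, 2, 3)), ">= 6")
})

test_that("noisy calibration slopes are unbiased", {
  cfg <- sim_config(cv_intra = 0.05, cv_inter_day = 0, rt_cv = 0,
                    recovery_true = 1, matrix_factor_true = 1,
                    matrix_factor_is = 1)
  slopes <- vapply(1:200, function(s) {
    r <- area_ratios(generate_injection_table(calibrator_design(), cfg,
                                              seed = 2000 + s))
    fit_calibration(r$nominal, r$ratio)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) / 8.5133 - 1), 0.01)
})

test_that("calibration acceptance gate matches a brute-force oracle", {
  mk_fit <- function(dev_pct) {
    x <- six_levels
    # construct ratios whose back-calculation deviates by dev_pct exactly
    f0 <- fit_calibration(x, line_ratio(x))
    y <- line_ratio(x * (1 + dev_pct / 100))
    fit <- f0
    fit$calibrators <- data.frame(
      nominal = x, ratio = y, back_calc = x * (1 + dev_pct / 100),
      deviation_pct = dev_pct)
    fit
  }
  cases <- list(
    rep(5, 6),                     # all within -> pass
    c(0, 18, 18, 5, 5, 5),         # 4/6 = 66.7% < 75% -> fail
    c(25, 0, 0, 0, 0, 0),          # LLOQ beyond 20% -> fail
    c(19, 0, 0, 0, 0, 0),          # LLOQ within its 20% window -> pass
    c(0, 16, 0, 0, 0, 0),          # one of six out -> 83% -> pass
    c(0, 16, -16, 0, 0, 0))        # 4/6 -> fail
  for (dev in cases) {
    got <- calibration_acceptance(mk_fit(dev))$pass
    expect_identical(got, oracle_calibration_gate(dev), info = paste(dev,
                                                                 collapse = ","))
  }
})

test_that("LOD/LOQ keep the 10/3.3 coupling and handle degenerate spread", {
  x <- six_levels
  mk <- function(b) fit_calibration(x, 8.5133 * x + b)
  sigma <- 0.14 * 8.5133 / 3.3
  fits <- list(mk(1.7962 - sigma), mk(1.7962), mk(1.7962 + sigma))
  s <- lod_loq(fits)
  expect_equal(round(s$lod, 2), 0.14)
  expect_equal(round(s$loq, 2), 0.42)
  expect_equal(s$loq / s$lod, 10 / 3.3, tolerance = 1e-12)

  same <- lod_loq(list(mk(1), mk(1), mk(1)))
  expect_equal(same$lod, 0)
  expect_equal(same$loq, 0)
  expect_error(lod_loq(fits[1:2]), ">= 3")
})

test_that("precision and accuracy follow their definitions", {
  # grand mean 7.15 at nominal 7.5 -> accuracy 95.33%
  qc <- data.frame(level = "MQC", nominal = 7.5, day = rep(1:3, each = 2),
                   measured = 7.15 + c(-0.1, 0.1, -0.2, 0.2, -0.15, 0.15))
  pa <- precision_accuracy(qc)
  expect_equal(pa$grand_mean, 7.15)
  expect_equal(round(pa$accuracy_pct, 2), 95.33)
  expect_true(pa$pass)

  same <- precision_accuracy(data.frame(level = "HQC", nominal = 15,
                                        day = rep(1:2, each = 3),
                                        measured = 14.5))
  expect_equal(same$cv_intra_pct, 0)
  expect_equal(same$cv_inter_pct, 0)
  expect_equal(same$accuracy_pct, 100 * 14.5 / 15)

  expect_warning(precision_accuracy(
    data.frame(level = "LQC", nominal = 0.5, day = c(1, 1, 2),
               measured = c(0.5, 0.51, 0.49))), "single replicate")
})

test_that("intra-day CV estimates recover the generator's truth", {
  cfg <- sim_config(cv_intra = 0.04, cv_inter_day = 0.06)
  cvs <- vapply(1:100, function(s) {
    des <- rbind(calibrator_design(day = 1),
                 data.frame(role = "qc", nominal = 7.5, day = 1)[rep(1, 5), ])
    tab <- generate_injection_table(des, cfg, seed = 3000 + s)
    r <- area_ratios(tab)
    fit <- fit_calibration(r$nominal[r$role == "calibrator"],
                           r$ratio[r$role == "calibrator"],
                           weighting = "1/x2")
    m <- quantify(r$ratio[r$role == "qc"], fit)$conc
    100 * sd(m) / mean(m)
  }, numeric(1))
  expect_gte(mean(cvs), 2.5)
  expect_lte(mean(cvs), 5.5)
})

test_that("recovery is the pre/post mean ratio", {
  r <- recovery(pre_ratios = c(0.68, 0.678, 0.676),
                post_ratios = c(1, 1, 1))
  expect_equal(round(r$recovery_pct, 2), 67.8)
  same <- recovery(c(1, 1.01, 0.99), c(1, 1.01, 0.99))
  expect_equal(same$recovery_pct, 100)
  expect_error(recovery(c(1, 1, 1), c(0, 0, 0)), "zero post")
  expect_error(recovery(c(1, 1), c(1, 1, 1)), ">= 3")
})

test_that("stochastic recovery estimates land on the configured truth", {
  cfg <- sim_config(recovery_true = 0.70)
  des <- data.frame(role = rep(c("pre_spike", "post_spike"), each = 3),
                    nominal = 7.5)
  est <- vapply(1:100, function(s) {
    r <- area_ratios(generate_injection_table(des, cfg, seed = 4000 + s))
    recovery(r$ratio[r$role == "pre_spike"],
             r$ratio[r$role == "post_spike"])$recovery_pct
  }, numeric(1))
  expect_lt(abs(mean(est) - 70), 3)
})

test_that("matrix effect arithmetic and gate behave as defined", {
  me <- matrix_effect(matrix_analyte = c(80, 80, 80),
                      solvent_analyte = c(100, 100, 100),
                      matrix_is = c(90, 90, 90),
                      solvent_is = c(100, 100, 100))
  expect_equal(me$mf_analyte, 0.8)
  expect_equal(me$mf_is, 0.9)
  expect_equal(round(me$is_normalized_mf, 3), 0.889)
  expect_true(me$suppression)
  expect_true(me$pass)

  unity <- matrix_effect(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(unity$is_normalized_mf, 1)
  expect_false(unity$suppression)
  expect_error(matrix_effect(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)),
               "zero solvent")
})

test_that("matrix-effect gate holds at the configured suppression", {
  cfg <- sim_config(matrix_factor_true = 0.88, matrix_factor_is = 1)
  des <- data.frame(role = rep(c("post_spike", "solvent_spike"), each = 3),
                    nominal = 7.5)
  pass <- vapply(1:100, function(s) {
    r <- area_ratios(generate_injection_table(des, cfg, seed = 5000 + s))
    mx <- r[r$role == "post_spike", ]
    sv <- r[r$role == "solvent_spike", ]
    matrix_effect(mx$analyte_area, sv$analyte_area,
                  mx$is_area, sv$is_area)$pass
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("quantification inverts the line and flags out-of-range values", {
  fit <- fit_calibration(six_levels, line_ratio(six_levels))
  q <- quantify(line_ratio(5), fit)
  expect_equal(q$conc, 5, tolerance = 1e-9)
  expect_identical(q$flag, "")
  expect_identical(quantify(1.0, fit)$flag, "BLQ")      # below intercept
  expect_identical(quantify(line_ratio(25), fit)$flag, "ALQ")
  # round-trip identity across the range on noiseless data
  r <- area_ratios(generate_injection_table(calibrator_design(),
                                            noiseless_config(), seed = 1))
  expect_equal(quantify(r$ratio, fit)$conc, r$nominal, tolerance = 1e-9)
})

test_that("unknown quantification is unbiased at 4% noise", {
  cfg <- sim_config(cv_intra = 0.04, cv_inter_day = 0, rt_cv = 0,
                    recovery_true = 1, matrix_factor_true = 1,
                    matrix_factor_is = 1)
  fit <- fit_calibration(six_levels, line_ratio(six_levels))
  des <- data.frame(role = "unknown", nominal = 7.5)[rep(1, 200), ]
  r <- area_ratios(generate_injection_table(des, cfg, seed = 77))
  est <- quantify(r$ratio, fit)$conc
  expect_lt(abs(mean(est) / 7.5 - 1), 0.02)
})

test_that("unit bridge between homogenate and tissue is exact", {
  expect_equal(homogenate_to_tissue(14.37), 0.1437)
  expect_equal(homogenate_to_tissue(0), 0)
  expect_equal(tissue_to_homogenate(homogenate_to_tissue(7.31)), 7.31)
  expect_error(homogenate_to_tissue(1, 0), "positive")
})

test_that("validation statistics are invariant under area rescaling", {
  cfg <- sim_config()
  des <- rbind(calibrator_design(day = 1), calibrator_design(day = 2),
               calibrator_design(day = 3))
  tab <- generate_injection_table(des, cfg, seed = 88)
  r1 <- area_ratios(tab)
  tab2 <- tab; tab2$area <- tab2$area * 40
  r2 <- area_ratios(tab2)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
  fits1 <- lapply(split(r1, r1$day), function(d)
    fit_calibration(d$nominal, d$ratio))
  fits2 <- lapply(split(r2, r2$day), function(d)
    fit_calibration(d$nominal, d$ratio))
  expect_equal(lod_loq(fits2)$lod, lod_loq(fits1)$lod, tolerance = 1e-12)
  expect_equal(lod_loq(fits2)$loq, lod_loq(fits1)$loq, tolerance = 1e-12)
})
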