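test_that("injection tables are deterministic and follow the response line", {
  cfg <- sim_config()
  des <- data.frame(role = c("blank", "zero", "calibrator", "qc"),
                    nominal = c(0, 0, 5, 7.5))
  t1 <- generate_injection_table(des, cfg, seed = 7)
  t2 <- generate_injection_table(des, cfg, seed = 7)
  expect_identical(t1, t2)
  t3 <- generate_injection_table(des, cfg, seed = 8)
  expect_false(identical(t1$area, t3$area))

  # noiseless calibrator at C = 5 with unit recovery/matrix factors
  nl <- generate_injection_table(calibrator_design(5:10 / 1),
                                 noiseless_config(), seed = 1)
  r <- area_ratios(nl)
  expect_equal(r$ratio[r$nominal == 5], 8.5133 * 5 + 1.7962)  # 44.3627
  expect_equal(r$ratio, line_ratio(r$nominal))
})

test_that("pre-extraction and matrix factors scale the expected ratio", {
  cfg <- sim_config(cv_intra = 0, cv_inter_day = 0, rt_cv = 0,
                    recovery_true = 0.7, matrix_factor_true = 0.88,
                    matrix_factor_is = 1)
  des <- data.frame(role = c("pre_spike", "post_spike", "solvent_spike"),
                    nominal = 5)
  r <- area_ratios(generate_injection_table(des, cfg, seed = 1))
  expect_equal(r$ratio[r$role == "solvent_spike"], line_ratio(5))
  expect_equal(r$ratio[r$role == "post_spike"], line_ratio(5) * 0.88)
  expect_equal(r$ratio[r$role == "pre_spike"], line_ratio(5) * 0.88 * 0.7)
  # analyte areas carry the analyte-channel matrix factor
  tab <- generate_injection_table(des, cfg, seed = 1)
  q <- tab[tab$channel == "analyte" & tab$transition_role == "quantifier", ]
  expect_equal(q$area[q$role == "post_spike"] /
                 q$area[q$role == "solvent_spike"], 0.88)
})

test_that("blank analyte areas stay far below the LLOQ response", {
  cfg <- sim_config()
  des <- rbind(data.frame(role = "calibrator", nominal = 0.5),
               data.frame(role = "blank", nominal = 0)[rep(1, 1000), ])
  tab <- generate_injection_table(des, cfg, seed = 3)
  q <- tab[tab$channel == "analyte" & tab$transition_role == "quantifier", ]
  lloq_area <- q$area[q$role == "calibrator"]
  frac_ok <- mean(q$area[q$role == "blank"] < 0.2 * lloq_area)
  expect_gte(frac_ok, 0.95)
  expect_error(generate_injection_table(
    data.frame(role = "calibrator", nominal = -1), cfg), "negative nominal")
  expect_error(generate_injection_table(
    data.frame(role = "mystery", nominal = 1), cfg), "invalid role")
})

test_that("synthetic chromatograms render peaks on the requested grid", {
  pk <- data.frame(rt_min = 11.22, height = 100, width_s = 3)
  ch <- generate_chromatogram(pk, noise_sd = 0, gradient_length = 15.6)
  expect_equal(max(ch$intensity), 100)
  expect_equal(ch$time_min[which.max(ch$intensity)], 11.22, tolerance = 1e-3)
  # >= 10 samples per peak width
  expect_lte(diff(ch$time_min)[1] * 60, 3 / 10 + 1e-12)
  expect_error(generate_chromatogram(
    data.frame(rt_min = 1, height = -5, width_s = 3)), "positive")
  expect_error(generate_chromatogram(
    data.frame(rt_min = 20, height = 5, width_s = 3),
    gradient_length = 15.6), "within")
})

test_that("pure-noise traces yield no detections at the 3-sigma threshold", {
  hits <- 0L
  for (s in 1:50) {
    ch <- generate_chromatogram(NULL, noise_sd = 1, gradient_length = 5,
                                seed = s)
    if (nrow(detect_peaks(ch, threshold_sigma = 3)) > 0) hits <- hits + 1L
  }
  expect_lte(hits / 50, 0.01)
})

test_that("pk generator matches the bi-exponential model", {
  cfg <- sim_config(pk_bsv_cv = 0)
  tab <- generate_pk_dataset(cfg, seed = 2)
  expect_equal(tab$conc[tab$time_h == 0], rep(0, 5))
  # every animal appears exactly once
  expect_equal(anyDuplicated(tab$animal), 0L)
  # noiseless concentrations equal the model curve
  model <- function(t) 95 * (exp(-0.0405 * t) - exp(-0.8 * t))
  expect_equal(tab$conc, model(tab$time_h))
  # grid argmax at 4 h; continuous-time maximum at ln(ka/lz)/(ka-lz)
  tmax_cont <- log(0.8 / 0.0405) / (0.8 - 0.0405)
  expect_equal(round(tmax_cont, 2), 3.93)
  pr <- mean_profile(tab)
  expect_equal(unname(cmax_tmax(pr)["tmax"]), 4)
  # monotone decline after the continuous-time peak
  dense <- model(seq(4, 24, by = 0.1))
  expect_true(all(diff(dense) < 0))
  expect_error(generate_pk_dataset(sim_config(pk_ka = 0.9, pk_lambda_z = 0.03,
                                              n_per_time = 0)), "n_per_time")
})

test_that("noiseless terminal slope matches the closed-form log regression", {
  cfg <- sim_config(pk_bsv_cv = 0)
  pr <- mean_profile(generate_pk_dataset(cfg, seed = 4))
  lz <- fit_lambda_z(pr)
  # independent oracle: log-OLS on the exact curve at the last three times
  t3 <- c(6, 8, 24)
  c3 <- 95 * (exp(-0.0405 * t3) - exp(-0.8 * t3))
  oracle <- -unname(coef(lm(log(c3) ~ t3))[2L])
  expect_equal(lz$lambda_z, oracle, tolerance = 1e-10)
  # absorption still contributes ~1% at 6 h, so truth recovery is ~1%
  expect_lt(abs(lz$lambda_z - 0.0405) / 0.0405, 0.015)
})

test_that("behavior generator honors configured group truths", {
  # perfect alternation propensity
  pars <- data.frame(group = "perfect", dr_mean = 0.6, dr_phi = 30,
                     explore_total_s = 40, explore_cv = 0.3,
                     n_bouts_mean = 10, alternation = 1, entries_mean = 20)
  cfg <- sim_config(behavior_group_params = pars)
  s <- generate_behavior_dataset(cfg, 5, seed = 9, type = "ymaze")
  expect_true(all(vapply(s, spontaneous_alternation, numeric(1)) == 100))

  expect_identical(length(generate_behavior_dataset(cfg, 0)), 0L)

  # two groups with distinct discrimination-ratio means, n = 50
  pars2 <- data.frame(group = c("hi", "lo"), dr_mean = c(0.70, 0.50),
                      dr_phi = 30, explore_total_s = 40, explore_cv = 0.3,
                      n_bouts_mean = 10, alternation = 0.6, entries_mean = 20)
  s2 <- generate_behavior_dataset(sim_config(behavior_group_params = pars2),
                                  50, seed = 10, type = "nor")
  sm <- behavior_summary(s2)
  for (g in c("hi", "lo")) {
    row <- sm[sm$group == g, ]
    truth <- pars2$dr_mean[pars2$group == g]
    expect_lt(abs(row$mean - truth), 2 * row$sem)
  }
})

test_that("sim_config rejects inconsistent truths", {
  expect_error(sim_config(pk_ka = 0.02), "pk_ka > pk_lambda_z")
  expect_error(sim_config(cv_intra = -0.1), "non-negative")
  expect_error(sim_config(sampling_times = c(1, 2)), "start at 0")
  expect_error(sim_config(recovery_true = 2), "0, 1.5")
})
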