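profile_df <- function(t, m) data.frame(time_h = t, mean = m)

test_that("mean profiles pool per-time statistics", {
  tab <- conc_time_table(
    data.frame(animal = paste0("m", 1:10),
               time_h = rep(c(0, 2), each = 5),
               conc = c(rep(0, 5), rep(40, 5))), dose = 20000)
  pr <- mean_profile(tab)
  expect_equal(pr$mean, c(0, 40))
  expect_equal(pr$sd, c(0, 0))
  expect_equal(pr$n, c(5L, 5L))
  expect_error(conc_time_table(
    data.frame(animal = c("a", "a"), time_h = c(0, 2), conc = c(0, 1)),
    dose = 1), "exactly once")
})

test_that("Cmax/Tmax take the profile maximum with earliest-time ties", {
  pr <- profile_df(c(0, 2, 4, 6, 8, 24), c(0, 50, 77, 60, 20, 3))
  expect_equal(unname(cmax_tmax(pr)), c(77, 4))
  dec <- profile_df(c(1, 2, 3), c(9, 5, 1))
  expect_equal(unname(cmax_tmax(dec)["tmax"]), 1)
  tie <- profile_df(c(0, 4, 6, 8), c(0, 70, 70, 10))
  expect_equal(unname(cmax_tmax(tie)["tmax"]), 4)
  expect_error(cmax_tmax(profile_df(c(0, 1), c(0, 0))), "all-zero")
})

test_that("terminal fits recover exact exponentials", {
  t <- c(0, 2, 4, 6, 8, 24)
  pr <- profile_df(t, 100 * exp(-0.0405 * t))
  lz <- fit_lambda_z(pr)
  expect_equal(lz$lambda_z, 0.0405, tolerance = 1e-10)
  expect_equal(lz$r2_adj, 1, tolerance = 1e-8)
  expect_equal(lz$t_half, log(2) / 0.0405, tolerance = 1e-10)
  expect_equal(round(log(2) / 0.0405, 2), 17.11)
  expect_error(fit_lambda_z(profile_df(c(0, 2, 4), c(0, 5, 9))),
               "insufficient terminal data")
})

test_that("AUC and AUMC quadrature match closed forms", {
  expect_equal(auc(profile_df(c(0, 2), c(0, 10))), 10)    # triangle
  const <- profile_df(c(0, 5, 10), c(3, 3, 3))
  expect_equal(auc(const), 30)
  expect_equal(aumc(const) / auc(const), 5)               # MRT = T/2
  t <- seq(0, 60, by = 0.05)
  expo <- profile_df(t, 50 * exp(-0.1 * t))
  expect_equal(auc(expo), 50 / 0.1 * (1 - exp(-6)), tolerance = 1e-3)
  expect_error(auc(profile_df(c(2, 1), c(1, 1))), "sorted")
  # log-down trapezoids are exact on exponential declines
  sparse <- profile_df(c(0, 6, 12), 50 * exp(-0.1 * c(0, 6, 12)))
  a_log <- auc(sparse, method = "lin_up_log_down")
  expect_equal(a_log, 50 / 0.1 * (1 - exp(-1.2)), tolerance = 1e-9)
})

test_that("AUC agrees with an independent quadrature oracle", {
  set.seed(99)
  for (i in 1:10) {
    t <- sort(c(0, runif(8, 0.1, 24)))
    y <- abs(rnorm(9, 50, 20))
    expect_equal(auc(profile_df(t, y)), pracma::trapz(t, y),
                 tolerance = 1e-10)
  }
})

test_that("extrapolation reconstructs the printed AUC pair", {
  expect_equal(extrapolate_auc(10, 0, 0.04)$frac_auc, 1)
  # an AUC(0-t) of 571.48 with observed fraction 0.51 implies
  # AUC(0-inf) = 1120.55; check via the extrapolation inverse
  tail_auc <- 571.48 / 0.51 - 571.48
  ext <- suppressWarnings(extrapolate_auc(571.48, tail_auc * 1, 1))
  expect_equal(round(ext$auc_0_inf, 2), 1120.55)
  expect_equal(ext$frac_auc, 0.51, tolerance = 1e-12)
  # truncated exponential: frac = 1 - exp(-lambda t)
  lambda <- 0.2; C0 <- 30; tend <- 10
  t <- seq(0, tend, by = 0.001)
  a_t <- auc(profile_df(t, C0 * exp(-lambda * t)))
  ext2 <- extrapolate_auc(a_t, C0 * exp(-lambda * tend), lambda)
  expect_equal(ext2$frac_auc, 1 - exp(-lambda * tend), tolerance = 1e-4)
  expect_warning(extrapolate_auc(30, 100, 1), "high extrapolation")
})

test_that("clearance and volume satisfy their identities", {
  cv <- clearance_volume(20000, 571.48 / 0.51, 0.0405)
  expect_equal(round(unname(cv["cl_f"]), 2), 17.85)
  expect_equal(unname(cv["vz_f"] * 0.0405), unname(cv["cl_f"]),
               tolerance = 1e-12)
  # dose-proportional profiles leave Cl/F invariant
  cfg <- sim_config(pk_bsv_cv = 0)
  n1 <- suppressWarnings(nca(generate_pk_dataset(cfg, dose = 20000,
                                                 seed = 5)))
  cfg2 <- cfg; cfg2$pk_scale <- cfg$pk_scale * 2
  n2 <- suppressWarnings(nca(generate_pk_dataset(cfg2, dose = 40000,
                                                 seed = 5)))
  expect_equal(n2$parameters$cl_f, n1$parameters$cl_f, tolerance = 1e-9)
})

test_that("full NCA composes the parts with exact internal identities", {
  cfg <- sim_config(pk_bsv_cv = 0)
  res <- suppressWarnings(nca(generate_pk_dataset(cfg, seed = 6)))
  p <- res$parameters
  expect_equal(p$tmax, 4)
  expect_lt(abs(p$t_half - 17.1) / 17.1, 0.05)
  expect_equal(p$t_half * p$lambda_z, log(2), tolerance = 1e-12)
  expect_equal(p$cl_f, p$lambda_z * p$vz_f, tolerance = 1e-12)
  expect_true(p$frac_auc > 0 && p$frac_auc <= 1)
  expect_equal(p$mrt_0_t, p$aumc_0_t / p$auc_0_t, tolerance = 1e-12)
  # constant-rate profile: MRT = T/2 exactly
  flat <- conc_time_table(
    data.frame(animal = paste0("x", 1:4), time_h = c(0.01, 8, 16, 24),
               conc = 10), dose = 1000)
  pr <- mean_profile(flat)
  expect_equal(aumc(pr) / auc(pr), (24 + 0.01) / 2, tolerance = 1e-9)
})

test_that("dense noiseless sampling approaches the closed-form AUC(0-inf)", {
  ka <- 0.8; lz <- 0.0405; A <- 95
  t <- seq(0, 400, length.out = 1000)
  pr <- profile_df(t, A * (exp(-lz * t) - exp(-ka * t)))
  total <- auc(pr) + pr$mean[1000] / lz
  expect_equal(total, A * (1 / lz - 1 / ka), tolerance = 1e-3)
})

test_that("AUC is additive over adjacent intervals and linear in scale", {
  t <- c(0, 2, 4, 6, 8, 24)
  y <- c(0, 50, 77, 60, 20, 3)
  whole <- auc(profile_df(t, y))
  left <- auc(profile_df(t[1:3], y[1:3]))
  right <- auc(profile_df(t[3:6], y[3:6]))
  expect_equal(left + right, whole, tolerance = 1e-12)
  expect_equal(auc(profile_df(t, 3 * y)), 3 * whole, tolerance = 1e-12)
})

test_that("stochastic composite NCA recovers the half-life", {
  cfg <- sim_config(pk_bsv_cv = 0.15)
  th <- vapply(1:100, function(s) {
    res <- suppressWarnings(nca(generate_pk_dataset(cfg, seed = 6000 + s)))
    res$parameters$t_half
  }, numeric(1))
  expect_lt(abs(median(th) - 17.1) / 17.1, 0.15)
})
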