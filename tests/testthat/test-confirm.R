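test_that("retention-time window applies relative to the reference", {
  r1 <- check_rt(11.30, 11.22)
  expect_equal(r1$observed, 100 * 0.08 / 11.22, tolerance = 1e-9)  # 0.713%
  expect_true(r1$pass)
  r2 <- check_rt(11.40, 11.22)
  expect_equal(round(r2$observed, 3), 1.604)
  expect_false(r2$pass)
  expect_true(check_rt(11.22, 11.22)$pass)
  expect_error(check_rt(11, 0), "positive")
})

test_that("ion-ratio checks use relative deviation from the reference", {
  # reference RA 73, sample RA 60: deviation 17.8% -> pass
  s <- c(q = 1000, a = 600)
  r <- check_ion_ratios(s, c(a = 73), quantifier = "q")
  expect_equal(round(r$observed, 1), 17.8)
  expect_true(r$pass)
  # reference RA 44, sample RA 33: deviation 25% -> fail
  r2 <- check_ion_ratios(c(q = 1000, b = 330), c(b = 44), quantifier = "q")
  expect_equal(r2$observed, 25)
  expect_false(r2$pass)
  # exact agreement
  r3 <- check_ion_ratios(c(q = 1000, a = 730), c(a = 73), quantifier = "q")
  expect_equal(r3$observed, 0)
  expect_true(r3$pass)
  # absent qualifier fails with a named reason
  r4 <- check_ion_ratios(c(q = 1000), c(a = 73), quantifier = "q")
  expect_false(r4$pass)
  expect_match(r4$note, "qualifier absent")
})

test_that("blank limits follow the 20%/5% selectivity rule", {
  ok <- check_blank(10, 2, 100, 100)
  expect_true(all(ok$pass))
  bad <- check_blank(25, 2, 100, 100)
  expect_false(bad$pass[bad$criterion == "blank_analyte"])
  zero <- check_blank(0, 0, 100, 100)
  expect_true(all(zero$pass))
  expect_error(check_blank(1, 1, 0, 100), "positive")
})

test_that("identity decision aggregates all criteria", {
  cfg <- sim_config()
  des <- data.frame(
    role = c("blank", "solvent_spike", "pre_spike", "calibrator", "blank"),
    nominal = c(0, 5, 5, 0.5, 0),
    sample_id = c("B1", "REF", "S1", "LLOQ", "B2"))
  tab <- generate_injection_table(des, cfg, seed = 31)
  res <- confirm_identity(tab, "S1", "REF", blank_id = "B1",
                          carryover_blank_id = "B2", lloq_id = "LLOQ")
  expect_s3_class(res, "confirmation_result")
  expect_identical(res$confirmed, all(res$criteria$pass))

  # a 30% qualifier deviation flips the overall decision and is named
  tab2 <- tab
  i <- which(tab2$sample_id == "S1" & tab2$transition == "451>435")
  tab2$area[i] <- tab2$area[i] * 1.30
  ref_i <- which(tab2$sample_id == "REF" & tab2$transition == "451>435")
  tab2$area[ref_i] <- tab2$area[ref_i] / 1.05
  res2 <- confirm_identity(tab2, "S1", "REF", blank_id = "B1",
                           lloq_id = "LLOQ")
  if (!res2$confirmed)
    expect_match(res2$diagnostics, "ion_ratio_451>435", fixed = TRUE)
  expect_error(confirm_identity(tab, "S1", "NOPE"), "reference")
})

test_that("decision is monotone in the tolerances", {
  cfg <- sim_config(cv_intra = 0.08, rt_cv = 0.004)
  des <- data.frame(role = c("solvent_spike", "pre_spike"), nominal = 5,
                    sample_id = c("REF", "S1"))
  for (s in 1:30) {
    tab <- generate_injection_table(des, cfg, seed = 500 + s)
    tight <- confirm_identity(tab, "S1", "REF",
                              criteria = confirmation_criteria(
                                rt_tolerance_pct = 0.2,
                                ion_ratio_tolerance_pct = 5))
    loose <- confirm_identity(tab, "S1", "REF",
                              criteria = confirmation_criteria(
                                rt_tolerance_pct = 2,
                                ion_ratio_tolerance_pct = 40))
    if (tight$confirmed) expect_true(loose$confirmed)
  }
})

test_that("synthetic batches classify spikes and blanks correctly", {
  cfg <- sim_config()
  des <- data.frame(
    role = c("blank", "solvent_spike", "pre_spike", "calibrator"),
    nominal = c(0, 5, 5, 0.5),
    sample_id = c("B1", "REF", "S1", "LLOQ"))
  n <- 100
  sens <- spec <- logical(n)
  for (s in seq_len(n)) {
    tab <- generate_injection_table(des, cfg, seed = 1000 + s)
    sens[s] <- confirm_identity(tab, "S1", "REF", blank_id = "B1",
                                lloq_id = "LLOQ")$confirmed
    spec[s] <- !confirm_identity(tab, "B1", "REF", lloq_id = "LLOQ")$confirmed
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(spec), 0.99)
})
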