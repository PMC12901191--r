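# Shared fixtures: built in code, never stored.

# the assay's final and initial oven programs
final_program <- function()
  oven_program(200, 1, data.frame(rate = c(30, 2), target = c(280, 300),
                                  hold = c(0, 2)))
initial_program <- function()
  oven_program(70, 1, data.frame(rate = 5, target = 300, hold = 2))

# noiseless configuration pinned to the printed calibration line
noiseless_config <- function(...)
  sim_config(cv_intra = 0, cv_inter_day = 0, rt_cv = 0,
             recovery_true = 1, matrix_factor_true = 1,
             matrix_factor_is = 1, ...)

six_levels <- c(0.5, 0.75, 1.5, 5, 10, 20)

calibrator_design <- function(levels = six_levels, day = 1L)
  data.frame(role = "calibrator", nominal = levels, day = day)

# exact line used throughout: y = 8.5133 x + 1.7962
line_ratio <- function(x) 8.5133 * x + 1.7962

# independent brute-force oracle for the calibration acceptance gate
oracle_calibration_gate <- function(dev_pct, lloq_idx = 1L,
                                    tol = 15, tol_lloq = 20) {
  ok <- logical(length(dev_pct))
  for (i in seq_along(dev_pct))
    ok[i] <- abs(dev_pct[i]) <= (if (i == lloq_idx) tol_lloq else tol)
  (sum(ok) / length(ok) >= 0.75) && ok[lloq_idx]
}

# independent window-enumeration oracle for spontaneous alternation
oracle_alternation <- function(entries) {
  n <- length(entries)
  hits <- 0L
  for (i in 1:(n - 2L)) {
    w <- entries[i:(i + 2L)]
    if (w[1] != w[2] && w[2] != w[3] && w[1] != w[3]) hits <- hits + 1L
  }
  100 * hits / (n - 2L)
}

# all arm sequences of length n without immediate re-entries
valid_sequences <- function(n) {
  arms <- c("A", "B", "C")
  seqs <- as.list(arms)
  for (k in 2:n) {
    seqs <- unlist(lapply(seqs, function(s) {
      lapply(setdiff(arms, s[length(s)]), function(a) c(s, a))
    }), recursive = FALSE)
  }
  seqs
}
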