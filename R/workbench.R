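.INJECTION_COLS <- c("sample_id", "role", "nominal", "day", "channel",
                     "transition", "transition_role", "rt_min", "area")

#' Injection-table CSV input/output
#'
#' Round-trip-lossless CSV serialization of per-transition injection tables
#' (numeric fields written at full double precision).  Unknown extra columns
#' are preserved with a warning on read; a missing required column or a
#' malformed numeric cell is a schema error naming the column (and row).
#'
#' @param path CSV file path.
#' @return `read_injection_table()`: an `injection_table` data.frame.
#' @export
read_injection_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(.INJECTION_COLS, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(d), .INJECTION_COLS)
  if (length(extra))
    warning("preserving unknown column(s): ", paste(extra, collapse = ", "))
  for (col in c("nominal", "rt_min", "area")) {
    raw <- d[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
    if (length(bad))
      stop("malformed numeric cell in column '", col, "', row ",
           bad[1L], ": '", raw[bad[1L]], "'")
    d[[col]] <- val
  }
  if (!is.null(d$day)) d$day <- utils::type.convert(d$day, as.is = TRUE)
  class(d) <- c("injection_table", "data.frame")
  d
}

#' @rdname read_injection_table
#' @param table an injection table to write.
#' @export
write_injection_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (col in names(out))
    if (is.double(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA,
                           sprintf("%.17g", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Consolidated bioanalytical validation report
#'
#' Composes the ICH-M10-style validation blocks from the standard design
#' tables: per-assay calibration fits with acceptance gates and CV/accuracy
#' ranges, LOD/LOQ from the intercept SD and mean slope, intra/inter-day
#' precision and accuracy, extraction recovery, and the matrix-effect gate.
#'
#' @param cal_table injection table of calibrators with columns `assay` and
#'   `day` in the design (nine independent assays in the reference design).
#' @param qc_table injection table of QC replicates with columns `level` and
#'   `day`.
#' @param recovery_table injection table with roles `pre_spike` and
#'   `post_spike` and a `level` column.
#' @param me_table injection table with roles `post_spike` (matrix) and
#'   `solvent_spike`, with a `level` column.
#' @param lloq_level LLOQ nominal concentration, ug/mL.
#' @param cal_range calibration range, ug/mL.
#' @param weighting calibration regression weighting used throughout the
#'   report.  The default `"1/x2"` is the standard bioanalytical choice over
#'   a wide range with signal-proportional noise (it keeps back-calculation
#'   at the low end, and hence the intercept-SD-based LOD/LOQ, from being
#'   dominated by the top calibrators); `"none"` gives plain OLS.
#' @return list of class `"validation_report"` with blocks `linearity`,
#'   `lod_loq`, `precision_accuracy`, `recovery`, `matrix_effect` and an
#'   `overall_pass` verdict.
#' @export
validation_report <- function(cal_table, qc_table, recovery_table, me_table,
                              lloq_level = 0.5, cal_range = c(0.5, 20),
                              weighting = c("1/x2", "none")) {
  weighting <- match.arg(weighting)
  cal <- area_ratios(cal_table)
  if (is.null(cal$assay)) cal$assay <- cal$day
  fits <- lapply(split(cal, cal$assay), function(d)
    fit_calibration(d$nominal, d$ratio, assay = d$assay[1L],
                    weighting = weighting))
  gates <- lapply(fits, calibration_acceptance, lloq_level = lloq_level)
  backs <- do.call(rbind, lapply(fits, function(f) f$calibrators))
  per_level_cv <- vapply(split(backs, backs$nominal), function(x)
    100 * stats::sd(x$back_calc) / mean(x$back_calc), numeric(1))
  per_level_acc <- vapply(split(backs, backs$nominal), function(x)
    100 * mean(x$back_calc) / x$nominal[1L], numeric(1))
  linearity <- list(
    n_assays = length(fits),
    slopes = vapply(fits, `[[`, numeric(1), "slope"),
    intercepts = vapply(fits, `[[`, numeric(1), "intercept"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    cv_range_pct = range(per_level_cv),
    accuracy_range_pct = range(per_level_acc),
    gate_pass = all(vapply(gates, `[[`, logical(1), "pass")))

  limits <- lod_loq(fits)

  qc <- area_ratios(qc_table)
  day_fit <- lapply(split(cal, cal$day), function(d)
    fit_calibration(d$nominal, d$ratio, assay = paste0("day", d$day[1L]),
                    weighting = weighting))
  qc$measured <- NA_real_
  for (dy in unique(qc$day)) {
    f <- day_fit[[as.character(dy)]]
    if (is.null(f)) f <- fits[[1L]]
    sel <- qc$day == dy
    qc$measured[sel] <- quantify(qc$ratio[sel], f, range = cal_range)$conc
  }
  if (is.null(qc$level)) qc$level <- paste0("QC", qc$nominal)
  pa <- precision_accuracy(qc[, c("level", "nominal", "day", "measured")],
                           lloq_level = lloq_level)

  rec_r <- area_ratios(recovery_table)
  rec <- lapply(split(rec_r, rec_r$level), function(d)
    recovery(d$ratio[d$role == "pre_spike"],
             d$ratio[d$role == "post_spike"]))

  me_r <- area_ratios(me_table)
  me <- lapply(split(me_r, me_r$level), function(d) {
    mx <- d[d$role == "post_spike", ]
    sv <- d[d$role == "solvent_spike", ]
    matrix_effect(mx$analyte_area, sv$analyte_area,
                  mx$is_area, sv$is_area)
  })

  structure(list(
    linearity = linearity,
    lod_loq = limits,
    precision_accuracy = pa,
    recovery = rec,
    matrix_effect = me,
    overall_pass = linearity$gate_pass && all(pa$pass) &&
      all(vapply(me, `[[`, logical(1), "pass"))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$overall_pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  linearity: %d assays, mean slope %.4f, r^2 >= %.4f, gate %s\n",
              x$linearity$n_assays, mean(x$linearity$slopes),
              min(x$linearity$r_squared),
              if (x$linearity$gate_pass) "pass" else "FAIL"))
  cat(sprintf("  LOD %.2f / LOQ %.2f ug/mL\n", x$lod_loq$lod, x$lod_loq$loq))
  cat("  precision/accuracy:\n")
  print.data.frame(
    within(x$precision_accuracy, {
      grand_mean <- round(grand_mean, 2); sd <- round(sd, 2)
      cv_intra_pct <- round(cv_intra_pct, 2)
      cv_inter_pct <- round(cv_inter_pct, 2)
      cv_pooled_pct <- round(cv_pooled_pct, 2)
      accuracy_pct <- round(accuracy_pct, 2)
    }), row.names = FALSE)
  for (lev in names(x$recovery))
    cat(sprintf("  recovery %s: %.2f%% (CV %.2f%%)\n", lev,
                x$recovery[[lev]]$recovery_pct, x$recovery[[lev]]$cv_pct))
  for (lev in names(x$matrix_effect))
    cat(sprintf("  IS-normalized MF %s: %.3f (CV %.2f%%) %s\n", lev,
                x$matrix_effect[[lev]]$is_normalized_mf,
                x$matrix_effect[[lev]]$cv_pct,
                if (x$matrix_effect[[lev]]$pass) "pass" else "FAIL"))
  invisible(x)
}

config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %%
            .Machine$integer.max)
}

#' Study configuration for the end-to-end pipeline
#'
#' @param sim a [sim_config()] describing the synthetic study conditions.
#' @param criteria a [confirmation_criteria()].
#' @param dose_ug_kg pharmacokinetic dose, ug/kg (default 20 mg/kg).
#' @param unknown_groups named true homogenate concentrations (ug/mL) for the
#'   group-quantification stage.
#' @param n_unknowns_per_group replicates per quantified group.
#' @param n_behavior_per_group animals per behavioral group.
#' @param buffer_volume_per_mass homogenization ratio, mL/mg.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(sim = sim_config(),
                         criteria = confirmation_criteria(),
                         dose_ug_kg = 20000,
                         unknown_groups = c(LPS_LCA = 14.37, LCA = 2.91),
                         n_unknowns_per_group = 6L,
                         n_behavior_per_group = 10L,
                         buffer_volume_per_mass = 0.01) {
  structure(as.list(environment()), class = "study_config")
}

#' Run the end-to-end synthetic study
#'
#' Simulate, confirm, validate, quantify, analyze pharmacokinetics and score
#' behavior, consolidating everything into one deterministic report.  Gate
#' failures are recorded in the report, never fatal.
#'
#' @param config a [study_config()].
#' @param seed integer seed driving every stage.
#' @return list of class `"study_report"` with per-stage blocks, warnings
#'   and provenance (`seed`, `config_hash`).
#' @export
run_pipeline <- function(config = study_config(), seed = 1L) {
  sim <- config$sim
  warnings <- character()
  note <- function(w) warnings <<- c(warnings, w)

  # --- calibration + QC + recovery + matrix-effect designs ----------------
  levels6 <- c(0.5, 0.75, 1.5, 5, 10, 20)
  qc_levels <- c(LQC = 0.5, MQC = 7.5, HQC = 15)
  cal_design <- do.call(rbind, lapply(1:3, function(day)
    do.call(rbind, lapply(1:3, function(rep)
      data.frame(role = "calibrator", nominal = levels6, day = day,
                 assay = sprintf("d%dr%d", day, rep), level = NA)))))
  qc_design <- do.call(rbind, lapply(1:3, function(day)
    do.call(rbind, lapply(names(qc_levels), function(lv)
      data.frame(role = "qc", nominal = unname(qc_levels[lv]), day = day,
                 assay = NA, level = lv)))))
  qc_design <- qc_design[rep(seq_len(nrow(qc_design)), each = 5), ]
  # the truth line describes the processed matrix calibrator response
  sim_cal <- sim; sim_cal$recovery_true <- 1
  sim_cal$matrix_factor_true <- sim_cal$matrix_factor_is
  # one generator call so calibrators and QCs share each day's batch effect,
  # as they would on the instrument
  cal_qc <- generate_injection_table(rbind(cal_design, qc_design), sim_cal,
                                     seed = seed)
  cal_table <- cal_qc[cal_qc$role == "calibrator", ]
  qc_table <- cal_qc[cal_qc$role == "qc", ]

  rec_design <- do.call(rbind, lapply(names(qc_levels), function(lv)
    data.frame(role = rep(c("pre_spike", "post_spike"), each = 3),
               nominal = unname(qc_levels[lv]), day = 1, level = lv)))
  rec_table <- generate_injection_table(rec_design, sim, seed = seed + 2L)

  me_design <- do.call(rbind, lapply(names(qc_levels), function(lv)
    data.frame(role = rep(c("post_spike", "solvent_spike"), each = 3),
               nominal = unname(qc_levels[lv]), day = 1, level = lv)))
  me_table <- generate_injection_table(me_design, sim, seed = seed + 3L)

  # --- identity confirmation ---------------------------------------------
  conf_design <- data.frame(
    role = c("blank", "zero", "solvent_spike", "pre_spike", "calibrator",
             "blank"),
    nominal = c(0, 0, 5, 5, 0.5, 0),
    sample_id = c("BLK_PRE", "ZERO", "REF_STD", "SAMPLE", "LLOQ",
                  "BLK_POST"))
  conf_table <- generate_injection_table(conf_design, sim, seed = seed + 4L)
  confirmation <- confirm_identity(conf_table, "SAMPLE", "REF_STD",
                                   blank_id = "BLK_PRE",
                                   carryover_blank_id = "BLK_POST",
                                   lloq_id = "LLOQ",
                                   criteria = config$criteria)
  if (!confirmation$confirmed) note("identity not confirmed")

  # --- validation ---------------------------------------------------------
  validation <- withCallingHandlers(
    validation_report(cal_table, qc_table, rec_table, me_table),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
  if (!validation$overall_pass) note("validation gate failure")

  # --- group quantification ----------------------------------------------
  fit <- fit_calibration(area_ratios(cal_table)$nominal,
                         area_ratios(cal_table)$ratio, assay = "pooled")
  unk_design <- do.call(rbind, lapply(names(config$unknown_groups),
                                      function(g)
    data.frame(role = "unknown", nominal = config$unknown_groups[[g]],
               day = 1, group = g,
               rep = seq_len(config$n_unknowns_per_group))))
  unk_table <- generate_injection_table(unk_design, sim_cal, seed = seed + 5L)
  unk <- area_ratios(unk_table)
  q <- quantify(unk$ratio, fit)
  unk$conc_ug_ml <- q$conc
  unk$flag <- q$flag
  unk$tissue_ug_mg <- homogenate_to_tissue(q$conc,
                                           config$buffer_volume_per_mass)
  keep <- unk$flag == ""
  if (any(!keep)) note(sprintf("%d quantified sample(s) flagged BLQ/ALQ",
                               sum(!keep)))
  quantification <- do.call(rbind, lapply(split(unk, unk$group), function(d) {
    k <- d$flag == ""
    data.frame(group = d$group[1L], n = sum(k),
               mean_ug_ml = mean(d$conc_ug_ml[k]),
               sd_ug_ml = stats::sd(d$conc_ug_ml[k]),
               mean_tissue_ug_mg = mean(d$tissue_ug_mg[k]),
               stringsAsFactors = FALSE)
  }))
  rownames(quantification) <- NULL

  # --- pharmacokinetics ---------------------------------------------------
  pk_table <- generate_pk_dataset(sim, dose = config$dose_ug_kg,
                                  seed = seed + 6L)
  pk_fit <- withCallingHandlers(
    nca(pk_table),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })

  # --- behavior -----------------------------------------------------------
  sessions <- generate_behavior_dataset(sim, config$n_behavior_per_group,
                                        seed = seed + 7L)
  behavior <- behavior_summary(sessions)
  excl <- apply_exclusions(sessions)
  if (nrow(excl$excluded))
    note(sprintf("%d behavioral session(s) excluded", nrow(excl$excluded)))

  structure(list(
    seed = seed,
    config_hash = config_hash(config),
    confirmation = list(confirmed = confirmation$confirmed,
                        criteria = confirmation$criteria),
    validation = validation,
    quantification = quantification,
    pk = list(profile = pk_fit$profile, parameters = pk_fit$parameters),
    behavior = behavior,
    warnings = warnings),
    class = "study_report")
}

#' Write a study (or any) report as JSON
#'
#' @param report a `study_report` (or any JSON-serializable list).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, unclass_deep))
  if (!is.null(attributes(x)) && !is.null(names(x))) return(as.list(x))
  x
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$seed, " config", x$config_hash, "\n")
  cat("  identity:", if (x$confirmation$confirmed) "confirmed"
      else "NOT confirmed", "\n")
  cat("  validation:", if (x$validation$overall_pass) "pass" else "FAIL",
      sprintf(" (LOD %.2f, LOQ %.2f ug/mL)\n", x$validation$lod_loq$lod,
              x$validation$lod_loq$loq))
  cat(sprintf("  PK: Tmax %.1f h, Cmax %.1f ug/mg, T1/2 %.1f h\n",
              x$pk$parameters$tmax, x$pk$parameters$cmax,
              x$pk$parameters$t_half))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
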