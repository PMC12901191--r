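#' Identity-confirmation criteria
#'
#' Tolerances for FDA-style qualitative confirmation: retention time within
#' +/-1% of the same-batch reference standard, each qualifier's relative
#' abundance within +/-20% (relative) of the reference ratio, and blank /
#' carry-over limits of 20% of the LLOQ analyte area and 5% of the mean
#' internal-standard area.
#'
#' @param rt_tolerance_pct retention-time window, % of the reference RT.
#' @param ion_ratio_tolerance_pct relative ion-ratio window, %.
#' @param blank_analyte_max_pct_of_lloq blank analyte-area limit, % of the
#'   LLOQ calibrator's analyte area.
#' @param blank_is_max_pct blank IS-area limit, % of the mean IS area.
#' @return list of class `"confirmation_criteria"`.
#' @export
confirmation_criteria <- function(rt_tolerance_pct = 1,
                                  ion_ratio_tolerance_pct = 20,
                                  blank_analyte_max_pct_of_lloq = 20,
                                  blank_is_max_pct = 5) {
  vals <- c(rt_tolerance_pct, ion_ratio_tolerance_pct,
            blank_analyte_max_pct_of_lloq, blank_is_max_pct)
  if (any(vals <= 0)) stop("all tolerances must be positive")
  structure(list(rt_tolerance_pct = rt_tolerance_pct,
                 ion_ratio_tolerance_pct = ion_ratio_tolerance_pct,
                 blank_analyte_max_pct_of_lloq = blank_analyte_max_pct_of_lloq,
                 blank_is_max_pct = blank_is_max_pct),
            class = "confirmation_criteria")
}

criterion_record <- function(name, observed, limit, pass, note = "") {
  data.frame(criterion = name, observed = observed, limit = limit,
             pass = pass, note = note, stringsAsFactors = FALSE)
}

#' Retention-time agreement check
#'
#' Passes iff `100 * |rt_sample - rt_reference| / rt_reference` is within the
#' tolerance.  The denominator is always the reference (documented
#' asymmetry).
#'
#' @param rt_sample,rt_reference retention times, min (`rt_reference` > 0).
#' @param criteria a [confirmation_criteria()].
#' @return one-row criterion record (criterion, observed, limit, pass, note).
#' @export
check_rt <- function(rt_sample, rt_reference,
                     criteria = confirmation_criteria()) {
  if (!is.finite(rt_reference) || rt_reference <= 0)
    stop("reference RT must be positive")
  dev <- 100 * abs(rt_sample - rt_reference) / rt_reference
  criterion_record("rt_agreement", dev, criteria$rt_tolerance_pct,
                   is.finite(dev) && dev <= criteria$rt_tolerance_pct)
}

#' MRM ion-ratio agreement checks
#'
#' For each qualifier, the sample relative abundance is
#' `100 * qualifier area / quantifier area`; the check passes iff its
#' relative deviation from the reference relative abundance is within the
#' tolerance (`|RA_s - RA_ref| / RA_ref <= 20%` at defaults).  A missing
#' qualifier peak fails automatically.
#'
#' @param sample_areas named numeric vector of the sample's transition areas;
#'   the first element (or the one named in `quantifier`) is the quantifier.
#' @param reference_ra named numeric vector of reference relative abundances
#'   (% of quantifier) for the qualifiers.
#' @param criteria a [confirmation_criteria()].
#' @param quantifier name of the quantifier transition in `sample_areas`.
#' @return criterion records, one row per qualifier.
#' @export
check_ion_ratios <- function(sample_areas, reference_ra,
                             criteria = confirmation_criteria(),
                             quantifier = names(sample_areas)[1L]) {
  quant <- sample_areas[[quantifier]]
  if (is.null(quant) || !is.finite(quant) || quant <= 0) {
    # no quantifiable peak in the sample: every qualifier check fails
    return(do.call(rbind, lapply(names(reference_ra), function(q)
      criterion_record(paste0("ion_ratio_", q), NA_real_,
                       criteria$ion_ratio_tolerance_pct, FALSE,
                       "quantifier absent"))))
  }
  out <- NULL
  for (q in names(reference_ra)) {
    ref <- reference_ra[[q]]
    if (!(q %in% names(sample_areas)) || !is.finite(sample_areas[[q]]) ||
        sample_areas[[q]] <= 0) {
      out <- rbind(out, criterion_record(
        paste0("ion_ratio_", q), NA_real_,
        criteria$ion_ratio_tolerance_pct, FALSE, "qualifier absent"))
      next
    }
    ra <- 100 * sample_areas[[q]] / quant
    dev <- 100 * abs(ra - ref) / ref
    out <- rbind(out, criterion_record(
      paste0("ion_ratio_", q), dev, criteria$ion_ratio_tolerance_pct,
      dev <= criteria$ion_ratio_tolerance_pct))
  }
  out
}

#' Blank (selectivity) check
#'
#' Passes iff the blank's analyte-region area is below 20% of the LLOQ
#' calibrator's analyte area and the blank's IS-region area is below 5% of
#' the mean IS area (defaults).
#'
#' @param blank_analyte_area,blank_is_area areas observed in the blank.
#' @param lloq_analyte_area analyte area of the LLOQ calibrator (> 0).
#' @param mean_is_area mean internal-standard area (> 0).
#' @param criteria a [confirmation_criteria()].
#' @param label prefix for the criterion names (e.g. `"blank"`,
#'   `"carryover"`).
#' @return two criterion records (analyte and IS limits).
#' @export
check_blank <- function(blank_analyte_area, blank_is_area,
                        lloq_analyte_area, mean_is_area,
                        criteria = confirmation_criteria(),
                        label = "blank") {
  if (lloq_analyte_area <= 0 || mean_is_area <= 0)
    stop("LLOQ analyte area and mean IS area must be positive")
  pa <- 100 * blank_analyte_area / lloq_analyte_area
  pi <- 100 * blank_is_area / mean_is_area
  rbind(
    criterion_record(paste0(label, "_analyte"), pa,
                     criteria$blank_analyte_max_pct_of_lloq,
                     pa < criteria$blank_analyte_max_pct_of_lloq),
    criterion_record(paste0(label, "_is"), pi, criteria$blank_is_max_pct,
                     pi < criteria$blank_is_max_pct))
}

sample_channel <- function(table, id, channel = "analyte") {
  table[table$sample_id == id & table$channel == channel, , drop = FALSE]
}

#' Confirm the identity of an analyte in one injection
#'
#' Aggregates the retention-time check, one ion-ratio check per qualifier,
#' the pre-run blank selectivity check and (if a post-run blank is supplied)
#' the carry-over check into a single auditable decision.  The sample is
#' confirmed only if every criterion passes.
#'
#' @param table an injection table (see [generate_injection_table()]).
#' @param sample_id,reference_id sample and same-batch reference-standard
#'   injection ids in `table`.
#' @param blank_id pre-run blank injection id (optional).
#' @param carryover_blank_id post-run blank injection id (optional).
#' @param lloq_id LLOQ calibrator injection id (needed for blank checks;
#'   defaults to the lowest-nominal calibrator in the table).
#' @param criteria a [confirmation_criteria()].
#' @return list of class `"confirmation_result"` with elements `criteria`
#'   (record table), `confirmed`, `diagnostics`.
#' @export
confirm_identity <- function(table, sample_id, reference_id,
                             blank_id = NULL, carryover_blank_id = NULL,
                             lloq_id = NULL,
                             criteria = confirmation_criteria()) {
  ref <- sample_channel(table, reference_id)
  if (!nrow(ref)) stop("no same-batch reference standard: ", reference_id)
  smp <- sample_channel(table, sample_id)
  if (!nrow(smp)) stop("unknown sample id: ", sample_id)
  ref_q <- ref[ref$transition_role == "quantifier", ]
  smp_q <- smp[smp$transition_role == "quantifier", ]
  records <- check_rt(smp_q$rt_min, ref_q$rt_min, criteria)

  ref_qual <- ref[ref$transition_role == "qualifier", ]
  ref_ra <- stats::setNames(100 * ref_qual$area / ref_q$area,
                            ref_qual$transition)
  smp_areas <- stats::setNames(smp$area, smp$transition)
  # peakless channels (NA retention time) are treated as absent peaks
  smp_areas[is.na(smp$rt_min)] <- NA_real_
  records <- rbind(records,
                   check_ion_ratios(smp_areas, ref_ra, criteria,
                                    quantifier = smp_q$transition))

  if (!is.null(blank_id) || !is.null(carryover_blank_id)) {
    if (is.null(lloq_id)) {
      cal <- table[table$role == "calibrator" & table$channel == "analyte" &
                     table$transition_role == "quantifier", ]
      if (!nrow(cal)) stop("no calibrator available to anchor blank limits")
      lloq_id <- cal$sample_id[which.min(cal$nominal)]
    }
    lloq_area <- sample_channel(table, lloq_id)$area[
      sample_channel(table, lloq_id)$transition_role == "quantifier"]
    isq <- table[table$channel == "is" & table$transition_role == "quantifier" &
                   table$role != "blank", ]
    mean_is <- mean(isq$area)
    blanks <- list(blank = blank_id, carryover = carryover_blank_id)
    for (lab in names(blanks)) {
      bid <- blanks[[lab]]
      if (is.null(bid)) next
      b <- sample_channel(table, bid)
      if (!nrow(b)) stop("unknown blank id: ", bid)
      b_an <- b$area[b$transition_role == "quantifier"]
      b_is <- sample_channel(table, bid, "is")
      b_is_area <- b_is$area[b_is$transition_role == "quantifier"]
      records <- rbind(records,
                       check_blank(b_an, b_is_area, lloq_area, mean_is,
                                   criteria, label = lab))
    }
  }
  confirmed <- all(records$pass)
  failing <- records$criterion[!records$pass]
  structure(list(
    criteria = records,
    confirmed = confirmed,
    diagnostics = if (confirmed) "all criteria within limits"
                  else paste("failed:", paste(failing, collapse = ", "))),
    class = "confirmation_result")
}

#' @export
print.confirmation_result <- function(x, ...) {
  cat("<confirmation_result>",
      if (x$confirmed) "CONFIRMED" else "NOT CONFIRMED", "\n")
  df <- x$criteria
  df$observed <- round(df$observed, 3)
  print.data.frame(df, row.names = FALSE)
  cat(x$diagnostics, "\n")
  invisible(x)
}
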