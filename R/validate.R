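#' Fit a calibration line
#'
#' Ordinary least squares of the analyte/IS peak-area ratio on nominal
#' concentration over at least six distinct non-zero calibrator levels, with
#' per-calibrator back-calculated concentrations and percent deviations.
#' A weighted (1/x^2) fit is available behind `weighting`.
#'
#' @param nominal nominal concentrations, ug/mL.
#' @param ratio analyte/IS area ratios.
#' @param assay optional assay identifier (day/replicate) carried in the fit.
#' @param weighting `"none"` (default) or `"1/x2"`.
#' @param min_levels minimum number of distinct non-zero levels (default 6).
#' @return object of class `"calibration_fit"`: list with `slope`,
#'   `intercept`, `r_squared`, `calibrators` (nominal, ratio, back-calculated
#'   concentration, percent deviation), `assay`, `lm`.
#' @examples
#' fit <- fit_calibration(c(0.5, 0.75, 1.5, 5, 10, 20),
#'                        8.5133 * c(0.5, 0.75, 1.5, 5, 10, 20) + 1.7962)
#' coef(fit)
#' @export
fit_calibration <- function(nominal, ratio, assay = NA,
                            weighting = c("none", "1/x2"),
                            min_levels = 6L) {
  weighting <- match.arg(weighting)
  stopifnot(length(nominal) == length(ratio))
  if (length(unique(nominal[nominal > 0])) < min_levels)
    stop("need >= ", min_levels, " distinct non-zero calibrator levels")
  if (stats::var(nominal) == 0) stop("zero-variance concentrations")
  w <- if (weighting == "1/x2") 1 / nominal^2 else NULL
  fit <- stats::lm(ratio ~ nominal, weights = w)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  back <- (ratio - intercept) / slope
  structure(list(
    slope = slope, intercept = intercept,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    calibrators = data.frame(nominal = nominal, ratio = ratio,
                             back_calc = back,
                             deviation_pct = 100 * (back - nominal) / nominal),
    assay = assay, weighting = weighting, lm = fit),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, digits = 6, ...) {
  cat(sprintf("<calibration_fit> y = %.*g x + %.*g   r^2 = %.5f\n",
              digits, x$slope, digits, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_fit <- function(object, nominal, ...) {
  object$slope * nominal + object$intercept
}

#' Calibration-curve acceptance gate
#'
#' Passes iff at least 75% of the calibrators back-calculate within +/-15%
#' of nominal and the LLOQ calibrator is within +/-20%.
#'
#' @param fit a [fit_calibration()] object.
#' @param lloq_level the LLOQ calibrator's nominal concentration (default:
#'   lowest level in the fit).
#' @param tol_pct,tol_lloq_pct the +/-15% and +/-20% windows.
#' @return list with `pass`, `frac_within`, `lloq_within`, per-calibrator
#'   flags.
#' @export
calibration_acceptance <- function(fit, lloq_level = NULL, tol_pct = 15,
                                   tol_lloq_pct = 20) {
  stopifnot(inherits(fit, "calibration_fit"))
  cal <- fit$calibrators
  if (is.null(lloq_level)) lloq_level <- min(cal$nominal)
  is_lloq <- cal$nominal == lloq_level
  tol <- ifelse(is_lloq, tol_lloq_pct, tol_pct)
  within <- abs(cal$deviation_pct) <= tol
  frac <- mean(within)
  lloq_ok <- all(within[is_lloq])
  list(pass = frac >= 0.75 && lloq_ok, frac_within = frac,
       lloq_within = lloq_ok,
       calibrators = cbind(cal, within = within))
}

#' Detection and quantification limits from replicate calibrations
#'
#' `LOD = 3.3 sigma / S` and `LOQ = 10 sigma / S`, where `sigma` is the
#' standard deviation of the y-intercepts and `S` the mean slope across
#' independent assay calibrations (at least three; the assay used nine).
#' LOQ/LOD = 10/3.3 by construction.  Values are reported to two decimals;
#' full precision is retained in the returned object.
#'
#' @param fits list of [fit_calibration()] objects from independent assays.
#' @return list of class `"calibration_summary"` with `mean_slope`,
#'   `sd_intercept`, `lod`, `loq`, `n_assays`.
#' @export
lod_loq <- function(fits) {
  if (length(fits) < 3L) stop("need >= 3 independent calibration fits")
  stopifnot(all(vapply(fits, inherits, logical(1), "calibration_fit")))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  intercepts <- vapply(fits, `[[`, numeric(1), "intercept")
  s <- mean(slopes)
  sigma <- stats::sd(intercepts)
  structure(list(mean_slope = s, sd_intercept = sigma,
                 lod = 3.3 * sigma / s, loq = 10 * sigma / s,
                 n_assays = length(fits)),
            class = "calibration_summary")
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat(sprintf(
    "<calibration_summary> n = %d assays  S = %.4f  sigma = %.4f\n",
    x$n_assays, x$mean_slope, x$sd_intercept))
  cat(sprintf("  LOD = %.2f ug/mL   LOQ = %.2f ug/mL\n", x$lod, x$loq))
  invisible(x)
}

#' Intra- and inter-day precision and accuracy of QC batches
#'
#' For each QC level: intra-day CV% is `100 * sd / mean` within a day,
#' pooled across days by averaging the day CVs; inter-day CV% is computed on
#' the day means (ICH convention; a pooled-over-all-replicates CV is also
#' emitted); accuracy% is `100 * grand mean / nominal`.  Gates are +/-15%
#' (+/-20% when the level is the LLOQ).
#'
#' @param qc data.frame with columns `level` (label), `nominal` (ug/mL),
#'   `day`, `measured` (back-calculated concentration, ug/mL).
#' @param lloq_level nominal concentration treated as LLOQ for the +/-20%
#'   gate (default 0.5).
#' @return data.frame, one row per level: `level`, `nominal`, `n`,
#'   `grand_mean`, `sd`, `cv_intra_pct`, `cv_inter_pct`, `cv_pooled_pct`,
#'   `accuracy_pct`, `gate_tol_pct`, `pass`.
#' @export
precision_accuracy <- function(qc, lloq_level = 0.5) {
  stopifnot(is.data.frame(qc),
            all(c("level", "nominal", "day", "measured") %in% names(qc)))
  out <- lapply(split(qc, qc$level), function(d) {
    counts <- table(d$day)
    thin <- names(counts)[counts < 2]
    if (length(thin)) {
      warning("level ", d$level[1L], ": day(s) ",
              paste(thin, collapse = ", "),
              " have a single replicate and are excluded")
      d <- d[!(d$day %in% thin), , drop = FALSE]
    }
    if (!nrow(d)) return(NULL)
    day_stats <- do.call(rbind, lapply(split(d$measured, d$day), function(m)
      data.frame(mean = mean(m), cv = 100 * stats::sd(m) / mean(m))))
    grand <- mean(d$measured)
    nominal <- d$nominal[1L]
    acc <- 100 * grand / nominal
    tol <- if (isTRUE(all.equal(nominal, lloq_level))) 20 else 15
    cv_inter <- if (nrow(day_stats) > 1)
      100 * stats::sd(day_stats$mean) / mean(day_stats$mean) else NA_real_
    data.frame(level = d$level[1L], nominal = nominal, n = nrow(d),
               grand_mean = grand, sd = stats::sd(d$measured),
               cv_intra_pct = mean(day_stats$cv),
               cv_inter_pct = cv_inter,
               cv_pooled_pct = 100 * stats::sd(d$measured) / grand,
               accuracy_pct = acc, gate_tol_pct = tol,
               pass = abs(acc - 100) <= tol &
                 mean(day_stats$cv) <= tol &
                 (is.na(cv_inter) || cv_inter <= tol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extraction recovery
#'
#' `100 * mean(pre-extraction-spiked ratio) / mean(post-extraction-spiked
#' ratio)` at a matched QC level, with the CV% of the per-replicate
#' pre/post ratios.
#'
#' @param pre_ratios analyte/IS area ratios of samples spiked before
#'   extraction (>= 3 replicates).
#' @param post_ratios matched ratios of post-extraction spikes.
#' @return list with `recovery_pct`, `cv_pct`, `n`.
#' @export
recovery <- function(pre_ratios, post_ratios) {
  if (length(pre_ratios) < 3L || length(post_ratios) < 3L)
    stop("need >= 3 replicates on each side")
  if (mean(post_ratios) <= 0) stop("zero post-extraction ratio")
  rec <- 100 * mean(pre_ratios) / mean(post_ratios)
  percs <- 100 * pre_ratios / mean(post_ratios)
  list(recovery_pct = rec, cv_pct = 100 * stats::sd(percs) / mean(percs),
       n = length(pre_ratios))
}

#' Matrix effect
#'
#' `MF = mean matrix-spiked area / mean solvent-spiked area` per channel;
#' the IS-normalized MF is `MF_analyte / MF_IS`.  Gate: IS-normalized MF in
#' `[0.8, 1.2]` and CV% <= 15.  Values below 1 indicate ion suppression.
#'
#' @param matrix_analyte,solvent_analyte analyte peak areas in matrix- and
#'   solvent-based spikes (>= 3 replicates each).
#' @param matrix_is,solvent_is matching internal-standard areas.
#' @return list with `mf_analyte`, `mf_is`, `is_normalized_mf`, `cv_pct`,
#'   `suppression` (logical), `pass`.
#' @export
matrix_effect <- function(matrix_analyte, solvent_analyte,
                          matrix_is, solvent_is) {
  for (v in list(matrix_analyte, solvent_analyte, matrix_is, solvent_is))
    if (length(v) < 3L) stop("need >= 3 replicates on each side")
  if (mean(solvent_analyte) <= 0 || mean(solvent_is) <= 0)
    stop("zero solvent-spiked area")
  mf_a <- mean(matrix_analyte) / mean(solvent_analyte)
  mf_i <- mean(matrix_is) / mean(solvent_is)
  nmf <- mf_a / mf_i
  # per-replicate normalized MF spread (matrix replicates against the mean
  # solvent response)
  per_rep <- (matrix_analyte / mean(solvent_analyte)) /
    (matrix_is / mean(solvent_is))
  cv <- 100 * stats::sd(per_rep) / mean(per_rep)
  list(mf_analyte = mf_a, mf_is = mf_i, is_normalized_mf = nmf,
       cv_pct = cv, suppression = nmf < 1,
       pass = nmf >= 0.8 && nmf <= 1.2 && cv <= 15)
}

#' Quantify an unknown from its area ratio
#'
#' Inverts the calibration line, `C = (ratio - intercept) / slope`, and flags
#' results below the LOQ (`BLQ`) or above the highest calibrator (`ALQ`).
#' Flagged values are carried but conventionally excluded from group means.
#'
#' @param ratio analyte/IS area ratio(s).
#' @param fit a [fit_calibration()] object.
#' @param range calibration range, ug/mL (default `c(0.5, 20)`).
#' @param loq quantification limit used for the BLQ flag (default the lower
#'   end of `range`).
#' @return data.frame with columns `ratio`, `conc` (ug/mL), `flag`
#'   (`""`, `"BLQ"` or `"ALQ"`).
#' @export
quantify <- function(ratio, fit, range = c(0.5, 20), loq = range[1L]) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope == 0) stop("zero calibration slope")
  conc <- (ratio - fit$intercept) / fit$slope
  flag <- ifelse(conc < loq, "BLQ", ifelse(conc > range[2L], "ALQ", ""))
  data.frame(ratio = ratio, conc = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Homogenate concentration to tissue burden
#'
#' Brains were homogenized at a fixed buffer volume per tissue mass
#' (1 mL per 100 mg, i.e. 0.01 mL/mg), so tissue burden (ug/mg) is
#' homogenate concentration (ug/mL) times that ratio.
#'
#' @param conc homogenate concentration, ug/mL.
#' @param buffer_volume_per_mass mL of buffer per mg of tissue
#'   (default 0.01).
#' @return tissue burden, ug per mg tissue.
#' @export
homogenate_to_tissue <- function(conc, buffer_volume_per_mass = 0.01) {
  if (buffer_volume_per_mass <= 0)
    stop("buffer_volume_per_mass must be positive")
  conc * buffer_volume_per_mass
}

#' @rdname homogenate_to_tissue
#' @param tissue tissue burden, ug/mg.
#' @export
tissue_to_homogenate <- function(tissue, buffer_volume_per_mass = 0.01) {
  if (buffer_volume_per_mass <= 0)
    stop("buffer_volume_per_mass must be positive")
  tissue / buffer_volume_per_mass
}
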