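#' Destructive-sampling concentration-time tables
#'
#' Each animal contributes a single observation (one time point); profiles
#' are composites across animals.
#'
#' @param records data.frame with columns `animal`, `time_h`, `conc`
#'   (ug/mg tissue) and optionally `group`.
#' @param dose administered dose, ug/kg.
#' @return data.frame of class `"conc_time_table"` with a `dose` attribute.
#' @export
conc_time_table <- function(records, dose) {
  stopifnot(is.data.frame(records),
            all(c("animal", "time_h", "conc") %in% names(records)))
  if (any(records$time_h < 0)) stop("times must be non-negative")
  if (anyDuplicated(records$animal))
    stop("destructive design: each animal appears exactly once")
  structure(records, dose = dose,
            class = c("conc_time_table", "data.frame"))
}

#' Naive pooled mean concentration-time profile
#'
#' Per-time mean, SD and n across animals (the composite-profile summary of
#' destructive sampling).  By default below-limit handling keeps zeros at
#' t = 0 (pre-dose) and keeps all observed values elsewhere.
#'
#' @param table a [conc_time_table()].
#' @param blq optional quantification limit; values below it are set to 0 at
#'   t = 0 and excluded elsewhere.
#' @return data.frame with columns `time_h`, `mean`, `sd`, `n`.
#' @export
mean_profile <- function(table, blq = NULL) {
  stopifnot(inherits(table, "conc_time_table"))
  d <- as.data.frame(table)
  if (!is.null(blq)) {
    pre <- d$time_h == 0
    d$conc[pre & d$conc < blq] <- 0
    d <- d[pre | d$conc >= blq, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(d, d$time_h), function(x)
    data.frame(time_h = x$time_h[1L], mean = mean(x$conc),
               sd = stats::sd(x$conc), n = nrow(x))))
  out <- out[order(out$time_h), , drop = FALSE]
  empty <- out$n == 0
  if (any(empty)) {
    warning("dropping time(s) with no observations: ",
            paste(out$time_h[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Cmax and Tmax of a mean profile
#'
#' Maximum of the mean profile and its time; ties resolve to the earliest
#' time.
#'
#' @param profile data.frame with columns `time_h`, `mean` (from
#'   [mean_profile()]).
#' @return named numeric `c(cmax, tmax)`.
#' @export
cmax_tmax <- function(profile) {
  if (!any(profile$mean > 0)) stop("all-zero profile")
  i <- which.max(profile$mean)   # earliest index on ties
  c(cmax = profile$mean[i], tmax = profile$time_h[i])
}

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear ordinary least squares on the terminal mean concentrations.
#' The default policy evaluates every suffix of the last k >= 3 positive
#' post-Tmax points (excluding the Tmax point itself) and keeps the fit with
#' the best adjusted R-squared; `lambda_z` is the negated slope.  If fewer
#' than 3 post-Tmax points exist (a late composite peak on a sparse grid),
#' the Cmax point is admitted and the fit flagged `includes_cmax`.
#'
#' @param profile data.frame with `time_h`, `mean`.
#' @param policy `"best_adj_r2"` (default) or `"last3"`.
#' @return list with `lambda_z` (1/h), `t_half` (h), `r2_adj`, `points`
#'   (times used), `intercept` (log-scale).
#' @export
fit_lambda_z <- function(profile, policy = c("best_adj_r2", "last3")) {
  policy <- match.arg(policy)
  tm <- cmax_tmax(profile)
  cand <- profile[profile$time_h > tm["tmax"] & profile$mean > 0, ,
                  drop = FALSE]
  used_cmax <- FALSE
  if (nrow(cand) < 3L) {
    # sparse grids can peak late in the composite profile; fall back to the
    # last three positive points so a terminal fit remains possible
    pos <- profile[profile$mean > 0, , drop = FALSE]
    if (nrow(pos) >= 3L) cand <- pos[(nrow(pos) - 2L):nrow(pos), ]
    used_cmax <- TRUE
  }
  if (nrow(cand) < 3L)
    stop("insufficient terminal data: need >= 3 positive post-Tmax points")
  ks <- if (policy == "last3") 3L else 3:nrow(cand)
  best <- NULL
  for (k in ks) {
    d <- cand[(nrow(cand) - k + 1L):nrow(cand), ]
    fit <- stats::lm(log(mean) ~ time_h, data = d)
    r2a <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || r2a > best$r2_adj + 1e-12)
      best <- list(lambda_z = -unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   r2_adj = r2a, points = d$time_h,
                   includes_cmax = used_cmax && tm["tmax"] %in% d$time_h)
  }
  if (best$lambda_z <= 0)
    stop("non-positive terminal slope: no log-linear decline")
  best$t_half <- log(2) / best$lambda_z
  best
}

#' Area under the concentration-time curve
#'
#' Trapezoidal quadrature of the mean profile from zero to the last sampled
#' time.  `"linear"` (default) uses linear trapezoids throughout;
#' `"lin_up_log_down"` uses the log-trapezoid on strictly declining positive
#' intervals.
#'
#' @param profile data.frame with `time_h`, `mean`, sorted by time.
#' @param method `"linear"` or `"lin_up_log_down"`.
#' @return AUC(0-t), ug*h/mg.
#' @export
auc <- function(profile, method = c("linear", "lin_up_log_down")) {
  method <- match.arg(method)
  t <- profile$time_h; c1 <- profile$mean
  if (length(t) < 2L) stop("need >= 2 points")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be sorted increasing")
  segs <- vapply(seq_len(length(t) - 1L), function(i) {
    dt <- t[i + 1L] - t[i]
    a <- c1[i]; b <- c1[i + 1L]
    if (method == "lin_up_log_down" && a > b && b > 0)
      dt * (a - b) / log(a / b)
    else dt * (a + b) / 2
  }, numeric(1))
  sum(segs)
}

#' @rdname auc
#' @details `aumc()` integrates `t * C(t)` by the same trapezoidal rule
#'   (linear only); `MRT(0-t) = AUMC(0-t) / AUC(0-t)`.
#' @export
aumc <- function(profile) {
  moment <- profile
  moment$mean <- moment$time_h * moment$mean
  auc(moment, method = "linear")
}

#' Extrapolate the AUC to infinity
#'
#' `AUC(0-inf) = AUC(0-t) + C_last / lambda_z`; the observed fraction is
#' `AUC(0-t) / AUC(0-inf)`.  A fraction below 0.8 indicates heavy
#' extrapolation and raises a warning.
#'
#' @param auc_0_t AUC from zero to the last sampled time.
#' @param c_last last observed (positive) mean concentration.
#' @param lambda_z terminal rate constant, 1/h.
#' @return list with `auc_0_inf`, `frac_auc`.
#' @export
extrapolate_auc <- function(auc_0_t, c_last, lambda_z) {
  if (lambda_z <= 0) stop("lambda_z must be positive")
  if (c_last < 0) stop("c_last must be non-negative")
  auc_inf <- auc_0_t + c_last / lambda_z
  frac <- auc_0_t / auc_inf
  if (frac < 0.8)
    warning(sprintf(
      "high extrapolation: only %.0f%% of AUC(0-inf) is observed", 100 * frac))
  list(auc_0_inf = auc_inf, frac_auc = frac)
}

#' Apparent clearance and volume of distribution
#'
#' `Cl/F = dose / AUC(0-inf)` and `Vz/F = Cl/F / lambda_z`.  With dose in
#' ug/kg and AUC in ug*h/mg the quotient lands directly on the conventional
#' reporting scale: (ug/kg) / (ug*h/mg) = mg kg^-1 h^-1 (the 10^3 ug->mg
#' factor of the numerator cancels against the mg^-1 of the AUC), so Cl/F is
#' in (mg/kg)/h and Vz/F in mg/kg.
#'
#' @param dose dose in ug/kg.
#' @param auc_0_inf AUC(0-inf), ug*h/mg.
#' @param lambda_z terminal rate constant, 1/h.
#' @return named numeric `c(cl_f, vz_f)`: (mg/kg)/h and mg/kg.
#' @export
clearance_volume <- function(dose, auc_0_inf, lambda_z) {
  if (auc_0_inf <= 0) stop("AUC(0-inf) must be positive")
  cl <- dose / auc_0_inf
  c(cl_f = cl, vz_f = cl / lambda_z)
}

#' Non-compartmental analysis of a destructive-sampling dataset
#'
#' Composes the naive pooled mean profile, Cmax/Tmax, terminal log-linear
#' `lambda_z` (best adjusted-R-squared suffix), linear-trapezoid AUC and
#' AUMC, extrapolation to infinity, MRT, and apparent clearance/volume, with
#' provenance (points used, method flags) embedded in the result.
#'
#' @param table a [conc_time_table()].
#' @param dose dose in ug/kg (default the table's `dose` attribute).
#' @param auc_method passed to [auc()].
#' @param lambda_policy passed to [fit_lambda_z()].
#' @param blq passed to [mean_profile()].
#' @return object of class `"nca_result"`: list with `profile` and
#'   `parameters` (tmax, cmax, lambda_z, t_half, auc_0_t, auc_0_inf,
#'   frac_auc, aumc_0_t, mrt_0_t, vz_f, cl_f, lambda_z_points,
#'   lambda_z_r2_adj).
#' @export
nca <- function(table, dose = attr(table, "dose"),
                auc_method = "linear", lambda_policy = "best_adj_r2",
                blq = NULL) {
  profile <- mean_profile(table, blq = blq)
  ct <- cmax_tmax(profile)
  lz <- fit_lambda_z(profile, policy = lambda_policy)
  auc_t <- auc(profile, method = auc_method)
  aumc_t <- aumc(profile)
  ext <- extrapolate_auc(auc_t, profile$mean[nrow(profile)], lz$lambda_z)
  cv <- clearance_volume(dose, ext$auc_0_inf, lz$lambda_z)
  structure(list(
    profile = profile,
    dose_ug_kg = dose,
    auc_method = auc_method,
    parameters = list(
      tmax = unname(ct["tmax"]), cmax = unname(ct["cmax"]),
      lambda_z = lz$lambda_z, t_half = lz$t_half,
      auc_0_t = auc_t, auc_0_inf = ext$auc_0_inf, frac_auc = ext$frac_auc,
      aumc_0_t = aumc_t, mrt_0_t = aumc_t / auc_t,
      vz_f = unname(cv["vz_f"]), cl_f = unname(cv["cl_f"]),
      lambda_z_points = lz$points, lambda_z_r2_adj = lz$r2_adj)),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  p <- x$parameters
  cat("<nca_result> non-compartmental parameters (naive pooled profile)\n")
  cat(sprintf("  Tmax %.2f h   Cmax %.2f ug/mg   T1/2 %.2f h (lambda_z %.4f /h)\n",
              p$tmax, p$cmax, p$t_half, p$lambda_z))
  cat(sprintf("  AUC(0-t) %.2f   AUC(0-inf) %.2f ug*h/mg   observed fraction %.2f\n",
              p$auc_0_t, p$auc_0_inf, p$frac_auc))
  cat(sprintf("  MRT(0-t) %.2f h   Cl/F %.2f (mg/kg)/h   Vz/F %.2f mg/kg\n",
              p$mrt_0_t, p$cl_f, p$vz_f))
  cat("  lambda_z points:", paste(p$lambda_z_points, collapse = ", "),
      sprintf(" (adj r^2 %.4f)\n", p$lambda_z_r2_adj))
  invisible(x)
}

#' @export
coef.nca_result <- function(object, ...) {
  p <- object$parameters
  unlist(p[c("tmax", "cmax", "lambda_z", "t_half", "auc_0_t", "auc_0_inf",
             "frac_auc", "aumc_0_t", "mrt_0_t", "vz_f", "cl_f")])
}
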