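# Run code under a seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# mean-1 multiplicative lognormal noise at a given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulation configuration
#'
#' Ground-truth parameters for every synthetic dataset the pipeline consumes.
#' The defaults emulate the assay's printed summaries: calibration line
#' 8.5133 x + 1.7962 (area ratio per ug/mL), extraction recovery ~0.68,
#' analyte-channel matrix factor 0.88 (internal standard unsuppressed, so the
#' IS-normalized matrix factor is ~0.88), intra-day CV 4%, inter-day day
#' effect 6%, internal standard at 0.5 ug/mL, destructive sampling at
#' 0, 2, 4, 6, 8, 24 h with 5 animals per time, and a one-compartment
#' first-order-absorption brain profile (ka = 0.8 /h, lambda_z = 0.0405 /h,
#' so the sampling-grid Tmax is 4 h and the terminal half-life ~17.1 h;
#' scale 95 ug/mg gives a mean Cmax near 77).
#'
#' @param seed default seed carried with the config (used when a generator is
#'   called without its own seed).
#' @param slope_true,intercept_true calibration response line (area ratio per
#'   ug/mL; area ratio).
#' @param recovery_true extraction recovery fraction applied to pre-extraction
#'   matrix spikes, in (0, 1.5].
#' @param matrix_factor_true analyte-channel matrix factor for matrix-based
#'   samples, in (0, 1.5].
#' @param matrix_factor_is internal-standard-channel matrix factor.
#' @param cv_intra within-day proportional CV of the area ratio.
#' @param cv_inter_day CV of the shared per-day lognormal factor.
#' @param rt_cv proportional CV of retention times.
#' @param is_conc internal standard concentration, ug/mL.
#' @param is_area nominal internal-standard quantifier area, counts.
#' @param baseline_area_sd scale of the half-normal baseline area assigned to
#'   blank channels, counts.
#' @param pk_ka absorption rate constant, 1/h (> pk_lambda_z).
#' @param pk_lambda_z terminal elimination rate constant, 1/h.
#' @param pk_scale profile scale, ug/mg tissue.
#' @param pk_bsv_cv between-animal lognormal CV of the profile scale.
#' @param sampling_times destructive sampling times, h, strictly increasing
#'   from 0.
#' @param n_per_time animals per sampling time.
#' @param behavior_group_params per-group behavioral truth: columns `group`,
#'   `dr_mean` (novel-object discrimination ratio), `dr_phi` (beta precision),
#'   `explore_total_s` (mean total test-phase exploration), `explore_cv`,
#'   `n_bouts_mean`, `alternation` (Y-maze alternation propensity in [0, 1]),
#'   `entries_mean` (mean arm entries).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       slope_true = 8.5133,
                       intercept_true = 1.7962,
                       recovery_true = 0.68,
                       matrix_factor_true = 0.88,
                       matrix_factor_is = 1.0,
                       cv_intra = 0.04,
                       cv_inter_day = 0.06,
                       rt_cv = 0.002,
                       is_conc = 0.5,
                       is_area = 1e5,
                       baseline_area_sd = 300,
                       pk_ka = 0.8,
                       pk_lambda_z = 0.0405,
                       pk_scale = 95,
                       pk_bsv_cv = 0.15,
                       sampling_times = c(0, 2, 4, 6, 8, 24),
                       n_per_time = 5L,
                       behavior_group_params = NULL) {
  if (is.null(behavior_group_params))
    behavior_group_params <- data.frame(
      group = c("control", "LPS", "LPS_LCA", "LCA"),
      dr_mean = c(0.68, 0.52, 0.66, 0.68),
      dr_phi = 30,
      explore_total_s = 40,
      explore_cv = 0.3,
      n_bouts_mean = 10,
      alternation = c(0.70, 0.52, 0.67, 0.70),
      entries_mean = c(22, 18, 21, 22),
      stringsAsFactors = FALSE)
  if (cv_intra < 0 || cv_inter_day < 0 || pk_bsv_cv < 0)
    stop("coefficients of variation must be non-negative")
  if (!(pk_ka > pk_lambda_z && pk_lambda_z > 0))
    stop("need pk_ka > pk_lambda_z > 0")
  if (sampling_times[1] != 0 || any(diff(sampling_times) <= 0))
    stop("sampling_times must be strictly increasing and start at 0")
  if (recovery_true <= 0 || recovery_true > 1.5 ||
      matrix_factor_true <= 0 || matrix_factor_true > 1.5)
    stop("recovery_true and matrix_factor_true must lie in (0, 1.5]")
  structure(as.list(environment()), class = "sim_config")
}

# Default transition layout emitted with every injection: quantifier first,
# expected qualifier abundances as % of the quantifier (Table-2-style ratios).
.SIM_TRANSITIONS <- data.frame(
  channel = c("analyte", "analyte", "analyte", "is", "is", "is"),
  transition = c("451>347", "451>435", "451>421",
                 "569>554", "569>437", "569>343"),
  transition_role = c("quantifier", "qualifier", "qualifier",
                      "quantifier", "qualifier", "qualifier"),
  ra = c(100, 73, 44, 100, 89, 53),
  rt_true = c(11.22, 11.22, 11.22, 10.04, 10.04, 10.04),
  stringsAsFactors = FALSE
)

.SIM_ROLES <- c("blank", "zero", "calibrator", "qc", "pre_spike",
                "post_spike", "solvent_spike", "unknown")

#' Generate a synthetic injection table
#'
#' Simulates one GC-MS/MS injection per design row, emitting per-transition
#' retention times and integrated areas for the analyte and internal standard
#' channels.  The analyte/IS area ratio of a sample at concentration C has
#' expectation `slope_true * C + intercept_true`, multiplied by
#' `recovery_true` for pre-extraction matrix spikes (calibrators, QCs,
#' pre-spikes, unknowns) and by the IS-normalized matrix factor for
#' matrix-based samples, with mean-one lognormal noise `cv_intra` on the
#' ratio and a shared per-day lognormal factor `cv_inter_day`.  Blank
#' channels carry half-normal baseline areas only.
#'
#' @param design data.frame with columns `role` (one of blank, zero,
#'   calibrator, qc, pre_spike, post_spike, solvent_spike, unknown),
#'   `nominal` (ug/mL; 0 for
#'   blank/zero) and optionally `sample_id`, `day` (default 1).
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data.frame of class `"injection_table"`: one row per
#'   (injection, transition) with columns `sample_id`, `role`, `nominal`,
#'   `day`, `channel`, `transition`, `transition_role`, `rt_min`, `area`.
#' @export
generate_injection_table <- function(design, config = sim_config(),
                                     seed = config$seed) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L,
            "role" %in% names(design))
  if (!all(design$role %in% .SIM_ROLES))
    stop("invalid role(s): ",
         paste(setdiff(design$role, .SIM_ROLES), collapse = ", "))
  if (is.null(design$nominal)) design$nominal <- 0
  if (any(design$nominal < 0)) stop("negative nominal concentration")
  if (is.null(design$day)) design$day <- 1L
  if (is.null(design$sample_id))
    design$sample_id <- sprintf("S%03d", seq_len(nrow(design)))
  local_seed(seed, {
    days <- sort(unique(design$day))
    day_f <- stats::setNames(rlnorm_cv(length(days), config$cv_inter_day),
                             days)
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      tr <- .SIM_TRANSITIONS
      is_matrix <- d$role %in% c("blank", "zero", "calibrator", "qc",
                                 "pre_spike", "post_spike", "unknown")
      pre_extraction <- d$role %in% c("calibrator", "qc", "pre_spike",
                                      "unknown")
      has_is <- d$role != "blank"
      has_analyte <- !(d$role %in% c("blank", "zero"))
      out <- data.frame(sample_id = d$sample_id, role = d$role,
                        nominal = d$nominal, day = d$day, tr[, 1:3],
                        rt_min = NA_real_, area = NA_real_,
                        stringsAsFactors = FALSE)
      extras <- setdiff(names(design),
                        c("sample_id", "role", "nominal", "day"))
      for (e in extras) out[[e]] <- d[[e]]
      # internal standard channel
      is_q <- tr$channel == "is" & tr$transition_role == "quantifier"
      is_area <- if (has_is) {
        config$is_area * (if (is_matrix) config$matrix_factor_is else 1) *
          rlnorm_cv(1, config$cv_intra)
      } else abs(stats::rnorm(1, 0, config$baseline_area_sd))
      out$area[is_q] <- is_area
      # analyte quantifier via the ratio response model
      an_q <- tr$channel == "analyte" & tr$transition_role == "quantifier"
      if (has_analyte) {
        ratio <- (config$slope_true * d$nominal + config$intercept_true) *
          (if (pre_extraction) config$recovery_true else 1) *
          (if (is_matrix)
             config$matrix_factor_true / config$matrix_factor_is else 1) *
          day_f[as.character(d$day)] * rlnorm_cv(1, config$cv_intra)
        out$area[an_q] <- ratio * is_area
      } else {
        out$area[an_q] <- abs(stats::rnorm(1, 0, config$baseline_area_sd))
      }
      # qualifiers follow their channel quantifier at the expected relative
      # abundance, with independent proportional noise
      for (ch in c("analyte", "is")) {
        quant <- out$area[tr$channel == ch & tr$transition_role == "quantifier"]
        qual <- tr$channel == ch & tr$transition_role == "qualifier"
        present <- if (ch == "is") has_is else has_analyte
        out$area[qual] <- if (present) {
          quant * (tr$ra[qual] / 100) * rlnorm_cv(sum(qual), config$cv_intra)
        } else abs(stats::rnorm(sum(qual), 0, config$baseline_area_sd))
      }
      # retention times exist only where a real peak exists
      peak <- (tr$channel == "analyte" & has_analyte) |
        (tr$channel == "is" & has_is)
      out$rt_min[peak] <- tr$rt_true[peak] *
        (1 + stats::rnorm(sum(peak), 0, config$rt_cv))
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("injection_table", "data.frame")
    out
  })
}

#' Area ratios from an injection table
#'
#' Collapses an injection table to one row per injection with the
#' analyte-to-internal-standard quantifier area ratio used for calibration
#' and quantification.
#'
#' @param table an injection table (see [generate_injection_table()]).
#' @return data.frame with columns `sample_id`, `role`, `nominal`, `day`,
#'   `analyte_area`, `is_area`, `ratio`.
#' @export
area_ratios <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "channel", "transition_role", "area") %in%
                  names(table)))
  q <- table[table$transition_role == "quantifier", ]
  an <- q[q$channel == "analyte", ]
  is <- q[q$channel == "is", ]
  m <- match(an$sample_id, is$sample_id)
  drop <- c("channel", "transition", "transition_role", "rt_min", "area")
  out <- an[, setdiff(names(an), drop), drop = FALSE]
  out$analyte_area <- an$area
  out$is_area <- is$area[m]
  out$ratio <- out$analyte_area / out$is_area
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Synthesize a chromatogram trace
#'
#' Renders peaks as Gaussians on a flat baseline with white noise, on a
#' uniform time grid with at least 10 samples per peak width.
#'
#' @param peaks data.frame with columns `rt_min`, `height` (counts),
#'   `width_s` (Gaussian sigma, seconds) and optionally `transition`.
#' @param noise_sd white-noise standard deviation, counts.
#' @param gradient_length trace length, min.
#' @param seed integer seed (or `NULL` for the current RNG stream).
#' @param baseline flat baseline level, counts.
#' @param dt_s sampling interval, seconds (default `min(width_s)/10`,
#'   or 0.5 s for an empty peak list).
#' @return a single [chromatogram()] if the peaks share one transition (or
#'   none is given), otherwise a named list of chromatograms per transition.
#' @export
generate_chromatogram <- function(peaks, noise_sd = 0, gradient_length = 15.6,
                                  seed = NULL, baseline = 0, dt_s = NULL) {
  if (is.null(peaks) || nrow(peaks) == 0L)
    peaks <- data.frame(rt_min = numeric(), height = numeric(),
                        width_s = numeric())
  stopifnot(all(c("rt_min", "height", "width_s") %in% names(peaks)) ||
              nrow(peaks) == 0L)
  if (nrow(peaks)) {
    if (any(peaks$height <= 0) || any(peaks$width_s <= 0))
      stop("peak heights and widths must be positive")
    if (any(peaks$rt_min < 0 | peaks$rt_min > gradient_length))
      stop("peak retention times must lie within [0, gradient_length]")
  }
  if (is.null(peaks$transition))
    peaks$transition <- rep("T1", nrow(peaks))
  if (is.null(dt_s))
    dt_s <- if (nrow(peaks)) min(peaks$width_s) / 10 else 0.5
  local_seed(seed, {
    t_min <- seq(0, gradient_length, by = dt_s / 60)
    traces <- lapply(split(peaks, peaks$transition), function(pk) {
      y <- rep(baseline, length(t_min))
      for (j in seq_len(nrow(pk)))
        y <- y + pk$height[j] *
          exp(-(t_min - pk$rt_min[j])^2 / (2 * (pk$width_s[j] / 60)^2))
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      chromatogram(t_min, y, transition = pk$transition[1L])
    })
    if (!nrow(peaks)) {
      y <- rep(baseline, length(t_min))
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      return(chromatogram(t_min, y, transition = "T1"))
    }
    if (length(traces) == 1L) traces[[1L]] else traces
  })
}

#' Generate a destructive-sampling brain concentration-time dataset
#'
#' One-compartment first-order-absorption profile after intraperitoneal
#' dosing: animal i sampled (destructively) at its single time t contributes
#' `C = scale_i * (exp(-lambda_z t) - exp(-ka t))`, with `scale_i` lognormal
#' around `pk_scale` at between-animal CV `pk_bsv_cv`.
#'
#' @param config a [sim_config()].
#' @param dose administered dose, ug/kg (default 20 mg/kg = 20000 ug/kg).
#' @param seed integer seed (defaults to `config$seed`).
#' @param group group label attached to every record.
#' @return a [conc_time_table()] with the generating truth stored in
#'   `attr(, "truth")`.
#' @export
generate_pk_dataset <- function(config = sim_config(), dose = 20000,
                                seed = config$seed, group = "LPS_LCA") {
  if (config$n_per_time < 1L) stop("n_per_time must be >= 1")
  if (config$pk_ka <= config$pk_lambda_z)
    stop("ka <= lambda_z rejected (flip-flop ambiguity not modeled)")
  local_seed(seed, {
    times <- rep(config$sampling_times, each = config$n_per_time)
    n <- length(times)
    scale_i <- config$pk_scale * rlnorm_cv(n, config$pk_bsv_cv)
    conc <- scale_i * (exp(-config$pk_lambda_z * times) -
                         exp(-config$pk_ka * times))
    tab <- conc_time_table(
      data.frame(animal = sprintf("M%03d", seq_len(n)), time_h = times,
                 conc = conc, group = group, stringsAsFactors = FALSE),
      dose = dose)
    attr(tab, "truth") <- list(ka = config$pk_ka,
                               lambda_z = config$pk_lambda_z,
                               scale = config$pk_scale,
                               bsv_cv = config$pk_bsv_cv)
    tab
  })
}

#' Generate synthetic behavioral sessions
#'
#' Novel-object-recognition sessions draw each animal's true discrimination
#' ratio from a beta distribution with the group's mean and precision, split
#' total test-phase exploration accordingly, and partition each object's
#' seconds into exponential-like bouts.  Y-maze sessions draw arm-entry
#' sequences from a first-order process in which each entry after the second
#' completes an alternation (visits the arm absent from the last two entries)
#' with the group's alternation propensity, so the expected spontaneous
#' alternation percentage is `100 * alternation`.
#'
#' @param config a [sim_config()] (uses `behavior_group_params`).
#' @param n_per_group animals per group (0 yields an empty list).
#' @param seed integer seed (defaults to `config$seed`).
#' @param type `"nor"`, `"ymaze"`, or `"both"`.
#' @return list of session objects (class `"nor_session"` /
#'   `"arm_entry_sequence"`), with the group-level truth in
#'   `attr(, "truth")`.
#' @export
generate_behavior_dataset <- function(config = sim_config(), n_per_group = 10L,
                                      seed = config$seed,
                                      type = c("both", "nor", "ymaze")) {
  type <- match.arg(type)
  if (n_per_group < 0L) stop("n_per_group must be >= 0")
  pars <- config$behavior_group_params
  if (n_per_group == 0L) {
    out <- list()
    attr(out, "truth") <- pars
    return(out)
  }
  local_seed(seed, {
    sessions <- list()
    for (g in seq_len(nrow(pars))) {
      p <- pars[g, ]
      for (i in seq_len(n_per_group)) {
        id <- sprintf("%s_%02d", p$group, i)
        if (type %in% c("both", "nor")) {
          dr_i <- if (p$dr_phi > 0)
            stats::rbeta(1, p$dr_mean * p$dr_phi, (1 - p$dr_mean) * p$dr_phi)
          else p$dr_mean
          total <- p$explore_total_s * rlnorm_cv(1, p$explore_cv)
          bouts <- lapply(c(novel = dr_i, familiar = 1 - dr_i),
                          function(frac) {
            nb <- max(1L, stats::rpois(1, p$n_bouts_mean))
            w <- stats::rexp(nb)
            frac * total * w / sum(w)
          })
          sessions[[length(sessions) + 1L]] <- nor_session(
            animal = id, group = p$group,
            bouts = data.frame(
              object = rep(c("novel", "familiar"),
                           c(length(bouts$novel), length(bouts$familiar))),
              duration_s = c(bouts$novel, bouts$familiar),
              stringsAsFactors = FALSE))
        }
        if (type %in% c("both", "ymaze")) {
          n_e <- max(3L, stats::rpois(1, p$entries_mean))
          arms <- c("A", "B", "C")
          seqs <- character(n_e)
          seqs[1] <- sample(arms, 1)
          seqs[2] <- sample(setdiff(arms, seqs[1]), 1)
          for (k in 3:n_e) {
            new_arm <- setdiff(arms, c(seqs[k - 1], seqs[k - 2]))
            seqs[k] <- if (stats::runif(1) < p$alternation) new_arm
                       else seqs[k - 2]
          }
          sessions[[length(sessions) + 1L]] <- arm_entry_sequence(
            animal = id, group = p$group, entries = seqs)
        }
      }
    }
    attr(sessions, "truth") <- pars
    sessions
  })
}
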