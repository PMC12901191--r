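#' Chromatogram traces
#'
#' A uniformly sampled intensity trace for one MRM transition.
#'
#' @param time_min sampling times, min, strictly increasing and uniformly
#'   spaced.
#' @param intensity intensities, counts, finite.
#' @param transition transition label.
#' @return data.frame of class `"chromatogram"` with columns `time_min`,
#'   `intensity` and a `transition` attribute.
#' @export
chromatogram <- function(time_min, intensity, transition = "T1") {
  stopifnot(length(time_min) == length(intensity), length(time_min) >= 2L)
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  dt <- diff(time_min)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * max(dt))
    stop("times must be uniformly spaced")
  structure(data.frame(time_min = time_min, intensity = intensity),
            transition = transition,
            class = c("chromatogram", "data.frame"))
}

#' Read chromatogram traces from CSV
#'
#' Expects columns `transition`, `time_min`, `intensity`.
#'
#' @param path CSV file path.
#' @return named list of [chromatogram()] objects, one per transition.
#' @export
read_chromatogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transition", "time_min", "intensity")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  lapply(split(d, d$transition), function(x)
    chromatogram(x$time_min, x$intensity, transition = x$transition[1L]))
}

# Robust baseline level and noise scale for a trace that may contain peaks:
# median as the level, scaled MAD as the dispersion.
baseline_stats <- function(y) {
  list(level = stats::median(y),
       noise_sd = stats::mad(y, constant = 1.4826))
}

#' Detect candidate peak apexes
#'
#' Finds local maxima exceeding `baseline + threshold_sigma * noise_sd`
#' (robust median/MAD estimates over the whole trace), requiring a run of at
#' least `min_points` consecutive supra-threshold samples so that isolated
#' noise excursions are not called peaks.  Apex retention time is refined by
#' parabolic interpolation of the top three samples; a tie between
#' equal-height adjacent samples resolves to the earlier time.
#'
#' @param chrom a [chromatogram()] with at least 20 samples.
#' @param threshold_sigma detection threshold in noise SD units (default 3).
#' @param min_points minimum consecutive supra-threshold samples (default 3).
#' @return data.frame with one row per apex: `rt_min`, `apex_intensity`,
#'   `index`.  A flat or featureless trace yields zero rows.
#' @export
detect_peaks <- function(chrom, threshold_sigma = 3, min_points = 3L) {
  stopifnot(inherits(chrom, "chromatogram"))
  y <- chrom$intensity
  t <- chrom$time_min
  if (length(y) < 20L) stop("need >= 20 samples")
  bs <- baseline_stats(y)
  thr <- bs$level + threshold_sigma * bs$noise_sd
  above <- y > thr
  if (bs$noise_sd == 0) above <- y > bs$level   # noiseless traces
  out <- data.frame(rt_min = numeric(), apex_intensity = numeric(),
                    index = integer())
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_points)) {
    i0 <- starts[k]; i1 <- ends[k]
    for (j in run_apexes(y, i0, i1, 3 * bs$noise_sd)) {
      rt <- t[j]
      if (j > 1L && j < length(y)) {
        y1 <- y[j - 1L]; y2 <- y[j]; y3 <- y[j + 1L]
        denom <- y1 - 2 * y2 + y3
        if (denom < 0) {
          delta <- 0.5 * (y1 - y3) / denom
          rt <- t[j] + delta * (t[2] - t[1])
        }
      }
      out <- rbind(out, data.frame(rt_min = rt, apex_intensity = y[j],
                                   index = j))
    }
  }
  out[order(out$rt_min), , drop = FALSE]
}

# Apexes within one supra-threshold run [i0, i1]: strict local maxima, kept
# only if the valley separating them from a taller accepted maximum drops by
# more than `min_prominence` below the smaller of the two (so noise wiggle on
# a single peak's crest is merged, resolved shoulders are split).
run_apexes <- function(y, i0, i1, min_prominence) {
  idx <- i0:i1
  seg <- y[idx]
  n <- length(seg)
  if (n < 3L) return(idx[which.max(seg)])
  is_max <- c(FALSE, seg[2:(n - 1)] > seg[1:(n - 2)] &
                seg[2:(n - 1)] >= seg[3:n], FALSE)
  cand <- which(is_max)
  if (!length(cand)) return(idx[which.max(seg)])
  cand <- cand[order(-seg[cand], cand)]
  kept <- cand[1L]
  for (c in cand[-1L]) {
    sep <- vapply(kept, function(k) {
      valley <- min(seg[min(c, k):max(c, k)])
      valley < min(seg[c], seg[k]) - min_prominence
    }, logical(1))
    if (all(sep)) kept <- c(kept, c)
  }
  sort(idx[kept])
}

#' Integrate a detected peak
#'
#' Trapezoidal area above a straight baseline drawn between the window
#' endpoints; height is the apex intensity minus the baseline at the apex.
#' Areas are reported in counts * seconds.
#'
#' @param chrom a [chromatogram()].
#' @param apex apex retention time, min (e.g. from [detect_peaks()]).
#' @param window integration window `c(start, end)` in min, within the trace
#'   span and at least 3 samples wide.
#' @return list of class `"peak_measurement"` with elements `transition`,
#'   `rt_min`, `area` (counts*s), `height`, `baseline_level`.
#' @export
integrate_peak <- function(chrom, apex, window) {
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2L)
  t <- chrom$time_min
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9 ||
      window[1] >= window[2])
    stop("integration window outside the trace span")
  sel <- which(t >= window[1] - 1e-12 & t <= window[2] + 1e-12)
  if (length(sel) < 3L) stop("window narrower than 3 samples")
  ts <- t[sel]; ys <- chrom$intensity[sel]
  n <- length(ts)
  base <- ys[1] + (ys[n] - ys[1]) * (ts - ts[1]) / (ts[n] - ts[1])
  resid <- ys - base
  area_min <- sum((resid[-1] + resid[-n]) / 2 * diff(ts))
  base_at_apex <- ys[1] + (ys[n] - ys[1]) * (apex - ts[1]) / (ts[n] - ts[1])
  apex_y <- chrom$intensity[which.min(abs(t - apex))]
  structure(list(transition = attr(chrom, "transition"),
                 rt_min = apex,
                 area = area_min * 60,
                 height = apex_y - base_at_apex,
                 baseline_level = base_at_apex),
            class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  cat(sprintf(
    "<peak_measurement> %s  RT %.3f min  area %.4g counts*s  height %.4g\n",
    x$transition, x$rt_min, x$area, x$height))
  invisible(x)
}

#' Signal-to-noise ratio of a peak
#'
#' Baseline-corrected peak height divided by the standard deviation of the
#' detrended (linear-fit-removed) intensities in a flanking noise window that
#' contains no peak.  A zero-variance noise window yields `Inf` with a
#' warning, mirroring the 3:1 (detection) / 10:1 (quantification) reporting
#' convention.
#'
#' @param peak a `"peak_measurement"` from [integrate_peak()], or a numeric
#'   height.
#' @param chrom the [chromatogram()] supplying the noise window (not needed
#'   if `noise_sd` is given).
#' @param noise_window `c(start, end)` min of a peak-free region.
#' @param noise_sd directly supplied noise SD (overrides the window).
#' @return the dimensionless signal-to-noise ratio.
#' @export
signal_to_noise <- function(peak, chrom = NULL, noise_window = NULL,
                            noise_sd = NULL) {
  height <- if (inherits(peak, "peak_measurement")) peak$height else peak
  if (is.null(noise_sd)) {
    stopifnot(inherits(chrom, "chromatogram"), length(noise_window) == 2L)
    sel <- chrom$time_min >= noise_window[1] & chrom$time_min <= noise_window[2]
    if (sum(sel) < 4L) stop("noise window too narrow")
    ts <- chrom$time_min[sel]; ys <- chrom$intensity[sel]
    noise_sd <- stats::sd(stats::resid(stats::lm(ys ~ ts)))
  }
  if (noise_sd == 0) {
    warning("zero-variance noise window: S/N is infinite")
    return(Inf)
  }
  height / noise_sd
}
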