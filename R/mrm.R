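#' MRM transitions
#'
#' A multiple-reaction-monitoring transition: precursor and product m/z,
#' collision energy, role (one quantifier per analyte, the rest qualifiers)
#' and the expected relative abundance of a qualifier as a percentage of the
#' quantifier.
#'
#' @param analyte analyte label.
#' @param precursor precursor ion m/z.
#' @param product product ion m/z (< precursor).
#' @param ce collision energy, V (the optimizer scans 3-42 V in 3 V steps).
#' @param role `"quantifier"` or `"qualifier"`.
#' @param relative_abundance expected abundance as % of the quantifier
#'   (100 for the quantifier itself).
#' @param dwell dwell time, ms.
#' @return one-row data.frame of class `"mrm_transition"`.
#' @export
mrm_transition <- function(analyte, precursor, product, ce,
                           role = c("quantifier", "qualifier"),
                           relative_abundance = 100, dwell = NA_real_) {
  role <- match.arg(role)
  if (product >= precursor)
    stop("product m/z must be below the precursor m/z")
  if (ce < 0) stop("collision energy must be non-negative")
  if (ce < 3 || ce > 42)
    # the product-ion scan covers 3-42 V; vendor optimizers may refine the
    # final CE slightly off-grid, so this is advisory
    warning("collision energy ", ce, " V outside the scanned 3-42 V grid")
  structure(data.frame(analyte = analyte, precursor = precursor,
                       product = product, ce = ce, role = role,
                       relative_abundance = relative_abundance,
                       dwell = dwell, stringsAsFactors = FALSE),
            class = c("mrm_transition", "data.frame"))
}

#' Select quantifier and qualifier transitions from product-ion scans
#'
#' Given a product-ion scan table for one precursor (product m/z, collision
#' energy, abundance; the best collision energy per product is used), picks
#' the most abundant product as the quantifier and the next two most abundant
#' as qualifiers, with expected relative abundances reported as
#' `100/x` (x = 100 * qualifier / quantifier, rounded).  Abundance ties are
#' broken toward the lower product m/z.
#'
#' @param scans data.frame with columns `product`, `ce`, `abundance` for a
#'   single precursor.
#' @param analyte analyte label carried into the output.
#' @param precursor precursor m/z carried into the output.
#' @return data.frame of three transitions (quantifier first) with columns of
#'   [mrm_transition()] plus `ra_string` (e.g. `"100/73"`).
#' @examples
#' scans <- data.frame(product = c(347, 435, 421, 300), ce = 33,
#'                     abundance = c(1000, 730, 440, 90))
#' select_transitions(scans, "2-TMS LCA", 451)
#' @export
select_transitions <- function(scans, analyte = "analyte", precursor = NA) {
  stopifnot(is.data.frame(scans),
            all(c("product", "ce", "abundance") %in% names(scans)))
  # best CE per product ion
  best <- do.call(rbind, lapply(split(scans, scans$product), function(d) {
    d[order(-d$abundance, d$ce), ][1L, ]
  }))
  if (nrow(best) < 3L)
    stop("need >= 3 distinct product ions for the precursor (got ",
         nrow(best), ")")
  best <- best[order(-best$abundance, best$product), ]
  top <- best[1:3, ]
  role <- c("quantifier", "qualifier", "qualifier")
  ra <- 100 * top$abundance / top$abundance[1L]
  out <- do.call(rbind, lapply(1:3, function(i)
    mrm_transition(analyte, precursor, top$product[i], top$ce[i], role[i],
                   relative_abundance = ra[i])))
  out$ra_string <- c("100/100", sprintf("100/%d", round(ra[2:3])))
  class(out) <- c("mrm_transition", "data.frame")
  out
}

#' Time-segmented MRM acquisition schedules
#'
#' Partitions the run into half-open time segments `[start, end)` at the given
#' boundaries and assigns each analyte's transitions to the segment containing
#' its retention time (a boundary retention time belongs to the later
#' segment).  Segments containing no analyte retention time are assigned the
#' transitions of the non-internal-standard analytes, so the quantified
#' analyte is monitored throughout the run outside the internal standard's
#' window.
#'
#' @param analytes data.frame with columns `analyte`, `rt` (min) and
#'   optionally `is_internal_standard` (logical, default `FALSE`).
#' @param transitions data.frame of transitions with an `analyte` column
#'   (e.g. rbind of [select_transitions()] outputs).
#' @param runtime total runtime, min.
#' @param solvent_delay acquisition start, min (default 0).
#' @param boundaries interior segment boundaries, min (may be empty).
#' @return data.frame of class `"mrm_schedule"`: one row per
#'   (segment, transition) with columns `start`, `end` and the transition
#'   columns.
#' @examples
#' an <- data.frame(analyte = c("2-TMS LCA", "3-TMS IC"),
#'                  rt = c(11.22, 10.04),
#'                  is_internal_standard = c(FALSE, TRUE))
#' tr <- data.frame(analyte = rep(c("2-TMS LCA", "3-TMS IC"), each = 3),
#'                  precursor = rep(c(451, 569), each = 3),
#'                  product = c(347, 435, 421, 554, 437, 343))
#' build_schedule(an, tr, runtime = 15.6, solvent_delay = 4,
#'                boundaries = c(9.5, 11))
#' @export
build_schedule <- function(analytes, transitions, runtime,
                           solvent_delay = 0, boundaries = numeric()) {
  stopifnot(is.data.frame(analytes),
            all(c("analyte", "rt") %in% names(analytes)))
  if (is.null(analytes$is_internal_standard))
    analytes$is_internal_standard <- FALSE
  if (any(analytes$rt < solvent_delay | analytes$rt > runtime))
    stop("analyte retention time outside [solvent_delay, runtime]")
  cuts <- sort(unique(c(solvent_delay, boundaries, runtime)))
  if (length(cuts) < 2L) stop("runtime must exceed the solvent delay")
  segs <- data.frame(start = cuts[-length(cuts)], end = cuts[-1L])
  # half-open [start, end); the final segment closes at the runtime
  in_seg <- function(rt, i)
    rt >= segs$start[i] & (rt < segs$end[i] | i == nrow(segs))
  rows <- lapply(seq_len(nrow(segs)), function(i) {
    here <- analytes$analyte[in_seg(analytes$rt, i)]
    if (!length(here))
      here <- analytes$analyte[!analytes$is_internal_standard]
    tr <- transitions[transitions$analyte %in% here, , drop = FALSE]
    if (!nrow(tr)) return(NULL)
    cbind(start = segs$start[i], end = segs$end[i], tr)
  })
  out <- do.call(rbind, rows)
  # every transition must be active in a segment containing its analyte's RT
  for (k in seq_len(nrow(analytes))) {
    a <- analytes$analyte[k]
    ok <- any(out$analyte == a & out$start <= analytes$rt[k] &
                (analytes$rt[k] < out$end |
                   abs(out$end - runtime) < 1e-12))
    if (!ok) stop("analyte ", a, " has no segment containing its RT")
  }
  rownames(out) <- NULL
  class(out) <- c("mrm_schedule", "data.frame")
  out
}
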