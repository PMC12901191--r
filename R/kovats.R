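#' n-Alkane retention ladders
#'
#' A ladder of reference n-alkane retention times for Kovats retention-index
#' normalization: carbon numbers and retention times both strictly increasing.
#'
#' @param carbon integer carbon numbers, strictly increasing.
#' @param rt retention times (min), strictly increasing.
#' @return data.frame of class `"alkane_ladder"` with columns `carbon`, `rt`.
#' @examples
#' alkane_ladder(c(20, 21), c(9.909, 12.567))
#' @export
alkane_ladder <- function(carbon, rt) {
  stopifnot(length(carbon) == length(rt), length(carbon) >= 2L)
  if (any(carbon != round(carbon)) || any(diff(carbon) <= 0))
    stop("carbon numbers must be strictly increasing integers")
  if (any(rt <= 0) || any(diff(rt) <= 0))
    stop("retention times must be positive and strictly increasing")
  structure(data.frame(carbon = as.integer(carbon), rt = rt),
            class = c("alkane_ladder", "data.frame"))
}

#' Kovats retention index
#'
#' Normalizes a retention time to a bracketing pair of n-alkanes:
#' `I = 100 * (n + (log10 t_x - log10 t_n) / (log10 t_{n+1} - log10 t_n))`,
#' where `t_n`, `t_{n+1}` are the retention times of the tailing and heading
#' alkanes with `n` and `n+1` carbons.  The base-10 logarithmic form is applied
#' to the raw retention times exactly as conventionally printed; a
#' linear-interpolation variant (for temperature-programmed runs) is available
#' via `log = FALSE`.
#'
#' @param t_x analyte retention time (min); must satisfy
#'   `t_n <= t_x < t_{n+1}` for a consecutive ladder pair (the upper ladder
#'   endpoint itself is also accepted).
#' @param ladder an [alkane_ladder()].
#' @param log use base-10 logs of retention times (default) or raw times.
#' @return the dimensionless retention index (100 units per carbon).
#' @examples
#' lad <- alkane_ladder(c(20, 21), c(9.909, 12.567))
#' kovats_index(11.22, lad)
#' @export
kovats_index <- function(t_x, ladder, log = TRUE) {
  stopifnot(inherits(ladder, "alkane_ladder"), length(t_x) == 1L,
            is.finite(t_x))
  rt <- ladder$rt
  i <- findInterval(t_x, rt)
  if (i == length(rt) && abs(t_x - rt[length(rt)]) <= 1e-12)
    return(100 * ladder$carbon[length(rt)])
  if (i < 1L || i >= length(rt))
    stop("unbracketed retention time: ", t_x, " min outside ladder span [",
         rt[1], ", ", rt[length(rt)], "]")
  if (ladder$carbon[i + 1L] != ladder$carbon[i] + 1L)
    stop("ladder gap: bracketing alkanes are not consecutive carbon numbers")
  f <- if (log) log10 else identity
  100 * (ladder$carbon[i] +
           (f(t_x) - f(rt[i])) / (f(rt[i + 1L]) - f(rt[i])))
}

#' Solve a bracketing alkane pair from two (retention time, index) pairs
#'
#' Inverts the Kovats formula: given two analytes with known retention times
#' and known indices, both bracketed by the same consecutive alkane pair
#' C_n / C_{n+1}, solves the two-equation linear system (in log10 retention
#' time) for the alkane retention times.  Useful for reconstructing an unstated
#' reference ladder from a printed retention-index table.
#'
#' @param n carbon number of the tailing alkane.
#' @param t_x retention times (min) of the two analytes, length 2.
#' @param index their Kovats indices, length 2, both in `(100 n, 100 (n+1))`.
#' @return an [alkane_ladder()] with the two solved alkane retention times.
#' @examples
#' lad <- ladder_from_index_pairs(20, c(11.22, 10.04), c(2052.37, 2005.54))
#' kovats_index(11.22, lad)   # round-trips to 2052.37
#' @export
ladder_from_index_pairs <- function(n, t_x, index) {
  stopifnot(length(t_x) == 2L, length(index) == 2L)
  if (any(index <= 100 * n) || any(index >= 100 * (n + 1)))
    stop("indices must lie strictly inside (100 n, 100 (n + 1))")
  # I = 100 (n + (log tx - a)/d) with a = log10 t_n, d = log10 t_{n+1} - a:
  # log tx = a + f d, f = I/100 - n.  Two analytes give a linear system.
  f <- index / 100 - n
  if (abs(diff(f)) < 1e-12) stop("degenerate pair: equal indices")
  lt <- log10(t_x)
  d <- diff(lt) / diff(f)
  a <- lt[1] - f[1] * d
  alkane_ladder(c(n, n + 1L), 10^c(a, a + d))
}
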