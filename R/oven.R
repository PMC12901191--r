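#' GC oven temperature programs
#'
#' An oven program is an initial temperature held for `initial_hold` minutes
#' followed by ordered ramp segments, each a linear ramp at `rate` degC/min to
#' `target` degC with an optional `hold` (min) at the target.
#'
#' @param initial_temp starting oven temperature, degC.
#' @param initial_hold initial hold, min (>= 0).
#' @param segments data.frame with columns `rate` (degC/min, > 0), `target`
#'   (degC, non-decreasing across segments) and `hold` (min, >= 0).  May have
#'   zero rows.
#' @return an object of class `"oven_program"`.
#' @examples
#' # the assay's final program: 200 degC (1 min), 30 degC/min to 280,
#' # 2 degC/min to 300, hold 2 min
#' p <- oven_program(200, 1, data.frame(rate = c(30, 2),
#'                                      target = c(280, 300),
#'                                      hold = c(0, 2)))
#' program_duration(p)   # 15.6667 min
#' @export
oven_program <- function(initial_temp, initial_hold, segments = NULL) {
  if (is.null(segments))
    segments <- data.frame(rate = numeric(), target = numeric(),
                           hold = numeric())
  stopifnot(is.data.frame(segments),
            all(c("rate", "target", "hold") %in% names(segments)))
  if (initial_hold < 0 || any(segments$hold < 0))
    stop("holds must be non-negative")
  if (any(segments$rate <= 0))
    stop("ramp rates must be positive")
  temps <- c(initial_temp, segments$target)
  if (any(diff(temps) < 0))
    stop("cooling ramps unsupported: targets must be non-decreasing")
  structure(list(initial_temp = initial_temp, initial_hold = initial_hold,
                 segments = segments),
            class = "oven_program")
}

#' @export
print.oven_program <- function(x, ...) {
  cat(sprintf("<oven_program> %g degC hold %g min", x$initial_temp,
              x$initial_hold))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("; %g degC/min -> %g degC hold %g min",
                x$segments$rate[i], x$segments$target[i], x$segments$hold[i]))
  cat(sprintf("  (total %.4g min)\n", program_duration(x)))
  invisible(x)
}

#' Total runtime of an oven program
#'
#' `initial_hold + sum((target - previous) / rate + hold)` over the ramp
#' segments, in minutes.
#'
#' @param program an [oven_program()].
#' @return runtime in minutes.
#' @export
program_duration <- function(program) {
  stopifnot(inherits(program, "oven_program"))
  seg <- program$segments
  prev <- c(program$initial_temp, seg$target)[seq_len(nrow(seg))]
  program$initial_hold + sum((seg$target - prev) / seg$rate + seg$hold)
}

#' Oven temperature at a time point
#'
#' Evaluates the piecewise-linear temperature trajectory of an oven program.
#'
#' @param program an [oven_program()].
#' @param t time, minutes, within `[0, program_duration(program)]`.
#' @return temperature in degC.
#' @export
temperature_at <- function(program, t) {
  stopifnot(inherits(program, "oven_program"), length(t) == 1L, is.finite(t))
  total <- program_duration(program)
  if (t < 0 || t > total + 1e-9)
    stop("t outside the program's runtime [0, ", format(total), "]")
  clock <- program$initial_hold
  temp <- program$initial_temp
  if (t <= clock) return(temp)
  seg <- program$segments
  for (i in seq_len(nrow(seg))) {
    ramp <- (seg$target[i] - temp) / seg$rate[i]
    if (t <= clock + ramp) return(temp + (t - clock) * seg$rate[i])
    clock <- clock + ramp
    temp <- seg$target[i]
    if (t <= clock + seg$hold[i]) return(temp)
    clock <- clock + seg$hold[i]
  }
  temp
}
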