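# Nominal mass = integer mass of the most abundant isotope; monoisotopic from
# IUPAC values.  Embedded as constants: a unit-resolution quadrupole reads
# nominal masses, accurate-mass bookkeeping uses the monoisotopic column.
.ATOMIC_MASSES <- data.frame(
  element      = c("C", "H", "N", "O", "Si", "S", "F", "P"),
  nominal      = c(12L, 1L, 14L, 16L, 28L, 32L, 19L, 31L),
  monoisotopic = c(12.0, 1.0078250319, 14.0030740052, 15.9949146221,
                   27.9769265327, 31.97207069, 18.9984031627, 30.97376199),
  stringsAsFactors = FALSE
)

#' Elemental formulas
#'
#' An `elemental_formula` is a named integer vector of element counts
#' (e.g. `c(C = 21, H = 22, O = 4)`).  `parse_formula()` accepts the usual
#' Hill-style string ("C21H22O4"); `formula_string()` renders one back.
#'
#' @param x a formula string such as `"C27H38O4Si2"`, or a named numeric
#'   vector of non-negative integer counts.
#' @return `elemental_formula()` / `parse_formula()`: a named integer vector
#'   of class `"elemental_formula"`.
#' @examples
#' parse_formula("C21H22O4")
#' elemental_formula(c(C = 10, H = 13, O = 2, Si = 1))
#' @export
elemental_formula <- function(x) {
  if (is.character(x)) return(parse_formula(x))
  if (length(x) == 0L)
    return(structure(stats::setNames(integer(0), character(0)),
                     class = "elemental_formula"))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("element counts must be named by element symbol")
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("element counts must be non-negative integers")
  unknown <- setdiff(names(x), .ATOMIC_MASSES$element)
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  counts <- as.integer(round(x))
  names(counts) <- names(x)
  counts <- counts[counts > 0L]
  structure(counts, class = "elemental_formula")
}

#' @rdname elemental_formula
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  body <- gsub("\\s", "", x)
  if (!nzchar(body)) return(elemental_formula(numeric(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", body)[[1]]
  toks <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body))[[1]]
  if (!length(toks) || sum(attr(m, "match.length")) != nchar(body))
    stop("cannot parse formula string: ", x)
  el <- sub("[0-9]*$", "", toks)
  n  <- sub("^[A-Za-z]+", "", toks)
  n  <- ifelse(n == "", 1L, as.integer(n))
  counts <- tapply(n, el, sum)
  elemental_formula(stats::setNames(as.numeric(counts), names(counts)))
}

as_formula_counts <- function(f) {
  if (inherits(f, "elemental_formula")) return(unclass(f))
  unclass(elemental_formula(f))
}

#' @rdname elemental_formula
#' @param f an `elemental_formula` (or anything `elemental_formula()` accepts).
#' @export
formula_string <- function(f) {
  f <- as_formula_counts(f)
  if (!length(f)) return("")
  ord <- c(intersect(c("C", "H"), names(f)),
           sort(setdiff(names(f), c("C", "H"))))
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", formula_string(x),
      "  (nominal ", nominal_mass(x),
      ", monoisotopic ", sprintf("%.4f", monoisotopic_mass(x)), " Da)\n",
      sep = "")
  invisible(x)
}

#' Nominal and monoisotopic molecular masses
#'
#' `nominal_mass()` sums integer masses of the most abundant isotopes, the
#' scale a unit-resolution quadrupole reports; `monoisotopic_mass()` sums
#' IUPAC monoisotopic masses (full precision internally, conventionally
#' displayed to two decimals).
#'
#' @param f an `elemental_formula` or formula string.
#' @return `nominal_mass()`: integer Da; `monoisotopic_mass()`: double Da.
#' @examples
#' nominal_mass("C27H38O4Si2")        # 482
#' monoisotopic_mass("C21H22O4")      # 338.1518
#' @export
nominal_mass <- function(f) {
  f <- as_formula_counts(f)
  if (!length(f)) return(0L)
  i <- match(names(f), .ATOMIC_MASSES$element)
  as.integer(sum(f * .ATOMIC_MASSES$nominal[i]))
}

#' @rdname nominal_mass
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula_counts(f)
  if (!length(f)) return(0)
  i <- match(names(f), .ATOMIC_MASSES$element)
  sum(f * .ATOMIC_MASSES$monoisotopic[i])
}

formula_add <- function(a, b) {
  a <- as_formula_counts(a); b <- as_formula_counts(b)
  el <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(el)), el)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  elemental_formula(out)
}

formula_subtract <- function(a, b) {
  a <- as_formula_counts(a); b <- as_formula_counts(b)
  missing <- setdiff(names(b), names(a))
  if (length(missing) || any(b > a[names(b)]))
    stop("subtrahend is not a sub-formula of the composition")
  out <- a
  out[names(b)] <- out[names(b)] - b
  elemental_formula(out)
}

#' Trimethylsilyl (TMS) derivatization arithmetic
#'
#' Silylation with BSTFA replaces each active (hydroxyl) hydrogen with a
#' trimethylsilyl group Si(CH3)3: per substitution the composition changes by
#' -H +Si(CH3)3, i.e. a net gain of C3H8Si (+72 Da nominal).
#'
#' @param parent parent `elemental_formula` (or string).
#' @param n_tms number of TMS substitutions (non-negative integer).
#' @return the derivative's `elemental_formula`.
#' @examples
#' tms_derivatize("C21H22O4", 2)   # 2-TMS licochalcone A -> C27H38O4Si2
#' tms_derivatize("C21H20O6", 3)   # 3-TMS icaritin -> C30H44O6Si3
#' @export
tms_derivatize <- function(parent, n_tms) {
  parent <- elemental_formula(parent)
  if (!is.finite(n_tms) || n_tms < 0 || n_tms != round(n_tms))
    stop("n_tms must be a non-negative integer")
  n_tms <- as.integer(n_tms)
  if (n_tms == 0L) return(parent)
  h <- as_formula_counts(parent)["H"]
  if (is.na(h) || h < n_tms)
    stop("parent has fewer hydrogens than TMS substitutions requested")
  net <- elemental_formula(c(C = 3 * n_tms, H = 8 * n_tms, Si = n_tms))
  formula_add(parent, net)
}

# Named neutral losses at unit resolution.
.NEUTRAL_LOSSES <- list(
  Me  = c(C = 1, H = 3),           # methyl radical, 15 Da
  OMe = c(C = 1, H = 3, O = 1)     # methoxy radical, 31 Da
)

#' Annotate electron-impact fragments of a derivative
#'
#' Computes unit-resolution fragment m/z values as the nominal mass of the
#' derivative minus a named neutral loss (`"Me"` = CH3, `"OMe"` = OCH3, or any
#' formula string), plus directly computed named fragment ions such as the
#' chalcone acylium ion.
#'
#' @param derivative the derivatized molecule's formula.
#' @param losses character vector of neutral-loss names or formula strings.
#' @param named_fragments named list/character vector of fragment-ion formulas
#'   whose m/z is computed directly.
#' @return data.frame with columns `label` and `mz` (integer m/z).
#' @examples
#' annotate_fragments("C27H38O4Si2", losses = c("Me", "OMe"),
#'                    named_fragments = c(acylium = "C10H13O2Si"))
#' @export
annotate_fragments <- function(derivative, losses = character(),
                               named_fragments = list()) {
  derivative <- elemental_formula(derivative)
  m0 <- nominal_mass(derivative)
  out <- data.frame(label = character(), mz = integer(),
                    stringsAsFactors = FALSE)
  for (loss in losses) {
    lf <- if (loss %in% names(.NEUTRAL_LOSSES))
      elemental_formula(.NEUTRAL_LOSSES[[loss]]) else elemental_formula(loss)
    formula_subtract(derivative, lf)   # errors if loss exceeds composition
    out <- rbind(out, data.frame(
      label = sprintf("[M-%s]+", loss),
      mz = m0 - nominal_mass(lf), stringsAsFactors = FALSE))
  }
  if (length(named_fragments)) {
    labs <- names(named_fragments)
    if (is.null(labs)) labs <- vapply(named_fragments, formula_string, "")
    for (i in seq_along(named_fragments)) {
      out <- rbind(out, data.frame(
        label = labs[i],
        mz = nominal_mass(elemental_formula(named_fragments[[i]])),
        stringsAsFactors = FALSE))
    }
  }
  out
}
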