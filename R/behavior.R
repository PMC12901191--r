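#' Novel-object-recognition sessions
#'
#' Pre-scored object-exploration bouts for one animal's test session: each
#' bout is a (object, duration) pair, with objects labelled `"novel"` or
#' `"familiar"`.  (Scoring semantics upstream: an interaction is the head
#' within 2 cm of, and directed at, the object; sitting or leaning on the
#' object does not count.)
#'
#' @param animal animal id.
#' @param group group label.
#' @param bouts data.frame with columns `object` (`"novel"`/`"familiar"`)
#'   and `duration_s` (> 0).
#' @param phase `"test"` (default) or `"training"`.
#' @return list of class `"nor_session"`.
#' @export
nor_session <- function(animal, group, bouts, phase = "test") {
  stopifnot(is.data.frame(bouts),
            all(c("object", "duration_s") %in% names(bouts)))
  if (any(bouts$duration_s <= 0)) stop("bout durations must be positive")
  if (!all(bouts$object %in% c("novel", "familiar")))
    stop("objects must be labelled 'novel' or 'familiar'")
  structure(list(animal = animal, group = group, phase = phase,
                 bouts = bouts),
            class = "nor_session")
}

#' Y-maze arm-entry sequences
#'
#' An ordered sequence of arm entries over `{A, B, C}`.  Re-entering the arm
#' the animal is already in is not an entry: consecutive duplicates are
#' collapsed with a warning by default, or rejected under `strict = TRUE`.
#' (An entry requires all four paws and the tail inside the arm.)
#'
#' @param animal animal id.
#' @param group group label.
#' @param entries character vector of arm symbols in `{A, B, C}`.
#' @param strict reject (rather than collapse) consecutive duplicates.
#' @return list of class `"arm_entry_sequence"`.
#' @export
arm_entry_sequence <- function(animal, group, entries, strict = FALSE) {
  entries <- as.character(entries)
  if (!all(entries %in% c("A", "B", "C")))
    stop("arm symbols must be A, B or C")
  dup <- which(entries[-1] == entries[-length(entries)])
  if (length(dup)) {
    if (strict) stop("consecutive duplicate arm entries")
    warning("collapsing ", length(dup), " consecutive duplicate arm entries")
    entries <- entries[c(TRUE, entries[-1] != entries[-length(entries)])]
  }
  structure(list(animal = animal, group = group, entries = entries),
            class = "arm_entry_sequence")
}

#' Novel-object discrimination ratio
#'
#' Novel-object exploration seconds over total exploration seconds,
#' `DR = novel / (novel + familiar)`, in `[0, 1]`.
#'
#' @param session a [nor_session()], or novel seconds when `familiar` is
#'   given.
#' @param familiar familiar-object seconds (when calling with raw seconds).
#' @return the discrimination ratio.
#' @examples
#' discrimination_ratio(30, 20)   # 0.6
#' @export
discrimination_ratio <- function(session, familiar = NULL) {
  if (inherits(session, "nor_session")) {
    b <- session$bouts
    novel <- sum(b$duration_s[b$object == "novel"])
    familiar <- sum(b$duration_s[b$object == "familiar"])
  } else novel <- session
  total <- novel + familiar
  if (total <= 0) stop("zero total exploration: session should be excluded")
  novel / total
}

#' Y-maze spontaneous alternation percentage
#'
#' The number of length-3 windows of consecutive entries visiting three
#' distinct arms, over `(number of entries - 2)`, times 100.
#'
#' @param seq an [arm_entry_sequence()] or a character vector of arm symbols.
#' @return alternation percentage in `[0, 100]`.
#' @examples
#' spontaneous_alternation(c("A", "B", "C", "A", "B", "C"))  # 100
#' spontaneous_alternation(c("A", "B", "A", "B", "A", "B"))  # 0
#' @export
spontaneous_alternation <- function(seq) {
  entries <- if (inherits(seq, "arm_entry_sequence")) seq$entries
             else as.character(seq)
  n <- length(entries)
  if (n < 3L) stop("undefined for fewer than 3 entries: session excluded")
  wins <- vapply(seq_len(n - 2L), function(i)
    length(unique(entries[i:(i + 2L)])) == 3L, logical(1))
  100 * sum(wins) / (n - 2L)
}

#' Apply behavioral exclusion rules
#'
#' Novel-object sessions with total exploration below `min_exploration_s`
#' (default 7 s) and Y-maze sequences with fewer than `min_entries`
#' (default 8) arm entries are excluded, with per-animal reason codes.
#'
#' @param sessions list of [nor_session()] / [arm_entry_sequence()] objects.
#' @param min_exploration_s NOR exclusion threshold, seconds.
#' @param min_entries Y-maze exclusion threshold, entries.
#' @return list with `kept` (sessions), `excluded` (data.frame `animal`,
#'   `group`, `reason`), `group_counts` (exclusions per group).
#' @export
apply_exclusions <- function(sessions, min_exploration_s = 7,
                             min_entries = 8L) {
  kept <- list(); exc <- NULL
  for (s in sessions) {
    reason <- NULL
    if (inherits(s, "nor_session")) {
      if (sum(s$bouts$duration_s) < min_exploration_s)
        reason <- sprintf("exploration < %g s", min_exploration_s)
    } else if (inherits(s, "arm_entry_sequence")) {
      if (length(s$entries) < min_entries)
        reason <- sprintf("fewer than %d arm entries", min_entries)
    } else stop("unknown session type")
    if (is.null(reason)) kept[[length(kept) + 1L]] <- s
    else exc <- rbind(exc, data.frame(animal = s$animal, group = s$group,
                                      reason = reason,
                                      stringsAsFactors = FALSE))
  }
  counts <- if (is.null(exc)) integer(0) else table(exc$group)
  list(kept = kept,
       excluded = if (is.null(exc))
         data.frame(animal = character(), group = character(),
                    reason = character(), stringsAsFactors = FALSE) else exc,
       group_counts = counts)
}

#' Group summaries of behavioral scores
#'
#' Mean, SD, SEM and n of the discrimination ratio (NOR sessions) and
#' spontaneous alternation percentage (Y-maze sequences) per group, after
#' exclusions.
#'
#' @param sessions list of behavior sessions.
#' @param ... passed to [apply_exclusions()].
#' @return data.frame with columns `group`, `measure`, `mean`, `sd`, `sem`,
#'   `n`.
#' @export
behavior_summary <- function(sessions, ...) {
  keep <- apply_exclusions(sessions, ...)$kept
  rows <- lapply(keep, function(s) {
    if (inherits(s, "nor_session"))
      data.frame(group = s$group, measure = "discrimination_ratio",
                 value = discrimination_ratio(s), stringsAsFactors = FALSE)
    else
      data.frame(group = s$group, measure = "spontaneous_alternation_pct",
                 value = spontaneous_alternation(s), stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(d, list(d$group, d$measure), drop = TRUE),
                               function(x)
    data.frame(group = x$group[1L], measure = x$measure[1L],
               mean = mean(x$value), sd = stats::sd(x$value),
               sem = stats::sd(x$value) / sqrt(nrow(x)), n = nrow(x),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
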