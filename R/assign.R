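## State assignment: turn a person-wave panel of offense/arrest flags into
## the five model states and wave-to-wave transition outcomes.

#' Assign model states to a person-wave panel
#'
#' Applies the state definitions to each person's ordered history of
#' offense and arrest flags.  Precedence per wave:
#' \enumerate{
#'   \item arrested this wave -> `A` (regardless of offending);
#'   \item never arrested, offended this wave -> `C1`;
#'   \item never arrested, not offended -> `X`;
#'   \item ever arrested, offended this wave -> `C2`;
#'   \item ever arrested, inactive, fewer than 3 consecutive inactive
#'     years -> `R`;
#'   \item ever arrested, 3+ consecutive inactive years -> `X`
#'     (rehabilitated).
#' }
#' "Inactive" means neither offended nor arrested in that year.  For early
#' waves where a full 3-year window is unavailable, available history is
#' used (an arrestee at wave 1 cannot reach rehabilitated `X` before wave
#' 4).  Person-waves with a missing flag are excluded (listwise, never
#' imputed) and counted in the diagnostics.
#'
#' @param panel data.frame with columns `person_id`, `wave`, `offended`,
#'   `arrested` (0/1); extra columns (age, sex, race) are carried through.
#' @return A data.frame with columns of `panel` plus `state`,
#'   `ever_arrested`, `inactive_streak`; attribute `diagnostics` holds the
#'   counts of excluded person-waves and of "inconsistent" self-reports
#'   (offending after 3+ inactive post-arrest years, which re-enter `C2`).
#' @export
assign_states <- function(panel) {
  need <- c("person_id", "wave", "offended", "arrested")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(panel[c("person_id", "wave")]))
    stop("duplicate (person_id, wave) rows in panel", call. = FALSE)

  ok <- !is.na(panel$offended) & !is.na(panel$arrested)
  n_excluded <- sum(!ok)
  if (n_excluded)
    message(n_excluded,
            " person-wave(s) with missing flags excluded from assignment")
  panel <- panel[ok, , drop = FALSE]
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]

  off <- as.integer(panel$offended)
  arr <- as.integer(panel$arrested)
  if (any(!off %in% 0:1) || any(!arr %in% 0:1))
    stop("offended/arrested flags must be 0/1", call. = FALSE)

  id <- panel$person_id
  new_person <- c(TRUE, id[-1] != id[-length(id)])

  n <- nrow(panel)
  ever <- logical(n)
  streak <- integer(n)
  state <- character(n)
  n_inconsistent <- 0L
  ever_prev <- FALSE; streak_prev <- 0L
  for (i in seq_len(n)) {
    if (new_person[i]) { ever_prev <- FALSE; streak_prev <- 0L }
    inactive <- off[i] == 0L && arr[i] == 0L
    streak_i <- if (inactive) streak_prev + 1L else 0L
    ever_i <- ever_prev || arr[i] == 1L
    state[i] <-
      if (arr[i] == 1L) "A"
      else if (!ever_prev && off[i] == 1L) "C1"
      else if (!ever_prev) "X"
      else if (off[i] == 1L) {
        if (streak_prev >= 3L) n_inconsistent <- n_inconsistent + 1L
        "C2"
      }
      else if (streak_i >= 3L) "X"
      else "R"
    ever[i] <- ever_i
    streak[i] <- streak_i
    ever_prev <- ever_i
    streak_prev <- streak_i
  }
  out <- panel
  out$state <- state
  out$ever_arrested <- as.integer(ever)
  out$inactive_streak <- streak
  attr(out, "diagnostics") <- list(n_excluded = n_excluded,
                                   n_inconsistent = n_inconsistent)
  out
}

#' Build wave-to-wave transition outcomes
#'
#' One record per person per consecutive wave pair.  Pairs separated by a
#' wave gap are skipped (listwise, mirroring complete-case construction),
#' and observed pairs that do not fall on an admissible arrow of the flow
#' structure (possible only under data errors, e.g. a rehabilitated person
#' re-offending, which would appear as X->C2) are rejected and counted.
#'
#' @param states a data.frame from [assign_states()] (or any data.frame
#'   with `person_id`, `wave`, `state`; demographic columns `age`, `sex`,
#'   `race` are carried from the origin wave when present).
#' @return A data.frame with columns `person_id`, `from_wave`,
#'   `from_state`, `to_state`, `transition` (e.g. `"X->C1"`), plus carried
#'   demographics; attribute `diagnostics` holds counts of skipped gap
#'   pairs and rejected inadmissible pairs.
#' @export
build_transitions <- function(states) {
  stopifnot(all(c("person_id", "wave", "state") %in% names(states)))
  s <- states[order(states$person_id, states$wave), , drop = FALSE]
  n <- nrow(s)
  if (n < 2) return(empty_transitions())
  same <- s$person_id[-n] == s$person_id[-1]
  consec <- s$wave[-1] - s$wave[-n] == 1
  keep <- same & consec
  n_gap <- sum(same & !consec)
  i <- which(keep)
  tr <- data.frame(person_id = s$person_id[i],
                   from_wave = s$wave[i],
                   from_state = s$state[i],
                   to_state = s$state[i + 1],
                   stringsAsFactors = FALSE)
  tr$transition <- paste0(tr$from_state, "->", tr$to_state)
  for (col in intersect(c("age", "sex", "race"), names(s)))
    tr[[col]] <- s[[col]][i]
  adm <- tr$transition %in% admissible_arrows()
  n_bad <- sum(!adm)
  if (n_bad)
    message(n_bad, " observed pair(s) on inadmissible arrows rejected (",
            paste(unique(tr$transition[!adm]), collapse = ", "), ")")
  tr <- tr[adm, , drop = FALSE]
  rownames(tr) <- NULL
  attr(tr, "diagnostics") <- list(n_gap_pairs = n_gap,
                                  n_inadmissible = n_bad)
  tr
}

empty_transitions <- function() {
  data.frame(person_id = character(), from_wave = integer(),
             from_state = character(), to_state = character(),
             transition = character(), stringsAsFactors = FALSE)
}

#' Binary indicators for the 16 admissible arrows
#'
#' Expands transition records into the one-hot outcome matrix used by the
#' arrow-wise regressions: exactly one indicator is 1 per record.
#'
#' @param transitions a data.frame from [build_transitions()].
#' @return A logical incidence matrix with one column per admissible arrow.
#' @export
transition_indicators <- function(transitions) {
  arrows <- unique(admissible_arrows())
  out <- vapply(arrows, function(a) transitions$transition == a,
                logical(nrow(transitions)))
  if (nrow(transitions) == 1) out <- matrix(out, nrow = 1,
                                            dimnames = list(NULL, arrows))
  out
}

#' Empirical transition matrix from observed pairs
#'
#' Row s entry s' is `count(s -> s') / count(origin s)`; structural zeros
#' are honored and rows sum to 1 by construction.
#'
#' @param transitions a data.frame from [build_transitions()], optionally
#'   carrying `sex` and `race` columns.
#' @param sex,race optional subgroup filter values (e.g. `"man"`,
#'   `"Black"`).
#' @return A list with `matrix` (a `transition_matrix`; rows with no origin
#'   records are NA), `params` (a [transition_params] when all rows are
#'   defined, otherwise NULL), `counts` (the 5x5 count table) and
#'   `undefined_rows`.
#' @export
empirical_matrix <- function(transitions, sex = NULL, race = NULL) {
  tr <- transitions
  if (!is.null(sex)) tr <- tr[tr$sex %in% sex, , drop = FALSE]
  if (!is.null(race)) tr <- tr[tr$race %in% race, , drop = FALSE]
  counts <- table(factor(tr$from_state, STATE_NAMES),
                  factor(tr$to_state, STATE_NAMES))
  counts <- matrix(as.numeric(counts), 5, 5,
                   dimnames = list(STATE_NAMES, STATE_NAMES))
  origin <- rowSums(counts)
  M <- counts / ifelse(origin > 0, origin, NA_real_)
  M[origin == 0, ] <- NA_real_
  undefined <- STATE_NAMES[origin == 0]
  params <- NULL
  if (!length(undefined)) {
    params <- params_from_matrix(M, renormalize = FALSE)
  } else {
    warning("no origin records for state(s) ",
            paste(undefined, collapse = ", "),
            "; row(s) undefined, equilibrium computation refused",
            call. = FALSE)
  }
  list(matrix = structure(M, class = c("transition_matrix", "matrix")),
       params = params, counts = counts, undefined_rows = undefined)
}
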