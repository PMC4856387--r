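STEREOTYPY_FORMS <- c("bar_mouthing", "circling", "cage_top_twirling",
                      "back_flipping", "route_tracing")
DISCRETE_FORMS <- setdiff(STEREOTYPY_FORMS, "bar_mouthing")
BEHAVIOUR_LABELS <- c("inactive", "active", STEREOTYPY_FORMS)

#' Observation scheme for one-zero sampling
#'
#' Home-cage behaviour is scored by one-zero sampling: time is divided into
#' short intervals and a behaviour scores 1 for an interval if it occurs at
#' any point within it. The default scheme is 15-s intervals over four 15-min
#' blocks per day (the first 15 min of the 2nd-5th hour of the dark phase) on
#' two days: 480 data points per subject.
#'
#' @param interval_s Sampling interval in seconds (default 15). Must divide
#'   the block length.
#' @param block_starts_s Start of each observation block, seconds from the
#'   start of the day's dark phase.
#' @param block_length_s Length of each block in seconds (default 900).
#' @param days Number of observation days (default 2). Event times are on a
#'   single continuous timeline with day `d` offset by `(d - 1) * 86400` s.
#'
#' @return List of class `observation_scheme` with an `intervals` data.frame
#'   (`day`, `block`, `start_s`) and `n_intervals`.
#' @export
#'
#' @examples
#' observation_scheme()$n_intervals  # 480
observation_scheme <- function(interval_s = 15,
                               block_starts_s = c(3600, 7200, 10800, 14400),
                               block_length_s = 900, days = 2) {
  stopifnot(interval_s > 0, block_length_s > 0, days >= 1)
  if (block_length_s %% interval_s != 0)
    stop("interval_s must divide block_length_s", call. = FALSE)
  bs <- sort(block_starts_s)
  if (length(bs) > 1 && any(bs[-1] < bs[-length(bs)] + block_length_s))
    stop("observation blocks overlap", call. = FALSE)
  per_block <- block_length_s / interval_s
  grid <- expand.grid(offset = (seq_len(per_block) - 1) * interval_s,
                      block = seq_along(bs), day = seq_len(days))
  intervals <- data.frame(
    day = grid$day, block = grid$block,
    start_s = (grid$day - 1) * 86400 + bs[grid$block] + grid$offset
  )
  structure(list(interval_s = interval_s, block_starts_s = bs,
                 block_length_s = block_length_s, days = days,
                 intervals = intervals, n_intervals = nrow(intervals)),
            class = "observation_scheme")
}

validate_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("behaviour", "start_s", "end_s") %in% names(events)))
  bad <- setdiff(unique(events$behaviour), BEHAVIOUR_LABELS)
  if (length(bad))
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(events) && any(events$start_s >= events$end_s))
    stop("each event needs start_s < end_s", call. = FALSE)
  if (is.null(events$repeat_index)) events$repeat_index <- NA_integer_
  events
}

#' Classify stereotypic bouts from an ethogram event stream
#'
#' A behaviour pattern counts as stereotypic only when repeated: bar-mouthing
#' must be performed continuously for at least 3 s; the discrete-repetition
#' forms (circling, cage-top twirling, back-flipping, route-tracing) must be
#' repeated at least three times in a row without pauses longer than 3 s
#' between repetitions (a pause of exactly 3 s keeps the run). Each event row
#' of a discrete form is one repetition; a qualifying run is merged into a
#' single bout spanning the first start to the last end.
#'
#' Rows carrying a positive `n_reps` column (as the output of this function
#' does) are treated as pre-merged runs of that many repetitions, making the
#' classification idempotent on its own output.
#'
#' @param events data.frame with columns `behaviour`, `start_s`, `end_s`
#'   (optionally `repeat_index`, kept only for provenance, and `n_reps`).
#'
#' @return data.frame of qualifying bout spans: `behaviour`, `start_s`,
#'   `end_s`, `n_reps` (`NA` for bar-mouthing).
#' @export
#'
#' @examples
#' ev <- data.frame(behaviour = "back_flipping",
#'                  start_s = c(0, 3, 6), end_s = c(1, 4, 7))
#' classify_stereotypic(ev)  # one bout 0-7 s
classify_stereotypic <- function(events) {
  events <- validate_events(events)
  out <- list()
  bm <- events[events$behaviour == "bar_mouthing", , drop = FALSE]
  bm <- bm[bm$end_s - bm$start_s >= 3, , drop = FALSE]
  if (nrow(bm))
    out[[length(out) + 1L]] <- data.frame(
      behaviour = "bar_mouthing",
      start_s = bm$start_s, end_s = bm$end_s, n_reps = NA_integer_)
  for (form in DISCRETE_FORMS) {
    ev <- events[events$behaviour == form, , drop = FALSE]
    if (!nrow(ev)) next
    ev <- ev[order(ev$start_s), , drop = FALSE]
    reps <- if ("n_reps" %in% names(ev))
      ifelse(is.na(ev$n_reps) | ev$n_reps < 1, 1L, ev$n_reps) else
      rep(1L, nrow(ev))
    gap <- ev$start_s[-1] - ev$end_s[-nrow(ev)]
    run_id <- cumsum(c(1, as.integer(gap > 3)))
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (sum(reps[idx]) >= 3L)
        out[[length(out) + 1L]] <- data.frame(
          behaviour = form,
          start_s = ev$start_s[idx[1]], end_s = ev$end_s[idx[length(idx)]],
          n_reps = as.integer(sum(reps[idx])))
    }
  }
  if (!length(out))
    return(data.frame(behaviour = character(0), start_s = numeric(0),
                      end_s = numeric(0), n_reps = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start_s, res$behaviour), , drop = FALSE]
  rownames(res) <- NULL
  res
}

clipped_overlap <- function(start, end, lo, hi) {
  pmax(pmin(end, hi) - pmax(start, lo), 0)
}

#' One-zero sampling of an event stream
#'
#' Converts timed behaviour events into per-interval binary indicators under
#' an [observation_scheme()]. Intervals are half-open `[t, t + interval)`. A
#' stereotypy form scores 1 for an interval iff a qualifying bout (from
#' [classify_stereotypic()]) overlaps it. An interval is scored `inactive`
#' when the animal is motionless throughout — operationally, when non-inactive
#' events overlap it for at most 5 s in total (brief twitches) and no
#' stereotypic bout touches it; `active` is its complement. Events lying
#' entirely outside all observation blocks are ignored (their count is kept in
#' the `n_events_outside` attribute).
#'
#' @param events Ethogram event data.frame (see [classify_stereotypic()]).
#' @param scheme An [observation_scheme()].
#' @param bouts Optional precomputed bout table; recomputed from `events`
#'   when omitted.
#'
#' @return A `sample_matrix`: data.frame with the scheme's interval metadata
#'   plus 0/1 columns for each stereotypy form, `active` and `inactive`;
#'   attribute `n_intervals`.
#' @export
one_zero_sample <- function(events, scheme = observation_scheme(),
                            bouts = NULL) {
  events <- validate_events(events)
  stopifnot(inherits(scheme, "observation_scheme"))
  if (is.null(bouts)) bouts <- classify_stereotypic(events)
  iv <- scheme$intervals
  lo <- iv$start_s
  hi <- lo + scheme$interval_s
  mat <- iv
  for (form in STEREOTYPY_FORMS) {
    b <- bouts[bouts$behaviour == form, , drop = FALSE]
    flag <- rep(0L, nrow(iv))
    for (j in seq_len(nrow(b)))
      flag <- flag | (b$start_s[j] < hi & b$end_s[j] > lo)
    mat[[form]] <- as.integer(flag)
  }
  moving <- events[events$behaviour != "inactive", , drop = FALSE]
  move_time <- rep(0, nrow(iv))
  for (j in seq_len(nrow(moving)))
    move_time <- move_time +
      clipped_overlap(moving$start_s[j], moving$end_s[j], lo, hi)
  any_form <- as.integer(rowSums(mat[, STEREOTYPY_FORMS, drop = FALSE]) > 0)
  mat$active <- as.integer(move_time > 5 | any_form == 1L)
  mat$inactive <- 1L - mat$active
  n_outside <- if (nrow(moving)) {
    sum(vapply(seq_len(nrow(moving)), function(j)
      all(clipped_overlap(moving$start_s[j], moving$end_s[j], lo, hi) == 0),
      logical(1)))
  } else 0L
  structure(mat, class = c("sample_matrix", "data.frame"),
            n_intervals = nrow(iv), n_events_outside = n_outside)
}

#' Stereotypy level from a one-zero sample matrix
#'
#' The level of a form of stereotypic behaviour is the proportion of *active*
#' intervals in which it was scored (active time itself being a proportion of
#' observed intervals). `form = "all"` uses intervals flagged for any form —
#' the union, so levels of co-occurring forms are not additive.
#'
#' @param matrix A `sample_matrix` from [one_zero_sample()].
#' @param form One of the stereotypy labels, or `"all"`.
#'
#' @return Proportion in `[0, 1]`; `NA` (with a warning) when there are no
#'   active intervals.
#' @export
stereotypy_level <- function(matrix, form = "all") {
  stopifnot(inherits(matrix, "sample_matrix"))
  n_active <- sum(matrix$active)
  if (n_active == 0) {
    warning("stereotypy level undefined: no active intervals", call. = FALSE)
    return(NA_real_)
  }
  flag <- if (identical(form, "all")) {
    as.integer(rowSums(matrix[, STEREOTYPY_FORMS, drop = FALSE]) > 0)
  } else {
    if (!form %in% STEREOTYPY_FORMS)
      stop("unknown form: ", form, call. = FALSE)
    matrix[[form]]
  }
  sum(flag & matrix$active) / n_active
}

#' Per-subject ethogram level summary
#'
#' @param matrix A `sample_matrix` from [one_zero_sample()].
#' @param subject_id Identifier for the output row.
#'
#' @return One-row data.frame: active proportion, per-form levels, overall
#'   level, and their square roots (the transform conventionally applied
#'   before model fitting, exported as plain columns).
#' @export
ethogram_levels <- function(matrix, subject_id = "subject") {
  stopifnot(inherits(matrix, "sample_matrix"))
  n <- attr(matrix, "n_intervals")
  out <- data.frame(subject_id = subject_id,
                    n_intervals = n,
                    active_prop = sum(matrix$active) / n,
                    stringsAsFactors = FALSE)
  lv <- suppressWarnings(
    vapply(c(STEREOTYPY_FORMS, "all"), function(f)
      stereotypy_level(matrix, f), numeric(1)))
  for (f in names(lv)) {
    col <- paste0("level_", f)
    out[[col]] <- lv[[f]]
    out[[paste0("sqrt_", col)]] <- sqrt(lv[[f]])
  }
  out
}
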