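#' Arm-role map for the radial-maze cognitive-bias task
#'
#' The eight-arm maze contains four reference arms — two paired with a
#' positive outcome (food, light off) and two with a negative outcome (light,
#' white noise) — and four ambiguous arms adjacent to them (near-positive,
#' near-negative). During training the ambiguous arms are closed.
#'
#' @param roles Named character vector or list mapping arm ids (`"1"`..`"8"`)
#'   to roles in `positive`, `negative`, `near_positive`, `near_negative`,
#'   `closed`.
#'
#' @return Named character vector of class `arm_role_map`.
#' @export
#'
#' @examples
#' arm_role_map(c(`1` = "positive", `2` = "positive",
#'                `3` = "near_negative", `4` = "negative",
#'                `5` = "negative", `6` = "near_negative",
#'                `7` = "near_positive", `8` = "near_positive"))
arm_role_map <- function(roles) {
  roles <- unlist(roles)
  ok <- c("positive", "negative", "near_positive", "near_negative", "closed")
  if (is.null(names(roles)) || any(names(roles) == ""))
    stop("roles must be named by arm id", call. = FALSE)
  bad <- setdiff(unique(roles), ok)
  if (length(bad))
    stop("unknown arm roles: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(as.character(roles), names = names(roles),
            class = "arm_role_map")
}

#' Default testing-phase role map
#'
#' Positive arms opposite negative arms, each ambiguous arm adjacent to the
#' reference pair it is named after.
#' @return An [arm_role_map()].
#' @export
default_role_map <- function() {
  arm_role_map(c(`1` = "positive", `2` = "positive",
                 `3` = "near_positive", `4` = "near_negative",
                 `5` = "negative", `6` = "negative",
                 `7` = "near_negative", `8` = "near_positive"))
}

#' Construct an arm-visit log
#'
#' One maze session's timed arm entries and exits. Visits must be
#' non-overlapping and inside the session; a visit still open at session end
#' is truncated at `duration_s`.
#'
#' @param subject_id,session_id Identifiers.
#' @param visits data.frame with columns `arm_id`, `entry_s`, `exit_s`
#'   (`exit_s` may be `NA` for a visit open at session end).
#' @param duration_s Session duration in seconds (default 600, a ten-minute
#'   session).
#'
#' @return List of class `arm_visit_log`.
#' @export
arm_visit_log <- function(subject_id, visits, session_id = "test",
                          duration_s = 600) {
  stopifnot(is.data.frame(visits),
            all(c("arm_id", "entry_s", "exit_s") %in% names(visits)))
  v <- visits[order(visits$entry_s), c("arm_id", "entry_s", "exit_s"),
              drop = FALSE]
  v$exit_s[is.na(v$exit_s)] <- duration_s
  if (nrow(v)) {
    if (any(v$entry_s < 0) || any(v$exit_s > duration_s))
      stop("visits fall outside the session [0, duration_s]", call. = FALSE)
    if (any(v$entry_s >= v$exit_s))
      stop("each visit needs entry_s < exit_s", call. = FALSE)
    if (nrow(v) > 1 && any(v$entry_s[-1] < v$exit_s[-nrow(v)]))
      stop("visits overlap in time", call. = FALSE)
  }
  rownames(v) <- NULL
  structure(list(subject_id = as.character(subject_id)[1],
                 session_id = as.character(session_id)[1],
                 duration_s = duration_s, visits = v),
            class = "arm_visit_log")
}

#' Time spent per arm role
#'
#' Sums visit durations by role; time not spent in any arm is the central
#' arena.
#'
#' @param log An [arm_visit_log()].
#' @param roles An [arm_role_map()].
#'
#' @return Named numeric vector of seconds over
#'   `positive, negative, near_positive, near_negative, centre`.
#' @export
time_in_roles <- function(log, roles) {
  stopifnot(inherits(log, "arm_visit_log"))
  roles <- if (inherits(roles, "arm_role_map")) roles else arm_role_map(roles)
  v <- log$visits
  role_of <- roles[as.character(v$arm_id)]
  if (any(is.na(role_of)))
    stop("visit to an arm with no assigned role: arm ",
         paste(unique(v$arm_id[is.na(role_of)]), collapse = ", "),
         call. = FALSE)
  if (any(role_of == "closed"))
    stop("visit recorded to a closed arm", call. = FALSE)
  out <- c(positive = 0, negative = 0, near_positive = 0, near_negative = 0)
  if (nrow(v)) {
    agg <- tapply(v$exit_s - v$entry_s, role_of, sum)
    out[names(agg)] <- agg
  }
  c(out, centre = max(log$duration_s - sum(out), 0))
}

undefined_score <- function(what) {
  warning(sprintf("%s undefined: zero time in denominator arms", what),
          call. = FALSE)
  NA_real_
}

#' Cognitive-bias arm scores
#'
#' Three contrasts over arm-occupancy time, each in `[-1, 1]`:
#' * `positive_arm_score`: (positive - negative) / (time in all reference
#'   arms) — discrimination of the trained contingencies;
#' * `reference_arm_score`: (reference - ambiguous) / (time in all arms) —
#'   preference for trained over ambiguous arms;
#' * `ambiguous_arm_score`: (near-positive - near-negative) / (time in all
#'   ambiguous arms) — the judgement-bias readout proper: optimistic animals
#'   favour arms adjacent to the positive pair.
#'
#' A score whose denominator is zero is undefined and returned as `NA` (with a
#' warning), never as 0 — zero means indifference, a different claim.
#'
#' @param log An [arm_visit_log()].
#' @param roles An [arm_role_map()].
#' @return Score in `[-1, 1]`, or `NA` if undefined.
#' @export
positive_arm_score <- function(log, roles) {
  tt <- time_in_roles(log, roles)
  den <- tt[["positive"]] + tt[["negative"]]
  if (den <= 0) return(undefined_score("positive_arm_score"))
  (tt[["positive"]] - tt[["negative"]]) / den
}

#' @rdname positive_arm_score
#' @export
reference_arm_score <- function(log, roles) {
  tt <- time_in_roles(log, roles)
  t_ref <- tt[["positive"]] + tt[["negative"]]
  t_amb <- tt[["near_positive"]] + tt[["near_negative"]]
  if (t_ref + t_amb <= 0) return(undefined_score("reference_arm_score"))
  (t_ref - t_amb) / (t_ref + t_amb)
}

#' @rdname positive_arm_score
#' @export
ambiguous_arm_score <- function(log, roles) {
  tt <- time_in_roles(log, roles)
  den <- tt[["near_positive"]] + tt[["near_negative"]]
  if (den <= 0) return(undefined_score("ambiguous_arm_score"))
  (tt[["near_positive"]] - tt[["near_negative"]]) / den
}

#' Arm-entry summary
#'
#' Entry counts per role relative to all arm entries, plus the absolute total
#' (the activity / overall-exploration measure).
#'
#' @param log An [arm_visit_log()].
#' @param roles An [arm_role_map()].
#' @return List with `total_entries` and `rel_entries` (named numeric over
#'   roles; all `NA` when there were no entries).
#' @export
entry_summary <- function(log, roles) {
  stopifnot(inherits(log, "arm_visit_log"))
  roles <- if (inherits(roles, "arm_role_map")) roles else arm_role_map(roles)
  v <- log$visits
  role_levels <- c("positive", "negative", "near_positive", "near_negative")
  total <- nrow(v)
  if (total == 0L) {
    rel <- stats::setNames(rep(NA_real_, 4), role_levels)
    return(list(total_entries = 0L, rel_entries = rel))
  }
  role_of <- factor(roles[as.character(v$arm_id)], levels = role_levels)
  rel <- as.numeric(table(role_of)) / total
  names(rel) <- role_levels
  list(total_entries = total, rel_entries = rel)
}

#' All occupancy summaries and bias scores for one session
#'
#' @param log An [arm_visit_log()].
#' @param roles An [arm_role_map()].
#' @return One-row data.frame: ids, the three scores, relative time per role
#'   (including centre, relative to session duration), relative entries per
#'   role and total entries.
#' @export
bias_scores <- function(log, roles) {
  tt <- time_in_roles(log, roles)
  es <- entry_summary(log, roles)
  rel_t <- tt / log$duration_s
  out <- data.frame(
    subject_id = log$subject_id, session_id = log$session_id,
    positive_arm_score = suppressWarnings(positive_arm_score(log, roles)),
    reference_arm_score = suppressWarnings(reference_arm_score(log, roles)),
    ambiguous_arm_score = suppressWarnings(ambiguous_arm_score(log, roles)),
    total_entries = es$total_entries,
    stringsAsFactors = FALSE
  )
  for (r in names(rel_t)) out[[paste0("rel_time_", r)]] <- rel_t[[r]]
  for (r in names(es$rel_entries))
    out[[paste0("rel_entries_", r)]] <- es$rel_entries[[r]]
  out
}
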