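#' Stock choice-policy agents for the guessing task
#'
#' Builds a choice policy `function(choices, rewards) -> "L" | "R"` for use
#' with [run_session()]. Agents never see the baited side, matching the
#' information structure of the live task; any randomness they use comes from
#' the ambient RNG stream, so a session seeded via [controller_config()] is
#' fully reproducible.
#'
#' Kinds:
#' * `iid_biased` — chooses `"R"` independently with probability `p_right`;
#' * `markov_repeat` — first trial a fair coin, then repeats its previous
#'   choice with probability `p_repeat` (an order-1 perseverative agent);
#' * `alternator` — deterministic strict alternation starting with `first`;
#' * `win_stay_lose_shift` — first trial a fair coin; after a rewarded trial
#'   repeats with probability `p_stay`, after an unrewarded trial switches.
#'
#' @param kind One of `"iid_biased"`, `"markov_repeat"`, `"alternator"`,
#'   `"win_stay_lose_shift"`.
#' @param p_right,p_repeat,p_stay Policy probabilities in `[0, 1]`.
#' @param first Starting side for the alternator.
#'
#' @return A function of `(choices, rewards)`.
#' @export
#'
#' @examples
#' ag <- make_agent("markov_repeat", p_repeat = 0.9)
#' set.seed(1); ag(character(0), logical(0))
make_agent <- function(kind = c("iid_biased", "markov_repeat", "alternator",
                                "win_stay_lose_shift"),
                       p_right = 0.5, p_repeat = 0.5, p_stay = 1,
                       first = "L") {
  kind <- match.arg(kind)
  stopifnot(p_right >= 0, p_right <= 1, p_repeat >= 0, p_repeat <= 1,
            p_stay >= 0, p_stay <= 1, first %in% c("L", "R"))
  flip <- function(s) if (s == "L") "R" else "L"
  switch(kind,
    iid_biased = function(choices, rewards) {
      if (stats::runif(1) < p_right) "R" else "L"
    },
    markov_repeat = function(choices, rewards) {
      if (length(choices) == 0L)
        return(if (stats::runif(1) < 0.5) "R" else "L")
      prev <- choices[length(choices)]
      if (stats::runif(1) < p_repeat) prev else flip(prev)
    },
    alternator = function(choices, rewards) {
      if (length(choices) == 0L) return(first)
      flip(choices[length(choices)])
    },
    win_stay_lose_shift = function(choices, rewards) {
      if (length(choices) == 0L)
        return(if (stats::runif(1) < 0.5) "R" else "L")
      prev <- choices[length(choices)]
      if (rewards[length(rewards)]) {
        if (stats::runif(1) < p_stay) prev else flip(prev)
      } else {
        flip(prev)
      }
    })
}

#' Radial-maze occupancy profile
#'
#' Ground-truth parameters for [simulate_visit_log()]: the fraction of the
#' session to spend in arms of each role (the remainder is central-arena
#' time), the number of arm entries, and the session duration.
#'
#' @param occupancy Named numeric over (a subset of) the roles `positive`,
#'   `negative`, `near_positive`, `near_negative`; fractions of session time,
#'   non-negative with sum at most 1.
#' @param n_entries Total arm entries in the session.
#' @param duration_s Session length in seconds (default 600).
#' @param seed Optional integer seed.
#'
#' @return List of class `maze_profile`.
#' @export
maze_profile <- function(occupancy, n_entries = 60, duration_s = 600,
                         seed = NULL) {
  roles <- c("positive", "negative", "near_positive", "near_negative")
  occ <- stats::setNames(rep(0, 4), roles)
  bad <- setdiff(names(occupancy), roles)
  if (length(bad))
    stop("unknown occupancy roles: ", paste(bad, collapse = ", "),
         call. = FALSE)
  occ[names(occupancy)] <- as.numeric(occupancy)
  if (any(occ < 0) || sum(occ) > 1 + 1e-9)
    stop("occupancy fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  stopifnot(n_entries >= 0, duration_s > 0)
  structure(list(occupancy = occ, n_entries = as.integer(n_entries),
                 duration_s = duration_s,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "maze_profile")
}

# largest-remainder apportionment of n among weights w, with every positive
# weight guaranteed at least one unit (so its time budget can be placed)
apportion <- function(n, w) {
  if (n == 0 || sum(w) == 0) return(rep(0L, length(w)))
  q <- n * w / sum(w)
  k <- floor(q)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k <- as.integer(k)
  while (any(k == 0 & w > 0) && any(k > 1)) {
    k[which(k == 0 & w > 0)[1]] <- 1L
    donor <- which.max(k)
    k[donor] <- k[donor] - 1L
  }
  k
}

#' Simulate a radial-maze session
#'
#' Draws a visit log whose per-role occupancy matches the profile exactly:
#' entries are apportioned to roles in proportion to occupancy, within-role
#' visit durations are exponential draws rescaled to the role's time budget,
#' centre-stay gaps are exponential draws rescaled to the centre budget, and
#' the visit order is a random shuffle. Arms within a role are drawn
#' uniformly.
#'
#' @param profile A [maze_profile()].
#' @param roles An [arm_role_map()] supplying arm ids per role.
#' @param subject_id,session_id Identifiers for the log.
#'
#' @return An [arm_visit_log()].
#' @export
#'
#' @examples
#' p <- maze_profile(c(positive = 0.5, negative = 0.1), n_entries = 30,
#'                   seed = 1)
#' positive_arm_score(simulate_visit_log(p), default_role_map())
simulate_visit_log <- function(profile, roles = default_role_map(),
                               subject_id = "sim", session_id = "test") {
  stopifnot(inherits(profile, "maze_profile"))
  roles <- if (inherits(roles, "arm_role_map")) roles else arm_role_map(roles)
  if (!is.null(profile$seed)) set.seed(profile$seed)
  occ <- profile$occupancy
  n <- profile$n_entries
  empty <- data.frame(arm_id = integer(0), entry_s = numeric(0),
                      exit_s = numeric(0))
  if (n == 0L || sum(occ) == 0)
    return(arm_visit_log(subject_id, empty, session_id, profile$duration_s))
  counts <- apportion(n, occ)
  role_seq <- sample(rep(names(occ), counts))
  dur <- numeric(n)
  for (r in names(occ)[counts > 0]) {
    idx <- which(role_seq == r)
    d <- stats::rexp(length(idx))
    dur[idx] <- d / sum(d) * occ[[r]] * profile$duration_s
  }
  gaps <- stats::rexp(n + 1)
  gaps <- gaps / sum(gaps) * (1 - sum(occ)) * profile$duration_s
  entry <- cumsum(gaps[seq_len(n)]) + c(0, cumsum(dur))[seq_len(n)]
  exit <- entry + dur
  arm <- vapply(role_seq, function(r) {
    arms <- names(roles)[roles == r]
    if (!length(arms)) stop("role map has no arm for role ", r, call. = FALSE)
    if (length(arms) == 1) arms else sample(arms, 1)
  }, "")
  visits <- data.frame(arm_id = as.integer(arm), entry_s = entry,
                       exit_s = pmin(exit, profile$duration_s))
  arm_visit_log(subject_id, visits, session_id, profile$duration_s)
}

#' Home-cage ethogram profile
#'
#' Ground-truth parameters for [simulate_ethogram()]: the probability that a
#' sampling interval is active, and for each stereotypy form the probability
#' that an active interval contains a qualifying bout of that form (which is
#' exactly the expected stereotypy level, since levels are proportions of
#' active intervals).
#'
#' @param levels Named numeric over stereotypy forms (see
#'   [classify_stereotypic()] for labels); probabilities in `[0, 1]`.
#' @param activity Probability an interval is active (default 0.7).
#' @param bar_dur_range Bar-mouthing bout duration range in seconds, minimum
#'   at least 3 (default `c(3, 10)`).
#' @param rep_dur Duration of one repetition of a discrete form, seconds.
#' @param rep_gap_range Range of gaps between repetitions, seconds; must stay
#'   at or below 3 so runs qualify.
#' @param reps_lambda Extra repetitions beyond the minimum three are
#'   `rpois(reps_lambda)`, capped so a bout fits one interval.
#' @param seed Optional integer seed.
#'
#' @return List of class `etho_profile`.
#' @export
etho_profile <- function(levels = c(bar_mouthing = 0.1), activity = 0.7,
                         bar_dur_range = c(3, 10), rep_dur = 0.5,
                         rep_gap_range = c(0.2, 1), reps_lambda = 1,
                         seed = NULL) {
  bad <- setdiff(names(levels), STEREOTYPY_FORMS)
  if (length(bad))
    stop("unknown stereotypy forms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  stopifnot(all(levels >= 0), all(levels <= 1), activity >= 0, activity <= 1,
            bar_dur_range[1] >= 3, diff(bar_dur_range) >= 0, rep_dur > 0,
            rep_gap_range[1] >= 0, rep_gap_range[2] <= 3,
            diff(rep_gap_range) >= 0, reps_lambda >= 0)
  structure(list(levels = levels, activity = activity,
                 bar_dur_range = bar_dur_range, rep_dur = rep_dur,
                 rep_gap_range = rep_gap_range, reps_lambda = reps_lambda,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "etho_profile")
}

#' Simulate a home-cage ethogram event stream
#'
#' Each sampling interval of the scheme is independently active with the
#' profile's activity probability; an active interval carries a 15-s `active`
#' event and, independently per form with the form's level probability, one
#' qualifying stereotypic bout drawn from the profile's duration/gap
#' distributions and placed uniformly within the interval. Bouts therefore
#' never straddle interval boundaries (a deliberate simplification: it makes
#' the expected level of each form exactly the profile's level parameter).
#'
#' @param profile An [etho_profile()].
#' @param scheme An [observation_scheme()].
#'
#' @return Event data.frame (`behaviour`, `start_s`, `end_s`, `repeat_index`)
#'   with attribute `truth`: the scheme's intervals plus the planted `active`
#'   and per-form indicator columns.
#' @export
simulate_ethogram <- function(profile, scheme = observation_scheme()) {
  stopifnot(inherits(profile, "etho_profile"),
            inherits(scheme, "observation_scheme"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  iv <- scheme$intervals
  L <- scheme$interval_s
  n <- nrow(iv)
  active <- stats::runif(n) < profile$activity
  truth <- iv
  truth$active <- as.integer(active)
  ev <- list()
  for (i in which(active)) {
    t0 <- iv$start_s[i]
    ev[[length(ev) + 1L]] <- data.frame(
      behaviour = "active", start_s = t0, end_s = t0 + L,
      repeat_index = NA_integer_)
  }
  for (form in names(profile$levels)) {
    plant <- active & stats::runif(n) < profile$levels[[form]]
    truth[[form]] <- as.integer(plant)
    for (i in which(plant)) {
      t0 <- iv$start_s[i]
      if (form == "bar_mouthing") {
        d <- stats::runif(1, profile$bar_dur_range[1],
                          min(profile$bar_dur_range[2], L))
        s <- t0 + stats::runif(1, 0, L - d)
        ev[[length(ev) + 1L]] <- data.frame(
          behaviour = form, start_s = s, end_s = s + d,
          repeat_index = NA_integer_)
      } else {
        reps <- 3L + stats::rpois(1, profile$reps_lambda)
        repeat {
          gaps <- stats::runif(reps - 1L, profile$rep_gap_range[1],
                               profile$rep_gap_range[2])
          span <- reps * profile$rep_dur + sum(gaps)
          if (span <= L || reps == 3L) break
          reps <- reps - 1L
        }
        span <- min(span, L)
        s <- t0 + stats::runif(1, 0, max(L - span, 0))
        starts <- s + c(0, cumsum(gaps + profile$rep_dur))[seq_len(reps)]
        ev[[length(ev) + 1L]] <- data.frame(
          behaviour = form, start_s = starts,
          end_s = starts + profile$rep_dur, repeat_index = seq_len(reps))
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(behaviour = character(0), start_s = numeric(0),
               end_s = numeric(0), repeat_index = integer(0))
  events <- events[order(events$start_s), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "truth") <- truth
  events
}
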