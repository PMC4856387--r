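#' Controller configuration for the two-choice guessing task
#'
#' The guessing task counteracts side bias by baiting only one of the two goal
#' compartments on each trial, with the probability of baiting the right side
#' equal to the proportion of *left* responses in the subject's recent
#' history. Choosing each side equally often maximises expected reward; any
#' patterned (sequentially dependent) strategy does not improve on chance.
#'
#' @param window Number of previous trials over which the side bias is
#'   computed (default 20). Earlier trials, when fewer than `window` exist,
#'   all count.
#' @param n_trials Session length in trials (default 80).
#' @param seed Integer seed making a simulated session reproducible, or
#'   `NULL` to use the current RNG state.
#' @param shaping_block Apply the shaping-phase rule that closes a side after
#'   three identical consecutive choices. Off by default: during testing both
#'   sides stay open and only the bait moves.
#'
#' @return A list of class `controller_config`.
#' @export
controller_config <- function(window = 20, n_trials = 80, seed = NULL,
                              shaping_block = FALSE) {
  stopifnot(window >= 1, n_trials >= 1)
  structure(
    list(window = as.integer(window), n_trials = as.integer(n_trials),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         shaping_block = isTRUE(shaping_block)),
    class = "controller_config"
  )
}

#' Probability that the next trial baits the right compartment
#'
#' Equals the proportion of left responses in the subject's recent choices:
#' the window is the most recent `window` trials once that many exist, and all
#' previous trials before that. With no history the probability is 0.5.
#'
#' @param history Character vector of previous choices (`"L"`/`"R"`), oldest
#'   first.
#' @param window Sliding-window length in trials (default 20).
#'
#' @return Probability in `[0, 1]` of baiting the right side.
#' @export
#'
#' @examples
#' bait_probability(rep(c("L", "R"), c(12, 8)))  # 12/20 = 0.6
#' bait_probability(character(0))                # 0.5
bait_probability <- function(history, window = 20) {
  history <- as.character(history)
  assert_sides(history, "history")
  stopifnot(window >= 1)
  if (length(history) == 0L) return(0.5)
  span <- utils::tail(history, window)
  mean(span == "L")
}

#' Draw the baited side for the next trial
#'
#' Consumes exactly one uniform draw from the current RNG stream and returns
#' `"R"` with probability [bait_probability()] of the history, else `"L"`.
#'
#' @param history Previous choices, oldest first.
#' @param config A [controller_config()].
#'
#' @return `"L"` or `"R"`.
#' @export
next_bait <- function(history, config = controller_config()) {
  p_right <- bait_probability(history, config$window)
  if (stats::runif(1) < p_right) "R" else "L"
}

#' Shaping-phase side blocking
#'
#' During shaping (both goalpots baited) a side chosen three times in
#' succession is closed on the following trial, so the mouse is not shaped to
#' one side.
#'
#' @param history Shaping-phase choices so far, oldest first.
#'
#' @return The side (`"L"`/`"R"`) to close on the next trial, or `NULL` when
#'   the last three choices are not identical (or fewer than three exist).
#' @export
#'
#' @examples
#' shaping_block_side(c("L", "R", "R", "R"))  # "R"
#' shaping_block_side(c("R", "R"))            # NULL
shaping_block_side <- function(history) {
  history <- as.character(history)
  assert_sides(history, "history")
  if (length(history) < 3L) return(NULL)
  last3 <- utils::tail(history, 3)
  if (all(last3 == last3[1])) last3[1] else NULL
}

#' Run a simulated guessing-task session
#'
#' Plays a choice agent against the adaptive controller. On every trial the
#' baited side is drawn *before* the agent chooses (as the live goalpots are
#' baited pre-trial) and the agent never observes it; the agent sees only its
#' own past choices and reward outcomes. With `shaping_block = TRUE` in the
#' config, a side closed by [shaping_block_side()] is forced against the
#' agent's will, emulating the shaping protocol (and both sides are treated as
#' baited, so every completed trial is rewarded).
#'
#' @param agent A function `function(choices, rewards)` returning `"L"` or
#'   `"R"`; see [make_agent()] for stock policies. `choices` and `rewards` are
#'   the agent's own history so far (possibly length zero).
#' @param config A [controller_config()]. Its `seed` (if non-`NULL`) seeds the
#'   session, making controller draws and any agent randomness reproducible.
#' @param subject_id Identifier stored in the returned sequence.
#'
#' @return A [choice_sequence()] of `config$n_trials` trials.
#' @export
#'
#' @examples
#' ag <- make_agent("iid_biased", p_right = 0.5)
#' s <- run_session(ag, controller_config(seed = 1))
#' mean(s$rewarded)
run_session <- function(agent, config = controller_config(),
                        subject_id = "sim") {
  stopifnot(is.function(agent))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  choices <- character(n)
  baited <- character(n)
  rewarded <- logical(n)
  for (t in seq_len(n)) {
    hist_t <- choices[seq_len(t - 1L)]
    blocked <- if (config$shaping_block) shaping_block_side(hist_t) else NULL
    bait_t <- next_bait(hist_t, config)
    ch <- agent(hist_t, rewarded[seq_len(t - 1L)])
    if (!(is.character(ch) && length(ch) == 1L && ch %in% c("L", "R")))
      stop("agent must return a single side 'L' or 'R'", call. = FALSE)
    if (!is.null(blocked) && ch == blocked)
      ch <- if (blocked == "L") "R" else "L"
    choices[t] <- ch
    baited[t] <- bait_t
    rewarded[t] <- if (config$shaping_block) TRUE else ch == bait_t
  }
  if (config$shaping_block) {
    # both pots baited during shaping; bait draws are not meaningful
    choice_sequence(subject_id, choices, baited = choices)
  } else {
    choice_sequence(subject_id, choices, baited = baited)
  }
}
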