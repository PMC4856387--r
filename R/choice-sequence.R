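#' Construct a choice sequence
#'
#' A `choice_sequence` holds one subject's ordered two-choice responses from
#' the guessing task, together with the baited side and reward outcome of each
#' trial. Sides are the single characters `"L"` and `"R"` (case-sensitive).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param choices Character vector of sides chosen, one per trial.
#' @param baited Character vector of baited sides, same length as `choices`,
#'   or `NULL` if baiting is unknown (e.g. shaping-phase data).
#' @param rewarded Logical vector, `TRUE` where `choices == baited`. Computed
#'   from `choices` and `baited` when omitted.
#'
#' @return An object of class `choice_sequence`: a list with elements
#'   `subject_id`, `choices`, `baited`, `rewarded` and `n` (trial count).
#' @export
#'
#' @examples
#' choice_sequence("m1", c("L", "R", "R"), baited = c("L", "L", "R"))
choice_sequence <- function(subject_id, choices, baited = NULL,
                            rewarded = NULL) {
  choices <- as.character(choices)
  assert_sides(choices, "choices")
  n <- length(choices)
  if (!is.null(baited)) {
    baited <- as.character(baited)
    assert_sides(baited, "baited")
    if (length(baited) != n)
      stop("`baited` must have the same length as `choices`", call. = FALSE)
    expected <- choices == baited
    if (is.null(rewarded)) {
      rewarded <- expected
    } else {
      rewarded <- as.logical(rewarded)
      if (!identical(rewarded, expected))
        stop("`rewarded` must be TRUE exactly where choice equals the baited side",
             call. = FALSE)
    }
  } else if (!is.null(rewarded)) {
    stop("`rewarded` requires `baited`", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id)[1],
         choices = choices, baited = baited, rewarded = rewarded, n = n),
    class = "choice_sequence"
  )
}

assert_sides <- function(x, what) {
  bad <- !(x %in% c("L", "R"))
  if (any(bad))
    stop(sprintf("`%s` contains values other than 'L'/'R' (first offender: %s)",
                 what, deparse(x[bad][1])), call. = FALSE)
  invisible(x)
}

#' @export
print.choice_sequence <- function(x, ...) {
  cat(sprintf("<choice_sequence> subject %s, %d trials\n", x$subject_id, x$n))
  cat("  choices: ", paste(utils::head(x$choices, 40), collapse = ""),
      if (x$n > 40) "..." else "", "\n", sep = "")
  if (!is.null(x$rewarded))
    cat(sprintf("  rewarded: %d/%d\n", sum(x$rewarded), x$n))
  invisible(x)
}

#' @export
as.data.frame.choice_sequence <- function(x, ...) {
  data.frame(
    subject_id = rep(x$subject_id, x$n),
    trial = seq_len(x$n),
    choice = x$choices,
    baited = if (is.null(x$baited)) NA_character_ else x$baited,
    rewarded = if (is.null(x$rewarded)) NA_integer_ else as.integer(x$rewarded),
    stringsAsFactors = FALSE
  )
}
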