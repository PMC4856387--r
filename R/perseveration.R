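#' Tetragram distribution of a choice sequence
#'
#' Divides the response sequence into overlapping windows of four consecutive
#' choices (stride 1), so an 80-trial sequence yields 77 tetragrams over the
#' 16 possible L/R configurations. Under a random search strategy every
#' configuration has the same expected count (77/16 for 80 trials); an excess
#' of pure repetitions (`LLLL`, `RRRR`) or pure alternations (`LRLR`, `RLRL`)
#' marks a patterned, sequentially dependent strategy.
#'
#' @param seq A [choice_sequence()] (or plain character vector of sides) with
#'   at least 4 trials.
#'
#' @return A list of class `tetragram_table` with `counts` (named integer
#'   vector over all 16 configurations, zero-filled) and `n_windows`.
#' @export
#'
#' @examples
#' tetragram_counts(choice_sequence("m1", rep(c("L", "R"), 40)))
tetragram_counts <- function(seq) {
  ch <- seq_choices(seq)
  n <- length(ch)
  if (n < 4L)
    stop("tetragram analysis needs at least 4 trials", call. = FALSE)
  keys <- tetragram_keys()
  grams <- vapply(seq_len(n - 3L),
                  function(i) paste(ch[i:(i + 3L)], collapse = ""), "")
  counts <- table(factor(grams, levels = keys))
  out <- as.integer(counts)
  names(out) <- keys
  structure(list(counts = out, n_windows = n - 3L),
            class = "tetragram_table")
}

tetragram_keys <- function() {
  sides <- c("L", "R")
  apply(expand.grid(sides, sides, sides, sides)[, 4:1], 1, paste,
        collapse = "")
}

seq_choices <- function(seq) {
  if (inherits(seq, "choice_sequence")) return(seq$choices)
  ch <- as.character(seq)
  assert_sides(ch, "seq")
  ch
}

#' Pure repetition and pure alternation counts
#'
#' `pure_repetitions()` counts tetragrams `RRRR` + `LLLL`;
#' `pure_alternations()` counts `RLRL` + `LRLR`.
#'
#' @param table A `tetragram_table` from [tetragram_counts()], or anything
#'   accepted by it.
#' @return Integer count.
#' @export
pure_repetitions <- function(table) {
  tab <- as_tetragram_table(table)
  sum(tab$counts[c("RRRR", "LLLL")])
}

#' @rdname pure_repetitions
#' @export
pure_alternations <- function(table) {
  tab <- as_tetragram_table(table)
  sum(tab$counts[c("RLRL", "LRLR")])
}

as_tetragram_table <- function(x) {
  if (inherits(x, "tetragram_table")) x else tetragram_counts(x)
}

#' Side bias of a choice sequence
#'
#' Proportion of responses to the right compartment.
#'
#' @param seq A [choice_sequence()] or character vector of sides.
#' @return Proportion in `[0, 1]`.
#' @export
side_bias <- function(seq) {
  ch <- seq_choices(seq)
  if (length(ch) == 0L) stop("empty sequence", call. = FALSE)
  mean(ch == "R")
}

#' Proportion of rewarded (correct) choices
#'
#' @param seq A [choice_sequence()] carrying baited sides.
#' @return Mean of the per-trial reward indicator.
#' @export
correct_choice_proportion <- function(seq) {
  if (!inherits(seq, "choice_sequence") || is.null(seq$rewarded))
    stop("`seq` must be a choice_sequence with baited sides", call. = FALSE)
  mean(seq$rewarded)
}

#' Markov-chain recurrent-perseveration score
#'
#' Tests the sequential independence of a binary choice sequence at Markov
#' order `k` (default 3: each choice conditioned on the three preceding
#' responses). For every length-`k` context that occurs, the observed counts
#' of the following choice are compared with expected counts under the null of
#' sequential independence *preserving side bias*: the expected count for
#' choice `x` after context `c` is `n(c) * m(x)`, where `m(x)` is the marginal
#' proportion of `x` over the whole sequence. The sum chi-square over all
#' cells with positive expectation gives the tail probability `p` of
#' sequential independence; recurrent perseveration is `P = 1 - p`, reported
#' on the logit scale (`logitP`) after clamping `P` into
#' `[epsilon, 1 - epsilon]`.
#'
#' Because the marginal proportion is estimated from the sequence itself, one
#' degree of freedom is absorbed: `df = max(#occurring contexts - 1, 1)`
#' (when the marginal is degenerate — a fully one-sided sequence — the
#' statistic is 0 and `p = 1` by convention).
#'
#' @param seq A [choice_sequence()] or character vector of sides, length at
#'   least `order + 1`.
#' @param order Markov order `k` (default 3).
#' @param epsilon Clamp applied to `P` before the logit (default `1e-12`).
#'
#' @return A list of class `perseveration_result` with elements `chi_sq`,
#'   `df`, `p`, `P`, `logitP`, `clamped` (was the clamp active), `order`, `n`.
#' @export
#'
#' @examples
#' markov_perseveration(rep(c("L", "R"), 40))  # strict alternation
markov_perseveration <- function(seq, order = 3, epsilon = 1e-12) {
  ch <- seq_choices(seq)
  k <- as.integer(order)
  stopifnot(k >= 1, epsilon > 0, epsilon < 0.5)
  n <- length(ch)
  if (n < k + 1L)
    stop(sprintf("sequence of length %d is too short for order %d (need >= %d)",
                 n, k, k + 1L), call. = FALSE)
  marg <- c(L = mean(ch == "L"), R = mean(ch == "R"))
  ctx <- vapply(seq_len(n - k),
                function(i) paste(ch[i:(i + k - 1L)], collapse = ""), "")
  nxt <- factor(ch[(k + 1L):n], levels = c("L", "R"))
  obs <- table(factor(ctx), nxt)  # occurring contexts only
  expd <- outer(rowSums(obs), marg)
  keep <- expd > 0
  chi_sq <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  df <- max(nrow(obs) - 1L, 1L)
  p <- if (chi_sq <= 0) 1 else stats::pchisq(chi_sq, df, lower.tail = FALSE)
  P <- 1 - p
  Pc <- min(max(P, epsilon), 1 - epsilon)
  structure(
    list(chi_sq = chi_sq, df = df, p = p, P = P,
         logitP = log(Pc / (1 - Pc)), clamped = !identical(Pc, P),
         order = k, n = n),
    class = "perseveration_result"
  )
}

#' @export
print.perseveration_result <- function(x, ...) {
  cat(sprintf(
    "<perseveration_result> order %d, n = %d\n  chi_sq = %.3f on %d df, p = %.4g\n  P = 1 - p = %.4g, logit[P] = %.3f%s\n",
    x$order, x$n, x$chi_sq, x$df, x$p, x$P, x$logitP,
    if (x$clamped) " (clamped)" else ""))
  invisible(x)
}

#' Per-subject perseveration summary table
#'
#' Applies the full outcome-measure battery to each sequence: Markov
#' perseveration score, pure repetition and alternation counts, side bias and
#' (where baited sides are present) the proportion of correct choices.
#'
#' @param seqs A list of [choice_sequence()] objects (e.g. from
#'   [read_trials()]), or a single one.
#' @param order Markov order passed to [markov_perseveration()].
#'
#' @return A data.frame with one row per subject and columns `subject_id`,
#'   `n_trials`, `chi_sq`, `df`, `p`, `P`, `logitP`, `repetitions`,
#'   `alternations`, `side_bias`, `correct_prop`.
#' @export
perseveration_summary <- function(seqs, order = 3) {
  if (inherits(seqs, "choice_sequence")) seqs <- list(seqs)
  rows <- lapply(seqs, function(s) {
    pr <- markov_perseveration(s, order = order)
    tab <- tetragram_counts(s)
    data.frame(
      subject_id = s$subject_id, n_trials = s$n,
      chi_sq = pr$chi_sq, df = pr$df, p = pr$p, P = pr$P, logitP = pr$logitP,
      repetitions = pure_repetitions(tab),
      alternations = pure_alternations(tab),
      side_bias = side_bias(s),
      correct_prop = if (is.null(s$rewarded)) NA_real_ else mean(s$rewarded),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
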