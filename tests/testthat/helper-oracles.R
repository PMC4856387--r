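# Independent brute-force oracles, deliberately written as plain loops so they
# share no code with the package implementation.

# Explicit 2^k x 2 contingency-table chi-square for order-k sequential
# dependence, expected counts from the whole-sequence marginal.
oracle_markov_chisq <- function(ch, k = 3) {
  sides <- c("L", "R")
  contexts <- do.call(expand.grid, rep(list(sides), k))
  n <- length(ch)
  obs <- matrix(0, nrow = nrow(contexts), ncol = 2,
                dimnames = list(NULL, sides))
  for (i in seq_len(n - k)) {
    row <- 0
    for (j in seq_len(nrow(contexts))) {
      if (all(as.character(unlist(contexts[j, ])) == ch[i:(i + k - 1)])) {
        row <- j
        break
      }
    }
    obs[row, ch[i + k]] <- obs[row, ch[i + k]] + 1
  }
  mL <- sum(ch == "L") / n
  chi <- 0
  n_ctx <- 0
  for (j in seq_len(nrow(contexts))) {
    nc <- sum(obs[j, ])
    if (nc == 0) next
    n_ctx <- n_ctx + 1
    for (x in sides) {
      e <- nc * (if (x == "L") mL else 1 - mL)
      if (e > 0) chi <- chi + (obs[[j, x]] - e)^2 / e
    }
  }
  list(chi_sq = chi, n_contexts = n_ctx)
}

# Windowed tetragram counter by explicit loop.
oracle_tetragrams <- function(ch) {
  counts <- integer(0)
  for (i in seq_len(length(ch) - 3)) {
    g <- paste(ch[i:(i + 3)], collapse = "")
    counts[g] <- (if (g %in% names(counts)) counts[[g]] else 0L) + 1L
  }
  counts
}

# Which sampling intervals does a set of spans touch ([t, t+len) semantics)?
oracle_flagged_intervals <- function(spans, starts, len) {
  flagged <- rep(FALSE, length(starts))
  for (i in seq_along(starts)) {
    for (j in seq_len(nrow(spans))) {
      if (spans$start_s[j] < starts[i] + len && spans$end_s[j] > starts[i])
        flagged[i] <- TRUE
    }
  }
  flagged
}

# All L/R sequences of a given length, as a character matrix (rows = cases).
all_sequences <- function(len) {
  grid <- do.call(expand.grid,
                  c(rep(list(c("L", "R")), len), stringsAsFactors = FALSE))
  as.matrix(grid)
}

random_sides <- function(n) sample(c("L", "R"), n, replace = TRUE)
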