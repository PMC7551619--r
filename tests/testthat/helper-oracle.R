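# Independent brute-force oracles, written against the decision rules as
# stated, deliberately not sharing code with the package implementation.

# Three-branch BET rule, direct scan formulation.
oracle_bet <- function(outcomes, levels) {
  n <- length(levels)
  o <- outcomes
  below1 <- levels[1]^2 / levels[2]              # hypothetical level below
  above_n <- levels[n]^2 / levels[n - 1]         # theoretical level above
  gm <- function(a, b) sqrt(a * b)

  if (o[n]) {
    all_from <- vapply(seq_len(n), function(i) all(o[i:n]), logical(1))
    L <- min(which(all_from))
    lower <- if (L == 1) below1 else levels[L - 1]
    return(list(bet = gm(levels[L], lower),
                rule = if (L == 1) "lowest-extrapolated" else "standard",
                responder = TRUE))
  }
  # top wrong: any maximal run of >= 3 correct necessarily ends below a
  # later incorrect answer; take the run with the lowest start
  run_starts <- which(vapply(seq_len(n - 2), function(i) {
    (i == 1 || !o[i - 1]) && all(o[i:(i + 2)])
  }, logical(1)))
  if (length(run_starts) > 0) {
    s <- run_starts[1]
    lower <- if (s == 1) below1 else levels[s - 1]
    return(list(bet = gm(levels[s], lower), rule = "adaptation",
                responder = TRUE))
  }
  list(bet = gm(levels[n], above_n), rule = "non-responder-imputed",
       responder = FALSE)
}

# All outcome patterns of a given length, as a logical matrix (rows).
all_patterns <- function(n) {
  as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
}

# Closed-form simple linear regression via the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Pooled two-sample t statistic from the textbook formula.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Probability that an independent-guessing panelist (correct w.p. `p` at
# every level) is classified a responder, by exhaustive enumeration.
oracle_guesser_responder_rate <- function(n_levels, p) {
  pats <- all_patterns(n_levels)
  lv <- 10^seq_len(n_levels) # any valid ladder; classification ignores scale
  sum(apply(pats, 1, function(o) {
    pr <- prod(ifelse(o, p, 1 - p))
    if (oracle_bet(o, lv)$responder) pr else 0
  }))
}
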