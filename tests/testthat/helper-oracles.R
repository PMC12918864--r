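# Independent brute-force oracles; deliberately naive, never shared with the
# implementation paths they check.

# O(n^2) pairwise mean-absolute-difference Gini
gini_pairwise <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Welch t from the closed form
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-group log-rank by explicit per-event-time tabulation
logrank_oracle <- function(t1, e1, t2, e2) {
  tm <- c(t1, t2); ev <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  times <- sort(unique(tm[ev == 1]))
  O <- E <- V <- 0
  for (s in times) {
    at_risk <- tm >= s
    n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
    d <- sum(ev == 1 & tm == s); d1 <- sum(ev == 1 & tm == s & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Tiny screen fixture shared across quantification tests
tiny_screen <- function(n_genes = 20, guides = 4, reps = 2, depth = 8000,
                        effects = list(), seed = 11) {
  lib <- make_guide_library(n_genes, guides, seed = seed)
  tr <- screen_truth(lib, effects = effects, seed = seed)
  des <- screen_design(c("outlet4"), replicates = reps)
  sim <- simulate_screen_counts(lib, des, tr, depth = depth)
  list(lib = lib, truth = tr, design = des, counts = sim$counts)
}
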