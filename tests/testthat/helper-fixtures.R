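# regularly spaced SWR event table for pipeline tests
make_events <- function(n, start = 5, spacing = 1, dur = 0.08) {
  ons <- start + (seq_len(n) - 1) * spacing
  event_table(seq_len(n), ons, ons + dur / 2, ons + dur)
}

# brute-force HMM sequence log-likelihood by exhaustive state-path
# enumeration; independent oracle for the forward-backward recursion
brute_force_hmm_ll <- function(y, pi0, A, Lambda) {
  M <- length(pi0)
  Tn <- nrow(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), Tn)))
  lps <- apply(paths, 1, function(z) {
    lp <- log(pi0[z[1]])
    if (Tn > 1)
      for (t in 2:Tn) lp <- lp + log(A[z[t - 1], z[t]])
    for (t in seq_len(Tn))
      lp <- lp + sum(stats::dpois(y[t, ], Lambda[, z[t]], log = TRUE))
    lp
  })
  mx <- max(lps)
  mx + log(sum(exp(lps - mx)))
}

# all permutations of 1:3 (for label matching of 3-component fits)
perms3 <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                 ncol = 3, byrow = TRUE)

# best label-matching accuracy of fitted vs true component labels
match_accuracy <- function(fitted, truth, M = 3) {
  stopifnot(M == 3)
  max(apply(perms3, 1, function(p) mean(p[fitted] == truth)))
}

# best column permutation of a fitted 3-column matrix against truth
match_columns <- function(fitted, truth) {
  costs <- apply(perms3, 1, function(p) sum(abs(fitted[, p] - truth)))
  perms3[which.min(costs), ]
}
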