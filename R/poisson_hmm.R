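# log emission matrix (T x M): sum over cells of Poisson log-pmfs
.hmm_log_emission <- function(y, Lambda) {
  # y: T x N counts, Lambda: N x M expected counts
  y %*% log(Lambda) -
    matrix(colSums(Lambda), nrow(y), ncol(Lambda), byrow = TRUE) -
    rowSums(lgamma(y + 1))
}

# scaled forward-backward for one sequence; returns log-likelihood,
# state posteriors (gamma) and expected transition counts (xi_sum)
.hmm_forward_backward <- function(logB, pi0, A) {
  Tn <- nrow(logB); M <- ncol(logB)
  mx <- apply(logB, 1, max)
  B <- exp(logB - mx)
  alpha <- matrix(0, Tn, M); beta <- matrix(0, Tn, M)
  cs <- numeric(Tn)
  a <- pi0 * B[1, ]
  cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
  if (Tn > 1) for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
  }
  beta[Tn, ] <- 1
  if (Tn > 1) for (t in (Tn - 1):1)
    beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ])) / cs[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, M, M)
  if (Tn > 1) for (t in 1:(Tn - 1)) {
    xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A / cs[t + 1]
    xi_sum <- xi_sum + xi
  }
  list(ll = sum(log(cs)) + sum(mx), gamma = gamma, xi_sum = xi_sum)
}

#' Bin SWR spikes into a count sequence
#'
#' Bins the spikes of `cell_ids` within one SWR into nonoverlapping
#' 15-ms bins starting at onset; the number of bins is
#' `ceiling(duration / bin)`, so the final bin may extend past offset
#' and total spikes in `[onset, onset + T * bin)` are conserved.
#'
#' @param spikes a [spike_table()].
#' @param event one-row [event_table()] (or a list with `onset_s`,
#'   `offset_s`, `event_id`).
#' @param bin_ms bin width (default 15).
#' @param cell_ids cells forming the columns; defaults to all pyramidal
#'   cells present, in sorted order.
#' @return list of class `binned_sequence`: `counts` (T x N integer
#'   matrix), `bin_ms`, `swr_id`, `cell_ids`.
#' @export
bin_swr_spikes <- function(spikes, event, bin_ms = 15, cell_ids = NULL) {
  spikes <- validate_spikes(spikes)
  if (is.null(cell_ids))
    cell_ids <- sort(unique(spikes$cell_id[spikes$cell_class == "pyr"]))
  dur <- event$offset_s - event$onset_s
  Tn <- max(1L, as.integer(ceiling(round(dur / (bin_ms / 1000), 9))))
  edges <- event$onset_s + (0:Tn) * bin_ms / 1000
  counts <- matrix(0L, Tn, length(cell_ids),
                   dimnames = list(NULL, cell_ids))
  sub <- spikes[spikes$cell_id %in% cell_ids &
                  spikes$spike_time_s >= edges[1] &
                  spikes$spike_time_s < edges[Tn + 1], ]
  if (nrow(sub)) {
    b <- findInterval(sub$spike_time_s, edges, rightmost.closed = FALSE)
    for (k in seq_len(nrow(sub)))
      counts[b[k], sub$cell_id[k]] <- counts[b[k], sub$cell_id[k]] + 1L
  }
  structure(list(counts = counts, bin_ms = bin_ms,
                 swr_id = event$event_id, cell_ids = cell_ids),
            class = "binned_sequence")
}

# accept either binned_sequence objects or bare count matrices
.seq_counts <- function(s) if (inherits(s, "binned_sequence")) s$counts else s

#' Fit a Poisson-emission hidden Markov model by EM
#'
#' The sequence model: at each time bin the network occupies one of `M`
#' latent states (first-order Markov), and each cell's spike count is
#' Poisson with a state-specific mean. Parameters (initial distribution
#' `pi`, transition matrix `A`, expected-count matrix `Lambda`, N x M)
#' are estimated by Baum-Welch EM; several random restarts guard
#' against local optima and the best restart by log-likelihood is
#' returned. The log-likelihood is non-decreasing over iterations.
#'
#' @param sequences list of `binned_sequence` objects or T x N count
#'   matrices (shared cell order).
#' @param M number of latent states (the standard choice is 15).
#' @param n_restarts random restarts (default 5).
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter iteration cap per restart.
#' @param seed RNG seed.
#' @param rate_floor lower bound on `Lambda` entries (avoids log 0).
#' @return list of class `poisson_hmm`: `pi`, `A`, `Lambda`,
#'   `loglik` (total over sequences), `ll_trace` of the winning
#'   restart, `n_iter`, `M`.
#' @export
fit_poisson_hmm <- function(sequences, M = 15, n_restarts = 5, tol = 1e-6,
                            max_iter = 500, seed = NULL, rate_floor = 1e-4) {
  if (!is.null(seed)) set.seed(seed)
  ys <- lapply(sequences, .seq_counts)
  if (length(ys) < 1L) stop("need at least one sequence")
  N <- ncol(ys[[1]])
  all_bins <- do.call(rbind, ys)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    # init Lambda from a random hard assignment of bins to states
    assign0 <- sample.int(M, nrow(all_bins), replace = TRUE)
    Lambda <- vapply(seq_len(M), function(j) {
      rows <- all_bins[assign0 == j, , drop = FALSE]
      mu <- if (nrow(rows)) colMeans(rows) else colMeans(all_bins)
      pmax(mu * stats::runif(N, 0.8, 1.2), rate_floor)
    }, numeric(N))
    Lambda <- matrix(Lambda, N, M)
    A <- matrix(1, M, M) + diag(2, M); A <- A / rowSums(A)
    pi0 <- rep(1 / M, M)
    ll_trace <- numeric(0); ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      g1 <- matrix(0, length(ys), M)
      xi_tot <- matrix(0, M, M)
      num <- matrix(0, N, M); den <- numeric(M)
      ll <- 0
      for (s in seq_along(ys)) {
        y <- ys[[s]]
        fb <- .hmm_forward_backward(.hmm_log_emission(y, Lambda), pi0, A)
        ll <- ll + fb$ll
        g1[s, ] <- fb$gamma[1, ]
        xi_tot <- xi_tot + fb$xi_sum
        num <- num + t(y) %*% fb$gamma
        den <- den + colSums(fb$gamma)
      }
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) break
      ll_old <- ll
      pi0 <- colSums(g1) / sum(g1)
      rs <- rowSums(xi_tot)
      A <- xi_tot / pmax(rs, 1e-300)
      A[rs == 0, ] <- 1 / M
      Lambda <- sweep(num, 2, pmax(den, 1e-300), "/")
      Lambda <- pmax(Lambda, rate_floor)
    }
    if (is.null(best) || ll_trace[length(ll_trace)] > best$loglik)
      best <- list(pi = pi0, A = A, Lambda = Lambda,
                   loglik = ll_trace[length(ll_trace)],
                   ll_trace = ll_trace, n_iter = length(ll_trace), M = M)
  }
  structure(best, class = "poisson_hmm")
}

#' Per-bin normalized log-likelihood of a sequence
#'
#' Computes `log P(counts | model)` with the (scaled) forward
#' algorithm, in log space so long sequences do not underflow, and
#' divides by the number of bins.
#'
#' @param seq a `binned_sequence` or T x N count matrix.
#' @param params a `poisson_hmm` fit (or list with `pi`, `A`, `Lambda`).
#' @return normalized log-likelihood (per bin).
#' @export
sequence_loglik <- function(seq, params) {
  y <- .seq_counts(seq)
  fb <- .hmm_forward_backward(.hmm_log_emission(y, params$Lambda),
                              params$pi, params$A)
  fb$ll / nrow(y)
}

#' Cross-quintile sequence-similarity test
#'
#' Fits the sequence model separately to the Q1 and Q5 SWR groups and
#' measures, for each training group, the difference in mean per-bin
#' log-likelihood between the held-out group and the training group:
#' `LL(Q_test) - LL(Q_train)`. Negative values mean the model captures
#' its own quintile's sequences better than the other quintile's. As a
#' control, sequences are randomly reassigned to two groups of the same
#' sizes, models are refitted, and the differences recomputed
#' (`n_shuffles` times); the observed differences are compared
#' one-sidedly against the shuffled distribution.
#'
#' @param q1_seqs,q5_seqs lists of sequences (count matrices or
#'   `binned_sequence`s).
#' @param M number of latent states.
#' @param n_shuffles number of reassignment controls (default 100).
#' @param seed RNG seed.
#' @param ... passed to [fit_poisson_hmm()] (e.g. `n_restarts`, `tol`).
#' @return list with `observed` (named: `train_q1_test_q5`,
#'   `train_q5_test_q1`), `shuffled` (2 x n_shuffles matrix),
#'   `p_values` (one-sided: probability a shuffle is as negative as the
#'   observed), or `skipped = TRUE` when a group has < 2 sequences.
#' @export
cross_quintile_hmm_test <- function(q1_seqs, q5_seqs, M = 15,
                                    n_shuffles = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (length(q1_seqs) < 2L || length(q5_seqs) < 2L)
    return(list(skipped = TRUE, reason = "too_few_sequences"))
  diff_pair <- function(g1, g5) {
    f1 <- fit_poisson_hmm(g1, M = M, ...)
    f5 <- fit_poisson_hmm(g5, M = M, ...)
    ll <- function(seqs, fit) mean(vapply(seqs, sequence_loglik, numeric(1),
                                          params = fit))
    c(train_q1_test_q5 = ll(g5, f1) - ll(g1, f1),
      train_q5_test_q1 = ll(g1, f5) - ll(g5, f5))
  }
  observed <- diff_pair(q1_seqs, q5_seqs)
  pool <- c(q1_seqs, q5_seqs)
  n1 <- length(q1_seqs)
  shuffled <- matrix(NA_real_, 2, n_shuffles,
                     dimnames = list(names(observed), NULL))
  for (b in seq_len(n_shuffles)) {
    idx <- sample(length(pool))
    shuffled[, b] <- diff_pair(pool[idx[seq_len(n1)]], pool[idx[-seq_len(n1)]])
  }
  p_values <- vapply(1:2, function(k) {
    (1 + sum(shuffled[k, ] <= observed[k])) / (n_shuffles + 1)
  }, numeric(1))
  names(p_values) <- names(observed)
  list(observed = observed, shuffled = shuffled, p_values = p_values,
       skipped = FALSE)
}

#' Choose the number of latent states by two-fold cross-validation
#'
#' Splits the sequences into two folds, fits each candidate `M` on one
#' fold and scores mean per-bin log-likelihood on the other (both
#' directions, averaged).
#'
#' @param sequences list of sequences.
#' @param M_grid candidate state counts.
#' @param seed RNG seed.
#' @param ... passed to [fit_poisson_hmm()].
#' @return list with `M_grid`, `cv_loglik`, `M_star` (argmax).
#' @export
cv_select_states <- function(sequences, M_grid = c(5, 10, 15, 20),
                             seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sequences)
  fold <- sample(rep(1:2, length.out = n))
  score <- vapply(M_grid, function(M) {
    mean(vapply(1:2, function(f) {
      fit <- fit_poisson_hmm(sequences[fold != f], M = M, ...)
      mean(vapply(sequences[fold == f], sequence_loglik, numeric(1),
                  params = fit))
    }, numeric(1)))
  }, numeric(1))
  list(M_grid = M_grid, cv_loglik = score, M_star = M_grid[which.max(score)])
}
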