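# window means on half-open absolute-time intervals [from, to)
.window_mean <- function(trace, from_s, to_s) {
  mean(trace_window(trace, from_s, to_s)$samples)
}

#' Detect action potentials in a membrane-potential trace
#'
#' Spikes are peaks during periods with Vm above the threshold: within
#' each supra-threshold excursion, every local maximum counts as one
#' spike (a monotonic excursion contributes its single maximum).
#'
#' @param vm a [continuous_trace()] in mV.
#' @param threshold_mv detection threshold (default -20 mV).
#' @return numeric vector of spike times (s).
#' @export
detect_vm_spikes <- function(vm, threshold_mv = -20) {
  x <- vm$samples
  runs <- .runs(x > threshold_mv)
  if (nrow(runs) == 0L) return(numeric(0))
  tt <- trace_times(vm)
  out <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    if (length(seg) < 3L) {
      out <- c(out, tt[seg[which.max(x[seg])]])
      next
    }
    xi <- x[seg]
    is_peak <- c(FALSE, xi[2:(length(xi) - 1)] > xi[1:(length(xi) - 2)] &
                   xi[2:(length(xi) - 1)] >= xi[3:length(xi)], FALSE)
    if (!any(is_peak)) is_peak[which.max(xi)] <- TRUE
    out <- c(out, tt[seg[is_peak]])
  }
  sort(out)
}

#' Truncate spikes from a Vm trace by linear interpolation
#'
#' Subthreshold averaging requires spike-free traces. Following the
#' standard recipe: (i) the raw trace is smoothed with a 1-ms moving
#' average, (ii) the first index at which the rate of change of the
#' smoothed trace exceeds 4 V/s marks a spike's leading edge, and
#' (iii) the trace is linearly interpolated from the leading edge until
#' the first time point whose (smoothed) Vm falls below the edge value.
#' Edges that follow within an ongoing interpolation segment (complex
#' spikes) each start their own segment anchored at their own edge
#' value. If a spike never returns below its edge value before the
#' trace ends, interpolation runs to the end and a warning is issued.
#'
#' The operation is idempotent: a truncated trace contains no 4 V/s
#' edges, so a second pass returns it unchanged.
#'
#' @param vm a [continuous_trace()] in mV.
#' @param rate_thresh_v_per_s leading-edge threshold (V/s).
#' @param smooth_ms moving-average window before edge detection (ms).
#' @return a spike-free [continuous_trace()].
#' @export
truncate_spikes <- function(vm, rate_thresh_v_per_s = 4, smooth_ms = 1) {
  x <- vm$samples
  n <- length(x)
  sm <- .moving_avg(x, smooth_ms / 1000, vm$rate)
  # centered first difference x rate, in mV/s -> compare in V/s
  dvdt <- c(0, (sm[3:n] - sm[1:(n - 2)]) * vm$rate / 2, 0) / 1000
  out <- x
  i <- 2L
  while (i < n) {
    if (dvdt[i] > rate_thresh_v_per_s) {
      edge_val <- sm[i]
      j <- i + 1L
      while (j <= n && sm[j] > edge_val) j <- j + 1L
      if (j > n) {
        warning("spike at t = ", signif(trace_times(vm)[i], 6),
                " s never returns below its edge value; truncated to end")
        j <- n
      }
      out[i:j] <- seq(out[i], out[j], length.out = j - i + 1L)
      # re-smooth locally so a complex-spike edge inside [i, j] is
      # re-examined on the interpolated trace
      sm[i:j] <- out[i:j]
      i <- j
    }
    i <- i + 1L
  }
  continuous_trace(out, vm$rate, t0 = vm$t0, units = vm$units)
}

#' Pre-SWR membrane-potential change
#'
#' Finds the minimum Vm in the 50 ms before SWR onset, averages Vm in a
#' +/- 25 ms window around that minimum, and subtracts the baseline Vm
#' (the mean 2 to 1 s before onset). Negative values indicate a
#' pre-ripple hyperpolarization. The averaging window is applied
#' literally even when it extends past onset into the SWR.
#'
#' @param vm_sub a spike-truncated [continuous_trace()] covering at
#'   least `[onset - 2 s, onset + 25 ms]`.
#' @param onset_s SWR onset time (s).
#' @return the Vm change in mV, or `NA` (with a `"reason"` attribute)
#'   when the trace does not cover the required windows.
#' @export
compute_delta_vm_pre <- function(vm_sub, onset_s) {
  res <- try({
    baseline <- .window_mean(vm_sub, onset_s - 2, onset_s - 1)
    pre <- trace_window(vm_sub, onset_s - 0.050, onset_s)
    t_min <- trace_times(pre)[which.min(pre$samples)]
    win <- trace_window(vm_sub, t_min - 0.025, t_min + 0.025)
    mean(win$samples) - baseline
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_coverage"
    return(out)
  }
  res
}

#' Depolarization peak time relative to SWR onset
#'
#' Time of the highest Vm between -20 ms and +120 ms around onset, in
#' ms relative to onset. Ties go to the earliest sample.
#'
#' @param vm_sub a spike-truncated [continuous_trace()].
#' @param onset_s SWR onset time (s).
#' @return peak time in ms, or `NA` with a `"reason"` attribute when
#'   the window is not covered.
#' @export
compute_depol_peak <- function(vm_sub, onset_s) {
  res <- try({
    win <- trace_window(vm_sub, onset_s - 0.020,
                        onset_s + 0.120 + 1 / vm_sub$rate)
    (trace_times(win)[which.max(win$samples)] - onset_s) * 1000
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out <- NA_real_
    attr(out, "reason") <- "insufficient_coverage"
    return(out)
  }
  res
}

#' Build per-SWR intracellular records for one cell
#'
#' For each SWR with full `[-2 s, +120 ms]` coverage: baseline Vm, the
#' pre-SWR Vm change, the depolarization peak time, and first-spike
#' statistics (from the raw, un-truncated trace). Events without
#' coverage are skipped and listed with reason codes.
#'
#' @param vm raw [continuous_trace()] in mV.
#' @param events an [event_table()] of SWRs.
#' @param cell_id label copied into the records.
#' @return data.frame with columns `cell_id`, `swr_id`, `baseline_mv`,
#'   `delta_vm_pre_mv`, `depol_peak_time_ms`, `first_spike_time_ms`,
#'   `n_spikes_in_swr`, `active` (fired in any SWR); attribute
#'   `skipped` lists skipped events.
#' @export
delta_vm_records <- function(vm, events, cell_id = "cell1") {
  events <- validate_events(events)
  spikes <- detect_vm_spikes(vm)
  vm_sub <- truncate_spikes(vm)
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    dvm <- compute_delta_vm_pre(vm_sub, on)
    pk <- compute_depol_peak(vm_sub, on)
    if (is.na(dvm) || is.na(pk)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(swr_id = events$event_id[i], reason = "insufficient_coverage")
      next
    }
    in_swr <- spikes[spikes >= on & spikes <= off]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = cell_id, swr_id = events$event_id[i],
      baseline_mv = .window_mean(vm_sub, on - 2, on - 1),
      delta_vm_pre_mv = as.numeric(dvm), depol_peak_time_ms = as.numeric(pk),
      first_spike_time_ms = if (length(in_swr)) (in_swr[1] - on) * 1000
      else NA_real_,
      n_spikes_in_swr = length(in_swr))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), swr_id = integer(0),
               baseline_mv = numeric(0), delta_vm_pre_mv = numeric(0),
               depol_peak_time_ms = numeric(0),
               first_spike_time_ms = numeric(0), n_spikes_in_swr = integer(0))
  out$active <- any(out$n_spikes_in_swr >= 1)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(swr_id = integer(0), reason = character(0))
  out
}

#' Event-triggered average of a continuous trace
#'
#' Aligns the trace to event onsets and additively averages across
#' events. Events whose window is not fully covered are dropped.
#'
#' @param trace a [continuous_trace()].
#' @param onsets event onset times (s).
#' @param window_s length-2 window around onset, e.g. `c(-0.1, 0.2)`.
#' @return a [continuous_trace()] with `t0 = window_s[1]` (time relative
#'   to onset); attribute `n_events` gives the number of contributors.
#' @export
swr_triggered_average <- function(trace, onsets, window_s = c(-0.1, 0.2)) {
  n_win <- round((window_s[2] - window_s[1]) * trace$rate)
  acc <- numeric(n_win); used <- 0L
  for (on in onsets) {
    seg <- try(trace_window(trace, on + window_s[1], on + window_s[2]),
               silent = TRUE)
    if (inherits(seg, "try-error") || length(seg$samples) != n_win) next
    acc <- acc + seg$samples
    used <- used + 1L
  }
  if (used == 0L) stop("no event window fully covered by the trace")
  out <- continuous_trace(acc / used, trace$rate, t0 = window_s[1],
                          units = trace$units)
  attr(out, "n_events") <- used
  out
}

#' Synaptic conductance from a voltage-clamp current
#'
#' Converts a clamp current around an SWR into a conductance time
#' course: the mean current 2-1 s before onset is subtracted, and the
#' remainder is divided by the driving force (holding potential minus
#' reversal potential). With current in pA and potentials in mV the
#' result is in nS. Default holding/reversal pairs are (-70, 0) mV for
#' excitatory and (+10, -90) mV for inhibitory conductances.
#'
#' @param current a [continuous_trace()] in pA.
#' @param hold_mv holding potential (mV).
#' @param e_rev_mv reversal potential (mV); must differ from `hold_mv`.
#' @param onset_s SWR onset (s).
#' @param window_s window of the returned conductance trace, relative
#'   to onset.
#' @param kind `"EPSG"` or `"IPSG"`; inferred from the sign of the
#'   driving force when omitted.
#' @return list with `g` (conductance [continuous_trace()], nS, t0
#'   relative to onset), `kind`, `hold_mv`, `e_rev_mv`, `baseline_pa`.
#' @export
compute_conductance <- function(current, hold_mv, e_rev_mv, onset_s,
                                window_s = c(-2, 0.4), kind = NULL) {
  if (hold_mv == e_rev_mv)
    stop("holding potential must differ from the reversal potential")
  baseline <- .window_mean(current, onset_s - 2, onset_s - 1)
  seg <- trace_window(current, onset_s + window_s[1], onset_s + window_s[2])
  g <- (seg$samples - baseline) / (hold_mv - e_rev_mv)  # pA / mV = nS
  if (is.null(kind)) kind <- if (hold_mv < e_rev_mv) "EPSG" else "IPSG"
  list(g = continuous_trace(g, seg$rate, t0 = window_s[1], units = "nS"),
       kind = kind, hold_mv = hold_mv, e_rev_mv = e_rev_mv,
       baseline_pa = baseline)
}

#' Triplet rank-order permutation test
#'
#' For three simultaneously recorded cells, selects the SWRs whose
#' depolarization peaks occur in cell order 1 -> 2 -> 3 and tabulates
#' the frequencies of the six possible orders of the pre-SWR Vm
#' changes across those SWRs. A null distribution is built by randomly
#' exchanging the three Vm-change values across cells within each SWR
#' (`n_perm` simulated trials); orders whose observed frequency falls
#' outside the null's central 95% interval are flagged.
#'
#' @param delta n_swr x 3 matrix of pre-SWR Vm changes (mV).
#' @param peaks n_swr x 3 matrix of depolarization peak times (ms).
#' @param n_perm number of permutation trials.
#' @param seed RNG seed.
#' @param min_swr minimum number of complete SWRs required.
#' @return list with `orders` (the 6 labels, "123" = cell1 most
#'   negative first), `freq`, `lower`, `upper` (95% permutation band),
#'   `flag` (+1 above band, -1 below, 0 inside), `n_used`.
#' @export
triplet_order_test <- function(delta, peaks, n_perm = 10000, seed = NULL,
                               min_swr = 30) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(ncol(delta) == 3, ncol(peaks) == 3)
  complete <- stats::complete.cases(delta) & stats::complete.cases(peaks)
  if (sum(complete) < min_swr)
    stop("need at least ", min_swr, " SWRs with all three cells measured")
  delta <- delta[complete, , drop = FALSE]
  peaks <- peaks[complete, , drop = FALSE]
  sel <- peaks[, 1] < peaks[, 2] & peaks[, 2] < peaks[, 3]
  if (sum(sel) < 5)
    stop("fewer than 5 SWRs with depolarization peak order 1 -> 2 -> 3")
  d <- delta[sel, , drop = FALSE]
  n <- nrow(d)
  perms <- .permutations3()
  all_orders <- apply(perms, 1, paste, collapse = "")
  # identify a row's order by (argmin, argmax); ties go to the earliest
  # cell, matching the deterministic tie rule
  order_ids <- function(m) {
    first <- max.col(-m, ties.method = "first")
    last <- max.col(m, ties.method = "last")
    (first - 1L) * 3L + last
  }
  id_of_order <- (perms[, 1] - 1L) * 3L + perms[, 3]
  count6 <- function(ids) tabulate(match(ids, id_of_order), nbins = 6)
  freq <- count6(order_ids(d)) / n
  null_freq <- matrix(0, n_perm, 6)
  row_idx <- seq_len(n)
  for (b in seq_len(n_perm)) {
    pick <- sample.int(6, n, replace = TRUE)
    shuffled <- d
    for (k in 1:3) shuffled[, k] <- d[cbind(row_idx, perms[pick, k])]
    null_freq[b, ] <- count6(order_ids(shuffled)) / n
  }
  lower <- apply(null_freq, 2, stats::quantile, 0.025)
  upper <- apply(null_freq, 2, stats::quantile, 0.975)
  flag <- ifelse(freq > upper, 1L, ifelse(freq < lower, -1L, 0L))
  list(orders = all_orders, freq = freq, lower = lower, upper = upper,
       flag = flag, n_used = n)
}

.permutations3 <- function() {
  matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1), ncol = 3, byrow = TRUE)
}

#' Pairwise correlations of pre-SWR Vm changes and peak times
#'
#' For every cell pair, computes the Pearson correlation across shared
#' SWRs of (a) the pre-SWR Vm changes and (b) the depolarization peak
#' times, with two-sided t-tests of the correlation coefficients. A
#' second-level correlation relates the two sets of pair coefficients
#' (and, when given, pair distance).
#'
#' @param delta n_swr x n_cells matrix of pre-SWR Vm changes; `NA`
#'   marks SWRs where a cell was not measured.
#' @param peaks n_swr x n_cells matrix of depolarization peak times.
#' @param distances_um optional n_cells x n_cells matrix of soma
#'   distances.
#' @param min_shared minimum shared SWRs for a pair to enter.
#' @return list with `pairs` (data.frame: cell indices, `r_delta`,
#'   `p_delta`, `r_peak`, `p_peak`, `n`, `distance_um`) and
#'   `second_level` (`cor.test` of `r_delta` vs `r_peak` across pairs,
#'   or `NULL` with < 3 pairs).
#' @export
pairwise_vm_correlations <- function(delta, peaks, distances_um = NULL,
                                     min_shared = 10) {
  nc <- ncol(delta)
  stopifnot(ncol(peaks) == nc)
  out <- list()
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    sh <- stats::complete.cases(delta[, c(i, j)]) &
      stats::complete.cases(peaks[, c(i, j)])
    if (sum(sh) < min_shared) next
    td <- stats::cor.test(delta[sh, i], delta[sh, j])
    tp <- stats::cor.test(peaks[sh, i], peaks[sh, j])
    out[[length(out) + 1L]] <- data.frame(
      cell_i = i, cell_j = j, n = sum(sh),
      r_delta = unname(td$estimate), p_delta = td$p.value,
      r_peak = unname(tp$estimate), p_peak = tp$p.value,
      distance_um = if (is.null(distances_um)) NA_real_
      else distances_um[i, j])
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(cell_i = integer(0), cell_j = integer(0), n = integer(0),
               r_delta = numeric(0), p_delta = numeric(0),
               r_peak = numeric(0), p_peak = numeric(0),
               distance_um = numeric(0))
  second <- if (nrow(pairs) >= 3)
    stats::cor.test(pairs$r_delta, pairs$r_peak) else NULL
  list(pairs = pairs, second_level = second)
}
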