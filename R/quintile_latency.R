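#' Peri-event time histogram around SWR onsets
#'
#' Bins a cell's spikes relative to event onsets (2.5-ms bins by
#' default) and normalizes counts to a rate in Hz by the number of
#' events times the bin width.
#'
#' @param spike_times numeric vector of spike times (s) for one cell.
#' @param onsets event onset times (s).
#' @param window_ms length-2 window around onset in ms.
#' @param bin_ms bin width in ms.
#' @param cell_id optional label.
#' @return object of class `peth`: `bin_edges_ms`, `centers_ms`,
#'   `rate_hz`, `peak_time_ms` (`NA` and `peak_defined = FALSE` when
#'   the histogram is empty), `n_events`, `cell_id`.
#' @export
compute_peth <- function(spike_times, onsets, window_ms = c(-200, 200),
                         bin_ms = 2.5, cell_id = NA_character_) {
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  rel <- unlist(lapply(onsets, function(on) {
    (spike_times[spike_times >= on + window_ms[1] / 1000 &
                   spike_times < on + window_ms[2] / 1000] - on) * 1000
  }))
  counts <- if (length(rel))
    tabulate(findInterval(rel, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1L)
  else rep(0, length(edges) - 1L)
  rate <- counts / (length(onsets) * bin_ms / 1000)
  centers <- edges[-length(edges)] + bin_ms / 2
  has_peak <- any(counts > 0)
  structure(list(cell_id = cell_id, bin_edges_ms = edges,
                 centers_ms = centers, rate_hz = rate,
                 peak_time_ms = if (has_peak) centers[which.max(rate)]
                 else NA_real_,
                 peak_defined = has_peak, n_events = length(onsets)),
            class = "peth")
}

#' Select interneurons firing before SWR onset
#'
#' Given PETH peak firing times, returns the cells whose peak time lies
#' more than `criterion_sd` SDs below the population mean peak time
#' (i.e. cells that fire unusually early relative to onset). With zero
#' spread across cells nothing is selected. An optional `top_k`
#' restricts the result to the k most negative peak times.
#'
#' @param peak_times_ms named numeric vector of PETH peak times, one
#'   per interneuron.
#' @param criterion_sd selection threshold in SD units (default 1.5).
#' @param top_k optional cap: intersect with the `top_k` most negative.
#' @return character vector of selected interneuron ids.
#' @export
select_pre_swr_interneurons <- function(peak_times_ms, criterion_sd = 1.5,
                                        top_k = NULL) {
  pk <- peak_times_ms[is.finite(peak_times_ms)]
  if (length(pk) < 2L) return(character(0))
  s <- stats::sd(pk)
  if (!is.finite(s) || s == 0) return(character(0))
  cut <- mean(pk) - criterion_sd * s
  sel <- names(pk)[pk < cut]
  if (!is.null(top_k)) {
    most_neg <- names(sort(pk))[seq_len(min(top_k, length(pk)))]
    sel <- intersect(sel, most_neg)
  }
  sel
}

#' Gaussian-kernel smoothed firing rate
#'
#' Convolves a spike train with a Gaussian kernel specified by its full
#' width at half maximum (sigma = FWHM / (2 sqrt(2 ln 2))). The
#' integral of the returned rate equals the spike count.
#'
#' @param spike_times spike times (s).
#' @param fwhm_ms kernel FWHM in ms (default 15).
#' @param rate_hz sampling rate of the returned rate trace.
#' @param t_range length-2 time range (s) of the output; defaults to
#'   the spike range padded by 4 sigma.
#' @return a [continuous_trace()] in Hz.
#' @export
smoothed_rate <- function(spike_times, fwhm_ms = 15, rate_hz = 1000,
                          t_range = NULL) {
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2)))
  if (is.null(t_range)) {
    if (length(spike_times) == 0L) stop("need spikes or an explicit t_range")
    t_range <- range(spike_times) + c(-4, 4) * sigma
  }
  dt <- 1 / rate_hz
  grid <- seq(t_range[1], t_range[2], by = dt)
  counts <- numeric(length(grid))
  keep <- spike_times >= t_range[1] & spike_times <= t_range[2]
  idx <- round((spike_times[keep] - t_range[1]) * rate_hz) + 1L
  idx <- pmin(pmax(idx, 1L), length(grid))
  for (i in idx) counts[i] <- counts[i] + 1
  half <- ceiling(4 * sigma / dt)
  kern <- stats::dnorm(seq(-half, half) * dt, 0, sigma)
  padded <- c(numeric(half), counts, numeric(half))
  sm <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + length(grid))]
  continuous_trace(as.numeric(sm), rate_hz, t0 = t_range[1], units = "Hz")
}

#' Pre-SWR firing rate estimate
#'
#' Mean of the smoothed rate over the 30-ms window immediately before
#' event onset.
#'
#' @param rate_trace a rate [continuous_trace()] from [smoothed_rate()].
#' @param onset_s SWR onset (s).
#' @param window_ms pre-onset window length in ms (default 30).
#' @return rate in Hz (`NA` if the window is not covered).
#' @export
pre_swr_rate <- function(rate_trace, onset_s, window_ms = 30) {
  res <- try(.window_mean(rate_trace, onset_s - window_ms / 1000, onset_s),
             silent = TRUE)
  if (inherits(res, "try-error")) NA_real_ else res
}

#' Group SWRs into quintiles of pre-SWR firing rate
#'
#' Ranks events by an interneuron's pre-SWR rate and splits them into
#' five near-equal groups (sizes differing by at most 1). Q1 holds the
#' highest rates, Q5 the lowest. Ties are broken by a stable sort on
#' (rate, event index) so labels are deterministic.
#'
#' @param pre_rates_hz per-SWR pre-onset rates.
#' @param swr_id optional event ids (defaults to the index).
#' @return data.frame `swr_id`, `pre_rate_hz`, `quintile` (factor
#'   Q1..Q5).
#' @export
assign_quintiles <- function(pre_rates_hz, swr_id = seq_along(pre_rates_hz)) {
  n <- length(pre_rates_hz)
  if (n < 5) stop("need at least 5 SWRs to form quintiles")
  if (any(!is.finite(pre_rates_hz))) stop("pre-SWR rates must be finite")
  ord <- order(-pre_rates_hz, seq_len(n))   # stable: rate desc, index asc
  qlab <- integer(n)
  qlab[ord] <- ceiling(seq_len(n) * 5 / n)
  data.frame(swr_id = swr_id, pre_rate_hz = pre_rates_hz,
             quintile = factor(paste0("Q", qlab),
                               levels = paste0("Q", 1:5)))
}

#' First-spike latency and rank order within SWRs
#'
#' For every pyramidal cell and SWR: the latency from onset to the
#' cell's first spike inside `[onset, offset]`, and the cell's rank
#' order — its normalized temporal position among all pyramidal cells
#' participating in that SWR, 0 for the first and 1 for the last
#' (undefined when only one cell participates).
#'
#' @param spikes a [spike_table()] (only `cell_class == "pyr"` rows are
#'   used).
#' @param events an [event_table()] of SWRs.
#' @return data.frame `swr_id`, `cell_id`, `latency_ms`, `rank`,
#'   `n_participants`.
#' @export
spike_latency_and_rank <- function(spikes, events) {
  spikes <- validate_spikes(spikes)
  events <- validate_events(events)
  pyr <- spikes[spikes$cell_class == "pyr", ]
  out <- list()
  for (i in seq_len(nrow(events))) {
    on <- events$onset_s[i]; off <- events$offset_s[i]
    inwin <- pyr[pyr$spike_time_s >= on & pyr$spike_time_s <= off, ]
    if (nrow(inwin) == 0L) next
    first <- tapply(inwin$spike_time_s, inwin$cell_id, min)
    first <- first[!is.na(first)]
    np <- length(first)
    pos <- rank(first, ties.method = "first")
    out[[length(out) + 1L]] <- data.frame(
      swr_id = events$event_id[i], cell_id = names(first),
      latency_ms = (as.numeric(first) - on) * 1000,
      rank = if (np > 1) (pos - 1) / (np - 1) else NA_real_,
      n_participants = np)
  }
  if (length(out)) {
    res <- do.call(rbind, out); rownames(res) <- NULL; res
  } else data.frame(swr_id = integer(0), cell_id = character(0),
                    latency_ms = numeric(0), rank = numeric(0),
                    n_participants = integer(0))
}

#' Quintile latency shuffle test
#'
#' Tests whether a pyramidal cell's first-spike latency differs between
#' the highest (Q1) and lowest (Q5) pre-SWR interneuron-rate quintiles.
#' The observed statistic is mean(Q1 latency) - mean(Q5 latency);
#' the null distribution is built by shuffling latencies across
#' quintile labels (`n_shuffle` permutations, group sizes preserved);
#' the result is significant when the observed difference falls outside
#' the null's central 95% interval.
#'
#' @param latencies_ms per-SWR first-spike latency; `NA` where the
#'   cell did not fire.
#' @param grouping data.frame from [assign_quintiles()] aligned with
#'   `latencies_ms` (same event order).
#' @param n_shuffle number of shuffles (default 500).
#' @param seed RNG seed.
#' @return list with `observed_ms` (Q1 - Q5), `null_ms`, `ci`,
#'   `significant`, `n_q1`, `n_q5`; or, when a quintile has no latency,
#'   `skipped = TRUE` with a `reason`.
#' @export
quintile_latency_test <- function(latencies_ms, grouping, n_shuffle = 500,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(latencies_ms) == nrow(grouping))
  ok <- !is.na(latencies_ms)
  lat <- latencies_ms[ok]
  lab <- grouping$quintile[ok]
  n1 <- sum(lab == "Q1"); n5 <- sum(lab == "Q5")
  if (n1 == 0L || n5 == 0L)
    return(list(skipped = TRUE, reason = "empty_quintile",
                n_q1 = n1, n_q5 = n5))
  obs <- mean(lat[lab == "Q1"]) - mean(lat[lab == "Q5"])
  null <- vapply(seq_len(n_shuffle), function(b) {
    sl <- sample(lat)
    mean(sl[lab == "Q1"]) - mean(sl[lab == "Q5"])
  }, numeric(1))
  ci <- stats::quantile(null, c(0.025, 0.975))
  list(observed_ms = obs, null_ms = null, ci = ci,
       significant = obs < ci[1] || obs > ci[2],
       n_q1 = n1, n_q5 = n5, skipped = FALSE)
}

#' Within-SWR firing rate per quintile
#'
#' Mean within-event firing rate (spikes / event duration) of one
#' pyramidal cell, averaged within each quintile.
#'
#' @param spike_times the cell's spike times (s).
#' @param grouping data.frame from [assign_quintiles()], `swr_id`
#'   matching `events$event_id`.
#' @param events an [event_table()].
#' @return named numeric vector of mean rates (Hz), Q1..Q5.
#' @export
quintile_firing_rate <- function(spike_times, grouping, events) {
  events <- validate_events(events)
  rate <- vapply(seq_len(nrow(events)), function(i) {
    dur <- events$offset_s[i] - events$onset_s[i]
    sum(spike_times >= events$onset_s[i] &
          spike_times <= events$offset_s[i]) / dur
  }, numeric(1))
  m <- match(grouping$swr_id, events$event_id)
  tapply(rate[m], grouping$quintile, mean, default = NA_real_)
}

#' SWR duration per quintile
#'
#' @param grouping data.frame from [assign_quintiles()].
#' @param events an [event_table()] with matching `event_id`.
#' @return named numeric vector of mean durations (s), Q1..Q5; empty
#'   quintiles yield `NA` and are reported in the `"empty"` attribute.
#' @export
swr_duration_by_quintile <- function(grouping, events) {
  events <- validate_events(events)
  m <- match(grouping$swr_id, events$event_id)
  dur <- events$offset_s[m] - events$onset_s[m]
  out <- tapply(dur, grouping$quintile, mean, default = NA_real_)
  attr(out, "empty") <- names(out)[is.na(out)]
  out
}
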