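# --- shared helpers ----------------------------------------------------

# contiguous TRUE runs of a logical vector -> matrix of (start, end) indices
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# centered moving average with the requested window in seconds
.moving_avg <- function(x, win_s, rate) {
  w <- max(1L, round(win_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  y <- as.numeric(stats::filter(x, k, sides = 2, circular = FALSE))
  # fill the edges with shrinking windows so length is preserved
  half <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in seq_len(half)) {
    y[i] <- mean(x[1:(i + half)])
    y[n - i + 1L] <- mean(x[(n - i + 1L - half):n])
  }
  y
}

# from each peak run, walk outward until the statistic drops below the
# edge threshold; returns unique, overlap-merged (start, end) intervals
.walk_out <- function(peak_runs, stat, edge_level) {
  n <- length(stat)
  ev <- t(apply(peak_runs, 1, function(q) {
    a <- q[1]; while (a > 1L && stat[a - 1L] >= edge_level) a <- a - 1L
    b <- q[2]; while (b < n && stat[b + 1L] >= edge_level) b <- b + 1L
    c(a, b)
  }))
  ev <- unique(ev)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  if (nrow(ev) < 2L) return(ev)
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    if (ev[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], ev[i, 2])
    else out <- rbind(out, ev[i, , drop = FALSE])
  }
  out
}

# baseline mean/SD of a detection statistic, iteratively re-estimated
# with suprathreshold stretches (dilated by dilate_s) excluded so the
# events themselves do not inflate the estimate
.baseline_stats <- function(stat, thresh_sd, rate, dilate_s = 0.1,
                            n_iter = 3) {
  keep <- rep(TRUE, length(stat))
  mu <- mean(stat); s <- stats::sd(stat)
  dil <- round(dilate_s * rate)
  for (pass in seq_len(n_iter)) {
    mu_new <- mean(stat[keep]); s_new <- stats::sd(stat[keep])
    if (!is.finite(s_new) || s_new <= 0) break
    mu <- mu_new; s <- s_new
    above <- .runs((stat - mu) / s > thresh_sd)
    if (nrow(above) == 0L) break
    keep <- rep(TRUE, length(stat))
    for (i in seq_len(nrow(above)))
      keep[max(1L, above[i, 1] - dil):
             min(length(stat), above[i, 2] + dil)] <- FALSE
    if (sum(keep) < 100L) break
  }
  c(mu = mu, sd = s)
}

# ensure the trace is at (or near) the probe working rate
.to_rate <- function(trace, rate_hz = 1250) {
  if (trace$rate > rate_hz * 1.0001) downsample(trace, rate_hz) else trace
}

.runs_to_events <- function(runs, stat, trace, sd_base) {
  if (nrow(runs) == 0L)
    return(event_table())
  tt <- trace_times(trace)
  peaks <- numeric(nrow(runs)); power <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, 1]:runs[i, 2]
    j <- seg[which.max(stat[seg])]
    peaks[i] <- tt[j]
    power[i] <- stat[j] / sd_base
  }
  # runs are in time order already, so rows align after validation
  ev <- event_table(event_id = seq_len(nrow(runs)), onset_s = tt[runs[, 1]],
                    peak_s = peaks, offset_s = tt[runs[, 2]])
  ev$peak_power <- power
  ev
}

#' SWR detection for patch-clamp sessions (filtered-trace threshold)
#'
#' Band-passes the LFP to the 100-250 Hz ripple band, forms a smoothed
#' rectified envelope, and detects events where the envelope exceeds
#' `threshold_sd` times a robust estimate of the baseline noise SD
#' (median absolute deviation scaled to the Gaussian SD, re-estimated
#' once with detected events excluded so the events themselves do not
#' inflate the baseline). Event boundaries are refined by walking
#' outward from each detection to the crossings of `edge_sd` x SD, so
#' onset times track the leading edge of the ripple rather than the
#' point where it becomes strong; events closer than the merge gap are
#' merged.
#'
#' Traces sampled above 1250 Hz are first downsampled to 1250 Hz, which
#' keeps the full 100-250 Hz band below Nyquist.
#'
#' @param lfp a [continuous_trace()] of at least 5 s (noise estimation).
#' @param threshold_sd detection threshold in baseline-SD units.
#' @param edge_sd boundary threshold for onset/offset refinement.
#' @param band ripple band in Hz.
#' @param smooth_ms envelope moving-average window (ms).
#' @param merge_gap_ms events separated by less than this are merged.
#' @return an [event_table()]; the `peak_power` column gives the
#'   envelope maximum in SD units.
#' @export
detect_swr_patch <- function(lfp, threshold_sd = 3, edge_sd = 1,
                             band = c(100, 250), smooth_ms = 8,
                             merge_gap_ms = 30) {
  if (trace_duration(lfp) < 5)
    stop("need at least 5 s of LFP to estimate baseline noise")
  lfp <- .to_rate(lfp, 1250)
  filt <- bandpass(lfp, band[1], band[2])
  env <- .moving_avg(abs(filt$samples), smooth_ms / 1000, filt$rate)
  sd1 <- stats::mad(filt$samples)         # mad() includes the 1.4826 scale
  runs <- .runs(env > threshold_sd * sd1)
  keep <- rep(TRUE, length(env))
  if (nrow(runs) > 0L) {
    dil <- round(0.1 * filt$rate)
    for (i in seq_len(nrow(runs)))
      keep[max(1L, runs[i, 1] - dil):
             min(length(env), runs[i, 2] + dil)] <- FALSE
  }
  sd2 <- stats::mad(filt$samples[keep])
  if (!is.finite(sd2) || sd2 <= 0) sd2 <- sd1
  runs <- .runs(env > threshold_sd * sd2)
  if (nrow(runs) == 0L) return(event_table())
  ev <- .walk_out(runs, env, edge_sd * sd2)
  gap <- round(merge_gap_ms / 1000 * filt$rate)
  if (nrow(ev) > 1L) {
    out <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev[i, 1] - out[nrow(out), 2] < gap)
        out[nrow(out), 2] <- max(out[nrow(out), 2], ev[i, 2])
      else out <- rbind(out, ev[i, , drop = FALSE])
    }
    ev <- out
  }
  .runs_to_events(ev, env, filt, sd2)
}

#' SWR detection for silicon-probe sessions (normalized squared signal)
#'
#' Downsamples to 1250 Hz, band-passes 130-200 Hz with a fourth-order
#' type-I Chebyshev filter, squares the filtered signal, smooths it,
#' and z-scores it ("normalized squared signal"). The normalization
#' mean and SD are re-estimated with suprathreshold stretches excluded
#' so the ripples themselves do not inflate the baseline. Peaks are
#' detected at `peak_sd` SDs above the mean; each event's start and
#' stop are the surrounding crossings of `edge_sd`. Events outside the
#' 20-200 ms duration limits are discarded, as are events co-detected
#' on an optional noise channel (interpreted as false positives, e.g.
#' EMG artifacts).
#'
#' @param lfp a [continuous_trace()] of at least 5 s.
#' @param peak_sd peak threshold in SD units of the normalized squared
#'   signal.
#' @param edge_sd boundary threshold (SD units).
#' @param dur_s length-2 duration limits in seconds.
#' @param noise_channel optional [continuous_trace()]; events also
#'   detected there are removed.
#' @param band ripple band in Hz.
#' @param smooth_ms smoothing window for the squared signal (ms).
#' @return an [event_table()] with `peak_power` in SD units.
#' @export
detect_swr_probe <- function(lfp, peak_sd = 5, edge_sd = 2,
                             dur_s = c(0.020, 0.200), noise_channel = NULL,
                             band = c(130, 200), smooth_ms = 20) {
  if (trace_duration(lfp) < 5)
    stop("need at least 5 s of LFP to estimate the signal statistics")
  ev <- .probe_detect_core(lfp, peak_sd, edge_sd, band, smooth_ms)
  if (nrow(ev) > 0L) {
    dur <- ev$offset_s - ev$onset_s
    ev <- ev[dur >= dur_s[1] & dur <= dur_s[2], , drop = FALSE]
  }
  if (!is.null(noise_channel)) {
    if (!inherits(noise_channel, "continuous_trace"))
      stop("noise_channel must be a continuous_trace")
    noise_ev <- .probe_detect_core(noise_channel, peak_sd, edge_sd, band,
                                   smooth_ms)
    if (nrow(ev) > 0L && nrow(noise_ev) > 0L) {
      bad <- vapply(seq_len(nrow(ev)), function(i) {
        any(ev$onset_s[i] < noise_ev$offset_s &
              noise_ev$onset_s < ev$offset_s[i])
      }, logical(1))
      ev <- ev[!bad, , drop = FALSE]
    }
  }
  if (nrow(ev) > 0L) ev$event_id <- seq_len(nrow(ev))
  rownames(ev) <- NULL
  ev
}

.probe_detect_core <- function(lfp, peak_sd, edge_sd, band, smooth_ms,
                               boundary_smooth_ms = 4) {
  lfp <- .to_rate(lfp, 1250)
  filt <- bandpass(lfp, band[1], band[2], order = 4)
  nss <- .moving_avg(filt$samples^2, smooth_ms / 1000, filt$rate)
  bs <- .baseline_stats(nss, peak_sd, filt$rate)
  z <- (nss - bs[["mu"]]) / bs[["sd"]]
  pk <- .runs(z >= peak_sd)
  if (nrow(pk) == 0L) return(event_table())
  ev <- .walk_out(pk, z, edge_sd)
  # two-scale boundary localization: the long window stabilizes peak
  # detection, a short window localizes the edge crossings so slow
  # baseline fluctuations do not bleed the boundaries outward
  fine <- .moving_avg(filt$samples^2, boundary_smooth_ms / 1000, filt$rate)
  zf <- (fine - bs[["mu"]]) / bs[["sd"]]
  ev <- t(apply(ev, 1, function(q) {
    seg <- q[1]:q[2]
    p <- seg[which.max(z[seg])]
    a <- p; while (a > q[1] && zf[a - 1L] >= edge_sd) a <- a - 1L
    b <- p; while (b < q[2] && zf[b + 1L] >= edge_sd) b <- b + 1L
    c(a, b)
  }))
  ev <- unique(ev[order(ev[, 1]), , drop = FALSE])
  .runs_to_events(ev, z, filt, 1)
}

#' Programmatic quality control of detected SWR events
#'
#' Replaces by-eye curation with explicit, logged rules: a minimum
#' within-event ripple-band power (relative to the event's total power)
#' and a maximum line-noise ratio (power within +/- 2 Hz of the mains
#' frequency relative to ripple-band power). Rejected events are
#' returned in the `"rejected"` attribute with reason codes.
#'
#' @param events an [event_table()].
#' @param lfp the [continuous_trace()] the events were detected on.
#' @param min_band_frac minimum fraction of event spectral power inside
#'   `band` (`NULL` disables the rule).
#' @param max_line_ratio maximum line-noise / ripple-band power ratio
#'   (`NULL` disables the rule).
#' @param band ripple band (Hz).
#' @param line_hz mains frequency (Hz).
#' @return the accepted [event_table()]; attribute `rejected` holds the
#'   rejected rows plus a `reason` column.
#' @export
swr_qc <- function(events, lfp, min_band_frac = NULL, max_line_ratio = NULL,
                   band = c(100, 250), line_hz = 50) {
  events <- validate_events(events)
  if (nrow(events) == 0L ||
      (is.null(min_band_frac) && is.null(max_line_ratio))) {
    attr(events, "rejected") <- cbind(events[0, ], reason = character(0))
    return(events)
  }
  reasons <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(events))) {
    seg <- trace_window(lfp, events$onset_s[i], events$offset_s[i])
    x <- seg$samples - mean(seg$samples)
    spec <- stats::spec.pgram(stats::ts(x, frequency = seg$rate),
                              plot = FALSE, taper = 0, detrend = FALSE)
    in_band <- spec$freq >= band[1] & spec$freq <= band[2]
    p_band <- sum(spec$spec[in_band])
    p_tot <- sum(spec$spec)
    p_line <- sum(spec$spec[abs(spec$freq - line_hz) <= 2])
    if (!is.null(min_band_frac) &&
        (p_tot == 0 || p_band / p_tot < min_band_frac))
      reasons[i] <- "low_band_power"
    else if (!is.null(max_line_ratio) &&
             (p_band == 0 || p_line / p_band > max_line_ratio))
      reasons[i] <- "line_noise"
  }
  rejected <- cbind(events[!is.na(reasons), , drop = FALSE],
                    reason = reasons[!is.na(reasons)])
  accepted <- events[is.na(reasons), , drop = FALSE]
  rownames(accepted) <- NULL
  attr(accepted, "rejected") <- rejected
  accepted
}

#' Enforce the minimum-SWR session criterion
#'
#' Sessions entering the downstream analyses must contain at least
#' `min_n` SWRs; smaller sessions are flagged with a warning and an
#' empty table is returned.
#'
#' @param events an [event_table()].
#' @param min_n minimum number of events (default 30).
#' @return `events` unchanged if the criterion holds, otherwise an empty
#'   event table (with a warning).
#' @export
require_min_swrs <- function(events, min_n = 30) {
  events <- validate_events(events)
  if (nrow(events) < min_n) {
    warning("session has ", nrow(events), " SWRs; fewer than the required ",
            min_n, " - excluded from downstream analysis")
    return(events[0, , drop = FALSE])
  }
  events
}
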