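test_that("patch detector finds an isolated burst with accurate onset", {
  g <- gen_lfp(1, burst_dur_ms = 80, seed = 7, duration_s = 10)
  ev <- detect_swr_patch(g$trace)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s[1] - g$events$onset_s[1]), 0.010)
  # below-threshold burst is invisible
  glow <- gen_lfp(1, burst_dur_ms = 80, burst_snr = 1, seed = 3,
                  duration_s = 10)
  expect_equal(nrow(detect_swr_patch(glow$trace)), 0L)
  expect_error(detect_swr_patch(gen_lfp(0, seed = 1, duration_s = 3)$trace),
               "5 s")
})

test_that("patch detector stays silent on pure noise", {
  fp <- vapply(1:20, function(s) {
    nrow(detect_swr_patch(gen_lfp(0, seed = s, duration_s = 30)$trace))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.95)
})

test_that("probe detector enforces the 20-200 ms duration limits", {
  base <- gen_lfp(0, seed = 11, duration_s = 10)$trace
  fs <- base$rate
  add_burst <- function(x, dur_s, snr, at = 5) {
    nb <- round(dur_s * fs)
    tt <- (seq_len(nb) - 1) / fs
    i0 <- round(at * fs)
    x[i0:(i0 + nb - 1)] <- x[i0:(i0 + nb - 1)] +
      snr * 0.5 * (1 - cos(2 * pi * tt / dur_s)) * sin(2 * pi * 150 * tt)
    x
  }
  short <- continuous_trace(add_burst(base$samples, 0.010, snr = 6), fs)
  expect_equal(nrow(detect_swr_probe(short)), 0L)
  long <- continuous_trace(add_burst(base$samples, 0.300, snr = 10), fs)
  expect_equal(nrow(detect_swr_probe(long)), 0L)
  ok <- continuous_trace(add_burst(base$samples, 0.080, snr = 10), fs)
  evok <- detect_swr_probe(ok)
  expect_equal(nrow(evok), 1L)
  dur <- evok$offset_s - evok$onset_s
  expect_true(dur >= 0.02 && dur <= 0.2)
})

test_that("probe detector recovers embedded bursts with accurate onsets", {
  errs <- c()
  for (s in 1:3) {
    g <- gen_lfp(20, seed = s)
    ev <- detect_swr_probe(g$trace)
    m <- vapply(g$events$onset_s,
                function(o) min(abs(ev$onset_s - o)), numeric(1))
    errs <- c(errs, m)
    durs <- ev$offset_s - ev$onset_s
    expect_true(all(durs >= 0.02 & durs <= 0.2))
  }
  expect_gte(mean(errs < 0.02), 0.95)       # recall
  expect_lt(mean(errs[errs < 0.02]), 0.010) # matched onset error
})

test_that("both detectors are invariant to amplitude rescaling", {
  g <- gen_lfp(5, seed = 2)
  for (a in c(0.01, 12.3)) {
    scaled <- continuous_trace(a * g$trace$samples, g$trace$rate)
    expect_equal(detect_swr_patch(scaled)$onset_s,
                 detect_swr_patch(g$trace)$onset_s)
    expect_equal(detect_swr_probe(scaled)$onset_s,
                 detect_swr_probe(g$trace)$onset_s)
  }
})

test_that("raising the peak threshold never adds events", {
  g <- gen_lfp(10, burst_snr = 6, seed = 13)
  n_by_thresh <- vapply(c(3, 5, 8, 12),
                        function(th) nrow(detect_swr_probe(g$trace,
                                                           peak_sd = th)),
                        numeric(1))
  expect_true(all(diff(n_by_thresh) <= 0))
})

test_that("noise-channel co-detection removes artifact events", {
  g <- gen_lfp(5, seed = 2)
  # the trace itself as noise channel: every event is co-detected
  expect_equal(nrow(detect_swr_probe(g$trace, noise_channel = g$trace)), 0L)
  # an independent noise channel removes nothing
  clean <- gen_lfp(0, seed = 99,
                   duration_s = trace_duration(g$trace))$trace
  with_clean <- detect_swr_probe(g$trace, noise_channel = clean)
  expect_equal(nrow(with_clean), nrow(detect_swr_probe(g$trace)))
  expect_error(detect_swr_probe(g$trace, noise_channel = 1:10),
               "continuous_trace")
})

test_that("programmatic QC rejects power-defective and line-noise events", {
  g <- gen_lfp(3, seed = 5)
  ev <- detect_swr_probe(g$trace)
  # empty rule set: identity
  expect_equal(nrow(swr_qc(ev, g$trace)), nrow(ev))

  # an event over flat signal has no ripple-band power
  flat <- g$trace
  ev_flat <- validate_events(rbind(ev, data.frame(
    event_id = 999, onset_s = 0.5, peak_s = 0.55, offset_s = 0.6,
    channel_id = 0, peak_power = 0)))
  flat$samples[1:trunc(1250 * 1)] <- sin(2 * pi * 50 *
                                           (1:trunc(1250 * 1)) / 1250)
  kept <- swr_qc(ev_flat, flat, min_band_frac = 0.2)
  expect_false(999 %in% kept$event_id)
  expect_true(all(ev$event_id %in% kept$event_id))
  expect_equal(attr(kept, "rejected")$reason, "low_band_power")

  # a 50 Hz artifact event is caught by the line-noise rule
  art <- g$trace
  i <- trunc(1250 * 0.4):trunc(1250 * 0.6)
  art$samples[i] <- art$samples[i] + 10 * sin(2 * pi * 50 * i / 1250)
  ev_art <- validate_events(rbind(ev, data.frame(
    event_id = 998, onset_s = 0.45, peak_s = 0.5, offset_s = 0.55,
    channel_id = 0, peak_power = 0)))
  kept2 <- swr_qc(ev_art, art, max_line_ratio = 1)
  expect_false(998 %in% kept2$event_id)
  expect_equal(attr(kept2, "rejected")$reason, "line_noise")
})

test_that("sessions below the 30-SWR minimum are excluded with a warning", {
  ev <- make_events(10)
  expect_warning(out <- require_min_swrs(ev), "fewer than")
  expect_equal(nrow(out), 0L)
  ev30 <- make_events(30)
  expect_silent(expect_equal(nrow(require_min_swrs(ev30)), 30L))
})
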