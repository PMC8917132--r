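# build a Vm trace from a baseline plus triangular spikes at given times
make_spiky_vm <- function(spike_times, baseline = -55, rate = 2000,
                          dur = 2, peak = 20, width_ms = 2) {
  n <- round(dur * rate)
  x <- rep(baseline, n)
  half <- max(1L, round(width_ms / 2 / 1000 * rate))
  tri <- c(seq(0, 1, length.out = half + 1), seq(1, 0,
                                                 length.out = half + 1)[-1])
  for (ts in spike_times) {
    i0 <- round(ts * rate) + 1L
    seg <- i0:(i0 + length(tri) - 1L)
    x[seg] <- baseline + tri * (peak - baseline)
  }
  continuous_trace(x, rate, units = "mV")
}

test_that("spike detection counts supra-threshold excursions", {
  flat <- continuous_trace(rep(-60, 4000), 2000, units = "mV")
  expect_length(detect_vm_spikes(flat), 0L)

  one <- make_spiky_vm(0.5)
  sp <- detect_vm_spikes(one)
  expect_length(sp, 1L)
  expect_equal(sp, 0.501, tolerance = 2e-3)  # apex one half-width later

  burst <- make_spiky_vm(c(0.5, 0.51, 0.52))
  expect_length(detect_vm_spikes(burst), 3L)
})

test_that("spike truncation flattens spikes and is idempotent", {
  flat <- continuous_trace(rep(-55, 4000) + 0.01 * sin(1:4000 / 50), 2000,
                           units = "mV")
  expect_equal(truncate_spikes(flat)$samples, flat$samples)

  one <- make_spiky_vm(0.5)
  tr <- truncate_spikes(one)
  expect_lt(max(tr$samples), -20)
  expect_equal(tr$samples, rep(-55, 4000), tolerance = 0.5)

  doublet <- make_spiky_vm(c(0.5, 0.51))
  tr2 <- truncate_spikes(doublet)
  expect_lt(max(tr2$samples), -20)

  expect_equal(truncate_spikes(tr)$samples, tr$samples)
  expect_equal(truncate_spikes(tr2)$samples, tr2$samples)
})

test_that("pre-SWR Vm change recovers injected dips and shifts", {
  rate <- 2000
  n <- round(3.5 * rate)
  base <- continuous_trace(rep(-60, n), rate, units = "mV")
  onset <- 3.0
  expect_equal(compute_delta_vm_pre(base, onset), 0)

  # rectangular -3 mV dip spanning [-75, +25] ms covers any +/-25 ms
  # window around its minimum
  dip <- base
  tt <- trace_times(dip)
  dip$samples[tt >= onset - 0.075 & tt < onset + 0.025] <- -63
  expect_equal(compute_delta_vm_pre(dip, onset), -3, tolerance = 1e-6)

  shifted <- dip
  shifted$samples <- shifted$samples + 11.3
  expect_equal(compute_delta_vm_pre(shifted, onset),
               compute_delta_vm_pre(dip, onset))

  # missing pre-onset coverage is flagged, not fabricated
  res <- compute_delta_vm_pre(base, 1.0)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "insufficient_coverage")
})

test_that("depolarization peak time is located in the -20..120 ms window", {
  rate <- 2000
  n <- round(3.5 * rate)
  onset <- 3.0
  tt <- (seq_len(n) - 1) / rate
  bump <- continuous_trace(-60 + 5 * exp(-((tt - onset - 0.040) / 0.01)^2),
                           rate, units = "mV")
  expect_equal(compute_depol_peak(bump, onset), 40, tolerance = 1)

  ramp <- continuous_trace(tt, rate, units = "mV")
  expect_equal(compute_depol_peak(ramp, onset), 120, tolerance = 1)

  # two equal maxima: earliest wins
  two <- continuous_trace(rep(-60, n), rate, units = "mV")
  two$samples[round((onset + 0.030) * rate)] <- -50
  two$samples[round((onset + 0.080) * rate)] <- -50
  expect_equal(compute_depol_peak(two, onset), 30, tolerance = 1)
  # peak time ignores constant offsets
  two_up <- two; two_up$samples <- two_up$samples + 7
  expect_equal(compute_depol_peak(two_up, onset),
               compute_depol_peak(two, onset))
})

test_that("event-triggered averaging reduces noise as sqrt(n)", {
  rate <- 1000
  set.seed(31)
  x <- continuous_trace(rnorm(500 * rate), rate)
  onsets <- 2 + (0:399) * 1.2
  avg <- swr_triggered_average(x, onsets, window_s = c(-0.1, 0.1))
  expect_equal(attr(avg, "n_events"), 400L)
  expect_lt(stats::sd(avg$samples), 2 / sqrt(400))
  expect_gt(stats::sd(avg$samples), 0.5 / sqrt(400))

  one <- swr_triggered_average(x, onsets[1], window_s = c(-0.1, 0.1))
  expect_equal(one$samples,
               trace_window(x, onsets[1] - 0.1, onsets[1] + 0.1)$samples)

  same <- swr_triggered_average(x, rep(onsets[1], 10),
                                window_s = c(-0.1, 0.1))
  expect_equal(same$samples, one$samples)
})

test_that("conductance conversion follows the driving-force formula", {
  rate <- 1000
  n <- 4 * rate
  onset <- 3.0
  base_pa <- -120
  cur <- continuous_trace(rep(base_pa, n), rate, units = "pA")
  tt <- trace_times(cur)
  cur$samples[tt >= onset & tt < onset + 0.1] <- base_pa - 700
  g <- compute_conductance(cur, hold_mv = -70, e_rev_mv = 0, onset_s = onset)
  expect_equal(g$kind, "EPSG")
  i_on <- round((2 + 0.05) * rate)  # 50 ms after onset in window time
  expect_equal(max(g$g$samples), 10, tolerance = 1e-9)
  expect_equal(g$g$samples[1], 0, tolerance = 1e-9)

  cur2 <- continuous_trace(rep(50, n), rate, units = "pA")
  cur2$samples[tt >= onset & tt < onset + 0.1] <- 50 + 800
  g2 <- compute_conductance(cur2, hold_mv = 10, e_rev_mv = -90,
                            onset_s = onset)
  expect_equal(g2$kind, "IPSG")
  expect_equal(max(g2$g$samples), 8, tolerance = 1e-9)

  flat <- compute_conductance(cur2, 10, -90,
                              onset_s = 2.5, window_s = c(-0.5, 0))
  expect_equal(max(abs(flat$g$samples)), 0, tolerance = 1e-9)
  expect_error(compute_conductance(cur, -70, -70, onset), "differ")
})

test_that("conductance is linear in the baseline-subtracted current", {
  rate <- 1000
  set.seed(8)
  cur <- continuous_trace(rnorm(4 * rate), rate, units = "pA")
  g1 <- compute_conductance(cur, -70, 0, 3)$g$samples
  cur2 <- cur; cur2$samples <- 3 * cur$samples
  g3 <- compute_conductance(cur2, -70, 0, 3)$g$samples
  expect_equal(g3, 3 * g1, tolerance = 1e-9)
})

test_that("triplet order test is calibrated and detects coupling", {
  # exchangeable: flags rare
  flagged <- vapply(1:10, function(s) {
    set.seed(s)
    delta <- matrix(rnorm(300), 100, 3)
    peaks <- matrix(rnorm(300, 50, 10), 100, 3)
    any(triplet_order_test(delta, peaks, n_perm = 2000,
                           seed = s + 500)$flag != 0)
  }, logical(1))
  expect_lte(mean(flagged), 0.3)

  # deeper dip -> later peak: the concordant order exceeds the band
  set.seed(99)
  d <- matrix(rnorm(600, 2, 0.8), 200, 3)
  r <- triplet_order_test(-d, 50 + 3 * d + matrix(rnorm(600), 200, 3),
                          n_perm = 5000, seed = 1)
  expect_equal(sum(r$freq), 1, tolerance = 1e-12)
  concordant <- which(r$orders == "321")  # cell 3 dips deepest
  expect_equal(r$flag[concordant], 1L)

  r2 <- triplet_order_test(-d, 50 + 3 * d + matrix(rnorm(600), 200, 3),
                           n_perm = 5000, seed = 1)
  expect_identical(r$lower, r2$lower)
  expect_error(triplet_order_test(matrix(rnorm(30), 10, 3),
                                  matrix(rnorm(30), 10, 3)), "at least 30")
})

test_that("pairwise correlations recover shared structure", {
  set.seed(17)
  n <- 100
  shared <- rnorm(n)
  delta <- cbind(shared + rnorm(n, 0, 0.5), shared + rnorm(n, 0, 0.5),
                 rnorm(n))
  peaks <- cbind(shared + rnorm(n, 0, 0.5), shared + rnorm(n, 0, 0.5),
                 rnorm(n))
  r <- pairwise_vm_correlations(delta, peaks)
  expect_equal(nrow(r$pairs), 3L)
  p12 <- r$pairs[r$pairs$cell_i == 1 & r$pairs$cell_j == 2, ]
  expect_gt(p12$r_delta, 0.3)
  expect_lt(p12$p_delta, 0.01)

  ident <- pairwise_vm_correlations(cbind(delta[, 1], delta[, 1]),
                                    peaks[, 1:2])
  expect_equal(ident$pairs$r_delta, 1, tolerance = 1e-12)

  # independent series rarely exceed |r| = 0.3 at n = 100
  big <- vapply(1:40, function(s) {
    set.seed(200 + s)
    rr <- pairwise_vm_correlations(matrix(rnorm(200), 100, 2),
                                   matrix(rnorm(200), 100, 2))
    abs(rr$pairs$r_delta)
  }, numeric(1))
  expect_gte(mean(big < 0.3), 0.95)
})

test_that("per-SWR records skip uncovered events with reason codes", {
  ons <- c(1.0, 10, 14)  # first event lacks 2 s of baseline
  cfg <- vm_gen_config(n_swr = 3, seed = 41)
  g <- gen_vm(cfg, c(6, 10, 14))
  ev <- event_table(1:3, c(1.0, 10, 14), c(1.01, 10.01, 14.01),
                    c(1.05, 10.05, 14.05))
  rec <- delta_vm_records(g$trace, ev)
  expect_equal(nrow(rec), 2L)
  skipped <- attr(rec, "skipped")
  expect_equal(skipped$swr_id, 1)
  expect_equal(skipped$reason, "insufficient_coverage")
  expect_true(all(c("delta_vm_pre_mv", "depol_peak_time_ms",
                    "first_spike_time_ms", "n_spikes_in_swr") %in%
                    names(rec)))
})
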