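#' Synthetic LFP with embedded ripple bursts
#'
#' Generates Gaussian white noise with `n_swr` Hanning-enveloped
#' sinusoid bursts in the ripple band, at known ground-truth times, as a
#' substrate for detector testing. Burst peak amplitude is
#' `burst_snr * noise_sd`; inter-burst gaps are at least 500 ms.
#'
#' @param n_swr number of bursts to embed (0 gives pure noise).
#' @param burst_freq_hz oscillation frequency, 100-250 Hz.
#' @param burst_dur_ms burst duration in ms; a scalar, or a length-2
#'   range sampled uniformly per burst. Must lie in 20-200 ms.
#' @param burst_snr burst peak amplitude in units of the noise SD.
#' @param noise_sd noise standard deviation (arbitrary LFP units).
#' @param rate_hz sampling rate.
#' @param seed RNG seed.
#' @param duration_s total trace duration; defaults to what is needed to
#'   fit all bursts with 700 ms spacing plus 2 s of lead-in/out.
#' @return list with `trace` (a [continuous_trace()]) and `events`
#'   (ground-truth [event_table()] of burst onset/peak/offset).
#' @export
gen_lfp <- function(n_swr, burst_freq_hz = 150, burst_dur_ms = c(60, 120),
                    burst_snr = 10, noise_sd = 1, rate_hz = 1250,
                    seed = NULL, duration_s = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (burst_freq_hz < 100 || burst_freq_hz > 250)
    stop("burst_freq_hz must lie in the 100-250 Hz ripple band")
  if (any(burst_dur_ms < 20) || any(burst_dur_ms > 200))
    stop("burst_dur_ms must lie within 20-200 ms")
  durs_ms <- if (length(burst_dur_ms) == 2L && n_swr > 0L)
    stats::runif(n_swr, burst_dur_ms[1], burst_dur_ms[2])
  else rep(burst_dur_ms[1], n_swr)
  spacing_s <- 0.7
  if (is.null(duration_s))
    duration_s <- 4 + n_swr * (spacing_s + max(durs_ms, 0) / 1000)
  n <- round(duration_s * rate_hz)
  if (n_swr > 0 && 2 + n_swr * (0.5 + max(durs_ms) / 1000) > duration_s)
    stop("bursts do not fit in the requested trace duration")
  x <- stats::rnorm(n, 0, noise_sd)
  onsets <- numeric(0)
  if (n_swr > 0L) {
    onsets <- 2 + cumsum(c(0, rep(spacing_s, n_swr - 1)) +
                           c(0, durs_ms[-n_swr] / 1000))
    for (k in seq_len(n_swr)) {
      dur_s <- durs_ms[k] / 1000
      i0 <- round(onsets[k] * rate_hz) + 1L
      nb <- round(dur_s * rate_hz)
      tt <- (seq_len(nb) - 1) / rate_hz
      env <- 0.5 * (1 - cos(2 * pi * tt / dur_s))  # Hanning window
      x[i0:(i0 + nb - 1L)] <- x[i0:(i0 + nb - 1L)] +
        burst_snr * noise_sd * env * sin(2 * pi * burst_freq_hz * tt)
    }
  }
  events <- event_table(event_id = seq_len(n_swr), onset_s = onsets,
                        peak_s = onsets + durs_ms / 2000,
                        offset_s = onsets + durs_ms / 1000)
  list(trace = continuous_trace(x, rate_hz, units = "au"), events = events)
}

#' Configuration for the synthetic membrane-potential generator
#'
#' Encodes the structural features of SWR-locked intracellular dynamics:
#' a transient hyperpolarization shortly before ripple onset, a
#' depolarization during the ripple whose peak time is coupled to the
#' hyperpolarization depth (deeper pre-SWR dips push the depolarization
#' later), and threshold spiking on top of the depolarization.
#'
#' The hyperpolarization is a raised-cosine dip of half-width 25 ms
#' whose minimum sits 25 ms before onset, scaled so that the mean over
#' the 50-ms averaging window used by [compute_delta_vm_pre()] equals
#' the configured depth; that makes the measured pre-ripple Vm change
#' analytically `-depth` in the noiseless case.
#'
#' @param n_swr number of SWR events the trace will carry.
#' @param baseline_mv resting membrane potential (mV).
#' @param hyper_depth_mean_mv,hyper_depth_sd_mv per-SWR dip depth
#'   distribution, N(mean, sd^2), in mV (positive = hyperpolarizing).
#' @param coupling_ms_per_mv slope linking the pre-SWR Vm change
#'   (`-depth`) to the depolarization peak time; negative values
#'   reproduce the deeper-dip/later-peak structure.
#' @param depol_amp_mv depolarization amplitude (mV).
#' @param depol_base_ms mean depolarization peak time at zero dip (ms
#'   after onset).
#' @param peak_jitter_ms SD of the peak-time jitter (ms).
#' @param noise_sd_mv white-noise SD added to the trace (mV).
#' @param spike_threshold_mv Vm level above which a spike is emitted.
#' @param rate_hz sampling rate of the generated trace.
#' @param seed RNG seed.
#' @return a list of class `vm_gen_config`.
#' @export
vm_gen_config <- function(n_swr = 50, baseline_mv = -60,
                          hyper_depth_mean_mv = 2, hyper_depth_sd_mv = 0.8,
                          coupling_ms_per_mv = -3, depol_amp_mv = 8,
                          depol_base_ms = 50, peak_jitter_ms = 2,
                          noise_sd_mv = 0.3, spike_threshold_mv = -50,
                          rate_hz = 2000, seed = NULL) {
  if (n_swr < 1) stop("n_swr must be at least 1")
  if (noise_sd_mv < 0) stop("noise_sd_mv must be >= 0")
  structure(as.list(environment()), class = "vm_gen_config")
}

#' Synthetic intracellular Vm trace around SWRs
#'
#' Builds a membrane-potential trace carrying, for each SWR onset, a
#' pre-onset raised-cosine hyperpolarization of known depth, a
#' raised-cosine depolarization (half-width 25 ms) whose peak time is
#' `depol_base_ms + coupling_ms_per_mv * (-depth) + jitter`, and, where
#' the depolarized Vm crosses the spike threshold, a 2-ms triangular
#' spike transient to +20 mV.
#'
#' @param cfg a [vm_gen_config()].
#' @param swr_onsets SWR onset times in seconds, spaced at least 4 s
#'   apart (the baseline window reaches 2 s before onset).
#' @return list with `trace` (a [continuous_trace()], mV) and `truth`
#'   (data.frame of per-SWR injected depth, depolarization peak time in
#'   ms, and first spike time in s, `NA` when no spike was emitted).
#' @export
gen_vm <- function(cfg, swr_onsets) {
  stopifnot(inherits(cfg, "vm_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  swr_onsets <- sort(as.numeric(swr_onsets))
  if (length(swr_onsets) != cfg$n_swr)
    stop("length(swr_onsets) must equal cfg$n_swr")
  if (length(swr_onsets) > 1 && min(diff(swr_onsets)) < 4)
    stop("SWR onsets must be spaced at least 4 s apart")
  rate <- cfg$rate_hz
  dur <- max(swr_onsets) + 3
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1) / rate
  vm <- rep(cfg$baseline_mv, n) + stats::rnorm(n, 0, cfg$noise_sd_mv)

  depths <- stats::rnorm(cfg$n_swr, cfg$hyper_depth_mean_mv,
                         cfg$hyper_depth_sd_mv)
  jit <- stats::rnorm(cfg$n_swr, 0, cfg$peak_jitter_ms)
  peak_ms <- cfg$depol_base_ms + cfg$coupling_ms_per_mv * (-depths) + jit

  rc <- function(t_s, center_s, half_s) {
    # raised cosine with unit peak, compact support [center-half, center+half]
    u <- (t_s - center_s) / half_s
    ifelse(abs(u) <= 1, 0.5 * (1 + cos(pi * u)), 0)
  }
  first_spike <- rep(NA_real_, cfg$n_swr)
  for (k in seq_len(cfg$n_swr)) {
    on <- swr_onsets[k]
    dip_c <- on - 0.025
    idx <- which(tt >= dip_c - 0.025 & tt <= dip_c + 0.025)
    # window-mean of the unit raised cosine over its support is 1/2,
    # so scale by 2 to make the measured window mean equal -depth
    vm[idx] <- vm[idx] - 2 * depths[k] * rc(tt[idx], dip_c, 0.025)
    dep_c <- on + peak_ms[k] / 1000
    idx <- which(tt >= dep_c - 0.025 & tt <= dep_c + 0.025)
    vm[idx] <- vm[idx] + cfg$depol_amp_mv * rc(tt[idx], dep_c, 0.025)
    # threshold spiking: first suprathreshold crossing of the clean
    # depolarization gets a 2-ms triangular transient to +20 mV
    if (cfg$baseline_mv + cfg$depol_amp_mv > cfg$spike_threshold_mv) {
      frac <- (cfg$spike_threshold_mv - cfg$baseline_mv) / cfg$depol_amp_mv
      # solve rc(u) = frac on the rising flank
      u_cross <- -acos(2 * frac - 1) / pi
      t_spk <- dep_c + u_cross * 0.025
      i_spk <- round((t_spk - tt[1]) * rate) + 1L
      n_half <- max(1L, round(0.001 * rate))
      tri <- c(seq(0, 1, length.out = n_half + 1L),
               seq(1, 0, length.out = n_half + 1L)[-1])
      seg <- i_spk:(i_spk + length(tri) - 1L)
      keep <- seg >= 1L & seg <= n
      base_here <- vm[seg[keep]]
      vm[seg[keep]] <- base_here + tri[keep] * (20 - base_here)
      first_spike[k] <- t_spk + 0.001
    }
  }
  list(trace = continuous_trace(vm, rate, units = "mV"),
       truth = data.frame(swr_id = seq_len(cfg$n_swr), onset_s = swr_onsets,
                          depth_mv = depths, depol_peak_ms = peak_ms,
                          first_spike_s = first_spike))
}

#' Configuration for the synthetic spike-train generator
#'
#' Describes a population of interneurons whose firing rate transiently
#' rises in the 30 ms before each SWR, with per-SWR rate magnitudes that
#' vary across events, and pyramidal cells whose first-spike latency
#' within the SWR grows with the pre-SWR rate of a paired interneuron.
#'
#' @param n_int,n_pyr numbers of interneurons and pyramidal cells.
#' @param n_swr number of SWR events (at least 5; quintiles need 5).
#' @param int_pre_rate_mean_hz,int_pre_rate_cv mean and coefficient of
#'   variation of the per-SWR pre-onset interneuron rate (gamma draws).
#' @param latency_slope_ms_per_hz increase in pyramidal first-spike
#'   latency per Hz of the paired interneuron's pre-SWR rate.
#' @param base_latency_ms latency at zero pre-SWR rate.
#' @param latency_jitter_ms SD of latency jitter.
#' @param within_swr_rate_hz pyramidal firing rate inside the SWR after
#'   the first spike.
#' @param int_swr_rate_hz interneuron firing rate inside the SWR.
#' @param seed RNG seed.
#' @return a list of class `unit_gen_config`.
#' @export
unit_gen_config <- function(n_int = 5, n_pyr = 5, n_swr = 300,
                            int_pre_rate_mean_hz = 60, int_pre_rate_cv = 0.6,
                            latency_slope_ms_per_hz = 0.1,
                            base_latency_ms = 10, latency_jitter_ms = 5,
                            within_swr_rate_hz = 50, int_swr_rate_hz = 30,
                            seed = NULL) {
  if (n_swr < 5) stop("n_swr must be at least 5 (quintiles need 5 events)")
  if (int_pre_rate_mean_hz < 0 || within_swr_rate_hz < 0 || int_swr_rate_hz < 0)
    stop("rates must be >= 0")
  structure(as.list(environment()), class = "unit_gen_config")
}

#' Synthetic interneuron and pyramidal spike trains around SWRs
#'
#' Each interneuron fires an inhomogeneous-Poisson burst in the 30 ms
#' before each SWR onset, with a per-SWR rate drawn from a gamma
#' distribution (mean `int_pre_rate_mean_hz`, CV `int_pre_rate_cv`),
#' plus Poisson firing inside the SWR. Each pyramidal cell is paired
#' with one interneuron (by index, cyclically) and fires its first SWR
#' spike at `base_latency_ms + latency_slope_ms_per_hz * pre_rate +
#' jitter`, clipped into the event, followed by Poisson firing for the
#' rest of the event.
#'
#' @param cfg a [unit_gen_config()].
#' @param swr_events an [event_table()] with `cfg$n_swr` rows.
#' @return list with `spikes` (a [spike_table()]; interneurons named
#'   `int01, ...`, pyramidal cells `pyr01, ...`) and `truth`
#'   (`pre_rates`: n_swr x n_int matrix of injected pre-SWR rates;
#'   `pairing`: index of the interneuron paired with each pyramidal cell).
#' @export
gen_unit_spikes <- function(cfg, swr_events) {
  stopifnot(inherits(cfg, "unit_gen_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  swr_events <- validate_events(swr_events)
  if (nrow(swr_events) != cfg$n_swr)
    stop("swr_events must have cfg$n_swr rows")
  cv <- max(cfg$int_pre_rate_cv, 1e-6)
  shape <- 1 / cv^2
  scale <- cfg$int_pre_rate_mean_hz / shape
  pre_rates <- matrix(stats::rgamma(cfg$n_swr * cfg$n_int, shape = shape,
                                    scale = scale),
                      nrow = cfg$n_swr, ncol = cfg$n_int)
  ids <- character(0); cls <- character(0); tms <- numeric(0)
  int_names <- sprintf("int%02d", seq_len(cfg$n_int))
  pyr_names <- sprintf("pyr%02d", seq_len(cfg$n_pyr))
  pairing <- ((seq_len(cfg$n_pyr) - 1L) %% cfg$n_int) + 1L
  for (s in seq_len(cfg$n_swr)) {
    on <- swr_events$onset_s[s]; off <- swr_events$offset_s[s]
    dur <- off - on
    for (i in seq_len(cfg$n_int)) {
      n_pre <- stats::rpois(1, pre_rates[s, i] * 0.030)
      n_in <- stats::rpois(1, cfg$int_swr_rate_hz * dur)
      t_new <- c(stats::runif(n_pre, on - 0.030, on),
                 stats::runif(n_in, on, off))
      ids <- c(ids, rep(int_names[i], length(t_new)))
      cls <- c(cls, rep("int", length(t_new)))
      tms <- c(tms, t_new)
    }
    for (p in seq_len(cfg$n_pyr)) {
      lat_ms <- cfg$base_latency_ms +
        cfg$latency_slope_ms_per_hz * pre_rates[s, pairing[p]] +
        stats::rnorm(1, 0, cfg$latency_jitter_ms)
      lat_s <- min(max(lat_ms / 1000, 0.001), dur - 0.001)
      n_more <- stats::rpois(1, cfg$within_swr_rate_hz * (dur - lat_s))
      t_new <- c(on + lat_s,
                 if (n_more > 0) stats::runif(n_more, on + lat_s, off))
      ids <- c(ids, rep(pyr_names[p], length(t_new)))
      cls <- c(cls, rep("pyr", length(t_new)))
      tms <- c(tms, t_new)
    }
  }
  list(spikes = spike_table(ids, cls, tms),
       truth = list(pre_rates = pre_rates, pairing = pairing))
}

# draw a row-stochastic transition matrix with a self-transition bias
.random_transition <- function(M, self_bias) {
  A <- matrix(stats::runif(M * M), M, M) + diag(self_bias, M)
  A / rowSums(A)
}

#' Sample spike-count sequences from a Poisson-emission HMM
#'
#' The generative twin of the sequence model: a first-order Markov chain
#' over `M` latent network states, each emitting independent Poisson
#' spike counts per cell per time bin with state-specific means.
#'
#' @param n_cells number of cells (N).
#' @param M number of latent states.
#' @param T_per_seq bins per sequence; a scalar, or a length-2 range
#'   sampled uniformly (integers) per sequence.
#' @param n_seq number of sequences.
#' @param param_ranges list with `lambda` (length-2 range for the
#'   expected counts per bin) and `self_bias` (diagonal weight added
#'   before row normalization of the transition matrix).
#' @param seed RNG seed.
#' @param params optional [list] with `pi`, `A`, `Lambda` to sample from
#'   fixed parameters instead of drawing them.
#' @return list with `sequences` (list of T x N integer matrices),
#'   `states` (list of latent state paths), and the ground-truth `pi`,
#'   `A`, `Lambda` (N x M).
#' @export
gen_hmm_counts <- function(n_cells, M, T_per_seq, n_seq,
                           param_ranges = list(lambda = c(0.05, 3),
                                               self_bias = 2),
                           seed = NULL, params = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) {
    pi0 <- stats::runif(M); pi0 <- pi0 / sum(pi0)
    A <- .random_transition(M, param_ranges$self_bias)
    Lambda <- matrix(stats::runif(n_cells * M, param_ranges$lambda[1],
                                  param_ranges$lambda[2]), n_cells, M)
  } else {
    pi0 <- params$pi; A <- params$A; Lambda <- params$Lambda
    M <- length(pi0); n_cells <- nrow(Lambda)
  }
  Ts <- if (length(T_per_seq) == 2L)
    sample(T_per_seq[1]:T_per_seq[2], n_seq, replace = TRUE)
  else rep(as.integer(T_per_seq), n_seq)
  sequences <- vector("list", n_seq); states <- vector("list", n_seq)
  for (s in seq_len(n_seq)) {
    Tn <- Ts[s]
    z <- integer(Tn)
    z[1] <- sample.int(M, 1, prob = pi0)
    for (t in seq_len(Tn - 1))
      z[t + 1] <- sample.int(M, 1, prob = A[z[t], ])
    y <- matrix(stats::rpois(Tn * n_cells, t(Lambda[, z, drop = FALSE])),
                nrow = Tn, ncol = n_cells, byrow = FALSE)
    sequences[[s]] <- y; states[[s]] <- z
  }
  list(sequences = sequences, states = states,
       pi = pi0, A = A, Lambda = Lambda)
}

#' Sample per-SWR spike counts from a Poisson mixture
#'
#' Each SWR is assigned a latent ensemble label drawn from `pi`; the
#' spike count of each interneuron is then Poisson with the ensemble's
#' expected count.
#'
#' @param n_int number of interneurons (N).
#' @param M number of ensembles.
#' @param n_swr number of SWRs.
#' @param pi ensemble probabilities (length M, sums to 1); default uniform.
#' @param lambda N x M matrix of expected counts; default drawn so that
#'   adjacent ensembles have well-separated rate columns.
#' @param seed RNG seed.
#' @return list with `counts` (n_swr x N integer matrix), `labels`
#'   (ground-truth ensemble per SWR), `pi`, `lambda`.
#' @export
gen_mixture_counts <- function(n_int, M, n_swr, pi = NULL, lambda = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pi)) pi <- rep(1 / M, M)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  if (is.null(lambda)) {
    # columns separated by ~4x rate ratios cell-by-cell
    base <- stats::runif(n_int, 0.5, 2)
    gains <- 4^(sample.int(M, n_int * M, replace = TRUE) - 1)
    lambda <- base * matrix(gains, n_int, M)
  }
  if (!all(dim(lambda) == c(n_int, M))) stop("lambda must be n_int x M")
  labels <- sample.int(M, n_swr, replace = TRUE, prob = pi)
  counts <- matrix(stats::rpois(n_swr * n_int, t(lambda[, labels])),
                   nrow = n_swr, ncol = n_int, byrow = FALSE)
  colnames(counts) <- sprintf("int%02d", seq_len(n_int))
  list(counts = counts, labels = labels, pi = pi, lambda = lambda)
}
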