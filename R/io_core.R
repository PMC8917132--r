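#' Construct a continuous trace
#'
#' A `continuous_trace` holds a uniformly sampled single-channel signal
#' (LFP, intracellular Vm, or clamp current) together with its sampling
#' rate, the time of its first sample, and a physical unit label. Time is
#' carried in seconds everywhere; sample indices are 0-based so sample
#' `k` sits at `t0 + k / rate`.
#'
#' @param samples numeric vector of finite sample values.
#' @param rate sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds.
#' @param units unit label, e.g. `"mV"`, `"pA"`, `"au"`.
#' @return an object of class `continuous_trace` with fields `samples`,
#'   `rate`, `t0`, `units`.
#' @export
continuous_trace <- function(samples, rate, t0 = 0, units = "au") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number (Hz)")
  structure(
    list(samples = samples, rate = as.numeric(rate),
         t0 = as.numeric(t0), units = as.character(units)),
    class = "continuous_trace"
  )
}

#' @export
print.continuous_trace <- function(x, ...) {
  cat(sprintf("<continuous_trace> %d samples @ %g Hz, t0 = %g s, units = %s\n",
              length(x$samples), x$rate, x$t0, x$units))
  invisible(x)
}

#' @export
length.continuous_trace <- function(x) length(x$samples)

#' Time axis of a trace
#'
#' @param trace a [continuous_trace()].
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

#' Duration of a trace in seconds
#' @param trace a [continuous_trace()].
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate

# index of the sample at or immediately after time t (1-based R index)
.sample_index <- function(trace, t) {
  as.integer(ceiling(round((t - trace$t0) * trace$rate, 9))) + 1L
}

#' Extract a time window from a trace
#'
#' Half-open window `[from_s, to_s)` in absolute time. Errors if the
#' window is not fully covered by the trace.
#'
#' @param trace a [continuous_trace()].
#' @param from_s,to_s window bounds in seconds.
#' @return a `continuous_trace` covering the window.
#' @export
trace_window <- function(trace, from_s, to_s) {
  i0 <- .sample_index(trace, from_s)
  i1 <- .sample_index(trace, to_s) - 1L
  if (i0 < 1L || i1 > length(trace$samples) || i1 < i0)
    stop("requested window [", from_s, ", ", to_s, ") not covered by trace")
  continuous_trace(trace$samples[i0:i1], trace$rate,
                   t0 = trace$t0 + (i0 - 1L) / trace$rate, units = trace$units)
}

#' Read a continuous trace from flat float32 + JSON sidecar
#'
#' The on-disk format is a flat little-endian float32 binary file plus a
#' JSON sidecar declaring `rate_hz`, `n_samples`, `t0_s` and `units`.
#'
#' @param path_binary path to the `.f32` file.
#' @param path_sidecar path to the `.json` sidecar.
#' @return a [continuous_trace()].
#' @export
read_trace <- function(path_binary, path_sidecar) {
  meta <- jsonlite::read_json(path_sidecar, simplifyVector = TRUE)
  if (is.null(meta$rate_hz) || !is.finite(meta$rate_hz) || meta$rate_hz <= 0)
    stop("sidecar is missing a positive rate_hz")
  if (is.null(meta$n_samples)) stop("sidecar is missing n_samples")
  n_declared <- as.integer(meta$n_samples)
  n_on_disk <- file.size(path_binary) / 4
  if (n_on_disk != n_declared)
    stop("sidecar declares ", n_declared, " samples but file holds ", n_on_disk)
  con <- file(path_binary, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "numeric", n = n_declared, size = 4,
               endian = "little")
  continuous_trace(x, rate = meta$rate_hz,
                   t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s,
                   units = if (is.null(meta$units)) "au" else meta$units)
}

#' Write a continuous trace to flat float32 + JSON sidecar
#'
#' @param trace a [continuous_trace()].
#' @param path_binary path to the `.f32` file to create.
#' @param path_sidecar path to the `.json` sidecar to create.
#' @return invisibly, the two paths.
#' @export
write_trace <- function(trace, path_binary, path_sidecar) {
  con <- file(path_binary, "wb")
  writeBin(trace$samples, con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(rate_hz = trace$rate, n_samples = length(trace$samples),
         t0_s = trace$t0, units = trace$units),
    path_sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path_binary, path_sidecar))
}

#' Construct / validate an event table
#'
#' An event table is a data.frame with columns `event_id`, `onset_s`,
#' `peak_s`, `offset_s`, `channel_id`; rows sorted by onset, intervals
#' half-open `[onset, offset)`, event ids unique.
#'
#' @param event_id unique event identifiers.
#' @param onset_s,peak_s,offset_s event times in seconds with
#'   `onset <= peak <= offset`.
#' @param channel_id channel label (recycled).
#' @return a validated event table (data.frame).
#' @export
event_table <- function(event_id = integer(), onset_s = numeric(),
                        peak_s = onset_s, offset_s = onset_s,
                        channel_id = 0L) {
  if (length(channel_id) == 1L) channel_id <- rep(channel_id, length(event_id))
  df <- data.frame(event_id = event_id, onset_s = as.numeric(onset_s),
                   peak_s = as.numeric(peak_s),
                   offset_s = as.numeric(offset_s),
                   channel_id = channel_id)
  validate_events(df)
}

#' @rdname event_table
#' @param events a candidate event table.
#' @export
validate_events <- function(events) {
  need <- c("event_id", "onset_s", "peak_s", "offset_s", "channel_id")
  if (!all(need %in% names(events)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  if (nrow(events) == 0L) return(events[need])
  if (anyDuplicated(events$event_id)) stop("event_id values must be unique")
  if (any(!(events$onset_s <= events$peak_s & events$peak_s <= events$offset_s)))
    stop("events must satisfy onset <= peak <= offset")
  events <- events[order(events$onset_s), need, drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Read / write event tables as CSV
#'
#' @param path CSV path with header `event_id,onset_s,peak_s,offset_s,channel_id`.
#' @return `read_events`: a validated event table.
#' @export
read_events <- function(path) {
  validate_events(utils::read.csv(path))
}

#' @rdname read_events
#' @param events an event table.
#' @export
write_events <- function(events, path) {
  utils::write.csv(validate_events(events), path, row.names = FALSE)
  invisible(path)
}

#' Construct / validate a spike table
#'
#' A spike table is a data.frame with columns `cell_id`,
#' `cell_class` (one of `"pyr"`, `"int"`) and `spike_time_s`, with spike
#' times finite and sorted within each cell.
#'
#' @param cell_id cell identifiers.
#' @param cell_class `"pyr"` or `"int"` per spike.
#' @param spike_time_s spike times in seconds.
#' @return a validated spike table (data.frame).
#' @export
spike_table <- function(cell_id = character(), cell_class = character(),
                        spike_time_s = numeric()) {
  df <- data.frame(cell_id = cell_id, cell_class = cell_class,
                   spike_time_s = as.numeric(spike_time_s))
  validate_spikes(df)
}

#' @rdname spike_table
#' @param spikes a candidate spike table.
#' @export
validate_spikes <- function(spikes) {
  need <- c("cell_id", "cell_class", "spike_time_s")
  if (!all(need %in% names(spikes)))
    stop("spike table must have columns ", paste(need, collapse = ", "))
  if (nrow(spikes) == 0L) return(spikes[need])
  if (!all(spikes$cell_class %in% c("pyr", "int")))
    stop("cell_class must be 'pyr' or 'int'")
  if (!all(is.finite(spikes$spike_time_s)))
    stop("spike times must be finite")
  spikes <- spikes[order(spikes$cell_id, spikes$spike_time_s), need,
                   drop = FALSE]
  rownames(spikes) <- NULL
  spikes
}

#' Read / write spike tables as CSV
#'
#' @param path CSV path with header `cell_id,cell_class,spike_time_s`.
#' @return `read_spikes`: a validated spike table.
#' @export
read_spikes <- function(path) {
  validate_spikes(utils::read.csv(path))
}

#' @rdname read_spikes
#' @param spikes a spike table.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(validate_spikes(spikes), path, row.names = FALSE)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Type-I Chebyshev band-pass (1 dB passband ripple) applied
#' forward-backward so the output is zero-phase: event timing is not
#' biased by filter delay. The ripple band used for SWR work is
#' 100-250 Hz (tungsten LFP) or 130-200 Hz (probe recordings).
#'
#' @param trace a [continuous_trace()].
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo < hi < rate/2`.
#' @param order filter order (the paper-standard choice is 4).
#' @param ripple_db passband ripple of the Chebyshev design.
#' @return a filtered `continuous_trace` of the same length and rate.
#' @export
bandpass <- function(trace, lo_hz, hi_hz, order = 4, ripple_db = 1) {
  nyq <- trace$rate / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq))
    stop("band edges must satisfy 0 < lo_hz < hi_hz < rate/2 (Nyquist = ",
         nyq, " Hz)")
  flt <- signal::cheby1(order, ripple_db, c(lo_hz, hi_hz) / nyq, type = "pass")
  y <- signal::filtfilt(flt, trace$samples)
  continuous_trace(y, trace$rate, t0 = trace$t0, units = trace$units)
}

#' Anti-aliased downsampling
#'
#' Low-pass filters at 80% of the target Nyquist (zero-phase Butterworth)
#' and resamples by linear interpolation onto the target time grid, so
#' rational (non-integer) rate ratios are handled uniformly.
#'
#' @param trace a [continuous_trace()].
#' @param target_hz new sampling rate, `< rate`.
#' @return a `continuous_trace` at `target_hz`.
#' @export
downsample <- function(trace, target_hz) {
  if (!(target_hz > 0 && target_hz < trace$rate))
    stop("target_hz must be positive and below the current rate")
  cutoff <- 0.8 * (target_hz / 2)
  flt <- signal::butter(4, cutoff / (trace$rate / 2), type = "low")
  # pad with edge replication so filter start-up transients fall
  # outside the retained samples
  pad <- min(length(trace$samples),
             max(100L, round(0.05 * trace$rate)))
  x <- c(rep(trace$samples[1], pad), trace$samples,
         rep(trace$samples[length(trace$samples)], pad))
  y <- signal::filtfilt(flt, x)[(pad + 1):(pad + length(trace$samples))]
  t_old <- trace_times(trace)
  n_new <- floor(trace_duration(trace) * target_hz)
  t_new <- trace$t0 + (seq_len(n_new) - 1) / target_hz
  y_new <- stats::approx(t_old, y, xout = t_new, rule = 2)$y
  continuous_trace(y_new, target_hz, t0 = trace$t0, units = trace$units)
}

#' Write a JSON provenance record
#'
#' Captures parameters, seed and input file hashes alongside any pipeline
#' output so a run can be reproduced.
#'
#' @param path output JSON path.
#' @param params named list of run parameters.
#' @param seed the RNG seed used.
#' @param inputs character vector of input file paths (hashed if present).
#' @return invisibly, the record list.
#' @export
write_provenance <- function(path, params = list(), seed = NULL,
                             inputs = character()) {
  hashes <- lapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  })
  names(hashes) <- inputs
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, params = params, input_md5 = hashes)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec)
}
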