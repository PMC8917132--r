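#!/usr/bin/env Rscript

# Runs both SWR detectors on the simulated LFP (01_simulate.R) and
# compares the detected events against the generator's ground truth.

library(rippletiming)

sess <- "results/session"
lfp <- read_trace(file.path(sess, "lfp.f32"), file.path(sess, "lfp.json"))
truth <- read_events(file.path(sess, "swr_truth.csv"))

probe <- detect_swr_probe(lfp)
patch <- detect_swr_patch(lfp, band = c(130, 200))

score <- function(det, label) {
  err <- vapply(truth$onset_s, function(o) min(abs(det$onset_s - o)),
                numeric(1))
  message(sprintf(
    "%s: %d events; recall %.0f%%; matched onset error %.1f ms",
    label, nrow(det), 100 * mean(err < 0.02),
    1000 * mean(err[err < 0.02])))
}
score(probe, "probe detector (5/2 SD normalized squared signal)")
score(patch, "patch detector (3 SD envelope threshold)")

qc <- swr_qc(probe, lfp, min_band_frac = 0.1)
message(sprintf("QC: %d of %d events kept (%d rejected)",
                nrow(qc), nrow(probe), nrow(attr(qc, "rejected"))))

write_events(require_min_swrs(qc), file.path(sess, "swr_detected.csv"))
message("detected events written to ", file.path(sess, "swr_detected.csv"))
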