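#!/usr/bin/env Rscript

# Generates one synthetic "session" of every input the pipeline consumes
# (ripple-embedded LFP, intracellular Vm, spike trains, latent-variable
# count data) and writes them in the repository's exchange formats,
# alongside the ground truth each generator knows.

library(rippletiming)

seed <- 20260922L
out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## LFP with embedded ripples -------------------------------------------------
lfp <- gen_lfp(30, burst_snr = 10, seed = seed)
write_trace(lfp$trace, file.path(out, "lfp.f32"), file.path(out, "lfp.json"))
write_events(lfp$events, file.path(out, "swr_truth.csv"))
message(sprintf("LFP: %.1f s at %g Hz with %d embedded ripples",
                trace_duration(lfp$trace), lfp$trace$rate, nrow(lfp$events)))

## intracellular Vm around SWRs ----------------------------------------------
n_vm <- 120
ons <- 10 + (0:(n_vm - 1)) * 4.2
vcfg <- vm_gen_config(n_swr = n_vm, coupling_ms_per_mv = -3, seed = seed + 1)
vm <- gen_vm(vcfg, ons)
write_trace(vm$trace, file.path(out, "vm.f32"), file.path(out, "vm.json"))
write_events(event_table(seq_len(n_vm), ons, ons + 0.04, ons + 0.08),
             file.path(out, "vm_swr.csv"))
utils::write.csv(vm$truth, file.path(out, "vm_truth.csv"), row.names = FALSE)
message(sprintf("Vm: %d SWRs, mean injected dip %.2f mV",
                n_vm, mean(vm$truth$depth_mv)))

## extracellular units --------------------------------------------------------
n_sw <- 300
ev <- event_table(seq_len(n_sw), 5 + (0:(n_sw - 1)),
                  5 + (0:(n_sw - 1)) + 0.04, 5 + (0:(n_sw - 1)) + 0.08)
ucfg <- unit_gen_config(n_int = 4, n_pyr = 4, n_swr = n_sw, seed = seed + 2)
units <- gen_unit_spikes(ucfg, ev)
write_spikes(units$spikes, file.path(out, "spikes.csv"))
write_events(ev, file.path(out, "unit_swr.csv"))
message(sprintf("units: %d spikes from %d cells across %d SWRs",
                nrow(units$spikes), length(unique(units$spikes$cell_id)),
                n_sw))

## latent-variable count data -------------------------------------------------
mix <- gen_mixture_counts(12, 3, 500, seed = seed + 3)
utils::write.csv(as.data.frame(mix$counts),
                 file.path(out, "interneuron_counts.csv"), row.names = FALSE)
message(sprintf("mixture counts: %d SWRs x %d interneurons, true M = 3",
                nrow(mix$counts), ncol(mix$counts)))

write_provenance(file.path(out, "provenance.json"),
                 params = list(n_lfp_swr = 30, n_vm_swr = n_vm,
                               n_unit_swr = n_sw),
                 seed = seed)
message("done; session written under ", out)
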