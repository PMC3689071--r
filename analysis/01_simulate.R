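#!/usr/bin/env Rscript
# Stage 1: simulate a recording experiment.
#
# Builds a 72-unit cohort emulating a prelimbic test-session population:
# spontaneous rates span 0.31-34.6 Hz; a third of the units carry
# context-A-gated CS responses (transient x4 in the first 150 ms and/or
# sustained x2 decaying over 10 s). Writes the spike, event and behavioral
# CSVs that the later stages read back, plus the ground truth.

suppressPackageStartupMessages(library(cdfd))
seed <- 2026
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

units <- synthetic_cohort(72, seed = seed)
both <- 1:12; transient_only <- 13:20; sustained_only <- 21:28
units$transient_gain_A[c(both, transient_only)] <- 4
units$sustained_gain_A[c(both, sustained_only)] <- 2
ds <- generate_session(units, session_spec(seed = seed + 1))

freezing <- generate_freezing(ds$events, c(A = 0.8, B = 0.25),
                              seed = seed + 2)
startle <- generate_startle(n_per_type = 15, ss_mean = 200, ppi_true = 55,
                            cv = 0.3, seed = seed + 3)

write_spikes(ds$spikes, file.path(out, "spikes.csv"))
write_events(ds$events, file.path(out, "events.csv"))
write.csv(freezing, file.path(out, "freezing.csv"), row.names = FALSE)
write.csv(startle, file.path(out, "startle.csv"), row.names = FALSE)
jsonlite::write_json(ds$truth, file.path(out, "truth.json"), digits = NA)

cat(sprintf("simulated %d units over %.0f s (%d CS trials)\n",
            nrow(units), ds$span[2], nrow(ds$events)))
cat(sprintf("rates %.2f-%.2f Hz; %d units context-modulated\n",
            min(units$baseline_rate), max(units$baseline_rate), 28))
cat("wrote", out, "\n")
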