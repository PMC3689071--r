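#!/usr/bin/env Rscript
# Stage 2: responsive-unit classification.
#
# Reads the simulated session and applies both 3-SD criteria: short-latency
# (any of the first three 50-ms bins over baseline + 3 SD) and persistent
# firing (two or more of the first ten 1-s bins over baseline + 3 SD),
# with trials pooled across contexts.

suppressPackageStartupMessages(library(cdfd))
spikes <- read_spikes("results/data/spikes.csv")
events <- read_events("results/data/events.csv")

cls <- classify_population(spikes, events, pipeline_config())
dir.create("results", showWarnings = FALSE)
write.csv(cls$units, "results/classification.csv", row.names = FALSE)

s <- cls$summary
cat(sprintf("units: %d analyzed, %d excluded\n", s$n_analyzed, s$n_excluded))
cat(sprintf("short-latency CS-responsive: %d (%.1f%%)\n",
            s$n_short_latency, s$pct_short_latency))
cat(sprintf("persistently firing (PFU):   %d (%.1f%%)\n",
            s$n_persistent, s$pct_persistent))
cat(sprintf("overlap (both criteria):     %d\n", s$n_overlap))
cat("wrote results/classification.csv\n")
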