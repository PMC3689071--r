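#!/usr/bin/env Rscript
# Stage 4: behavioral metrics.
#
# Freezing percentage (merged immobility intervals over the first CS
# presentation in each context) and prepulse inhibition from the startle
# trial table.

suppressPackageStartupMessages(library(cdfd))
events <- read_events("results/data/events.csv")
freezing <- read.csv("results/data/freezing.csv")
startle <- read_startle("results/data/startle.csv")

first_cs <- events[!duplicated(events$context), ]
for (i in seq_len(nrow(first_cs))) {
  ctx <- first_cs$context[i]
  iv <- freezing[freezing$context == ctx, c("start_s", "end_s")]
  pct <- freezing_percentage(as.matrix(iv),
                             c(first_cs$cs_onset_s[i], first_cs$cs_offset_s[i]))
  cat(sprintf("freezing, first CS in context %s: %.1f%%\n", ctx, pct))
}

ppi <- ppi_from_trials(startle)
cat(sprintf("PPI: %.1f%% (SS = %.1f over %d trials, PS = %.1f over %d)\n",
            ppi$ppi_percent, ppi$ss, ppi$n_ss, ppi$ps, ppi$n_ps))
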