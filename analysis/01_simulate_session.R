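#!/usr/bin/env Rscript
# Simulate a USV recording session with planted ground truth: a stream of
# vocal bouts, one spike train per unit for all eight canonical response
# profiles, and a short audio snippet for the segmenter. Writes the raw
# session tables under results/session/.

suppressPackageStartupMessages(library(vocalmod))

seed <- 1
out <- "results/session"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

duration <- 600
usv <- gen_usv_stream(duration, bout_rate = 12, seed = seed)
cat(sprintf("USV stream: %d syllables in %d bouts (%d first calls)\n",
            nrow(usv), max(usv$bout_id), sum(usv$is_first)))
write.csv(usv, file.path(out, "syllables.csv"), row.names = FALSE)

types <- rep(c("E1", "E2", "I1", "I2", "I3", "I4", "O", "NR"),
             c(70, 70, 70, 70, 70, 70, 70, 490))
pop <- gen_population(types, usv, duration, baseline_rate = 5,
                      seed = seed + 1)
write.csv(pop$units, file.path(out, "units_ground_truth.csv"),
          row.names = FALSE)
spikes_df <- data.frame(unit_id = rep(pop$units$unit_id,
                                      lengths(pop$spikes)),
                        time_s = unlist(pop$spikes))
write.csv(spikes_df, file.path(out, "spikes.csv"), row.names = FALSE)
cat(sprintf("population: %d units, %d spikes total\n",
            nrow(pop$units), nrow(spikes_df)))

# 4 s audio snippet (full-session ultrasonic audio would be ~1 GB)
snip_len <- 4
snip <- usv[usv$offset_s < snip_len, ]
wav <- gen_audio(snip, sample_rate = 250e3, duration = snip_len,
                 noise_sd = sqrt(0.05), seed = seed + 2)
write_wav(wav / max(abs(wav)), file.path(out, "snippet.wav"),
          sample_rate = 250e3)
cat(sprintf("audio snippet: %.1f s with %d planted syllables\n",
            snip_len, nrow(snip)))
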