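#!/usr/bin/env Rscript
# Segment the rendered audio snippet back into syllables and compare the
# detections with the planted ground truth: recall, onset accuracy and
# flat/FM agreement. Writes results/segmentation_eval.csv.

suppressPackageStartupMessages(library(vocalmod))

wav <- read_wav("results/session/snippet.wav")
truth <- read.csv("results/session/syllables.csv")
truth <- truth[truth$offset_s < 4, ]

seg <- segment_audio(wav)
cat(sprintf("detected %d syllables (planted: %d)\n", nrow(seg), nrow(truth)))

err <- vapply(truth$onset_s, function(o) min(abs(seg$onset_s - o)),
              numeric(1))
hit <- err <= 0.005
match <- vapply(truth$onset_s, function(o) which.min(abs(seg$onset_s - o)),
                integer(1))
eval_df <- data.frame(
  planted_onset_s = truth$onset_s,
  recovered = hit,
  onset_error_ms = err * 1000,
  planted_class = truth$call_class,
  detected_class = seg$call_class[match])
write.csv(eval_df, "results/segmentation_eval.csv", row.names = FALSE)

cat(sprintf("recall within 5 ms: %.1f%%; mean onset error %.2f ms\n",
            100 * mean(hit), 1000 * mean(err[hit])))
cat(sprintf("call-class agreement on recovered syllables: %.1f%%\n",
            100 * mean(eval_df$planted_class[hit] ==
                         eval_df$detected_class[hit])))
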