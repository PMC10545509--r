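#!/usr/bin/env Rscript
# Stage 1: stimulus construction.
# Builds the 100-item design (4 clear + 4 per channel count 24..1),
# synthesizes stand-in spoken-number audio, vocodes one utterance across a
# sweep of channel counts, and quantifies how spectral shape degrades while
# the temporal envelope survives. Writes:
#   results/stimulus_manifest.csv
#   results/vocoder_similarity.csv
#   scratch/audio/*.wav   (audio examples; regenerated on demand)

library(vocometrics)

seed <- 20260927L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/audio", recursive = TRUE, showWarnings = FALSE)

design <- build_stimulus_list(derive_seed(seed, "design"))
write.csv(design, "results/stimulus_manifest.csv", row.names = FALSE)
cat(sprintf("Design: %d items (%d clear, %d vocoded at %d levels)\n",
            nrow(design), sum(design$level == "clear"),
            sum(design$level != "clear"),
            length(unique(design$level[design$level != "clear"]))))

u <- synth_utterance("587", rate = 16000, seed = derive_seed(seed, "utt"))
write_wav(u, "scratch/audio/clear_587.wav")

rows <- lapply(c(1, 2, 4, 8, 16, 24), function(nch) {
  cfg <- vocoder_config(nch, seed = derive_seed(seed, "voc", nch))
  v <- vocode(u, cfg)
  write_wav(v, sprintf("scratch/audio/voc_587_ch%02d.wav", nch))
  env_cor <- cor(extract_envelope(u, 30)$samples,
                 extract_envelope(v, 30)$samples)
  data.frame(channels = nch,
             spectral_similarity = spectral_similarity(u, v),
             envelope_correlation = env_cor,
             rms_ratio = rms(v) / rms(u))
})
sim <- do.call(rbind, rows)
write.csv(sim, "results/vocoder_similarity.csv", row.names = FALSE)

cat("\nChannel sweep on utterance '587' (input vs vocoded):\n")
print(sim, row.names = FALSE, digits = 3)
cat("\nSpectral shape is destroyed at 1 channel and recovers with channel",
    "count,\nwhile the broadband envelope correlation stays high",
    "throughout and RMS is\nconserved -- spectral degradation with",
    "preserved temporal structure.\n")
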