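#!/usr/bin/env Rscript
# Rate matching across the stimulus variants: for each design, run the model
# at its rate set on the strongest cell (coherence 8, duration 7) and report
# which rate carries the largest figure-minus-ground response. The winning
# rate tracks the rate at which figure tones arrive in a channel: 20 Hz for
# 50 ms chords (whole stimulus or isolated figure), 40 Hz for 25 ms chords,
# ~10 Hz for the 2-step ramp whose trajectory dwells only ~2 chords within a
# channel's spectral neighborhood. The 5-step ramp and the noise-interleaved
# design give responses near the Monte-Carlo floor at this n_iter -- the
# hardest conditions for listeners are the hardest for the model too.

library(sfgmodel)

dir.create("results", showWarnings = FALSE)
n_iter <- 100
rows <- list()
for (nm in c("exp1", "exp3", "exp4a", "exp4b", "exp5", "exp6a")) {
  sp <- experiment_spec(nm, n_iter = n_iter, seed = 21)
  mc <- model_config(rates_hz = sp$rates_hz,
                     scale_cyc_per_oct = sp$scale_cyc_per_oct, n_iter = n_iter)
  res <- suppressWarnings(model_response(
    data.frame(coherence = 8, duration = 7), sp$config, mc,
    window = sp$window, seed = 21))
  res <- cbind(experiment = nm, res)
  rows[[nm]] <- res
  cat(sprintf("%-6s best rate %5.2f Hz | deltas: %s\n", nm, best_rate(res),
              paste(sprintf("%.4f", res$delta), collapse = " ")))
}
all <- do.call(rbind, rows)
write.csv(all, "results/variant_rates.csv", row.names = FALSE)
cat("Written to results/variant_rates.csv\n")
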