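#!/usr/bin/env Rscript
# Calibrate the detection model from reference-standard replicates:
# simulate the dilution series, fit the wild-type background, derive
# detection thresholds, and tabulate single-variant and panel-level
# sensitivity/specificity — analytically and against the Monte-Carlo
# oracle.

suppressPackageStartupMessages(library(ctdnafp))

seed <- 20260921L
outdir <- "results/calibration"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

series <- reference_noise_table()

# replicate-level simulation of the dilution series
reps <- do.call(rbind, lapply(seq_len(nrow(series)), function(i) {
  obs <- simulate_reference_replicates(
    noise_params(series$expected_af[i], series$mean_observed[i],
                 series$sd_observed[i]),
    n = series$n_replicates[i], seed = seed + i
  )
  data.frame(expected_af = series$expected_af[i], observed_af = obs)
}))
write.table(reps, file.path(outdir, "reference_replicates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

bg_fit <- fit_background(reps$observed_af[reps$expected_af == 0])
thr <- derive_thresholds(bg_fit$mean, bg_fit$sd)
cat(sprintf("Simulated background: %.3f%% +/- %.3f%% -> thresholds %.3f%% / %.3f%%\n",
            bg_fit$mean, bg_fit$sd, thr$single_threshold,
            thr$ccf_threshold))

# the reported model uses the published replicate summary directly
model <- detection_model()
write_detection_model_json(model, file.path(outdir, "detection_model.json"))
cat(sprintf("Reference model: single %.3f%%, CCF %.3f%% (~%.2f%%)\n",
            model$single_threshold, model$ccf_threshold,
            round(model$ccf_threshold, 2)))

# empirical single-variant sensitivity on the simulated replicates
sens <- vapply(split(reps$observed_af, reps$expected_af),
               single_variant_sensitivity,
               numeric(1), threshold = model$single_threshold)
cat("Single-variant sensitivity at threshold 0.127% (simulated replicates):\n")
print(round(100 * sens[names(sens) != "0"], 1))

# panel-level performance, analytic
perf <- build_performance_table(series, ks = c(5L, 10L))
write.table(perf, file.path(outdir, "panel_performance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
key <- perf[perf$expected_af %in% c(0, 0.25, 0.5), ]
cat("Panel-level performance (percent):\n")
print(data.frame(
  expected_af = key$expected_af, k = key$k,
  sensitivity = round(100 * key$sensitivity, 2),
  specificity = round(100 * key$specificity, 2)
))

# Monte-Carlo cross-check at the 0.25% standard, 5 targets
std025 <- noise_params(0.25, 0.276, 0.168)
mc <- panel_detection_probability_mc(5, std025, n_sims = 1e5,
                                     seed = seed)
cat(sprintf("MC check (k=5 @ 0.25%%): %.4f +/- %.4f vs analytic %.4f\n",
            mc$probability, mc$se,
            panel_detection_probability(5, std025)))
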