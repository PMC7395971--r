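#!/usr/bin/env Rscript
# Simulate the study inputs: a patient cohort with clonally structured
# somatic mutation profiles, written as VCF + TSV per patient, plus a
# cohort manifest. Everything downstream (panel design, quantification,
# monitoring) runs off these files or their in-memory equivalents.

suppressPackageStartupMessages(library(ctdnafp))

seed <- 20260921L
n_patients <- 50L # a manageable slice of the 313-patient scale
outdir <- "results/simulated"
dir.create(file.path(outdir, "variants"), recursive = TRUE,
           showWarnings = FALSE)

cfg <- cohort_config(n_patients = n_patients, seed = seed)
manifest <- simulate_cohort_manifest(cfg)
write.table(manifest, file.path(outdir, "cohort_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_mut <- integer(n_patients)
for (i in seq_len(n_patients)) {
  prof <- simulate_patient_profile(cfg, i)
  n_mut[i] <- nrow(prof)
  stem <- file.path(outdir, "variants", manifest$patient_id[i])
  write_variants_vcf(prof, paste0(stem, ".vcf"))
  write_variants_tsv(prof, paste0(stem, ".tsv"))
}

cat(sprintf("Simulated %d patients (seed %d)\n", n_patients, seed))
cat(sprintf("  somatic mutations per patient: median %d (range %d-%d)\n",
            as.integer(median(n_mut)), min(n_mut), max(n_mut)))
print(table(manifest$outcome))
cat("Wrote", outdir, "\n")
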