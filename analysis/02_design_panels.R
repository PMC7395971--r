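#!/usr/bin/env Rscript
# Design a ctDNA fingerprint panel per simulated patient: cluster
# clonal populations on purity/CNA-adjusted VAFs, take the top 10-45
# clonal SNVs, drop weak amplicons, and report how personalised the
# resulting panels are against the bundled known-cancer-gene list.
# Run analysis/01_simulate_cohort.R first.

suppressPackageStartupMessages(library(ctdnafp))

indir <- "results/simulated"
outdir <- "results/panels"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

manifest <- read.delim(file.path(indir, "cohort_manifest.tsv"))
panels <- list()
rows <- list()
tmb <- numeric(0)

for (i in seq_len(nrow(manifest))) {
  pid <- manifest$patient_id[i]
  prof <- read_variants_tsv(file.path(indir, "variants",
                                      paste0(pid, ".tsv")))
  tmb[pid] <- compute_tmb(prof, exome_mb = 30)
  clusters <- cluster_clonal_populations(prof, purity = manifest$purity[i])
  panel <- select_fingerprint_targets(clusters)
  status <- "ineligible"
  if (is_eligible(panel)) {
    eff <- simulate_amplicon_efficiency(panel, seed = 1000L + i)
    panel <- filter_amplicons(panel, eff)
    if (is_eligible(panel)) {
      status <- "designed"
      panels[[pid]] <- panel
      write_panel_tsv(panel,
                      tsv_path = file.path(outdir, paste0(pid, "_panel.tsv")),
                      bed_path = file.path(outdir, paste0(pid, "_panel.bed")))
    }
  }
  rows[[pid]] <- data.frame(
    patient_id = pid, status = status,
    k = if (status == "designed") panels[[pid]]$k else NA_integer_,
    tmb = tmb[pid]
  )
}

summary_df <- do.call(rbind, rows)
write.table(summary_df, file.path(outdir, "panel_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

designed <- summary_df[summary_df$status == "designed", ]
cat(sprintf("Designed %d/%d panels; target count median %d (range %d-%d)\n",
            nrow(designed), nrow(summary_df),
            as.integer(median(designed$k)), min(designed$k),
            max(designed$k)))
cat(sprintf("TMB: median %.1f mutations/Mb\n", median(tmb)))

report <- panel_specificity_report(panels, read_known_genes())
cat(sprintf("Targets unique to one panel: %.1f%%\n",
            100 * report$frac_unique_targets))
cat(sprintf("Panels with <10 known cancer genes: %.1f%%\n",
            100 * report$frac_panels_lt10_known))
write.table(report$per_panel, file.path(outdir, "panel_known_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
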