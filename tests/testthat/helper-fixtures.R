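# shared in-code fixtures; everything is generated, nothing is stored

# a minimal fingerprint panel with k synthetic SNV targets
make_panel <- function(k = 23L, patient_id = "P0001", seed = 1L) {
  withr::with_seed(seed, {
    targets <- tibble::tibble(
      chrom = as.character(sample.int(22L, k, replace = TRUE)),
      pos = sample.int(1e8L, k),
      ref = sample(c("A", "C", "G", "T"), k, replace = TRUE),
      alt = "T",
      gene = sprintf("GENE%05d", sample.int(99999L, k)),
      adjusted_vaf = sort(runif(k, 0.3, 0.9), decreasing = TRUE),
      cluster_id = "C1"
    )
    targets$alt <- ifelse(targets$alt == targets$ref, "A", targets$alt)
    targets$target_id <- paste(targets$chrom, targets$pos, targets$ref,
                               targets$alt, sep = ":")
    fingerprint_panel(patient_id, targets)
  })
}

# a ctdna_test whose CTRs are given exactly (read depth 1e6 keeps
# rounding negligible; depth 'exact' uses alt/total chosen to be exact)
make_test <- function(ctrs, date, patient_id = "P0001",
                      total = 1000000L) {
  counts <- tibble::tibble(
    target_id = sprintf("t%03d", seq_along(ctrs)),
    alt_reads = as.integer(round(ctrs * total)),
    total_reads = total
  )
  ctdna_test(patient_id, as.Date(date), counts)
}

passing_qc <- function() run_qc_metrics(0.95, 0.60, 25000, 0.95)

# clonal clusters built by hand for selection tests
make_clusters <- function(sizes, means, high = NULL, seed = 7L) {
  high <- high %||% (means >= 0.6 * max(means))
  withr::with_seed(seed, {
    cls <- purrr::pmap(
      list(seq_along(sizes), sizes, means, high),
      function(i, n, m, h) {
        members <- tibble::tibble(
          patient_id = "P0001",
          chrom = as.character(sample.int(22L, n, replace = TRUE)),
          pos = sample.int(1e8L, n),
          ref = "A", alt = "G",
          gene = sprintf("GENE%05d", sample.int(99999L, n)),
          vaf = pmin(pmax(rnorm(n, m, 0.02), 0.01), 0.99),
          cna = 2, loh = FALSE
        )
        members$adjusted_vaf <- members$vaf
        structure(
          list(cluster_id = sprintf("C%d", i),
               mean_adjusted_vaf = mean(members$adjusted_vaf),
               members = members, is_high_frequency = h),
          class = "clonal_cluster"
        )
      }
    )
    structure(cls, class = "clonal_clusters")
  })
}
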