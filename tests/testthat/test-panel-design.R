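test_that("VAF adjustment handles purity, copy number and LOH", {
  expect_equal(adjust_vaf(0.25, purity = 0.5), 0.5)
  expect_equal(adjust_vaf(0.5, purity = 1), 0.5)
  expect_equal(adjust_vaf(0.3, purity = 0.6, cna = 4), 1) # capped
  expect_equal(adjust_vaf(0.2, purity = 0.8, cna = 2, loh = TRUE),
               0.2 * 2 / 0.8)
  expect_error(adjust_vaf(0.5, purity = 0), "purity")
})

test_that("clustering handles degenerate and well-separated inputs", {
  # identical adjusted VAFs: one cluster, no error
  v <- tibble::tibble(vaf = rep(0.3, 10), cna = 2, loh = FALSE)
  cl <- cluster_clonal_populations(v, purity = 1)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mean_adjusted_vaf, 0.3)
  expect_error(cluster_clonal_populations(v[1, ], purity = 1), "at least 2")
})

test_that("cluster means equal the mean of member adjusted VAFs", {
  v <- tibble::tibble(vaf = rep(0.3, 10), cna = 2, loh = FALSE)
  cl <- cluster_clonal_populations(v, purity = 1)
  expect_equal(cl[[1]]$mean_adjusted_vaf,
               mean(cl[[1]]$members$adjusted_vaf))
  expect_true(cl[[1]]$is_high_frequency)
})

test_that("clustering is invariant to variant order", {
  cfg <- cohort_config(n_patients = 2, mutations_per_patient = c(80, 80),
                       seed = 31)
  prof <- simulate_patient_profile(cfg, 1, cluster_means = c(0.5, 0.2))
  cl1 <- cluster_clonal_populations(prof, purity = 1)
  shuffled <- prof[withr::with_seed(4, sample(nrow(prof))), ]
  cl2 <- cluster_clonal_populations(shuffled, purity = 1)
  expect_equal(length(cl1), length(cl2))
  key <- function(cl) {
    lapply(cl, function(c) sort(paste(c$members$chrom, c$members$pos)))
  }
  expect_equal(key(cl1), key(cl2))
})

test_that("strict copy-neutral mode excludes CNA/LOH variants from clustering", {
  v <- tibble::tibble(
    vaf = c(rep(0.4, 20), 0.4, 0.4),
    cna = c(rep(2, 20), 3.5, 2),
    loh = c(rep(FALSE, 21), TRUE)
  )
  cl <- cluster_clonal_populations(v, purity = 1)
  expect_equal(sum(purrr::map_int(cl, ~ nrow(.x$members))), 20)
  cl_all <- cluster_clonal_populations(v, purity = 1,
                                       strict_copy_neutral = FALSE)
  expect_equal(sum(purrr::map_int(cl_all, ~ nrow(.x$members))), 22)
})

test_that("only near-top clusters are flagged high-frequency", {
  cl <- make_clusters(sizes = c(20, 20, 20), means = c(0.5, 0.35, 0.1))
  expect_equal(purrr::map_lgl(cl, "is_high_frequency"),
               c(TRUE, TRUE, FALSE)) # 0.35 >= 0.6 * 0.5, 0.1 < 0.3
  one_top <- make_clusters(sizes = c(20, 20, 20),
                           means = c(0.5, 0.25, 0.1))
  expect_equal(sum(purrr::map_lgl(one_top, "is_high_frequency")), 1)
})

test_that("target selection takes the top clonal SNVs by adjusted VAF", {
  # 50 clonal candidates -> panel capped at 45
  cl <- make_clusters(sizes = c(50, 30), means = c(0.45, 0.1))
  panel <- select_fingerprint_targets(cl)
  expect_true(is_eligible(panel))
  expect_equal(panel$k, 45)
  # all targets come from the high-frequency cluster
  expect_true(all(panel$targets$cluster_id == "C1"))
  # 23 candidates -> panel of 23, ordered by adjusted VAF descending
  cl <- make_clusters(sizes = c(23, 30), means = c(0.45, 0.1))
  panel <- select_fingerprint_targets(cl)
  expect_equal(panel$k, 23)
  expect_true(all(diff(panel$targets$adjusted_vaf) <= 0))
  # 9 candidates -> typed ineligible outcome, not an error
  cl <- make_clusters(sizes = c(9, 30), means = c(0.45, 0.1))
  out <- select_fingerprint_targets(cl)
  expect_false(is_eligible(out))
  expect_s3_class(out, "ineligible_panel")
  expect_equal(out$n_candidates, 9)
})

test_that("VAF ties break by genomic coordinate ascending", {
  cl <- make_clusters(sizes = 12, means = 0.4)
  cl[[1]]$members$adjusted_vaf <- 0.4 # force an all-tied ranking
  panel <- select_fingerprint_targets(cl, min_k = 5)
  m <- panel$targets
  num <- as.numeric(m$chrom)
  expect_true(all(diff(num) > 0 | (diff(num) == 0 & diff(m$pos) > 0)))
})

test_that("amplicon filtering drops weak targets and respects min_k", {
  panel <- make_panel(45)
  eff <- setNames(rep(1, 45), panel$targets$target_id)
  expect_equal(filter_amplicons(panel, eff)$k, 45) # unchanged
  eff[panel$targets$target_id[3]] <- 0.2
  expect_equal(filter_amplicons(panel, eff)$k, 44)
  small <- make_panel(10)
  eff10 <- setNames(c(0.2, rep(1, 9)), small$targets$target_id)
  expect_false(is_eligible(filter_amplicons(small, eff10)))
  expect_error(filter_amplicons(panel, eff[-1]), "No efficiency entry")
})

test_that("TMB counts nonsynonymous mutations per megabase and is additive", {
  v <- tibble::tibble(consequence = rep("nonsynonymous", 150))
  expect_equal(compute_tmb(v, 30), 5)
  expect_equal(compute_tmb(v[0, ], 30), 0)
  mixed <- tibble::tibble(consequence = c(rep("nonsynonymous", 7),
                                          rep("synonymous", 3)))
  expect_equal(compute_tmb(mixed, 30), 7 / 30)
  expect_equal(compute_tmb(dplyr::bind_rows(v, mixed), 30),
               compute_tmb(v, 30) + compute_tmb(mixed, 30))
  expect_error(compute_tmb(v, 0), "positive")
})

test_that("specificity report counts known genes and unique targets", {
  known <- read_known_genes()
  p <- make_panel(20, seed = 2)
  r <- panel_specificity_report(list(p), known)
  expect_equal(r$per_panel$n_known_genes, 0) # anonymous gene labels
  expect_equal(r$frac_unique_targets, 1)
  # the same targets in two patients' panels: nothing unique
  p_dup <- p
  p_dup$patient_id <- "P0002"
  r2 <- panel_specificity_report(list(p, p_dup), known)
  expect_equal(r2$frac_unique_targets, 0)
  # a panel containing known cancer genes is counted
  p3 <- make_panel(12, seed = 3)
  p3$targets$gene[1:3] <- c("TP53", "KRAS", "APC")
  r3 <- panel_specificity_report(list(p3), known)
  expect_equal(r3$per_panel$n_known_genes, 3)
  expect_equal(r3$frac_panels_lt10_known, 1)
})
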