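test_that("reference replicates follow the truncated-normal noise model", {
  # zero variance: a point mass at the mean
  expect_equal(
    simulate_reference_replicates(noise_params(1, 0.9, 0), 5, seed = 1),
    rep(0.9, 5)
  )
  # all frequencies non-negative, reproducible under a fixed seed
  bg <- noise_params(0, 0.065, 0.062)
  x1 <- simulate_reference_replicates(bg, 5000, seed = 11)
  x2 <- simulate_reference_replicates(bg, 5000, seed = 11)
  expect_identical(x1, x2)
  expect_true(all(x1 >= 0))
  # large-n mean matches the closed-form truncated moments, not the
  # untruncated 0.065 (truncation at 0 lifts the mean)
  x <- simulate_reference_replicates(bg, 2e5, seed = 5)
  mom <- truncnorm_moments(0.065, 0.062)
  expect_gt(mom$mean, 0.065)
  expect_lt(abs(mean(x) - mom$mean), 3 * mom$sd / sqrt(length(x)))
  expect_lt(abs(sd(x) - mom$sd) / mom$sd, 0.02)
  expect_error(simulate_reference_replicates(bg, 0), "positive")
})

test_that("replicate sensitivity at the 0.25% standard is near the assay's 75%", {
  # the empirical assay distribution is skewed, so the normal model is
  # only expected to approximate the printed 75.0%
  x <- simulate_reference_replicates(noise_params(0.25, 0.276, 0.168),
                                     157, seed = 3)
  sens <- single_variant_sensitivity(x, 0.127)
  expect_gt(sens, 0.65)
  expect_lt(sens, 0.90)
})

test_that("cohort configuration validates its probability maps", {
  expect_error(cohort_config(outcome_weights = c(PD = 0.5, SD = 0.5)),
               "PD/SD/OR")
  expect_error(
    cohort_config(tumor_type_weights = c(colorectal = 0.5, lung = 0.4)),
    "sum to 1"
  )
  expect_s3_class(cohort_config(n_patients = 10), "cohort_config")
})

test_that("cohort outcome proportions converge to the configured weights", {
  cfg <- cohort_config(n_patients = 1e4, seed = 20)
  man <- simulate_cohort_manifest(cfg)
  tab <- table(factor(man$outcome, levels = names(cfg$outcome_weights)))
  gof <- chisq.test(tab, p = cfg$outcome_weights)
  expect_gt(gof$p.value, 0.01)
  expect_true(all(man$purity >= 0.3 & man$purity <= 0.9))
})

test_that("patient profiles carry clonal structure and unique identifiers", {
  cfg <- cohort_config(n_patients = 300, seed = 8)
  # single cluster: all VAFs within its spread
  p1 <- simulate_patient_profile(cfg, 1, cluster_means = 0.4,
                                 cluster_sd = 0.02)
  expect_true(all(abs(p1$vaf - 0.4) < 0.02 * 5))
  # determinism
  expect_identical(simulate_patient_profile(cfg, 2),
                   simulate_patient_profile(cfg, 2))
  expect_error(simulate_patient_profile(cfg, 301), "n_patients")
  # cross-patient sharing of (chrom,pos,ref,alt) identifiers is rare
  ids <- unlist(lapply(seq_len(300), function(i) {
    v <- simulate_patient_profile(cfg, i)
    unique(paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"))
  }))
  expect_gt(mean(table(ids) == 1), 0.9)
})

test_that("two-cluster profiles are recovered by the clustering stage", {
  cfg <- cohort_config(n_patients = 5, mutations_per_patient = c(100, 100),
                       seed = 77)
  prof <- simulate_patient_profile(cfg, 1, cluster_means = c(0.45, 0.10),
                                   cluster_sd = 0.02)
  # default strict copy-neutral mode keeps the adjusted VAFs on the
  # cluster means; CNA/LOH sites would otherwise scatter them
  cl <- cluster_clonal_populations(prof, purity = 1)
  expect_length(cl, 2)
  got <- sort(purrr::map_dbl(cl, "mean_adjusted_vaf"))
  expect_lt(max(abs(got - c(0.10, 0.45))), 0.03)
})

test_that("longitudinal tests follow the trajectory profile", {
  panel <- make_panel(23)
  # point-mass multiplier 1, no noise: every test has the same CCF
  flat <- trajectory_profile("SD", baseline_ccf = 1, multiplier_median = 1,
                             multiplier_sdlog = 0)
  tests <- simulate_longitudinal_tests(panel, flat, 4, seed = 2,
                                       measurement_noise = FALSE)
  ccfs <- purrr::map_dbl(tests, "ccf")
  expect_lt(diff(range(ccfs)), 0.02) # read-count rounding only
  # OR worked example: baseline 1.02%, one interval multiplier 0.31
  or <- trajectory_profile("OR", baseline_ccf = 1.02)
  tests <- simulate_longitudinal_tests(panel, or, 2, seed = 2,
                                       multipliers = 0.31,
                                       measurement_noise = FALSE)
  expect_lt(abs(tests[[2]]$ccf - 0.32), 0.02)
  # PD relapse example: baseline 0.29%, multiplier 291 -> fold change ~290
  pd <- trajectory_profile("PD", baseline_ccf = 0.29)
  tests <- simulate_longitudinal_tests(panel, pd, 2, seed = 2,
                                       multipliers = 291,
                                       measurement_noise = FALSE)
  fc <- fold_change_ccf(tests[[2]]$ccf, tests[[1]]$ccf)
  expect_equal(signif(fc, 2), 290)
  # schedule: 2w, 4w, then every 3 months, with <= 7-day jitter
  tests <- simulate_longitudinal_tests(panel, flat, 5, seed = 9)
  days <- as.numeric(purrr::map_vec(tests, "test_date") -
                       tests[[1]]$test_date)
  expect_true(all(diff(days) > 0))
  expect_lt(max(abs(days - c(0, 14, 28, 118, 208))), 8)
  expect_error(simulate_longitudinal_tests(panel, flat, 1), "pair")
})

test_that("trajectory multiplier medians sit on the correct side of 1", {
  expect_gt(trajectory_profile("PD")$multiplier_median, 1)
  expect_lt(trajectory_profile("OR")$multiplier_median, 1)
  expect_equal(trajectory_profile("SD")$multiplier_median, 1)
})
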