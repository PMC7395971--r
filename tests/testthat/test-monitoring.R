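day0 <- as.Date("2020-06-01")

tests_at <- function(offsets, ccfs, patient_id = "P1") {
  purrr::map2(offsets, ccfs, function(d, c) {
    make_test(rep(c / 200, 10), day0 + d, patient_id = patient_id)
  })
}

test_that("definitive test selection follows the 10-day/just-before rule", {
  # tests at day -40 and -3 relative to imaging: -3 is definitive
  tt <- tests_at(c(-40, -3), c(1, 2))
  sel <- select_definitive_test(tt, day0)
  expect_equal(sel$definitive$test_date, day0 - 3)
  expect_equal(sel$proceeding$test_date, day0 - 40)
  # none within 10 days: latest on/before imaging ("just before"),
  # even 4 months out, as in the hepatocellular case with an 8-month gap
  tt <- tests_at(c(-240, -120), c(1, 2))
  sel <- select_definitive_test(tt, day0)
  expect_equal(sel$definitive$test_date, day0 - 120)
  expect_equal(sel$proceeding$test_date, day0 - 240)
  # a test shortly AFTER imaging is eligible within the 10-day window
  tt <- tests_at(c(-60, 4), c(1, 2))
  expect_equal(select_definitive_test(tt, day0)$definitive$test_date,
               day0 + 4)
  # ... but never beyond 10 days after imaging
  tt <- tests_at(c(-90, -60, 11), c(1, 2, 3))
  sel <- select_definitive_test(tt, day0)
  expect_equal(sel$definitive$test_date, day0 - 60)
  expect_equal(sel$proceeding$test_date, day0 - 90)
  # ties inside the window go to the earlier draw
  tt <- tests_at(c(-30, -5, 5), c(1, 2, 3))
  expect_equal(select_definitive_test(tt, day0)$definitive$test_date,
               day0 - 5)
})

test_that("unpairable situations give a typed outcome", {
  expect_s3_class(select_definitive_test(tests_at(0, 1), day0),
                  "unpairable")
  # definitive is the earliest test: nothing proceeds it
  expect_s3_class(select_definitive_test(tests_at(c(-3, 20), c(1, 2)), day0),
                  "unpairable")
  # QC-failing tests are invisible to the selection
  bad <- ctdna_test("P1", day0 - 3,
                    tibble::tibble(target_id = "a", alt_reads = 5L,
                                   total_reads = 1000L),
                    qc = run_qc_metrics(0.5, 0.6, 25000, 0.95))
  expect_s3_class(select_definitive_test(list(bad, tests_at(0, 1)[[1]]),
                                         day0),
                  "unpairable")
})

test_that("fold change of CCF matches its definition and worked examples", {
  expect_equal(signif(fold_change_ccf(84.4, 0.29), 3), 290)
  expect_equal(fold_change_ccf(5, 5), 0)
  expect_equal(fold_change_ccf(0.16, 0.2), -0.2)
  expect_warning(fc <- fold_change_ccf(1, 0), "undefined")
  expect_true(is.na(fc))
  # invariance under common rescaling of both CCFs
  expect_equal(fold_change_ccf(8.44, 0.029), fold_change_ccf(84.4, 0.29))
})

test_that("trend classification partitions pairs into one label each", {
  expect_equal(classify_trend(0.1, 0.1), "undetectable")
  expect_equal(classify_trend(5, 5), "stable")
  expect_equal(classify_trend(3, 1, stability_band = 0.1), "increase")
  expect_equal(classify_trend(1, 3), "decrease")
  expect_equal(classify_trend(1, 0), "increase") # from zero to detectable
  expect_equal(classify_trend(0.2, 0), "undetectable")
  withr::with_seed(1, {
    def <- runif(50, 0, 2)
    pro <- runif(50, 0, 2)
    labs <- classify_trend(def, pro)
    expect_true(all(labs %in% c("undetectable", "stable", "increase",
                                "decrease")))
    expect_length(labs, 50)
  })
})

test_that("evaluation pairing assembles fold changes and folds CR into OR", {
  tbp <- list(
    P1 = tests_at(c(-60, -3), c(0.29, 84.4), "P1"),
    P2 = tests_at(c(-90, -5), c(1.02, 0.32), "P2")
  )
  clinical <- tibble::tibble(
    patient_id = c("P1", "P2"),
    imaging_date = c(day0, day0),
    outcome = c("PD", "CR")
  )
  pairs <- pair_with_evaluations(tbp, clinical)
  expect_equal(nrow(pairs), 2)
  expect_equal(signif(pairs$fold_change[1], 3), 290)
  expect_equal(pairs$outcome, c("PD", "OR"))
  expect_equal(pairs$outcome_raw, c("PD", "CR"))
  # a patient with several evaluations contributes several pairs
  clinical2 <- tibble::tibble(patient_id = "P1",
                              imaging_date = c(day0, day0 - 50),
                              outcome = c("PD", "SD"))
  expect_equal(nrow(suppressMessages(
    pair_with_evaluations(tbp["P1"], clinical2)
  )), 1) # the day0-50 evaluation has only one earlier test: unpairable
})

test_that("outcome summaries report group statistics and rank tests", {
  withr::with_seed(9, {
    pairs <- tibble::tibble(
      patient_id = sprintf("P%02d", 1:30),
      imaging_date = day0,
      ccf_pro = c(runif(10, 0.5, 2), runif(10, 0.1, 0.3), runif(10, 1, 3)),
      outcome_raw = rep(c("PD", "SD", "OR"), each = 10),
      outcome = rep(c("PD", "SD", "OR"), each = 10)
    )
    pairs$ccf_def <- pairs$ccf_pro * rep(c(3, 1, 0.15), each = 10)
    pairs$fold_change <- (pairs$ccf_def - pairs$ccf_pro) / pairs$ccf_pro
  })
  s <- summarize_by_outcome(pairs)
  gs <- s$group_summary
  expect_equal(gs$median_fold_change[gs$outcome == "PD"], 2)
  expect_equal(gs$median_fold_change[gs$outcome == "SD"], 0)
  expect_equal(gs$median_fold_change[gs$outcome == "OR"], -0.85)
  expect_lt(s$kruskal_fold_change, 0.01)
  expect_lt(s$kruskal_ccf_def, 0.05)
  expect_equal(nrow(s$pairwise_wilcoxon), 3)
  # an all-tied group yields a non-computable signed-rank p, not an error
  tied <- pairs
  tied$ccf_def[tied$outcome == "SD"] <- tied$ccf_pro[tied$outcome == "SD"]
  s2 <- summarize_by_outcome(tied)
  expect_true(is.na(s2$signed_rank$p_signed_rank[
    s2$signed_rank$outcome == "SD"
  ]))
  # two identical groups: Kruskal-Wallis cannot separate them
  same <- dplyr::bind_rows(
    dplyr::mutate(pairs[pairs$outcome == "PD", ], outcome = "A"),
    dplyr::mutate(pairs[pairs$outcome == "PD", ], outcome = "B")
  )
  expect_gt(summarize_by_outcome(same)$kruskal_ccf_def, 0.9)
})

test_that("per-mutation dynamics flags single mutations moving against the panel", {
  # all targets move with the panel: nothing flagged
  t1 <- make_test(rep(0.010, 5), day0)
  t2 <- make_test(rep(0.005, 5), day0 + 30)
  dyn <- per_mutation_dynamics(list(t1, t2))
  expect_equal(nrow(dyn$discordant), 0)
  expect_equal(dyn$ccf_series$ccf, c(2 * 0.010 * 100, 2 * 0.005 * 100))
  # one target doubles while the panel halves: flagged
  up <- c(0.020, rep(0.004, 4))
  dyn <- per_mutation_dynamics(list(t1, make_test(up, day0 + 30)))
  expect_equal(dyn$discordant$target_id, "t001")
  expect_equal(dyn$discordant$interval, 1)
  # a target below the single-variant threshold at both points is never
  # flagged, whatever its direction
  lo <- rep(0.0005, 5)
  hi <- c(0.0011, rep(0.0004, 4)) # falls, rises: still sub-threshold
  dyn <- per_mutation_dynamics(list(make_test(lo, day0),
                                    make_test(hi, day0 + 30)))
  expect_equal(nrow(dyn$discordant), 0)
  expect_error(per_mutation_dynamics(list(t1)), "length")
})

test_that("hotspot screening reports panel mutations above the AF threshold", {
  hp <- hotspot_panel()
  expect_setequal(hp$genes, c("BRAF", "EGFR", "ERBB2", "KIT", "KRAS",
                              "MET", "NRAS", "PIK3CA"))
  calls <- tibble::tibble(
    gene = c("KRAS", "KRAS", "EGFR", "TP53"),
    protein_change = c("p.G12D", "p.G12D", "p.T790M", "p.R175H"),
    af = c(0.0006, 0.0005, 0.0227, 0.5)
  )
  rep <- suppressMessages(screen_drug_mutations(calls, hp))
  # 0.0005 is not strictly above the 0.0005 threshold; TP53 is off-panel
  expect_equal(nrow(rep), 2)
  expect_equal(rep$af, c(0.0006, 0.0227))
  expect_match(rep$annotation[rep$gene == "EGFR"], "osimertinib")
  expect_message(screen_drug_mutations(calls, hp), "TP53")
})
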