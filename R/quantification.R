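#' Sequencing-run QC metrics
#'
#' @param frac_bases_q20 Fraction of bases at or above Q20.
#' @param frac_reads_on_target Fraction of reads mapping to the panel
#'   template.
#' @param mean_coverage Average per-target coverage (fold).
#' @param frac_amplicons_ge_1000x Fraction of amplicons covered above
#'   1000x.
#' @return A `run_qc_metrics` list.
#' @export
run_qc_metrics <- function(frac_bases_q20, frac_reads_on_target,
                           mean_coverage, frac_amplicons_ge_1000x) {
  stopifnot(
    frac_bases_q20 >= 0, frac_bases_q20 <= 1,
    frac_reads_on_target >= 0, frac_reads_on_target <= 1,
    mean_coverage >= 0,
    frac_amplicons_ge_1000x >= 0, frac_amplicons_ge_1000x <= 1
  )
  structure(
    list(
      frac_bases_q20 = frac_bases_q20,
      frac_reads_on_target = frac_reads_on_target,
      mean_coverage = mean_coverage,
      frac_amplicons_ge_1000x = frac_amplicons_ge_1000x
    ),
    class = "run_qc_metrics"
  )
}

#' QC-gate a sequencing run
#'
#' A run passes when all four criteria hold, each with strict
#' inequality: more than 70% of bases at Q20+, more than 40% of reads
#' on target, average coverage above 18,000x, and more than 80% of
#' amplicons covered above 1000x. A run exactly at a boundary fails.
#'
#' @param metrics A [run_qc_metrics()] object.
#' @return List with `pass` (logical) and `criteria`, a tibble of
#'   per-criterion verdicts.
#' @examples
#' qc_run(run_qc_metrics(0.95, 0.60, 25000, 0.95))$pass
#' @export
qc_run <- function(metrics) {
  stopifnot(inherits(metrics, "run_qc_metrics"))
  criteria <- tibble::tibble(
    criterion = c("bases_q20", "reads_on_target", "mean_coverage",
                  "amplicons_ge_1000x"),
    value = c(metrics$frac_bases_q20, metrics$frac_reads_on_target,
              metrics$mean_coverage, metrics$frac_amplicons_ge_1000x),
    threshold = c(0.70, 0.40, 18000, 0.80),
    pass = c(metrics$frac_bases_q20 > 0.70,
             metrics$frac_reads_on_target > 0.40,
             metrics$mean_coverage > 18000,
             metrics$frac_amplicons_ge_1000x > 0.80)
  )
  list(pass = all(criteria$pass), criteria = criteria)
}

#' Content ratio of one target
#'
#' CTR_i is the fraction of mutant reads at panel target i:
#' `alt_reads / total_reads`. A target with zero total reads carries no
#' measurement and is excluded from the CCF denominator upstream.
#'
#' @param alt_reads,total_reads Read counts, `0 <= alt <= total`.
#' @return Fraction in \[0, 1\] (vectorised); `NA` where
#'   `total_reads = 0`.
#' @export
estimate_ctr <- function(alt_reads, total_reads) {
  stopifnot(all(alt_reads >= 0), all(total_reads >= 0),
            all(alt_reads <= total_reads))
  ifelse(total_reads > 0, alt_reads / total_reads, NA_real_)
}

#' One ctDNA test (blood draw)
#'
#' Computes per-target content ratios and the panel-level ctDNA content
#' fraction \deqn{CCF = 2 \times (\sum_i CTR_i) / k} (reported in
#' percent), where `k` counts the targets that presented a measurement
#' (total reads above zero). The doubling reflects that each diploid
#' locus carries two allele copies. CCF is computed only when the run
#' passes QC.
#'
#' @param patient_id Patient label.
#' @param test_date A `Date`.
#' @param counts Tibble with `target_id`, `alt_reads`, `total_reads`.
#' @param qc A [run_qc_metrics()] object, or `NULL` to assume a passing
#'   run.
#' @param zero_coverage_as_zero Count zero-coverage targets as CTR = 0
#'   instead of excluding them from `k` (default `FALSE`: a failed
#'   amplicon presents no measurement).
#' @return A `ctdna_test` with fields `patient_id`, `test_date`, `counts`
#'   (with a `ctr` column), `k`, `ccf` (percent, `NA` if QC failed or no
#'   evaluable targets) and `qc_pass`.
#' @examples
#' counts <- tibble::tibble(target_id = letters[1:4],
#'                          alt_reads = rep(5L, 4),
#'                          total_reads = rep(1000L, 4))
#' ctdna_test("P1", as.Date("2020-01-01"), counts)$ccf  # 1.0
#' @export
ctdna_test <- function(patient_id, test_date, counts, qc = NULL,
                       zero_coverage_as_zero = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("target_id", "alt_reads", "total_reads") %in%
                  names(counts)),
            inherits(test_date, "Date"))
  if (anyDuplicated(counts$target_id)) {
    rlang::abort("Duplicate target_id in counts.")
  }
  counts <- tibble::as_tibble(counts)
  counts$ctr <- estimate_ctr(counts$alt_reads, counts$total_reads)
  qc_pass <- if (is.null(qc)) TRUE else qc_run(qc)$pass
  if (zero_coverage_as_zero) {
    counts$ctr[is.na(counts$ctr)] <- 0
  }
  evaluable <- !is.na(counts$ctr)
  k <- sum(evaluable)
  ccf <- if (qc_pass && k >= 1) {
    2 * mean(counts$ctr[evaluable]) * 100
  } else {
    NA_real_
  }
  structure(
    list(
      patient_id = patient_id,
      test_date = test_date,
      counts = counts,
      k = k,
      ccf = ccf,
      qc_pass = qc_pass,
      qc = qc
    ),
    class = "ctdna_test"
  )
}

#' @export
print.ctdna_test <- function(x, ...) {
  cat(sprintf("ctDNA test %s @ %s: k = %d, CCF = %s%%, QC %s\n",
              x$patient_id, format(x$test_date), x$k,
              if (is.na(x$ccf)) "NA" else sprintf("%.4f", x$ccf),
              if (x$qc_pass) "pass" else "FAIL"))
  invisible(x)
}

#' CCF of a ctDNA test
#'
#' @param test A [ctdna_test()].
#' @return CCF in percent; `NA` (with a warning) when the run failed QC
#'   or no target was evaluable.
#' @export
estimate_ccf <- function(test) {
  stopifnot(inherits(test, "ctdna_test"))
  if (!test$qc_pass) {
    rlang::warn("Run failed QC; CCF not evaluable.")
    return(NA_real_)
  }
  if (test$k == 0) {
    rlang::warn("No evaluable targets; CCF not evaluable.")
    return(NA_real_)
  }
  test$ccf
}

#' ctDNA positivity call
#'
#' Positive when CCF strictly exceeds the threshold; a CCF exactly at
#' the threshold is negative. The CCF value itself is always retained
#' regardless of the call.
#'
#' @param ccf CCF in percent (vectorised).
#' @param threshold Positivity threshold in percent (> 0); the clinical
#'   convention is 0.25.
#' @return Character vector, `"positive"` or `"negative"` (`NA` in,
#'   `NA` out).
#' @examples
#' call_positivity(c(0.30, 0.25, 0), 0.25)
#' @export
call_positivity <- function(ccf, threshold = 0.25) {
  stopifnot(threshold > 0)
  ifelse(is.na(ccf), NA_character_,
         ifelse(ccf > threshold, "positive", "negative"))
}

#' Flatten ctDNA tests to a per-test tibble
#'
#' @param tests List of [ctdna_test()] objects.
#' @param threshold Positivity threshold, percent.
#' @return Tibble: `patient_id`, `test_date`, `k`, `ccf_percent`,
#'   `positive`, `qc_pass`.
#' @export
tests_summary <- function(tests, threshold = 0.25) {
  purrr::map_dfr(tests, function(t) {
    tibble::tibble(
      patient_id = t$patient_id,
      test_date = t$test_date,
      k = t$k,
      ccf_percent = t$ccf,
      positive = call_positivity(t$ccf, threshold) == "positive",
      qc_pass = t$qc_pass
    )
  })
}
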