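#' Select the definitive and proceeding ctDNA tests
#'
#' The definitive test is the QC-passing test within 10 days of the
#' imaging examination (inclusive, whole days) closest to it, ties
#' going to the earlier draw; when no test falls in that window, the
#' latest test dated on or before the imaging date is taken instead
#' ("just before"). The proceeding test is the QC-passing test
#' immediately preceding the definitive one. A definitive test is never
#' dated more than 10 days after imaging.
#'
#' @param tests List of [ctdna_test()] objects for one patient.
#' @param imaging_date A `Date`.
#' @return List with `definitive` and `proceeding` [ctdna_test()]s, or
#'   an `unpairable` object (with a `reason`) when no valid pair
#'   exists.
#' @export
select_definitive_test <- function(tests, imaging_date) {
  stopifnot(inherits(imaging_date, "Date"))
  tests <- purrr::keep(tests, ~ .x$qc_pass)
  if (length(tests) < 2) {
    return(structure(list(reason = "fewer than 2 QC-passing tests"),
                     class = "unpairable"))
  }
  dates <- as.Date(purrr::map_vec(tests, "test_date"))
  ord <- order(dates)
  tests <- tests[ord]
  dates <- dates[ord]

  delta <- as.numeric(dates - imaging_date)
  in_window <- abs(delta) <= 10
  if (any(in_window)) {
    idx <- which(in_window)
    # closest to imaging; ties -> earlier test
    def_i <- idx[order(abs(delta[idx]), dates[idx])][1]
  } else if (any(delta <= 0)) {
    def_i <- max(which(delta <= 0))
  } else {
    return(structure(list(reason = "no test on or before imaging date"),
                     class = "unpairable"))
  }
  if (def_i == 1) {
    return(structure(list(reason = "no proceeding test before the definitive one"),
                     class = "unpairable"))
  }
  list(definitive = tests[[def_i]], proceeding = tests[[def_i - 1]])
}

#' Fold change of CCF
#'
#' `(CCF_def - CCF_pro) / CCF_pro`: the signed relative change between
#' the definitive test and its immediate predecessor. Undefined when
#' the proceeding CCF is zero (such pairs are described by their
#' absolute CCFs only).
#'
#' @param ccf_def,ccf_pro CCFs in percent; `ccf_pro > 0`.
#' @return Signed ratio; `NA_real_` with a warning when `ccf_pro = 0`.
#' @examples
#' fold_change_ccf(84.4, 0.29)  # ~290
#' fold_change_ccf(0.16, 0.2)   # -0.2
#' @export
fold_change_ccf <- function(ccf_def, ccf_pro) {
  stopifnot(all(ccf_def >= 0, na.rm = TRUE),
            all(ccf_pro >= 0, na.rm = TRUE))
  out <- ifelse(ccf_pro > 0, (ccf_def - ccf_pro) / ccf_pro, NA_real_)
  if (any(ccf_pro == 0, na.rm = TRUE)) {
    rlang::warn("Fold change undefined where the proceeding CCF is 0; returned NA.")
  }
  out
}

#' Pair ctDNA tests with clinical evaluations
#'
#' For each imaging evaluation, selects the definitive/proceeding test
#' pair and assembles one paired observation. Complete-response (CR)
#' evaluations are grouped with OR for statistics while the raw label
#' is preserved. Patients with several evaluations contribute several
#' pairs.
#'
#' @param tests_by_patient Named list (patient_id -> list of
#'   [ctdna_test()]s).
#' @param clinical Tibble: `patient_id`, `imaging_date` (`Date`),
#'   `outcome` in PD/SD/OR/CR.
#' @return Tibble of paired observations: `patient_id`, `imaging_date`,
#'   `ccf_def`, `ccf_pro`, `fold_change`, `outcome_raw`, `outcome`
#'   (CR folded into OR). Unpairable evaluations are dropped with a
#'   message.
#' @export
pair_with_evaluations <- function(tests_by_patient, clinical) {
  stopifnot(is.data.frame(clinical),
            all(c("patient_id", "imaging_date", "outcome") %in%
                  names(clinical)),
            all(clinical$outcome %in% c("PD", "SD", "OR", "CR")))
  rows <- purrr::pmap(clinical, function(patient_id, imaging_date,
                                         outcome, ...) {
    tests <- tests_by_patient[[patient_id]]
    if (is.null(tests)) {
      return(NULL)
    }
    sel <- select_definitive_test(tests, imaging_date)
    if (inherits(sel, "unpairable")) {
      rlang::inform(sprintf("%s @ %s unpairable: %s", patient_id,
                            format(imaging_date), sel$reason))
      return(NULL)
    }
    ccf_def <- sel$definitive$ccf
    ccf_pro <- sel$proceeding$ccf
    tibble::tibble(
      patient_id = patient_id,
      imaging_date = imaging_date,
      ccf_def = ccf_def,
      ccf_pro = ccf_pro,
      fold_change = if (ccf_pro > 0) (ccf_def - ccf_pro) / ccf_pro
                    else NA_real_,
      outcome_raw = outcome,
      outcome = if (outcome == "CR") "OR" else outcome
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Classify a paired observation's trajectory
#'
#' `undetectable` when both CCFs sit at or below the positivity
#' threshold; `stable` when the absolute fold change is within the
#' stability band; otherwise `increase` or `decrease` by the sign of
#' the fold change. Undetectable-at-both-timepoints counts as "no
#' change" in stable-disease style summaries.
#'
#' @param ccf_def,ccf_pro CCFs in percent.
#' @param ccf_threshold Positivity threshold, percent (default 0.25).
#' @param stability_band Maximum `|fold change|` still called stable
#'   (default 0.1).
#' @return One of `"undetectable"`, `"stable"`, `"increase"`,
#'   `"decrease"` (vectorised).
#' @export
classify_trend <- function(ccf_def, ccf_pro, ccf_threshold = 0.25,
                           stability_band = 0.1) {
  stopifnot(ccf_threshold > 0, stability_band >= 0)
  fc <- ifelse(ccf_pro > 0, (ccf_def - ccf_pro) / ccf_pro, NA_real_)
  dplyr::case_when(
    ccf_def <= ccf_threshold & ccf_pro <= ccf_threshold ~ "undetectable",
    !is.na(fc) & abs(fc) <= stability_band ~ "stable",
    !is.na(fc) & fc > 0 ~ "increase",
    !is.na(fc) & fc < 0 ~ "decrease",
    is.na(fc) & ccf_def > ccf_threshold ~ "increase", # from zero to detectable
    TRUE ~ "stable"
  )
}

#' Summarise paired observations by outcome group
#'
#' Per-group medians and means of the definitive CCF and of the fold
#' change (undefined fold changes excluded from fold-change statistics
#' only), a Kruskal-Wallis test across groups on each quantity,
#' pairwise Wilcoxon rank-sum tests on the definitive CCF, and a
#' within-group Wilcoxon signed-rank test of proceeding vs definitive
#' CCF. Degenerate all-tied groups get `NA` signed-rank p-values rather
#' than an error.
#'
#' @param pairs Tibble from [pair_with_evaluations()].
#' @return List: `group_summary` tibble, `kruskal_ccf_def` and
#'   `kruskal_fold_change` p-values, `pairwise_wilcoxon` tibble,
#'   `signed_rank` tibble.
#' @export
summarize_by_outcome <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("ccf_def", "ccf_pro", "fold_change", "outcome") %in%
                  names(pairs)))
  group_summary <- pairs |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_ccf_def = stats::median(.data$ccf_def),
      mean_ccf_def = mean(.data$ccf_def),
      median_fold_change = stats::median(.data$fold_change, na.rm = TRUE),
      mean_fold_change = mean(.data$fold_change, na.rm = TRUE),
      n_undetectable_both = sum(classify_trend(.data$ccf_def, .data$ccf_pro) ==
                                  "undetectable"),
      .groups = "drop"
    )

  groups <- unique(pairs$outcome)
  enough <- length(groups) >= 2 &&
    all(table(pairs$outcome) >= 2)

  safe_p <- function(expr) {
    tryCatch(suppressWarnings(expr)$p.value, error = function(e) NA_real_)
  }

  kruskal_ccf_def <- if (enough) {
    safe_p(stats::kruskal.test(pairs$ccf_def, factor(pairs$outcome)))
  } else {
    NA_real_
  }
  fc_ok <- !is.na(pairs$fold_change)
  kruskal_fold_change <- if (enough && sum(fc_ok) >= 4 &&
                             length(unique(pairs$outcome[fc_ok])) >= 2) {
    safe_p(stats::kruskal.test(pairs$fold_change[fc_ok],
                               factor(pairs$outcome[fc_ok])))
  } else {
    NA_real_
  }

  pairwise <- if (length(groups) >= 2) {
    combos <- utils::combn(sort(groups), 2, simplify = FALSE)
    purrr::map_dfr(combos, function(gg) {
      a <- pairs$ccf_def[pairs$outcome == gg[1]]
      b <- pairs$ccf_def[pairs$outcome == gg[2]]
      tibble::tibble(
        group1 = gg[1], group2 = gg[2],
        p_rank_sum = if (length(a) >= 2 && length(b) >= 2) {
          safe_p(stats::wilcox.test(a, b))
        } else {
          NA_real_
        }
      )
    })
  } else {
    tibble::tibble(group1 = character(), group2 = character(),
                   p_rank_sum = numeric())
  }

  signed_rank <- pairs |>
    dplyr::group_by(.data$outcome) |>
    dplyr::summarise(
      p_signed_rank = {
        d <- .data$ccf_def - .data$ccf_pro
        if (dplyr::n() >= 2 && any(d != 0)) {
          safe_p(stats::wilcox.test(.data$ccf_def, .data$ccf_pro,
                                    paired = TRUE))
        } else {
          NA_real_ # all tied/zero differences: not computable
        }
      },
      .groups = "drop"
    )

  list(
    group_summary = group_summary,
    kruskal_ccf_def = kruskal_ccf_def,
    kruskal_fold_change = kruskal_fold_change,
    pairwise_wilcoxon = pairwise,
    signed_rank = signed_rank
  )
}

#' Per-mutation dynamics across a patient's tests
#'
#' Tracks each target's content ratio over time next to the panel CCF
#' and flags intervals where a single mutation moves against the
#' overall trend: the CTR change has the opposite sign to the CCF
#' change and its magnitude exceeds the single-variant detection
#' threshold expressed as a read fraction. Targets absent from a test
#' leave a gap (no interpolation).
#'
#' @param tests List of [ctdna_test()]s on the same panel, any order.
#' @param single_threshold Single-variant threshold in percent
#'   (default 0.127); converted to a CTR fraction internally.
#' @return List: `ccf_series` tibble (`test_date`, `ccf`), `ctr_series`
#'   long tibble (`target_id`, `test_date`, `ctr`), `discordant` tibble
#'   of flagged (target, interval) rows.
#' @export
per_mutation_dynamics <- function(tests, single_threshold = 0.127) {
  stopifnot(length(tests) >= 2,
            all(purrr::map_lgl(tests, inherits, "ctdna_test")))
  ord <- order(as.Date(purrr::map_vec(tests, "test_date")))
  tests <- tests[ord]
  dates <- as.Date(purrr::map_vec(tests, "test_date"))
  ccf <- purrr::map_dbl(tests, "ccf")

  ctr_series <- purrr::map2_dfr(tests, seq_along(tests), function(t, i) {
    tibble::tibble(
      target_id = t$counts$target_id,
      test_date = dates[i],
      test_index = i,
      ctr = t$counts$ctr
    )
  })

  thr_frac <- single_threshold / 100
  wide <- tidyr::pivot_wider(ctr_series[c("target_id", "test_index", "ctr")],
                             names_from = "test_index",
                             values_from = "ctr")
  flags <- list()
  for (i in seq_len(length(tests) - 1)) {
    a <- wide[[as.character(i)]]
    b <- wide[[as.character(i + 1)]]
    d_ctr <- b - a
    d_ccf <- ccf[i + 1] - ccf[i]
    disc <- !is.na(d_ctr) & d_ccf != 0 &
      sign(d_ctr) != sign(d_ccf) & abs(d_ctr) > thr_frac
    if (any(disc)) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        target_id = wide$target_id[disc],
        interval = i,
        from_date = dates[i],
        to_date = dates[i + 1],
        delta_ctr = d_ctr[disc],
        delta_ccf = d_ccf
      )
    }
  }
  list(
    ccf_series = tibble::tibble(test_date = dates, ccf = ccf),
    ctr_series = ctr_series[c("target_id", "test_date", "ctr")],
    discordant = dplyr::bind_rows(flags) %||%
      tibble::tibble(target_id = character(), interval = integer())
  )
}

#' The fixed eight-gene hotspot drug-resistance panel
#'
#' @param variants Tibble (`gene`, `protein_change`) of the specific
#'   hotspot mutations assayed; defaults to the bundled synthetic
#'   stand-in list.
#' @param af_threshold Minimum allelic frequency (fraction) for
#'   reporting an acquired mutation; default 0.0005 (0.05%).
#' @return A `hotspot_panel` with the fixed gene set BRAF, EGFR, ERBB2,
#'   KIT, KRAS, MET, NRAS, PIK3CA.
#' @export
hotspot_panel <- function(variants = NULL, af_threshold = 0.0005) {
  genes <- c("BRAF", "EGFR", "ERBB2", "KIT", "KRAS", "MET", "NRAS",
             "PIK3CA")
  if (is.null(variants)) {
    path <- system.file("extdata", "hotspot_variants_synthetic.tsv",
                        package = "ctdnafp")
    variants <- tibble::as_tibble(utils::read.delim(path))
  }
  stopifnot(all(c("gene", "protein_change") %in% names(variants)),
            af_threshold > 0)
  bad <- setdiff(unique(variants$gene), genes)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Hotspot variants outside the eight-gene set: %s",
                         paste(bad, collapse = ", ")))
  }
  structure(
    list(genes = genes, variants = tibble::as_tibble(variants),
         af_threshold = af_threshold),
    class = "hotspot_panel"
  )
}

#' Screen ctDNA calls for acquired drug-related mutations
#'
#' Reports calls that match the hotspot panel's (gene, protein change)
#' list with allelic frequency strictly above the panel threshold.
#' EGFR p.T790M is annotated as osimertinib-relevant (it marks
#' resistance to first-line EGFR inhibitors and eligibility for
#' osimertinib). Calls in genes outside the eight-gene set are ignored
#' with a message.
#'
#' @param calls Tibble: `gene`, `protein_change`, `af` (fraction), plus
#'   any carried columns (e.g. `patient_id`).
#' @param panel A [hotspot_panel()].
#' @return Tibble of reported calls with an `annotation` column.
#' @examples
#' calls <- tibble::tibble(gene = "KRAS", protein_change = "p.G12D",
#'                         af = 0.0006)
#' screen_drug_mutations(calls, hotspot_panel())
#' @export
screen_drug_mutations <- function(calls, panel = hotspot_panel()) {
  stopifnot(is.data.frame(calls),
            all(c("gene", "protein_change", "af") %in% names(calls)),
            inherits(panel, "hotspot_panel"))
  outside <- setdiff(unique(calls$gene), panel$genes)
  if (length(outside) > 0) {
    rlang::inform(sprintf("Ignoring calls in non-panel gene(s): %s",
                          paste(outside, collapse = ", ")))
  }
  hits <- calls |>
    dplyr::semi_join(panel$variants, by = c("gene", "protein_change")) |>
    dplyr::filter(.data$af > panel$af_threshold)
  hits$annotation <- ifelse(
    hits$gene == "EGFR" & hits$protein_change == "p.T790M",
    "EGFR resistance mutation; osimertinib-relevant",
    "acquired drug-related mutation"
  )
  tibble::as_tibble(hits)
}
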