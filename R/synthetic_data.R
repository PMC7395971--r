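#' Simulate reference-standard replicate measurements
#'
#' Draws replicate observed allelic frequencies for one dilution-series
#' concentration from a normal distribution with the concentration's
#' mean/SD, truncated at zero (a frequency cannot be negative; the
#' wild-type replicates indeed bottom out at exactly 0).
#'
#' @param params A [noise_params()] object (percent scale).
#' @param n Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n` observed allelic frequencies, percent.
#' @examples
#' simulate_reference_replicates(noise_params(0, 0.065, 0.062), 5, seed = 1)
#' @export
simulate_reference_replicates <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "noise_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    rlang::abort("`n` must be a positive count.")
  }
  withr::with_seed(seed, {
    rtruncnorm0(n, params$mean_observed, params$sd_observed)
  })
}

# gene-symbol pool for the "known cancer gene" fraction of simulated
# profiles; mirrors the bundled synthetic known-gene fixture
cancer_gene_pool <- c(
  "TP53", "APC", "KRAS", "EGFR", "PIK3CA", "SMAD4", "ARID1A", "CTNNB1",
  "GNAQ", "KMT2C", "BRAF", "NRAS", "KIT", "MET", "ERBB2", "PTEN", "RB1",
  "ATM", "BRCA1", "BRCA2", "NF1", "FBXW7", "STK11", "CDKN2A", "IDH1",
  "NOTCH1", "ALK", "RET", "MYC", "VHL"
)

#' Configuration of a simulated patient cohort
#'
#' Defaults emulate the monitored cohort: eight tumour types dominated
#' by colorectal and hepatocellular carcinoma, imaging outcomes in the
#' 15:26:14 PD:SD:OR proportion of the paired clinical datasets, and
#' enough somatic mutations per patient that the clonal cluster yields a
#' 10-45 target panel for most patients.
#'
#' @param n_patients Cohort size.
#' @param tumor_type_weights Named probabilities over tumour-type labels.
#' @param outcome_weights Named probabilities over `PD`, `SD`, `OR`.
#' @param mutations_per_patient Integer range (length 2) of somatic
#'   mutation counts.
#' @param clonal_cluster_count Integer range (length 2) of the number of
#'   clonal populations per tumour.
#' @param purity_range Pathologist tumour-purity range; biopsies below
#'   20% tumour content are not assayed, so the floor is above that.
#' @param seed Integer seed; fixing it makes every downstream draw
#'   reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 300L,
                          tumor_type_weights = c(
                            colorectal = 0.38, hepatocellular = 0.20,
                            lung = 0.12, cholangiocarcinoma = 0.10,
                            gastric = 0.07, breast = 0.06,
                            pancreatic = 0.04, esophageal = 0.03
                          ),
                          outcome_weights = c(PD = 15, SD = 26, OR = 14) / 55,
                          mutations_per_patient = c(30L, 120L),
                          clonal_cluster_count = c(1L, 4L),
                          purity_range = c(0.3, 0.9),
                          seed = 1L) {
  stopifnot(
    n_patients >= 1,
    length(mutations_per_patient) == 2,
    mutations_per_patient[1] >= 2,
    diff(mutations_per_patient) >= 0,
    length(clonal_cluster_count) == 2,
    clonal_cluster_count[1] >= 1,
    diff(clonal_cluster_count) >= 0,
    length(purity_range) == 2, purity_range[1] > 0, purity_range[2] <= 1
  )
  if (abs(sum(tumor_type_weights) - 1) > 1e-8) {
    rlang::abort("`tumor_type_weights` must sum to 1.")
  }
  if (!setequal(names(outcome_weights), c("PD", "SD", "OR")) ||
      abs(sum(outcome_weights) - 1) > 1e-8) {
    rlang::abort("`outcome_weights` must be named PD/SD/OR and sum to 1.")
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      tumor_type_weights = tumor_type_weights,
      outcome_weights = outcome_weights,
      mutations_per_patient = as.integer(mutations_per_patient),
      clonal_cluster_count = as.integer(clonal_cluster_count),
      purity_range = purity_range,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Patient-level cohort manifest
#'
#' Draws per-patient metadata (tumour type, imaging outcome, tumour
#' purity) without generating mutation profiles, so cohort-level
#' composition can be studied cheaply at large n.
#'
#' @param config A [cohort_config()].
#' @return Tibble: `patient_id`, `tumor_type`, `outcome`, `purity`.
#' @export
simulate_cohort_manifest <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      tumor_type = sample(names(config$tumor_type_weights), n,
                          replace = TRUE, prob = config$tumor_type_weights),
      outcome = sample(names(config$outcome_weights), n,
                       replace = TRUE, prob = config$outcome_weights),
      purity = stats::runif(n, config$purity_range[1], config$purity_range[2])
    )
  })
}

#' Simulate one patient's somatic mutation profile
#'
#' Variant allele frequencies are drawn from a mixture of clonal
#' populations: one high-frequency (clonal) cluster around VAF
#' 0.35-0.50 and zero or more subclonal clusters at lower prevalence,
#' each with small within-cluster spread. Variant identities are
#' (chrom, pos, ref, alt) tuples over a virtual exome large enough that
#' cross-patient sharing is rare, matching how personalised the real
#' panels turned out to be. A small fraction of variants is assigned a
#' known cancer-gene symbol; the rest get anonymous gene labels.
#'
#' @param config A [cohort_config()].
#' @param patient_index 1-based index below `config$n_patients`.
#' @param cluster_means Optional fixed cluster mean VAFs (overrides the
#'   random cluster layout; used for parameter-recovery checks).
#' @param cluster_sd Within-cluster VAF standard deviation.
#' @return Tibble of somatic variants: `patient_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `vaf`, `cna`, `loh`, `consequence`,
#'   `true_cluster`.
#' @export
simulate_patient_profile <- function(config, patient_index,
                                     cluster_means = NULL,
                                     cluster_sd = 0.02) {
  stopifnot(inherits(config, "cohort_config"))
  if (patient_index < 1 || patient_index > config$n_patients) {
    rlang::abort("`patient_index` must be in 1..n_patients.")
  }
  withr::with_seed(config$seed + as.integer(patient_index), {
    n_mut <- sample(seq(config$mutations_per_patient[1],
                        config$mutations_per_patient[2]), 1)
    if (is.null(cluster_means)) {
      n_cl <- sample(seq(config$clonal_cluster_count[1],
                         config$clonal_cluster_count[2]), 1)
      clonal_mean <- stats::runif(1, 0.35, 0.50)
      sub_means <- if (n_cl > 1) {
        sort(stats::runif(n_cl - 1, 0.05, clonal_mean * 0.55),
             decreasing = TRUE)
      } else {
        numeric(0)
      }
      cluster_means <- c(clonal_mean, sub_means)
    }
    n_cl <- length(cluster_means)
    # clonal cluster holds a moderate share so panels span the 10-45 range
    w <- stats::rgamma(n_cl, shape = 2)
    w[1] <- w[1] * 1.5
    w <- w / sum(w)
    assign <- sample.int(n_cl, n_mut, replace = TRUE, prob = w)
    vaf <- stats::rnorm(n_mut, cluster_means[assign], cluster_sd)
    vaf <- pmin(pmax(vaf, 0.001), 0.999)

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_mut, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    known <- stats::runif(n_mut) < 0.06
    gene <- ifelse(known,
                   sample(cancer_gene_pool, n_mut, replace = TRUE),
                   sprintf("GENE%05d", sample.int(99999L, n_mut,
                                                  replace = TRUE)))
    tibble::tibble(
      patient_id = sprintf("P%04d", as.integer(patient_index)),
      chrom = as.character(sample.int(22L, n_mut, replace = TRUE)),
      pos = sample.int(1e8L, n_mut, replace = TRUE),
      ref = ref,
      alt = unname(alt),
      gene = gene,
      vaf = vaf,
      cna = ifelse(stats::runif(n_mut) < 0.10,
                   stats::runif(n_mut, 1, 4), 2),
      loh = stats::runif(n_mut) < 0.05,
      consequence = sample(c("nonsynonymous", "synonymous", "other"),
                           n_mut, replace = TRUE,
                           prob = c(0.8, 0.15, 0.05)),
      true_cluster = assign
    )
  })
}

#' Trajectory profile of a simulated outcome group
#'
#' Encodes how the true CCF evolves between consecutive blood draws for
#' a clinical outcome group: per-interval multipliers are log-normal
#' with median above 1 for progressive disease (PD), about 1 for stable
#' disease (SD) and well below 1 for objective response (OR, where the
#' median CCF drop observed clinically was 86.3%). Default baseline CCFs
#' anchor each group's definitive test to the scale the clinic reported
#' (measured medians 2.22% PD, 0.18% SD, 0.31% OR) under the standard
#' three-draw schedule: the printed medians are assay observations, so
#' the anchors are the true CCFs whose expected observed value equals
#' the printed median (inverting the censored-normal observation bias,
#' which lifts low concentrations: observed 0.18 corresponds to true
#' 0.067), divided by the two inter-test multipliers between baseline
#' and definitive draw.
#'
#' @param outcome One of `"PD"`, `"SD"`, `"OR"`.
#' @param baseline_ccf True CCF (percent) at the first blood draw.
#' @param multiplier_median Median of the per-interval CCF multiplier.
#' @param multiplier_sdlog Log-scale spread of the multiplier.
#' @return A `trajectory_profile` list.
#' @examples
#' trajectory_profile("OR", baseline_ccf = 1.02, multiplier_median = 0.31)
#' @export
trajectory_profile <- function(outcome = c("PD", "SD", "OR"),
                               baseline_ccf = NULL,
                               multiplier_median = NULL,
                               multiplier_sdlog = NULL) {
  outcome <- match.arg(outcome)
  # true-CCF anchors whose expected observed definitive values are the
  # reported group medians 2.22 / 0.18 / 0.31 (see the methods vignette)
  defaults <- list(
    PD = list(baseline = 1.957 / 3^2, median = 3.0, sdlog = 0.6),
    SD = list(baseline = 0.067, median = 1.0, sdlog = 0.25),
    OR = list(baseline = 0.243 / 0.15^2, median = 0.15, sdlog = 0.6)
  )[[outcome]]
  baseline_ccf <- baseline_ccf %||% defaults$baseline
  multiplier_median <- multiplier_median %||% defaults$median
  multiplier_sdlog <- multiplier_sdlog %||% defaults$sdlog
  stopifnot(baseline_ccf >= 0, multiplier_median >= 0,
            multiplier_sdlog >= 0)
  structure(
    list(
      outcome = outcome,
      baseline_ccf = baseline_ccf,
      multiplier_median = multiplier_median,
      multiplier_sdlog = multiplier_sdlog
    ),
    class = "trajectory_profile"
  )
}

# quick random panel for trajectory simulations (no clustering stage)
random_panel <- function(patient_id, k, seed = 1L) {
  withr::with_seed(seed, {
    targets <- tibble::tibble(
      chrom = as.character(sample.int(22L, k, replace = TRUE)),
      pos = sample.int(1e8L, k),
      ref = sample(c("A", "C", "G", "T"), k, replace = TRUE),
      alt = "T",
      gene = sprintf("GENE%05d", sample.int(99999L, k)),
      adjusted_vaf = sort(stats::runif(k, 0.3, 0.9), decreasing = TRUE),
      cluster_id = "C1"
    )
    targets$alt <- ifelse(targets$alt == targets$ref, "A", targets$alt)
    targets$target_id <- paste(targets$chrom, targets$pos, targets$ref,
                               targets$alt, sep = ":")
    fingerprint_panel(patient_id, targets)
  })
}

#' Simulate a paired clinical-evaluation cohort
#'
#' Generates the full monitoring scenario for a cohort with fixed
#' outcome-group sizes (default 15 PD, 26 SD, 14 OR, the paired-dataset
#' composition): each patient gets a random 10-44 target panel, a
#' baseline CCF drawn log-normally around the group scale, three blood
#' draws following the group's trajectory profile, and one imaging
#' evaluation shortly after the last draw; the definitive/proceeding
#' pair and its fold change are then extracted exactly as for real
#' data.
#'
#' @param n_pd,n_sd,n_or Outcome-group sizes.
#' @param seed Integer seed.
#' @param baseline_sdlog Log-scale spread of baseline CCFs around the
#'   group default.
#' @return Tibble of paired observations (as
#'   [pair_with_evaluations()]).
#' @export
simulate_paired_cohort <- function(n_pd = 15L, n_sd = 26L, n_or = 14L,
                                   seed = 1L, baseline_sdlog = 0.6) {
  outcomes <- rep(c("PD", "SD", "OR"), times = c(n_pd, n_sd, n_or))
  rows <- lapply(seq_along(outcomes), function(i) {
    g <- outcomes[i]
    pid <- sprintf("P%04d", i)
    sub_seed <- seed + i
    withr::with_seed(sub_seed, {
      k <- sample(10:44, 1)
      base <- stats::rlnorm(1, log(trajectory_profile(g)$baseline_ccf),
                            baseline_sdlog)
    })
    panel <- random_panel(pid, k, seed = sub_seed)
    profile <- trajectory_profile(g, baseline_ccf = base)
    tests <- simulate_longitudinal_tests(panel, profile, n_tests = 3,
                                         seed = sub_seed)
    imaging <- tests[[3]]$test_date + 5
    sel <- select_definitive_test(tests, imaging)
    if (inherits(sel, "unpairable")) {
      return(NULL)
    }
    ccf_def <- sel$definitive$ccf
    ccf_pro <- sel$proceeding$ccf
    tibble::tibble(
      patient_id = pid,
      imaging_date = imaging,
      ccf_def = ccf_def,
      ccf_pro = ccf_pro,
      fold_change = if (ccf_pro > 0) (ccf_def - ccf_pro) / ccf_pro
                    else NA_real_,
      outcome_raw = g,
      outcome = g
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

# measurement-noise parameters at a true allelic frequency: both the
# observed mean (which carries the assay's low-concentration bias) and
# the SD are linearly interpolated from the reference dilution series;
# beyond the 15% standard the assay is effectively unbiased, so the
# mean follows the true frequency with the last tabulated SD
noise_model_at <- function(af_percent,
                           noise_table = reference_noise_table()) {
  top <- max(noise_table$expected_af)
  m <- stats::approx(noise_table$expected_af, noise_table$mean_observed,
                     xout = pmin(af_percent, top), rule = 2)$y
  m <- ifelse(af_percent > top, af_percent, m)
  s <- stats::approx(noise_table$expected_af, noise_table$sd_observed,
                     xout = af_percent, rule = 2)$y
  list(mean = m, sd = s)
}

#' Simulate a patient's longitudinal ctDNA tests
#'
#' Blood draws follow the monitoring schedule (2 and 4 weeks after the
#' definitive treatment, then every 3 months) with uniform +/- 7 day
#' jitter. The true CCF starts at the profile's baseline and is
#' multiplied by one log-normal draw per interval; per-target allele
#' fractions scatter around CCF/2 with fixed per-target weights (mean
#' 1), observed frequencies are zero-censored normal draws whose mean
#' and SD are interpolated from the reference dilution series — the
#' censoring leaves an atom at exactly zero, as in real low-input tests
#' where a mutation simply is not read (the reference replicates bottom
#' out at exactly 0) — and read counts are Poisson totals with binomial
#' alt counts.
#'
#' @param panel A [fingerprint_panel()].
#' @param profile A [trajectory_profile()].
#' @param n_tests Number of blood draws (>= 2; a fold change needs a
#'   pair).
#' @param seed Integer seed.
#' @param start_date Date of the first draw.
#' @param mean_total_reads Expected per-target read depth.
#' @param multipliers Optional fixed per-interval multipliers (length
#'   `n_tests - 1`), overriding the random draws.
#' @param measurement_noise Logical; `FALSE` removes observation noise
#'   (true fractions are reported exactly).
#' @return List of [ctdna_test()] objects, ordered by date.
#' @export
simulate_longitudinal_tests <- function(panel, profile, n_tests, seed = 1L,
                                        start_date = as.Date("2020-01-01"),
                                        mean_total_reads = 20000,
                                        multipliers = NULL,
                                        measurement_noise = TRUE) {
  stopifnot(inherits(panel, "fingerprint_panel"),
            inherits(profile, "trajectory_profile"))
  if (n_tests < 2) {
    rlang::abort("`n_tests` must be >= 2: fold change needs a pair of tests.")
  }
  if (!is.null(multipliers) && length(multipliers) != n_tests - 1) {
    rlang::abort("`multipliers` must have length n_tests - 1.")
  }
  k <- nrow(panel$targets)
  withr::with_seed(seed, {
    nominal <- c(0, 14, 28, 28 + 90 * seq_len(max(0, n_tests - 3)))
    nominal <- nominal[seq_len(n_tests)]
    jitter <- c(0, sample(-7:7, n_tests - 1, replace = TRUE))
    days <- nominal + jitter
    # jitter may reorder or collide draws; force strictly increasing days
    days <- Reduce(function(a, b) max(a + 1, b), days, accumulate = TRUE)
    dates <- start_date + days

    if (is.null(multipliers)) {
      multipliers <- stats::rlnorm(n_tests - 1,
                                   meanlog = log(profile$multiplier_median),
                                   sdlog = profile$multiplier_sdlog)
    }
    true_ccf <- profile$baseline_ccf * cumprod(c(1, multipliers))

    weights <- stats::rlnorm(k, 0, 0.4)
    weights <- weights / mean(weights)

    lapply(seq_len(n_tests), function(t) {
      af_true <- (true_ccf[t] / 2) * weights # percent per target
      af_obs <- if (measurement_noise) {
        nm <- noise_model_at(af_true)
        pmax(stats::rnorm(k, nm$mean, nm$sd), 0) # censored at 0
      } else {
        af_true
      }
      total <- stats::rpois(k, mean_total_reads)
      alt <- stats::rbinom(k, total, pmin(af_obs / 100, 1))
      counts <- tibble::tibble(
        target_id = panel$targets$target_id,
        alt_reads = alt,
        total_reads = total
      )
      qc <- run_qc_metrics(
        frac_bases_q20 = stats::runif(1, 0.85, 0.99),
        frac_reads_on_target = stats::runif(1, 0.55, 0.90),
        mean_coverage = mean(total) * stats::runif(1, 1.1, 1.6),
        frac_amplicons_ge_1000x = stats::runif(1, 0.9, 1.0)
      )
      ctdna_test(panel$patient_id, dates[t], counts, qc)
    })
  })
}
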