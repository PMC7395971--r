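#' Per-concentration noise parameters of the amplicon assay
#'
#' A `noise_params` object holds the observed allelic-frequency
#' distribution (in percent) of one reference-standard concentration:
#' the expected (nominal) frequency and the mean/SD actually measured
#' across replicate tests.
#'
#' @param expected_af Nominal allelic frequency of the standard, percent.
#' @param mean_observed Mean observed allelic frequency, percent.
#' @param sd_observed Standard deviation of the observed frequency, percent.
#' @return A `noise_params` list.
#' @examples
#' noise_params(0, 0.065, 0.062)  # wild-type background
#' @export
noise_params <- function(expected_af, mean_observed, sd_observed) {
  stopifnot(
    is.numeric(expected_af), length(expected_af) == 1, expected_af >= 0,
    is.numeric(mean_observed), mean_observed >= 0,
    is.numeric(sd_observed), sd_observed >= 0
  )
  structure(
    list(
      expected_af = expected_af,
      mean_observed = mean_observed,
      sd_observed = sd_observed
    ),
    class = "noise_params"
  )
}

#' Reference-standard dilution-series noise table
#'
#' Replicate summary of the multiplex-PCR assay on a commercial cfDNA
#' reference standard serially diluted to nominal allelic frequencies of
#' 15, 10, 6, 3, 1, 0.5, 0.25 and 0 percent (wild type): number of
#' replicate tests and the mean/SD of the observed allelic frequency at
#' each concentration. These figures are the package's default noise
#' model; the 0% row is the background against which detection
#' thresholds are derived.
#'
#' @return A tibble with columns `expected_af`, `mean_observed`,
#'   `sd_observed` (all percent) and `n_replicates`.
#' @examples
#' reference_noise_table()
#' @export
reference_noise_table <- function() {
  tibble::tibble(
    expected_af   = c(0,     0.10,  0.25,  0.50,  1.0,   3.0,   6.0,   10,    15),
    mean_observed = c(0.065, 0.122, 0.276, 0.577, 1.132, 3.380, 6.358, 9.858, 15.2),
    sd_observed   = c(0.062, 0.113, 0.168, 0.268, 0.197, 0.466, 0.751, 0.900, 1.142),
    n_replicates  = c(157L,  160L,  160L,  160L,  157L,  155L,  157L,  157L,  157L)
  )
}

#' Fit the background-noise parameters from wild-type replicates
#'
#' @param observations Observed allelic frequencies (percent) of
#'   wild-type (0% mutant) reference replicates.
#' @return A list with `mean` and `sd` (sample SD, n-1 denominator),
#'   both in percent.
#' @examples
#' fit_background(c(0, 0.13))
#' @export
fit_background <- function(observations) {
  if (!is.numeric(observations) || length(observations) < 2) {
    rlang::abort("`observations` must be numeric with at least 2 values.")
  }
  list(mean = mean(observations), sd = stats::sd(observations))
}

#' Derive single-variant and CCF detection thresholds
#'
#' The upper limit of background noise for a single variant is
#' `mean + sd` of the wild-type observations. Because each diploid locus
#' contributes two allele copies, the CCF positivity threshold is twice
#' that single-variant threshold. For the assay's measured background of
#' 0.065% +/- 0.062% this gives 0.127% and 0.254% (reported clinically as
#' "approximately 0.25%"; the model keeps the exact value).
#'
#' @param mean,sd Background mean and SD, percent.
#' @return List with `single_threshold` and `ccf_threshold`, percent.
#' @examples
#' derive_thresholds(0.065, 0.062)
#' @export
derive_thresholds <- function(mean, sd) {
  stopifnot(sd >= 0)
  single <- mean + sd
  list(single_threshold = single, ccf_threshold = 2 * single)
}

#' Empirical single-variant sensitivity
#'
#' Fraction of replicate observations strictly above the single-variant
#' detection threshold.
#'
#' @param observations Observed allelic frequencies, percent.
#' @param threshold Single-variant threshold, percent.
#' @return Fraction in \[0, 1\].
#' @export
single_variant_sensitivity <- function(observations, threshold) {
  stopifnot(is.numeric(observations), length(observations) >= 1)
  mean(observations > threshold)
}

#' Panel-level detection probability under the normal approximation
#'
#' A panel of `k` targets measures CCF = 2 x (mean of k per-target
#' allele fractions). With per-target noise \eqn{N(m, s^2)} the CCF is
#' approximately \eqn{N(2m, (2s/\sqrt{k})^2)}, so the probability of a
#' positive call (CCF strictly above the threshold) is
#' \deqn{P = 1 - \Phi\big((t - 2m) / (2s/\sqrt{k})\big).}
#' Evaluated at a mutant concentration this is the panel's sensitivity;
#' evaluated at the wild-type background it is the false-positive rate,
#' whose complement is the panel specificity.
#'
#' Note the threshold regime: when the expected CCF `2m` exceeds the
#' threshold, sensitivity grows with `k`; when `2m` sits below the
#' threshold (as at the 0.10% standard, expected CCF 0.244% vs 0.254%),
#' adding targets concentrates the CCF below the threshold and the
#' detection probability falls with `k`.
#'
#' @param k Number of panel targets (>= 1).
#' @param noise A [noise_params()] object (percent scale).
#' @param ccf_threshold CCF positivity threshold, percent. Default is the
#'   exact doubled background limit 0.254; pass 0.25 for the rounded
#'   clinical convention.
#' @return Detection probability in \[0, 1\]. With `sd = 0` the result is
#'   a step function (0 or 1) computed without division.
#' @examples
#' # five-target panel at the 0.25% standard
#' panel_detection_probability(5, noise_params(0.25, 0.276, 0.168))
#' @export
panel_detection_probability <- function(k, noise, ccf_threshold = 0.254) {
  stopifnot(inherits(noise, "noise_params"), k >= 1)
  m <- noise$mean_observed
  s <- noise$sd_observed
  if (s == 0) {
    return(as.numeric(2 * m > ccf_threshold))
  }
  1 - stats::pnorm((ccf_threshold - 2 * m) / (2 * s / sqrt(k)))
}

#' Monte-Carlo oracle for the panel detection probability
#'
#' Simulates panels of `k` per-target draws, forms CCF = 2 x mean, and
#' counts exceedances of the threshold. By default the draws follow the
#' same untruncated normal the analytic formula assumes, so the estimate
#' converges to [panel_detection_probability()] and serves as its
#' independent check. With `truncate = TRUE` the draws come from the
#' zero-truncated generator used for synthetic frequencies, which
#' quantifies how much the truncation (material only near 0%) shifts the
#' panel-level probability away from the closed form.
#'
#' @inheritParams panel_detection_probability
#' @param n_sims Number of simulated panels (>= 1e4).
#' @param seed Integer seed.
#' @param truncate Draw from the zero-truncated normal instead of the
#'   analytic model's untruncated normal. Default `FALSE`.
#' @return List with `probability`, `se` (binomial standard error) and
#'   `n_sims`.
#' @export
panel_detection_probability_mc <- function(k, noise, ccf_threshold = 0.254,
                                           n_sims = 1e5, seed = 1L,
                                           truncate = FALSE) {
  stopifnot(inherits(noise, "noise_params"), k >= 1, n_sims >= 1e4)
  m <- noise$mean_observed
  s <- noise$sd_observed
  if (s == 0) {
    p <- as.numeric(2 * m > ccf_threshold)
    return(list(probability = p, se = 0, n_sims = n_sims))
  }
  hits <- withr::with_seed(seed, {
    draw <- if (truncate) {
      function(n) rtruncnorm0(n, m, s)
    } else {
      function(n) stats::rnorm(n, m, s)
    }
    x <- matrix(draw(n_sims * k), nrow = k)
    ccf <- 2 * colMeans(x)
    sum(ccf > ccf_threshold)
  })
  p <- hits / n_sims
  list(probability = p, se = sqrt(p * (1 - p) / n_sims), n_sims = n_sims)
}

#' Detection model fitted from a reference-standard series
#'
#' Bundles the background-noise fit, the derived thresholds, and the
#' per-concentration noise table into one object used by the power
#' calculations and the monitoring stage.
#'
#' @param background_mean,background_sd Wild-type background mean/SD,
#'   percent.
#' @param noise_table Tibble like [reference_noise_table()].
#' @return A `detection_model` list with `background_mean`,
#'   `background_sd`, `single_threshold`, `ccf_threshold` and
#'   `noise_table`.
#' @examples
#' detection_model()  # the assay's reference calibration
#' @export
detection_model <- function(background_mean = 0.065,
                            background_sd = 0.062,
                            noise_table = reference_noise_table()) {
  thr <- derive_thresholds(background_mean, background_sd)
  structure(
    list(
      background_mean = background_mean,
      background_sd = background_sd,
      single_threshold = thr$single_threshold,
      ccf_threshold = thr$ccf_threshold,
      noise_table = noise_table
    ),
    class = "detection_model"
  )
}

#' @export
print.detection_model <- function(x, ...) {
  cat("Detection model\n")
  cat(sprintf("  background: %.3f%% +/- %.3f%%\n",
              x$background_mean, x$background_sd))
  cat(sprintf("  single-variant threshold: %.3f%%\n", x$single_threshold))
  cat(sprintf("  CCF threshold: %.3f%% (~%.2f%%)\n",
              x$ccf_threshold, round(x$ccf_threshold, 2)))
  cat(sprintf("  noise table: %d concentrations\n", nrow(x$noise_table)))
  invisible(x)
}

#' Panel performance table across the dilution series
#'
#' For each concentration in the series and each panel size in `ks`,
#' computes the panel-level detection probability under the normal
#' approximation; at mutant concentrations this is reported as
#' sensitivity, and the background (0%) row additionally yields the
#' panel specificity (1 - false-positive rate). Thresholds are derived
#' internally from the series' own 0% row.
#'
#' @param series Tibble with columns `expected_af`, `mean_observed`,
#'   `sd_observed` (percent), e.g. [reference_noise_table()].
#' @param ks Panel sizes to evaluate.
#' @param threshold_mode `"exact"` uses the derived CCF threshold
#'   (0.254% for the reference background); `"rounded"` uses it rounded
#'   to 2 decimals (the clinical 0.25% convention).
#' @return A tibble with one row per (concentration, k):
#'   `expected_af`, `k`, `detection_probability`, `sensitivity` (NA at
#'   0%), `specificity` (NA except at 0%).
#' @examples
#' build_performance_table(reference_noise_table(), ks = c(5, 10))
#' @export
build_performance_table <- function(series, ks = c(5L, 10L),
                                    threshold_mode = c("exact", "rounded")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(
    is.data.frame(series),
    all(c("expected_af", "mean_observed", "sd_observed") %in% names(series)),
    length(ks) >= 1, all(ks >= 1)
  )
  bg <- series[series$expected_af == 0, ]
  if (nrow(bg) != 1) {
    rlang::abort("`series` must contain exactly one background (0%) row.")
  }
  thr <- derive_thresholds(bg$mean_observed, bg$sd_observed)$ccf_threshold
  if (threshold_mode == "rounded") thr <- round(thr, 2)

  grid <- tidyr::expand_grid(
    series[c("expected_af", "mean_observed", "sd_observed")],
    k = as.integer(ks)
  )
  grid$detection_probability <- purrr::pmap_dbl(
    grid,
    function(expected_af, mean_observed, sd_observed, k) {
      panel_detection_probability(
        k, noise_params(expected_af, mean_observed, sd_observed), thr
      )
    }
  )
  grid |>
    dplyr::mutate(
      sensitivity = dplyr::if_else(.data$expected_af > 0,
                                   .data$detection_probability, NA_real_),
      specificity = dplyr::if_else(.data$expected_af == 0,
                                   1 - .data$detection_probability, NA_real_),
      ccf_threshold = thr
    ) |>
    dplyr::arrange(.data$expected_af, .data$k)
}
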