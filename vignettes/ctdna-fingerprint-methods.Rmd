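---
title: "Methods: patient-specific ctDNA fingerprint panels and CCF monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific ctDNA fingerprint panels and CCF monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnafp)
```

## The problem and the statistic

Fixed hotspot panels miss the mutations that actually drive an individual
patient's tumour, so this package implements the *fingerprint* strategy:
sequence the tumour exome once, identify the clonal (founding-population)
mutations, build a patient-specific multiplex-PCR amplicon panel over the
top 10–45 clonal SNVs, and then monitor treatment response from blood
draws alone.

Each blood draw yields per-target read counts. The content ratio of
target $i$ is $CTR_i = \text{alt reads}_i / \text{total reads}_i$, and the
panel-level tumour burden is the **ctDNA content fraction**

$$CCF = 2 \times \frac{1}{k}\sum_{i=1}^{k} CTR_i,$$

reported in percent, where $k$ counts the targets that presented a
measurement (total reads above zero) and the factor 2 reflects the two
allele copies at a diploid locus. A test is ctDNA-positive when its CCF
strictly exceeds the positivity threshold (clinically, 0.25%). Response
over time is summarised by the **fold change of CCF**,
$(CCF_{def} - CCF_{pro})/CCF_{pro}$, between the *definitive* test (the
draw within 10 days of a clinical imaging evaluation, or failing that the
last draw before it) and the immediately *proceeding* test.

## Panel design

`cluster_clonal_populations()` works on purity/copy-number–adjusted VAFs:
$\hat v = v \cdot (c/2)/\rho$ at copy-neutral sites and
$\hat v = v \cdot c/\rho$ under LOH (purity $\rho$, total copy number
$c$), capped at 1. The LOH branch is an approximation — the quantitative
role of the LOH ratio in the original clonality tooling is not published —
and by default (`strict_copy_neutral = TRUE`) non-copy-neutral and LOH
sites are excluded from the mixture fit altogether, the same restriction
classical clonality callers apply; they can still be panel candidates if
assigned later.

Clusters come from a one-dimensional Gaussian-mixture EM with BIC model
selection over 1–6 components (equal- and unequal-variance univariate
models). The univariate initialisation is quantile-based, so the fit is
deterministic and invariant to row order; a degenerate input (all adjusted
VAFs identical) short-circuits to a single cluster. "High-frequency"
clusters — the clonal population(s) feeding panel selection — are those
whose mean reaches 0.6× the largest cluster mean. The 0.6 ratio is a
design choice (the source assay does not define "high frequency"): it
keeps near-ties with the top cluster while excluding clearly subclonal
populations, and it is a user-settable argument.

Candidates are ranked by adjusted VAF descending, ties broken by genomic
coordinate ascending for determinism; whether the original assay ranked by
VAF, coverage or primer designability is unpublished, and VAF rank is the
choice here. The top 45 become the panel; patients with fewer than 10
candidates are *ineligible* — a typed outcome, not an error, mirroring the
study-design exclusion. Amplicons with simulated (or measured)
amplification efficiency below 0.6 are dropped afterwards, which is how
realised panels end up in the 10–44 range.

TMB is the count of nonsynonymous somatic mutations per megabase
(default 30 Mb callable exome).

## Detection model

The wild-type reference standard gives the background noise: mean 0.065%
± 0.062% (SD, $n-1$ denominator) observed allelic frequency. The
single-variant detection threshold is their sum, 0.127%, and because CCF
doubles the mean allele fraction, the CCF positivity threshold is
2 × 0.127 = 0.254%, rounded to "approximately 0.25%" in clinical
reporting. `derive_thresholds()` keeps the exact values; the power model
uses 0.254 by default because the printed panel-level percentages are
reproduced at that value (a `threshold_mode = "rounded"` option switches
to 0.25, shifting some cells by ~0.2 percentage points).

With per-target noise $N(m, s^2)$ at a given concentration, the CCF of a
$k$-target panel is approximately $N(2m, (2s/\sqrt{k})^2)$, so

$$P(\text{positive}) = 1 - \Phi\!\left(\frac{t - 2m}{2s/\sqrt{k}}\right).$$

```{r}
build_performance_table(reference_noise_table(), ks = c(5, 10)) |>
  subset(expected_af %in% c(0, 0.25, 0.5))
```

Evaluated at the 0.25% and 0.50% standards this reproduces sensitivities
of 97.6% / 99.7% ($k$ = 5 / 10) and 99.99% ($k$ = 5 at 0.50%); at the
background it gives specificities of 98.7% and 99.9%. Note the threshold
regime: at the 0.10% standard the expected CCF (2 × 0.122 = 0.244%) sits
*below* the 0.254% threshold, so adding targets concentrates the CCF
below the threshold and sensitivity *falls* with $k$ — which is why
sensitivities there hover at ~44–46% almost independently of panel size.
The single-variant specificity of the real wild-type replicates (80.3%)
does not follow from the normal model (~84%); it reflects the skew of the
empirical distribution and is treated as empirical, not reproducible.

`panel_detection_probability_mc()` is the independent Monte-Carlo oracle
for the closed form. Its default draws come from the same untruncated
normal the formula assumes — an oracle must share the model of the
quantity it checks — while `truncate = TRUE` switches to the
zero-truncated generator and quantifies how much truncation (material
only near 0%) lifts the panel-level exceedance probability above the
closed form.

## The synthetic-data generator

Nothing from the original cohort can be redistributed, so every input is
simulated:

* **Reference replicates** are zero-truncated normal draws with the
  dilution series' published mean/SD per concentration (15, 10, 6, 3, 1,
  0.5, 0.25, 0% — `reference_noise_table()`). The published summaries
  show right skew (medians below means at low concentrations) that a
  truncated normal does not reproduce; panel-level quantities, which
  average over targets, are insensitive to this.
* **Patient profiles** draw VAFs from a mixture of clonal populations
  (clonal mean 0.35–0.50, subclones lower, within-cluster SD 0.02),
  with mutation counts uniform on 30–120 per patient, tumour purity
  uniform on 0.3–0.9 (biopsies under 20% tumour content are not
  assayed), 10% of sites copy-number altered and 5% LOH. Variant
  identities are (chrom, pos, ref, alt) tuples over a virtual exome of
  22 × 10^8 positions, so cross-patient sharing is rare — matching how
  personalised the real panels were (96% of panel mutations occurred in
  a single panel).
* **Longitudinal tests** follow the monitoring schedule (2 and 4 weeks
  after treatment, then every 3 months, ±7 days uniform jitter). The
  true CCF starts at the outcome group's baseline and is multiplied by
  one log-normal draw per interval, with multiplier medians 3 (PD),
  1 (SD) and 0.15 (OR — the clinic saw a median 86.3% drop). Observed
  per-target frequencies are **zero-censored** normal draws whose mean
  and SD are interpolated from the dilution series: the interpolated
  mean carries the assay's low-concentration bias, and the censoring
  leaves an atom at exactly zero, as in real low-input tests where a
  mutation simply is not read (the reference replicates bottom out at
  exactly 0). Read counts are Poisson totals (mean 20,000×) with
  binomial alt counts.

Baseline CCF defaults anchor each group's *observed* definitive test to
the reported group medians (2.22% PD, 0.18% SD, 0.31% OR). Because the
censored observation model lifts low concentrations (a true CCF of 0.067%
reads as ~0.18%), the anchors are obtained by numerically inverting the
observation function and dividing by the two inter-test multipliers
between baseline and the definitive draw: true baselines 1.957/9 (PD),
0.067 (SD) and 0.243/0.15² (OR) percent.

Free parameters with no published value, chosen once: the SD-group
multiplier spread (sdlog 0.25 — tight, since 73% of SD cases showed no
change), the between-patient baseline spread (sdlog 0.6), and the
per-target weight spread (lognormal, sdlog 0.4, mean-normalised).

What the simulator does **not** emulate: the skew/zero-inflation details
of real read-level noise beyond the censoring atom, clonal haematopoiesis
contamination (the real assay removes it by design through matched
tumour/normal exomes), tumour-type-specific mutation signatures, and
indels/CNVs/fusions (the assay targets SNVs only). Passing simulation
checks therefore demonstrate that the *pipeline arithmetic and decision
rules* behave as specified under realistic noise magnitudes — not that
the assay's wet-lab performance is re-validated.

## Monitoring rules

* Definitive test: nearest QC-passing draw within ±10 days (inclusive,
  whole days) of imaging, ties to the earlier draw; otherwise the last
  draw on/before imaging. Never later than 10 days after imaging.
* CR evaluations fold into OR for group statistics (the clinical figures
  use PD/SD/OR); the raw label is preserved.
* Fold change is undefined when the proceeding CCF is 0; such pairs are
  excluded from fold-change statistics but keep contributing to
  absolute-CCF summaries (the 18 doubly-undetectable SD pairs are
  described by absolute status).
* Trend classification: *undetectable* when both CCFs are at or below
  the positivity threshold, *stable* when |fold change| ≤ 0.1 (the
  stability band is configurable; no published value exists), otherwise
  *increase*/*decrease* by sign.
* Group summaries use Kruskal–Wallis across groups, pairwise Wilcoxon
  rank-sum on definitive CCF, and within-group Wilcoxon signed-rank on
  (proceeding, definitive) pairs, all via the standard implementations;
  an all-tied group reports a non-computable signed-rank p rather than
  erroring.
* Per-mutation dynamics flag a target as discordant over an interval
  when its CTR change opposes the CCF change in sign and exceeds the
  single-variant threshold expressed as a read fraction (0.00127). The
  threshold magnitude is a documented stand-in — the original report
  does not define when a single mutation "increased significantly" —
  and it guarantees that targets below threshold at both time points
  are never flagged.
* Hotspot screening reports calls matching the eight-gene panel's
  (gene, protein change) list with allelic frequency strictly above
  0.05%; EGFR p.T790M carries an osimertinib-relevance annotation.

## Numerical conventions and edge cases

All QC and positivity comparisons are strict (`>`), matching the assay's
"greater than" phrasing; boundary behaviour is unit-tested. Sample SDs
use the $n-1$ denominator. Zero-coverage targets are excluded from $k$
(a failed amplicon presents no measurement) unless
`zero_coverage_as_zero = TRUE`. The truncated-normal sampler is an
inverse-CDF transform with a guard against the uniform draw landing on
the truncation boundary; `sd = 0` returns a point mass without division,
and the analytic power formula likewise degenerates to a step function.
Coordinates are 1-based (VCF convention) internally; BED exports are
0-based half-open. Seeds are explicit arguments everywhere; no function
leaves the global RNG state altered.

## Problem sizes in the test suite

The packaged checks run at sizes chosen to give stable statistics while
staying quick: 10^5 replicates for background parameter recovery (with
closed-form truncated-normal moments and a numerically integrated fourth
moment as the independent oracle), 10^6 simulations per cell for the
Monte-Carlo/analytic agreement sweep, 20 seeds for the cluster-recovery
and outcome-separation properties, and 300 simulated patients for the
panel-personalisation checks.

## Known limitations

The clonality stage is a deliberately simple univariate mixture, not a
multi-sample subclone reconstruction; it recovers well-separated VAF
clusters but will merge populations closer than roughly twice the
within-cluster spread. The detection model is a central-limit
approximation whose accuracy degrades for very small panels combined
with strongly skewed per-target noise. Cohort-scale figures of the
original study that depend on the unshared patient data (total mutation
counts, the 76% positivity rate, exact p-values) are mirrored only
qualitatively by the simulator.
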