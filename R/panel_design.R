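#' Adjust VAF for purity and copy number
#'
#' Converts a somatic variant allele frequency measured in an impure,
#' possibly copy-number-altered tumour sample into an approximate
#' cellular-prevalence fraction: `vaf * (cna/2) / purity` at
#' copy-neutral/non-LOH sites, and `vaf * cna / purity` where
#' heterozygosity is lost (the remaining allele carries the full copy
#' load). Results are capped at 1. The LOH branch is a documented
#' approximation; clustering defaults to excluding non-copy-neutral
#' sites anyway (see [cluster_clonal_populations()]).
#'
#' @param vaf Variant allele frequency in \[0, 1\] (vectorised).
#' @param purity Tumour purity in (0, 1\].
#' @param cna Total copy number at the site (default diploid 2).
#' @param loh Logical, loss of heterozygosity at the site.
#' @return Adjusted cellular-prevalence fraction(s) in \[0, 1\].
#' @examples
#' adjust_vaf(0.25, purity = 0.5)           # 0.5
#' adjust_vaf(0.3, purity = 0.6, cna = 4)   # capped at 1
#' @export
adjust_vaf <- function(vaf, purity, cna = 2, loh = FALSE) {
  if (any(purity <= 0) || any(purity > 1)) {
    rlang::abort("`purity` must be in (0, 1].")
  }
  stopifnot(all(vaf >= 0 & vaf <= 1), all(cna > 0))
  adj <- ifelse(loh, vaf * cna / purity, vaf * (cna / 2) / purity)
  pmin(adj, 1)
}

#' Cluster clonal populations from adjusted VAFs
#'
#' One-dimensional Gaussian-mixture clustering (EM, model selection by
#' BIC over 1..`max_clusters` components) of purity/CNA-adjusted VAFs;
#' each variant goes to its maximum-responsibility component. Clusters
#' whose mean adjusted VAF reaches `high_freq_ratio` times the largest
#' cluster mean are flagged as high-frequency (clonal) — these feed
#' panel selection. By default, variants outside a copy-neutral window
#' (`cna` in \[1.5, 2.5\] and no LOH) are excluded from clustering, the
#' same restriction classical clonality tools apply.
#'
#' The univariate mixture initialisation is quantile-based, so the
#' result is deterministic and invariant to the input row order.
#'
#' @param variants Tibble of somatic variants with at least `vaf`,
#'   `cna`, `loh` columns (as produced by [simulate_patient_profile()]
#'   or [read_variants_tsv()]).
#' @param purity Tumour purity in (0, 1\].
#' @param max_clusters Largest number of mixture components tried.
#' @param seed Integer seed (kept for interface stability; the fit is
#'   deterministic).
#' @param strict_copy_neutral Exclude non-copy-neutral / LOH variants
#'   from clustering (default `TRUE`).
#' @param high_freq_ratio Relative cutoff defining high-frequency
#'   clusters (default 0.6 x the maximum cluster mean).
#' @return A `clonal_clusters` list; each element has `cluster_id`,
#'   `mean_adjusted_vaf`, `members` (tibble with an `adjusted_vaf`
#'   column added) and `is_high_frequency`. Ordered by decreasing mean.
#' @export
cluster_clonal_populations <- function(variants, purity, max_clusters = 6L,
                                       seed = 1L,
                                       strict_copy_neutral = TRUE,
                                       high_freq_ratio = 0.6) {
  stopifnot(is.data.frame(variants),
            all(c("vaf", "cna", "loh") %in% names(variants)))
  if (nrow(variants) < 2) {
    rlang::abort("Need at least 2 variants to cluster.")
  }
  v <- variants
  v$adjusted_vaf <- adjust_vaf(v$vaf, purity, v$cna, v$loh)
  if (strict_copy_neutral) {
    keep <- v$cna >= 1.5 & v$cna <= 2.5 & !v$loh
    v <- v[keep, , drop = FALSE]
    if (nrow(v) < 2) {
      rlang::abort("Fewer than 2 copy-neutral variants; relax `strict_copy_neutral`.")
    }
  }
  x <- v$adjusted_vaf

  if (diff(range(x)) < 1e-12) {
    assignment <- rep(1L, length(x))
    means <- mean(x)
  } else {
    fit <- withr::with_seed(seed, {
      Mclust(x, G = seq_len(max_clusters),
             modelNames = c("E", "V"), verbose = FALSE)
    })
    assignment <- fit$classification
    means <- as.numeric(fit$parameters$mean)
  }
  ord <- order(means, decreasing = TRUE)
  relabel <- match(assignment, ord)
  means <- means[ord]
  max_mean <- max(means)

  clusters <- lapply(seq_along(means), function(i) {
    members <- v[relabel == i, , drop = FALSE]
    structure(
      list(
        cluster_id = sprintf("C%d", i),
        mean_adjusted_vaf = mean(members$adjusted_vaf),
        members = members,
        is_high_frequency = means[i] >= high_freq_ratio * max_mean
      ),
      class = "clonal_cluster"
    )
  })
  structure(clusters, class = "clonal_clusters")
}

#' @export
print.clonal_clusters <- function(x, ...) {
  cat(sprintf("%d clonal cluster(s):\n", length(x)))
  for (cl in x) {
    cat(sprintf("  %s: mean adjusted VAF %.3f, %d variants%s\n",
                cl$cluster_id, cl$mean_adjusted_vaf, nrow(cl$members),
                if (cl$is_high_frequency) " [high-frequency]" else ""))
  }
  invisible(x)
}

#' Construct a fingerprint panel
#'
#' @param patient_id Patient label.
#' @param targets Tibble with columns `target_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `adjusted_vaf`, `cluster_id`.
#' @return A `fingerprint_panel` with `k = nrow(targets)`.
#' @export
fingerprint_panel <- function(patient_id, targets) {
  stopifnot(is.data.frame(targets), nrow(targets) >= 1,
            all(c("target_id", "chrom", "pos", "ref", "alt") %in%
                  names(targets)))
  if (anyDuplicated(targets$target_id)) {
    rlang::abort("Panel targets must be unique.")
  }
  structure(
    list(patient_id = patient_id, targets = targets,
         k = nrow(targets)),
    class = "fingerprint_panel"
  )
}

#' @export
print.fingerprint_panel <- function(x, ...) {
  cat(sprintf("Fingerprint panel %s: %d targets\n", x$patient_id, x$k))
  print(utils::head(x$targets, 5))
  if (x$k > 5) cat(sprintf("  ... %d more\n", x$k - 5))
  invisible(x)
}

ineligible_panel <- function(patient_id, n_candidates, reason) {
  structure(
    list(patient_id = patient_id, n_candidates = n_candidates,
         reason = reason),
    class = "ineligible_panel"
  )
}

#' @export
print.ineligible_panel <- function(x, ...) {
  cat(sprintf("Patient %s ineligible: %s (%d candidates)\n",
              x$patient_id, x$reason, x$n_candidates))
  invisible(x)
}

#' Is a panel-design outcome an eligible panel?
#'
#' @param x Result of [select_fingerprint_targets()] or
#'   [filter_amplicons()].
#' @return `TRUE` for a `fingerprint_panel`, `FALSE` for an
#'   `ineligible_panel`.
#' @export
is_eligible <- function(x) inherits(x, "fingerprint_panel")

target_id_of <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Select fingerprint targets from clonal clusters
#'
#' Candidates are the union of all high-frequency cluster members,
#' ranked by adjusted VAF descending (ties broken by genomic coordinate
#' ascending); the top `max_k` become the panel. Patients with fewer
#' than `min_k` candidates are ineligible for a fingerprint assay and
#' get a typed `ineligible_panel` outcome rather than an error.
#'
#' @param clusters A `clonal_clusters` object from one patient.
#' @param min_k,max_k Panel size bounds (default 10 and 45).
#' @return A [fingerprint_panel()] or an `ineligible_panel`.
#' @export
select_fingerprint_targets <- function(clusters, min_k = 10L, max_k = 45L) {
  stopifnot(inherits(clusters, "clonal_clusters"), min_k >= 1,
            max_k >= min_k)
  hf <- purrr::keep(clusters, ~ .x$is_high_frequency)
  candidates <- purrr::map_dfr(hf, function(cl) {
    dplyr::mutate(cl$members, cluster_id = cl$cluster_id)
  })
  patient_id <- if ("patient_id" %in% names(candidates) &&
                    nrow(candidates) > 0) {
    candidates$patient_id[1]
  } else {
    "unknown"
  }
  if (nrow(candidates) < min_k) {
    return(ineligible_panel(patient_id, nrow(candidates),
                            sprintf("fewer than %d clonal targets", min_k)))
  }
  chrom_num <- suppressWarnings(as.numeric(candidates$chrom))
  chrom_ord <- ifelse(is.na(chrom_num), Inf, chrom_num)
  ord <- order(-candidates$adjusted_vaf, chrom_ord, candidates$chrom,
               candidates$pos)
  top <- candidates[ord, , drop = FALSE][seq_len(min(max_k, nrow(candidates))), ]
  top$target_id <- target_id_of(top)
  cols <- c("target_id", "chrom", "pos", "ref", "alt",
            intersect(c("gene", "vaf"), names(top)),
            "adjusted_vaf", "cluster_id")
  fingerprint_panel(patient_id, tibble::as_tibble(top[, cols]))
}

#' Filter panel targets by amplicon efficiency
#'
#' Drops targets whose multiplex-PCR amplicons amplified below
#' `min_efficiency`; if fewer than `min_k` targets survive, the panel
#' becomes ineligible (the assay realistically keeps 10-44 targets).
#'
#' @param panel A [fingerprint_panel()].
#' @param efficiency Named numeric vector, `target_id` -> fraction.
#' @param min_efficiency Minimum acceptable efficiency.
#' @param min_k Minimum surviving panel size (default 10).
#' @return A [fingerprint_panel()] or an `ineligible_panel`.
#' @export
filter_amplicons <- function(panel, efficiency, min_efficiency = 0.6,
                             min_k = 10L) {
  stopifnot(inherits(panel, "fingerprint_panel"))
  missing <- setdiff(panel$targets$target_id, names(efficiency))
  if (length(missing) > 0) {
    rlang::abort(sprintf("No efficiency entry for target(s): %s",
                         paste(utils::head(missing, 3), collapse = ", ")))
  }
  eff <- efficiency[panel$targets$target_id]
  keep <- panel$targets[eff >= min_efficiency, , drop = FALSE]
  if (nrow(keep) < min_k) {
    return(ineligible_panel(panel$patient_id, nrow(keep),
                            sprintf("fewer than %d targets after amplicon filtering",
                                    min_k)))
  }
  fingerprint_panel(panel$patient_id, keep)
}

#' Simulate amplicon amplification efficiencies
#'
#' Beta-distributed efficiencies (most amplicons near 1, a thin tail of
#' poor amplifiers) for a panel's targets; the input to
#' [filter_amplicons()] in simulations.
#'
#' @param panel A [fingerprint_panel()].
#' @param seed Integer seed.
#' @param shape1,shape2 Beta parameters (default mean ~0.93).
#' @return Named numeric vector `target_id` -> efficiency.
#' @export
simulate_amplicon_efficiency <- function(panel, seed = 1L,
                                         shape1 = 20, shape2 = 1.5) {
  stopifnot(inherits(panel, "fingerprint_panel"))
  withr::with_seed(seed, {
    stats::setNames(stats::rbeta(panel$k, shape1, shape2),
                    panel$targets$target_id)
  })
}

#' Tumour mutational burden
#'
#' Count of nonsynonymous somatic mutations per megabase of sequenced
#' exome.
#'
#' @param variants Tibble with a `consequence` column.
#' @param exome_mb Exome footprint in megabases (> 0; default 30, the
#'   approximate callable human exome).
#' @return Mutations per Mb.
#' @examples
#' compute_tmb(tibble::tibble(consequence = rep("nonsynonymous", 150)), 30)
#' @export
compute_tmb <- function(variants, exome_mb = 30) {
  if (!is.numeric(exome_mb) || exome_mb <= 0) {
    rlang::abort("`exome_mb` must be positive.")
  }
  stopifnot(is.data.frame(variants), "consequence" %in% names(variants))
  sum(variants$consequence == "nonsynonymous") / exome_mb
}

#' Cohort-level panel specificity report
#'
#' Summarises how personalised a set of fingerprint panels is: how many
#' known cancer genes each panel contains, the fraction of panels with
#' fewer than ten of them, and the fraction of targets (by
#' chrom:pos:ref:alt identity) occurring in exactly one panel.
#'
#' @param panels List of [fingerprint_panel()] objects.
#' @param known A list with `genes` (character vector) and optionally
#'   `variants` (tibble `gene`, `protein_change`), e.g. from
#'   [read_known_genes()].
#' @return List: `per_panel` tibble (`patient_id`, `k`,
#'   `n_known_genes`), `frac_panels_lt10_known`, `frac_unique_targets`.
#' @export
panel_specificity_report <- function(panels, known) {
  stopifnot(length(panels) >= 1, all(purrr::map_lgl(panels, is_eligible)))
  per_panel <- purrr::map_dfr(panels, function(p) {
    genes <- if ("gene" %in% names(p$targets)) p$targets$gene else character(0)
    tibble::tibble(
      patient_id = p$patient_id,
      k = p$k,
      n_known_genes = length(intersect(unique(genes), known$genes))
    )
  })
  all_targets <- purrr::map_dfr(panels, function(p) {
    tibble::tibble(panel = p$patient_id,
                   target_id = p$targets$target_id)
  })
  per_target <- dplyr::count(dplyr::distinct(all_targets), .data$target_id)
  list(
    per_panel = per_panel,
    frac_panels_lt10_known = mean(per_panel$n_known_genes < 10),
    frac_unique_targets = mean(per_target$n == 1)
  )
}
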