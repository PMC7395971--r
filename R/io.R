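# Readers and writers for the pipeline's plain-text interchange formats:
# VCF 4.2 / TSV somatic variant tables, per-test read-count TSVs, panel
# TSV + BED, and the detection-model JSON.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                      colClasses = NA))
}

#' Write somatic variants as VCF 4.2
#'
#' Emits one patient's somatic variant table as a VCF 4.2 file with
#' INFO keys `VAF` (variant allele frequency), `CNA` (total copy
#' number) and `LOH` (flag). Coordinates are 1-based, VCF convention.
#'
#' @param variants Variant tibble (see [simulate_patient_profile()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gene", "vaf", "cna",
                  "loh") %in% names(variants)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnafp",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Somatic variant allele frequency\">",
    "##INFO=<ID=CNA,Number=1,Type=Float,Description=\"Total copy number at site\">",
    "##INFO=<ID=LOH,Number=0,Type=Flag,Description=\"Loss of heterozygosity at site\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("VAF=%.6g;CNA=%.6g;GENE=%s%s",
                  variants$vaf, variants$cna, variants$gene,
                  ifelse(variants$loh, ";LOH", ""))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos, variants$ref,
                  variants$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a somatic variant VCF
#'
#' Parses a VCF (via vcfR) carrying the `VAF`/`CNA`/`LOH`/`GENE` INFO
#' keys written by [write_variants_vcf()] or an equivalent upstream
#' caller.
#'
#' @param path VCF file path.
#' @param patient_id Optional patient label to attach.
#' @return Variant tibble with `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `vaf`, `cna`, `loh`.
#' @export
read_variants_vcf <- function(path, patient_id = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(vcf),
                                         stringsAsFactors = FALSE))
  info_field <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  tibble::tibble(
    patient_id = patient_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_field("GENE"),
    vaf = as.numeric(info_field("VAF")),
    cna = as.numeric(info_field("CNA")),
    # LOH is a valueless Flag; detect it on the raw INFO string
    loh = grepl("(^|;)LOH(;|$)", vcfR::getINFO(vcf))
  )
}

#' Write / read somatic variants as TSV
#'
#' @param variants Variant tibble.
#' @param path File path.
#' @return `write_variants_tsv()` the path invisibly;
#'   `read_variants_tsv()` the tibble.
#' @export
write_variants_tsv <- function(variants, path) write_tsv_plain(variants, path)

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  df <- read_tsv_plain(path)
  if ("loh" %in% names(df)) df$loh <- as.logical(df$loh)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  df
}

#' Write ctDNA tests as a long read-count TSV
#'
#' One row per (test, target): `patient_id`, `test_date` (ISO-8601),
#' `target_id`, `alt_reads`, `total_reads`.
#'
#' @param tests List of [ctdna_test()] objects.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_counts_tsv <- function(tests, path) {
  long <- purrr::map_dfr(tests, function(t) {
    tibble::tibble(
      patient_id = t$patient_id,
      test_date = format(t$test_date, "%Y-%m-%d"),
      target_id = t$counts$target_id,
      alt_reads = t$counts$alt_reads,
      total_reads = t$counts$total_reads
    )
  })
  write_tsv_plain(long, path)
}

#' Read a read-count TSV back into ctDNA tests
#'
#' @param path File written by [write_counts_tsv()].
#' @param qc Optional named list (or `NULL`) mapping
#'   `patient_id|test_date` to [run_qc_metrics()]; tests without an
#'   entry are assumed QC-passing.
#' @return List of [ctdna_test()] objects ordered by patient and date.
#' @export
read_counts_tsv <- function(path, qc = NULL) {
  long <- read_tsv_plain(path)
  stopifnot(all(c("patient_id", "test_date", "target_id", "alt_reads",
                  "total_reads") %in% names(long)))
  keys <- unique(long[c("patient_id", "test_date")])
  keys <- keys[order(keys$patient_id, keys$test_date), ]
  purrr::pmap(keys, function(patient_id, test_date) {
    sub <- long[long$patient_id == patient_id &
                  long$test_date == test_date, ]
    key <- paste(patient_id, test_date, sep = "|")
    ctdna_test(patient_id, as.Date(test_date),
               sub[c("target_id", "alt_reads", "total_reads")],
               qc = qc[[key]])
  })
}

#' Write a fingerprint panel as TSV and BED
#'
#' The TSV carries `patient_id`, `target_id`, `chrom`, `pos` (1-based),
#' `ref`, `alt`, `gene`, `adjusted_vaf`, `cluster_id`; the BED is
#' 0-based half-open over the target loci for interoperability.
#'
#' @param panel A [fingerprint_panel()].
#' @param tsv_path,bed_path Output paths (`NULL` skips that file).
#' @return The TSV path (or BED path if only that was written),
#'   invisibly.
#' @export
write_panel_tsv <- function(panel, tsv_path = NULL, bed_path = NULL) {
  stopifnot(inherits(panel, "fingerprint_panel"))
  if (!is.null(tsv_path)) {
    df <- dplyr::mutate(panel$targets, patient_id = panel$patient_id,
                        .before = 1)
    write_tsv_plain(df, tsv_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = panel$targets$chrom,
      start = panel$targets$pos - 1L,
      end = panel$targets$pos,
      name = panel$targets$target_id
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path %||% bed_path)
}

#' Read a fingerprint panel TSV
#'
#' @param path File written by [write_panel_tsv()].
#' @return A [fingerprint_panel()].
#' @export
read_panel_tsv <- function(path) {
  df <- read_tsv_plain(path)
  df$chrom <- as.character(df$chrom)
  fingerprint_panel(df$patient_id[1],
                    dplyr::select(df, -"patient_id"))
}

#' Write / read a detection model as JSON
#'
#' @param model A [detection_model()].
#' @param path File path.
#' @return `write_detection_model_json()` the path invisibly;
#'   `read_detection_model_json()` the model.
#' @export
write_detection_model_json <- function(model, path) {
  stopifnot(inherits(model, "detection_model"))
  jsonlite::write_json(
    list(
      background_mean = model$background_mean,
      background_sd = model$background_sd,
      single_threshold = model$single_threshold,
      ccf_threshold = model$ccf_threshold,
      noise_table = model$noise_table
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_detection_model_json
#' @export
read_detection_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  detection_model(x$background_mean, x$background_sd,
                  tibble::as_tibble(x$noise_table))
}

#' Read a known-cancer-gene list
#'
#' Loads a TSV of curated cancer genes and specific variants (columns
#' `gene`, `protein_change`; empty `protein_change` rows contribute the
#' gene only). The bundled default is a small synthetic stand-in for a
#' clinical-interpretation knowledge-base export.
#'
#' @param path TSV path; default the bundled synthetic list.
#' @return List with `genes` (character) and `variants` (tibble
#'   `gene`, `protein_change`).
#' @export
read_known_genes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "known_genes_synthetic.tsv",
                                package = "ctdnafp")
  df <- read_tsv_plain(path)
  stopifnot("gene" %in% names(df))
  if (!"protein_change" %in% names(df)) df$protein_change <- NA_character_
  list(
    genes = unique(df$gene),
    variants = dplyr::filter(df, !is.na(.data$protein_change) &
                               .data$protein_change != "")
  )
}
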