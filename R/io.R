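# Readers and writers for the pipeline's concrete formats: cohort VCFs, the
# annotation table, and classification reports.

ANNOTATION_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "gene", "consequence", "splice_distance",
  "chgvs", "phgvs", "dbsnp_id", "gnomad_af", "dbsnp_af",
  "hgmd_described", "hgmd_phenotype",
  "mt_label", "mt_score", "snap2_label", "snap2_score",
  "sift_label", "sift_score", "pp2_label", "pp2_score",
  "phdsnp_label", "phdsnp_score",
  "bdgp_delta", "netgene2_delta", "assp_delta", "cadd_splice"
)

#' Read a variant annotation table
#'
#' Tab-separated, one row per unique variant, with header columns `chrom`,
#' `pos`, `ref`, `alt`, `gene`, `consequence`, `splice_distance`, `chgvs`,
#' `phgvs`, `dbsnp_id`, `gnomad_af`, `dbsnp_af`, `hgmd_described`,
#' `hgmd_phenotype`, per-tool prediction columns (`mt_label`/`mt_score`,
#' `snap2_*`, `sift_*`, `pp2_*`, `phdsnp_*`), and splice columns
#' (`bdgp_delta`, `netgene2_delta`, `assp_delta`, `cadd_splice`). Missing
#' optional cells (empty or `"-"`) become absent values. The table emulates
#' the gnomAD/dbSNP/HGMD/in-silico lookups that an annotation service would
#' provide.
#'
#' @param path Path to the TSV file.
#' @return A tibble in annotation layout with a `variant_key` column prepended.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      gene = readr::col_character(),
      consequence = readr::col_character(),
      .default = readr::col_character()
    ),
    na = c("", "NA", "-"),
    progress = FALSE
  )
  required <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(ANNOTATION_COLUMNS, names(df))) df[[col]] <- NA_character_
  df$chrom <- normalize_chrom(df$chrom)
  for (col in c("gnomad_af", "dbsnp_af", "mt_score", "snap2_score", "sift_score",
                "pp2_score", "phdsnp_score", "cadd_splice")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    if (any(!is.na(df[[col]]) & is.na(val))) {
      stop("unparseable numeric value in column '", col, "'", call. = FALSE)
    }
    df[[col]] <- val
  }
  df$splice_distance <- suppressWarnings(as.integer(df$splice_distance))
  df$hgmd_described <- !is.na(df$hgmd_described) &
    tolower(df$hgmd_described) %in% c("true", "t", "yes", "1")
  bad_af <- stats::na.omit(c(df$gnomad_af, df$dbsnp_af))
  if (any(bad_af < 0 | bad_af > 1)) {
    stop("allele frequency outside [0, 1] in annotation table", call. = FALSE)
  }
  key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(key)) {
    stop("duplicate variant_key rows in annotation table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(cbind(tibble::tibble(variant_key = key),
                          df[, ANNOTATION_COLUMNS]))
}

#' Construct a patient-by-variant presence matrix
#'
#' @param patients Ordered character vector of patient identifiers (the full
#'   cohort, including patients with no observations).
#' @param observations Data frame with columns `patient` and `variant_key`
#'   (plus any extra columns, which are kept). A (patient, variant) pair is
#'   recorded at most once regardless of zygosity.
#' @return A list of class `"cohort_matrix"`.
#' @export
cohort_matrix <- function(patients, observations) {
  patients <- as.character(patients)
  stopifnot(is.data.frame(observations),
            all(c("patient", "variant_key") %in% names(observations)))
  observations <- tibble::as_tibble(observations)
  observations <- dplyr::distinct(observations, .data$patient, .data$variant_key,
                                  .keep_all = TRUE)
  unknown <- setdiff(observations$patient, patients)
  if (length(unknown) > 0) {
    stop("observations reference unknown patient(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(patients = patients, observations = observations),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("Cohort matrix: %d patients, %d observations, %d unique variants\n",
              length(x$patients), nrow(x$observations),
              length(unique(x$observations$variant_key))))
  invisible(x)
}

#' Read one or more VCF files into a cohort matrix
#'
#' Accepts single-sample files or one multi-sample file (VCF 4.x, plain or
#' gzip-compressed). GRCh37 contig naming with or without the `"chr"` prefix is
#' normalized. Multi-allelic records are decomposed into one variant key per
#' alternate allele; an observation is recorded for every sample whose genotype
#' carries that allele, once per (patient, variant) pair regardless of
#' zygosity. Calls failing the per-call depth (`FORMAT/DP`) or site quality
#' (`QUAL`) thresholds are excluded; a missing `DP`/`QUAL` value is not
#' filtered.
#'
#' @param paths Character vector of VCF paths.
#' @param panel Optional [panel_definition()] with `regions`; observations
#'   outside the panel regions are excluded.
#' @param min_depth Minimum per-call read depth (default 30).
#' @param min_qual Minimum site quality (default 30).
#' @return A [cohort_matrix()] whose observations carry `chrom`, `pos`, `ref`,
#'   `alt` columns alongside `patient` and `variant_key`.
#' @export
read_cohort_vcf <- function(paths, panel = NULL, min_depth = 30, min_qual = 30) {
  stopifnot(length(paths) >= 1)
  all_obs <- list()
  all_samples <- character(0)
  for (path in paths) {
    if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- t(fix) # single-record files come back as a vector
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    samples <- colnames(vcf@gt)[-1]
    all_samples <- c(all_samples, setdiff(samples, all_samples))
    if (nrow(fix) == 0) next
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                   error = function(e) NULL)
    qual <- suppressWarnings(as.numeric(fix$QUAL))
    chrom <- normalize_chrom(fix$CHROM)
    pos <- as.integer(fix$POS)
    for (i in seq_len(nrow(fix))) {
      if (!is.na(qual[i]) && qual[i] < min_qual) next
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g) || g %in% c(".", "./.", ".|.")) next
        if (!is.null(dp) && !is.na(dp[i, s]) && dp[i, s] < min_depth) next
        alleles <- suppressWarnings(
          as.integer(strsplit(g, "[/|]")[[1]]))
        alleles <- alleles[!is.na(alleles) & alleles > 0]
        for (a in unique(alleles)) {
          if (a > length(alts)) {
            stop("genotype references absent ALT allele at ",
                 chrom[i], ":", pos[i], call. = FALSE)
          }
          all_obs[[length(all_obs) + 1L]] <- list(
            patient = s, chrom = chrom[i], pos = pos[i],
            ref = fix$REF[i], alt = alts[a]
          )
        }
      }
    }
  }
  obs <- if (length(all_obs) == 0) {
    tibble::tibble(patient = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character())
  } else {
    dplyr::bind_rows(lapply(all_obs, tibble::as_tibble))
  }
  if (!is.null(panel) && !is.null(panel$regions) && nrow(obs) > 0) {
    reg <- panel$regions
    inside <- vapply(seq_len(nrow(obs)), function(i) {
      any(reg$chrom == obs$chrom[i] &
            reg$start <= obs$pos[i] - 1L & obs$pos[i] - 1L < reg$end)
    }, logical(1))
    obs <- obs[inside, ]
  }
  obs$variant_key <- variant_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  cohort_matrix(all_samples,
                obs[, c("patient", "variant_key", "chrom", "pos", "ref", "alt")])
}

#' Write the classification report
#'
#' Emits a per-variant tab-separated table (`variants.tsv`: variant key, gene,
#' consequence, status, rationale) and a machine-readable run summary
#' (`run_summary.json`: cascade stage counts, per-gene tallies, carrier
#' prevalence). Output is byte-stable for identical inputs.
#'
#' @param assignments Tibble from [classify_variants()] / [run_cascade()].
#' @param report A `filter_report`, or `NULL`.
#' @param summary A `cohort_summary` (see [summarize_cohort()]), or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_classification_report <- function(assignments, report = NULL,
                                        summary = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  variants_path <- file.path(dir, "variants.tsv")
  readr::write_tsv(assignments, variants_path, progress = FALSE)
  summary_path <- file.path(dir, "run_summary.json")
  payload <- list(
    stage_counts = if (is.null(report)) NULL else unclass(report),
    cohort_summary = if (is.null(summary)) NULL else unclass(summary)
  )
  jsonlite::write_json(payload, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(variants = variants_path, summary = summary_path))
}

#' Read back a per-variant classification table
#'
#' Inverse of the `variants.tsv` half of [write_classification_report()].
#'
#' @param path Path to `variants.tsv`.
#' @return The assignments tibble.
#' @export
read_classification_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}
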