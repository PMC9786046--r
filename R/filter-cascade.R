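# The two-stage filter cascade and its stage bookkeeping.

#' Population allele-frequency filter
#'
#' Drops a variant whose frequency in either reference database strictly
#' exceeds the threshold. An absent frequency is treated as zero: a variant not
#' recorded in any database is rare by definition.
#'
#' @param gnomad_af,dbsnp_af Allele frequencies in `[0, 1]`, or `NA` when
#'   absent.
#' @param config A [classification_config()].
#' @return `"keep"` or `"drop"`.
#' @export
#' @examples
#' frequency_filter(0.02, NA)      # "drop"
#' frequency_filter(0.01, NA)      # "keep" — the rule is strictly "higher than"
#' frequency_filter(NA, NA)        # "keep" — novel variant
frequency_filter <- function(gnomad_af, dbsnp_af, config = classification_config()) {
  for (af in list(gnomad_af, dbsnp_af)) {
    if (!is.na(af) && (af < 0 || af > 1)) {
      stop("allele frequency outside [0, 1]: ", af, call. = FALSE)
    }
  }
  afs <- c(gnomad_af, dbsnp_af)
  afs[is.na(afs)] <- 0
  if (any(afs > config$maf_threshold)) "drop" else "keep"
}

#' Consequence / splice-proximity filter
#'
#' Excludes synonymous and intronic variants located farther than the keep
#' window (default 5 bases) from the nearest acceptor/donor splice site. Every
#' other consequence — including canonical splice acceptor/donor variants and
#' all protein-altering changes — is retained.
#'
#' @param consequence One of the consequence vocabulary (`"missense"`,
#'   `"synonymous"`, `"stop_gained"`, `"frameshift"`, `"inframe_indel"`,
#'   `"splice_acceptor"`, `"splice_donor"`, `"intronic"`, `"other_coding"`).
#' @param splice_distance Bases from the nearest exon/intron boundary (HGVS
#'   +1/-1 convention: distance 1 is the first base past the boundary);
#'   required for synonymous, intronic and splice-site consequences.
#' @param config A [classification_config()].
#' @return `"keep"` or `"drop"`.
#' @export
consequence_filter <- function(consequence, splice_distance = NA,
                               config = classification_config()) {
  consequence <- as.character(consequence)
  if (!consequence %in% CONSEQUENCES) {
    stop("unknown consequence '", consequence, "'", call. = FALSE)
  }
  splice_distance <- suppressWarnings(as.integer(splice_distance))
  if (consequence %in% SPLICE_DISTANCE_REQUIRED && is.na(splice_distance)) {
    stop("splice_distance is required for consequence '", consequence, "'",
         call. = FALSE)
  }
  if (consequence %in% c("synonymous", "intronic") &&
      splice_distance > config$splice_keep_window) {
    "drop"
  } else {
    "keep"
  }
}

#' Run the filter cascade and classification over unique variants
#'
#' Applies the frequency filter, the consequence filter and the category
#' decision tree to every row and tallies the telescoping stage counts. Input
#' rows must be unique variants (deduplicated on `chrom:pos:ref:alt`); patient
#' multiplicity is handled at the cohort level.
#'
#' @param variants Data frame in annotation-table layout, one row per unique
#'   variant.
#' @inheritParams classify_variant
#'
#' @return A list with `assignments` (the [classify_variants()] tibble) and
#'   `report` (a `filter_report`).
#' @export
run_cascade <- function(variants, config = classification_config(), panel = NULL) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) > 0) {
    keys <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    if (anyDuplicated(keys)) {
      stop("duplicate variant keys in input; deduplicate to unique ",
           "(chrom,pos,ref,alt) records before running the cascade",
           call. = FALSE)
    }
  }
  assignments <- classify_variants(variants, config = config, panel = panel)
  list(assignments = assignments, report = filter_report(assignments))
}

#' Build a stage-count report from classification assignments
#'
#' Counts telescope: unique input = common + rare; rare = consequence-filtered
#' + retained; retained = category I + category II, where I and II are parent
#' totals and Ip/IIp the flagged subsets.
#'
#' @param assignments Tibble from [classify_variants()].
#' @return A list of class `"filter_report"` with fields `n_unique_input`,
#'   `n_filtered_common`, `n_rare`, `n_filtered_consequence`, `n_retained`,
#'   `n_category_I`, `n_category_Ip`, `n_category_II`, `n_category_IIp`.
#' @export
filter_report <- function(assignments) {
  s <- assignments$status
  n_input <- length(s)
  n_common <- sum(s == "filtered_common")
  n_conseq <- sum(s == "filtered_consequence")
  n_I <- sum(s %in% c("category_I", "category_Ip"))
  n_Ip <- sum(s == "category_Ip")
  n_II <- sum(s %in% c("category_II", "category_IIp"))
  n_IIp <- sum(s == "category_IIp")
  report <- structure(
    list(
      n_unique_input = n_input,
      n_filtered_common = n_common,
      n_rare = n_input - n_common,
      n_filtered_consequence = n_conseq,
      n_retained = n_input - n_common - n_conseq,
      n_category_I = n_I,
      n_category_Ip = n_Ip,
      n_category_II = n_II,
      n_category_IIp = n_IIp
    ),
    class = "filter_report"
  )
  validate_filter_report(report)
  report
}

validate_filter_report <- function(report) {
  with(report, {
    stopifnot(
      n_unique_input == n_filtered_common + n_rare,
      n_rare == n_filtered_consequence + n_retained,
      n_retained == n_category_I + n_category_II,
      n_category_Ip <= n_category_I,
      n_category_IIp <= n_category_II
    )
  })
  invisible(report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Variant filter cascade\n")
  cat(sprintf("  unique variants in:        %d\n", x$n_unique_input))
  cat(sprintf("  filtered common (AF):      %d\n", x$n_filtered_common))
  cat(sprintf("  rare:                      %d\n", x$n_rare))
  cat(sprintf("  filtered by consequence:   %d\n", x$n_filtered_consequence))
  cat(sprintf("  retained for class'n:      %d\n", x$n_retained))
  cat(sprintf("  category I  (Ip flagged):  %d (%d)\n", x$n_category_I, x$n_category_Ip))
  cat(sprintf("  category II (IIp flagged): %d (%d)\n", x$n_category_II, x$n_category_IIp))
  invisible(x)
}
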