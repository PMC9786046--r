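# The category decision tree: known-phenotype categorization, in-silico
# consensus rules, the splice score-delta rule, and the per-variant classifier.

#' Categorize a variant by its curated-database record
#'
#' A variant already described in the curated mutation database is a "known"
#' variant (category I); when its recorded phenotype is a lipid metabolism
#' disorder or a cardiopathy it is a "known mutation" (category Ip). The
#' phenotype is matched case-insensitively against a keyword list.
#'
#' @param described Logical; is the variant present in the curated database?
#' @param phenotype Phenotype string recorded for the variant, or `NA`.
#' @param keywords Lowercase substrings marking lipid/cardiac phenotypes
#'   (default [default_phenotype_keywords()]).
#'
#' @return A list with `category` (`"category_Ip"`, `"category_I"` or
#'   `"not_known"`) and `rationale` (character vector of rule identifiers).
#' @export
#' @examples
#' categorize_known(TRUE, "Hypercholesterolaemia")$category
#' categorize_known(FALSE, NA)$category
categorize_known <- function(described, phenotype,
                             keywords = default_phenotype_keywords()) {
  stopifnot(is.logical(described), length(described) == 1L, !is.na(described))
  if (length(keywords) == 0) stop("keywords must be non-empty", call. = FALSE)
  if (!described) {
    if (!is.na(phenotype %||% NA) && nzchar(trimws(as.character(phenotype %||% "")))) {
      stop("phenotype may be present only for described variants", call. = FALSE)
    }
    return(list(category = "not_known", rationale = "not_described"))
  }
  phenotype <- as.character(phenotype %||% NA)
  if (is.na(phenotype) || !nzchar(trimws(phenotype))) {
    return(list(category = "category_I",
                rationale = c("hgmd_described", "phenotype_unavailable")))
  }
  hit <- vapply(keywords, function(k) grepl(k, tolower(phenotype), fixed = TRUE),
                logical(1))
  if (any(hit)) {
    list(category = "category_Ip", rationale = c("hgmd_described", "phenotype_match"))
  } else {
    list(category = "category_I", rationale = c("hgmd_described", "phenotype_no_match"))
  }
}

#' In-silico consensus over the five missense prediction tools
#'
#' Counts the tools calling the variant pathogenic (Mutation Taster, SNAP2,
#' SIFT, PolyPhen2, PhD-SNP). A tool without an available call never counts
#' toward either side; the threshold stays absolute over the available calls.
#'
#' @param labels Character vector of length 5 with values `"pathogenic"`,
#'   `"benign"` or `"missing"`, in tool order `mt`, `snap2`, `sift`, `pp2`,
#'   `phdsnp` (names optional).
#' @param config A [classification_config()].
#'
#' @return A list with `pathogenic_count`, `available_count`, `met` (logical)
#'   and `rationale`.
#' @export
missense_consensus <- function(labels, config = classification_config()) {
  labels <- check_labels(labels, length(MISSENSE_TOOLS))
  consensus_count(labels, config)
}

#' In-silico consensus over the five splice prediction tools
#'
#' Same counting contract as [missense_consensus()], over the splice tool set
#' (Mutation Taster, BDGP neural network, NetGene2, ASSP, CADD-Splice). Score
#' deltas and CADD-Splice scaled scores are converted to labels upstream with
#' the splice-delta rule (see [splice_delta_call()]) and the
#' `cadd_splice_min` cutoff.
#'
#' @inheritParams missense_consensus
#' @return A list with `pathogenic_count`, `available_count`, `met` and
#'   `rationale`.
#' @export
splice_consensus <- function(labels, config = classification_config()) {
  labels <- check_labels(labels, length(SPLICE_TOOLS))
  consensus_count(labels, config)
}

check_labels <- function(labels, n_tools) {
  labels <- as.character(labels)
  if (length(labels) != n_tools) {
    stop("expected ", n_tools, " tool labels, got ", length(labels), call. = FALSE)
  }
  bad <- !labels %in% LABEL_LEVELS
  if (any(bad)) {
    stop("invalid tool label(s): ", paste(unique(labels[bad]), collapse = ", "),
         call. = FALSE)
  }
  labels
}

consensus_count <- function(labels, config) {
  pathogenic_count <- sum(labels == "pathogenic")
  available_count <- sum(labels != "missing")
  met <- pathogenic_count >= config$consensus_min_pathogenic
  rationale <- if (available_count == 0) {
    "no_predictions"
  } else if (met) {
    "consensus_met"
  } else {
    "consensus_not_met"
  }
  list(
    pathogenic_count = pathogenic_count,
    available_count = available_count,
    met = met,
    rationale = rationale
  )
}

#' Splice score-delta rule
#'
#' A splice-site prediction counts as pathogenic when the tool's score changes
#' by at least the configured fraction (default 20%, boundary inclusive)
#' between the reference and the variant sequence, or when the site is lost
#' entirely (variant score 0 or site undetected).
#'
#' @param wildtype_score Tool score on the reference sequence; must be > 0 (a
#'   site undetected in the reference makes the tool uninformative and the
#'   caller must treat it as missing).
#' @param variant_score Tool score on the variant sequence; 0 (or `NA`, site
#'   lost) is pathogenic.
#' @param config A [classification_config()].
#'
#' @return `"pathogenic"` or `"benign"`.
#' @export
#' @examples
#' splice_delta_call(0.66, 0.50) # 24% drop -> pathogenic
#' splice_delta_call(0.94, 0.84) # 11% drop -> benign
splice_delta_call <- function(wildtype_score, variant_score,
                              config = classification_config()) {
  stopifnot(is.numeric(wildtype_score), length(wildtype_score) == 1L)
  if (is.na(wildtype_score) || wildtype_score <= 0) {
    stop("wildtype score undefined (site not detected in reference); ",
         "treat the tool as missing", call. = FALSE)
  }
  if (is.na(variant_score) || variant_score == 0) return("pathogenic")
  delta <- abs(wildtype_score - variant_score) / wildtype_score
  if (delta >= config$splice_delta_min) "pathogenic" else "benign"
}

# Extract the five missense-tool labels from an annotation row (a list or
# one-row data.frame with *_label columns).
missense_labels <- function(row) {
  vapply(
    c(mt = "mt_label", snap2 = "snap2_label", sift = "sift_label",
      pp2 = "pp2_label", phdsnp = "phdsnp_label"),
    function(col) parse_tool_label(row[[col]] %||% NA),
    character(1)
  )
}

# Extract the five splice-tool labels from an annotation row: Mutation Taster's
# categorical verdict, three score-delta tools, and the CADD-Splice score.
splice_labels <- function(row, config) {
  c(
    mt = parse_tool_label(row[["mt_label"]] %||% NA),
    bdgp = delta_to_label(row[["bdgp_delta"]] %||% NA, config),
    netgene2 = delta_to_label(row[["netgene2_delta"]] %||% NA, config),
    assp = delta_to_label(row[["assp_delta"]] %||% NA, config),
    cadd_splice = cadd_splice_to_label(
      suppressWarnings(as.numeric(row[["cadd_splice"]] %||% NA)), config)
  )
}

# Is this variant routed to the splice-assessment branch?
splice_proximal <- function(consequence, splice_distance, config) {
  if (consequence %in% c("splice_acceptor", "splice_donor")) return(TRUE)
  if (consequence %in% c("intronic", "synonymous")) {
    return(!is.na(splice_distance) && splice_distance <= config$splice_keep_window)
  }
  FALSE
}

#' Classify one annotated variant
#'
#' Runs the full decision tree on a single variant: (1) the population
#' frequency filter, (2) the consequence/splice-proximity filter, (3) the
#' known-database branch ([categorize_known()]; a described variant never
#' enters the prediction branch), (4) the category II branch — truncating
#' variants (stop gained, frameshift) are auto-included as IIp, missense and
#' other protein-altering coding variants go through [missense_consensus()],
#' splice-proximal variants through [splice_consensus()]; anything below the
#' consensus threshold stays plain category II.
#'
#' @param variant A list or one-row data frame in annotation-table layout (see
#'   [read_annotation_table()] for the column contract).
#' @param config A [classification_config()].
#' @param panel Optional [panel_definition()]; when given, a variant whose gene
#'   is not on the panel is an error.
#'
#' @return A list with `status` (one of `filtered_common`,
#'   `filtered_consequence`, `category_I`, `category_Ip`, `category_II`,
#'   `category_IIp`) and `rationale` (ordered character vector of the rules
#'   fired).
#' @export
classify_variant <- function(variant, config = classification_config(),
                             panel = NULL) {
  if (is.data.frame(variant)) {
    stopifnot(nrow(variant) == 1L)
    variant <- as.list(variant)
  }
  consequence <- as.character(variant$consequence)
  if (!consequence %in% CONSEQUENCES) {
    stop("unknown consequence '", consequence, "'", call. = FALSE)
  }
  if (!is.null(panel) && !variant$gene %in% panel$genes) {
    stop("gene '", variant$gene, "' is not in the configured panel", call. = FALSE)
  }
  splice_distance <- suppressWarnings(as.integer(variant$splice_distance %||% NA))
  if (consequence %in% SPLICE_DISTANCE_REQUIRED && is.na(splice_distance)) {
    stop("splice_distance is required for consequence '", consequence, "'",
         call. = FALSE)
  }

  rationale <- character(0)

  # (1) frequency filter
  freq <- frequency_filter(
    gnomad_af = suppressWarnings(as.numeric(variant$gnomad_af %||% NA)),
    dbsnp_af = suppressWarnings(as.numeric(variant$dbsnp_af %||% NA)),
    config = config
  )
  if (freq == "drop") {
    return(list(status = "filtered_common", rationale = "freq_gt_threshold"))
  }
  rationale <- c(rationale, "freq_pass")

  # (2) consequence filter
  cons <- consequence_filter(consequence, splice_distance, config)
  if (cons == "drop") {
    return(list(status = "filtered_consequence",
                rationale = c(rationale, "consequence_drop")))
  }
  rationale <- c(rationale, "consequence_pass")

  # (3) known-database branch takes precedence over every prediction rule
  described <- isTRUE(as.logical(variant$hgmd_described %||% FALSE))
  known <- categorize_known(described, variant$hgmd_phenotype %||% NA,
                            keywords = config$phenotype_keywords)
  rationale <- c(rationale, known$rationale)
  if (known$category != "not_known") {
    return(list(status = known$category, rationale = rationale))
  }

  # (4) category II branch
  if (consequence %in% TRUNCATING_CONSEQUENCES) {
    return(list(status = "category_IIp", rationale = c(rationale, "truncating")))
  }
  if (splice_proximal(consequence, splice_distance, config)) {
    cons_res <- splice_consensus(splice_labels(variant, config), config)
    rationale <- c(rationale, "splice_branch", cons_res$rationale)
    status <- if (cons_res$met) "category_IIp" else "category_II"
    return(list(status = status, rationale = rationale))
  }
  # missense and other protein-altering coding variants
  cons_res <- missense_consensus(missense_labels(variant), config)
  rationale <- c(rationale, "missense_branch", cons_res$rationale)
  status <- if (cons_res$met) "category_IIp" else "category_II"
  list(status = status, rationale = rationale)
}

#' Classify a table of annotated variants
#'
#' Vectorized wrapper around [classify_variant()].
#'
#' @param variants Data frame in annotation-table layout, one row per unique
#'   variant.
#' @inheritParams classify_variant
#'
#' @return A tibble with one row per input variant: `variant_key`, `gene`,
#'   `consequence`, `status`, `rationale` (rule identifiers joined by `";"`).
#' @export
classify_variants <- function(variants, config = classification_config(),
                              panel = NULL) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0) {
    return(tibble::tibble(variant_key = character(), gene = character(),
                          consequence = character(), status = character(),
                          rationale = character()))
  }
  rows <- split(variants, seq_len(nrow(variants)))
  res <- lapply(rows, classify_variant, config = config, panel = panel)
  tibble::tibble(
    variant_key = variant_key(variants$chrom, variants$pos,
                              variants$ref, variants$alt),
    gene = as.character(variants$gene),
    consequence = as.character(variants$consequence),
    status = vapply(res, `[[`, character(1), "status"),
    rationale = vapply(res, function(r) paste(r$rationale, collapse = ";"),
                       character(1))
  )
}
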