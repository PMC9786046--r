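#' Default phenotype keywords for the known-mutation branch
#'
#' Lowercase substrings that mark a curated-database phenotype as a lipid
#' metabolism disorder or a cardiopathy. A database-described variant whose
#' phenotype string contains any of these substrings (case-insensitive) is
#' classified `category_Ip` ("known mutation"); a described variant with an
#' unrelated phenotype stays `category_I`.
#'
#' The list covers the phenotype vocabulary of familial lipid disorders
#' (hyper-/hypo-cholesterolaemia and -lipidaemias, Tangier disease,
#' sitosterolaemia, xanthomatosis, Niemann-Pick disease, apolipoprotein and
#' lipoprotein deficiencies) together with cardiac and ischemic disease terms.
#' `"cd36"` is included because CD36 (platelet glycoprotein IV) deficiency is a
#' lipid scavenger-receptor disorder whose database phenotype string carries no
#' other lipid token.
#'
#' @return Character vector of lowercase substrings.
#' @export
default_phenotype_keywords <- function() {
  c(
    "cholesterol", "lipid", "lipoprotein", "lipidaemia", "lipidemia",
    "lipoproteinaemia", "triglycerid", "hdl", "ldl", "tangier",
    "sitosterol", "phytosterol", "xanthomatosis", "niemann-pick",
    "heart", "cardi", "ischemic", "ischaemic", "plasminogen",
    "apolipoprotein", "dyslipid", "cd36"
  )
}

#' Classification configuration
#'
#' Bundles every tunable threshold of the filter cascade and the category
#' decision tree.
#'
#' @param maf_threshold Population allele-frequency cutoff (fraction). A
#'   variant whose gnomAD-style or dbSNP-style frequency strictly exceeds this
#'   value is filtered out as common. Default 0.01, the classical common-variant
#'   boundary.
#' @param splice_keep_window Distance in bases from the nearest acceptor/donor
#'   splice site within which synonymous and intronic variants are retained for
#'   splice assessment. Default 5.
#' @param annotation_window Distance in bases bounding what is ingested around
#'   exon/intron boundaries. Default 10. Must be >= `splice_keep_window`.
#' @param consensus_min_pathogenic Minimum number of in-silico tools (out of
#'   five, counted over the tools with an available call) that must predict an
#'   impact for the consensus to be met. Default 3.
#' @param splice_delta_min Minimum relative change of a splice-site prediction
#'   score between reference and variant sequence for the tool call to count as
#'   pathogenic (fraction). Default 0.20; the boundary is inclusive.
#' @param cadd_splice_min Minimum CADD-Splice scaled score labelled pathogenic.
#'   Default 20.
#' @param phenotype_keywords Lowercase substrings marking lipid/cardiac
#'   phenotypes; see [default_phenotype_keywords()].
#'
#' @return A list of class `"classification_config"`.
#' @export
#' @examples
#' cfg <- classification_config()
#' cfg$maf_threshold
classification_config <- function(maf_threshold = 0.01,
                                  splice_keep_window = 5L,
                                  annotation_window = 10L,
                                  consensus_min_pathogenic = 3L,
                                  splice_delta_min = 0.20,
                                  cadd_splice_min = 20,
                                  phenotype_keywords = default_phenotype_keywords()) {
  stopifnot(
    is.numeric(maf_threshold), length(maf_threshold) == 1L,
    maf_threshold > 0, maf_threshold < 1,
    consensus_min_pathogenic >= 1L, consensus_min_pathogenic <= 5L,
    splice_delta_min > 0, splice_delta_min <= 1,
    splice_keep_window >= 0, annotation_window >= splice_keep_window,
    is.character(phenotype_keywords), length(phenotype_keywords) > 0
  )
  if (any(phenotype_keywords != tolower(phenotype_keywords))) {
    stop("phenotype_keywords must be lowercase", call. = FALSE)
  }
  structure(
    list(
      maf_threshold = maf_threshold,
      splice_keep_window = as.integer(splice_keep_window),
      annotation_window = as.integer(annotation_window),
      consensus_min_pathogenic = as.integer(consensus_min_pathogenic),
      splice_delta_min = splice_delta_min,
      cadd_splice_min = cadd_splice_min,
      phenotype_keywords = phenotype_keywords
    ),
    class = "classification_config"
  )
}

#' @export
print.classification_config <- function(x, ...) {
  cat("Classification configuration\n")
  cat("  MAF threshold (drop if >):      ", x$maf_threshold, "\n")
  cat("  splice keep window (bases):     ", x$splice_keep_window, "\n")
  cat("  annotation window (bases):      ", x$annotation_window, "\n")
  cat("  consensus minimum pathogenic:   ", x$consensus_min_pathogenic, "of 5\n")
  cat("  splice score-delta minimum:     ", x$splice_delta_min, "\n")
  cat("  CADD-Splice pathogenic cutoff:  ", x$cadd_splice_min, "\n")
  cat("  phenotype keywords:             ", length(x$phenotype_keywords), "terms\n")
  invisible(x)
}

#' Gene panel definition
#'
#' @param genes Character vector of unique gene symbols.
#' @param regions Optional `data.frame` with columns `gene`, `chrom`, `start`,
#'   `end` giving 0-based half-open genomic intervals per gene.
#'
#' @return A list of class `"panel_definition"`.
#' @export
panel_definition <- function(genes, regions = NULL) {
  stopifnot(is.character(genes), length(genes) > 0)
  if (anyDuplicated(genes)) stop("panel gene symbols must be unique", call. = FALSE)
  if (!is.null(regions)) {
    stopifnot(all(c("gene", "chrom", "start", "end") %in% names(regions)))
    if (!all(regions$gene %in% genes)) {
      stop("panel regions reference genes absent from the gene list", call. = FALSE)
    }
    if (any(regions$end <= regions$start)) {
      stop("panel regions must satisfy start < end", call. = FALSE)
    }
  }
  structure(list(genes = genes, regions = regions), class = "panel_definition")
}

#' Default cholesterol-metabolism gene panel
#'
#' Forty genes spanning cholesterol uptake, efflux, transport, storage,
#' utilization and excretion, assembled from the KEGG cholesterol-metabolism
#' pathway and the apolipoprotein/lipase/LDL-receptor families. This is the
#' package's default panel; any study-specific panel can be supplied through
#' [panel_definition()] or [read_panel()].
#'
#' @return A [panel_definition()] with 40 genes and no regions.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "panel_genes.txt", package = "cholvar")
  panel_definition(readLines(path))
}

#' Read a panel from a gene list or BED file
#'
#' A plain-text file with one gene symbol per line, or a BED file
#' (chrom, start, end, gene) giving 0-based half-open regions.
#'
#' @param path File path.
#' @return A [panel_definition()].
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty panel file: ", path, call. = FALSE)
  if (grepl("\t", lines[[1]])) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "gene"))
    bed$chrom <- normalize_chrom(bed$chrom)
    panel_definition(unique(bed$gene),
                     regions = bed[, c("gene", "chrom", "start", "end")])
  } else {
    panel_definition(trimws(lines))
  }
}
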