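# Small shared helpers: coordinate keys and tool-output parsing.

#' Normalize a chromosome label
#'
#' Strips a leading `"chr"` prefix so that `"chr2"` and `"2"` produce the same
#' variant key.
#'
#' @param chrom Character vector of contig names.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Build a unique variant key
#'
#' The pipeline identifies a variant by `chrom:pos:ref:alt` on GRCh37, with the
#' contig normalized via [normalize_chrom()].
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos), ref, alt, sep = ":")
}

# Map a raw tool cell to a canonical label.
# Accepts "PP"/"pathogenic", "NPP"/"benign"; "-", "" and NA are missing.
parse_tool_label <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  out[!is.na(x) & toupper(x) %in% c("PP", "PATHOGENIC", "P", "D", "DAMAGING")] <- "pathogenic"
  out[!is.na(x) & toupper(x) %in% c("NPP", "BENIGN", "B", "N", "TOLERATED")] <- "benign"
  out
}

# Parse a score-delta cell: a percent number ("24.24"), a lower bound (">20"),
# or missing ("", "-", NA). Returns list(value, is_bound).
parse_delta <- function(x) {
  x <- trimws(as.character(x))
  if (is.na(x) || x == "" || x == "-") {
    return(list(value = NA_real_, is_bound = FALSE))
  }
  is_bound <- startsWith(x, ">")
  num <- suppressWarnings(as.numeric(sub("^>", "", sub("%$", "", x))))
  if (is.na(num)) stop("unparseable score-delta cell: '", x, "'", call. = FALSE)
  list(value = num, is_bound = is_bound)
}

# Convert a score-delta cell (percent scale) to a canonical label.
# A bare number is pathogenic iff delta >= threshold; a lower bound ">x" is
# pathogenic when the bound already guarantees the threshold, otherwise the
# call is indeterminate and treated as missing.
delta_to_label <- function(x, config) {
  d <- parse_delta(x)
  threshold <- config$splice_delta_min * 100
  if (is.na(d$value)) return("missing")
  if (d$is_bound) {
    if (d$value >= threshold) "pathogenic" else "missing"
  } else {
    if (d$value >= threshold) "pathogenic" else "benign"
  }
}

# Label a CADD-Splice scaled score.
cadd_splice_to_label <- function(score, config) {
  if (is.na(score)) return("missing")
  if (score >= config$cadd_splice_min) "pathogenic" else "benign"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
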