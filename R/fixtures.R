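# Packaged fixture tables: the published known-mutation and potential-mutation
# variant sets, shipped as annotation-layout TSVs under inst/extdata.

fixture_path <- function(name) {
  path <- system.file("extdata", name, package = "cholvar")
  if (!nzchar(path)) stop("packaged fixture not found: ", name, call. = FALSE)
  path
}

#' Load the packaged known-mutation fixture table
#'
#' Thirty-seven database-described variants with lipid/cardiac phenotype
#' strings (category Ip anchors), in annotation-table layout. Allele columns
#' are transcribed from the coding-HGVS change; population frequency columns
#' are empty because every row already passed the rare-variant filter.
#'
#' @return Tibble of 37 annotated variants.
#' @export
#' @examples
#' nrow(load_fixture_table2())
load_fixture_table2 <- function() {
  read_annotation_table(fixture_path("table2_known_variants.tsv"))
}

#' Load the packaged potential-mutation fixture table
#'
#' Forty-three not-previously-described variants with per-tool in-silico
#' prediction labels/scores as published (category IIp anchors): five missense
#' tools, the splice score-delta columns and CADD-Splice scaled scores;
#' unavailable tool cells are missing.
#'
#' @return Tibble of 43 annotated variants.
#' @export
load_fixture_table3 <- function() {
  read_annotation_table(fixture_path("table3_predicted_variants.tsv"))
}
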