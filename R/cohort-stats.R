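# Gene-level and patient-level aggregation of classified variants, carrier
# frequencies, and carrier vs non-carrier group comparisons.

#' Summarize a classified cohort
#'
#' Joins the patient-by-variant presence matrix with per-variant category
#' assignments and tallies the quantities a panel study reports: per-gene
#' known/potential mutation counts, occurrence and carrier counts per class,
#' multi-variant carriers, and overall carrier prevalence. A patient is a
#' carrier of a class if at least one of their observed variants has that
#' status; occurrences count (patient, variant) pairs.
#'
#' @param matrix A [cohort_matrix()].
#' @param assignments Tibble from [classify_variants()]; must cover every
#'   observed variant.
#' @return A list of class `"cohort_summary"` with fields `per_gene`
#'   (tibble gene / n_Ip / n_IIp), `n_genes_hit`, `n_variants_Ip`,
#'   `n_variants_IIp`, `occurrences_Ip`, `occurrences_IIp`, `carriers_Ip`,
#'   `carriers_IIp`, `carriers_any`, `multi_variant_carriers_Ip`,
#'   `multi_variant_carriers_IIp`, `n_patients`, `prevalence_any`.
#' @export
summarize_cohort <- function(matrix, assignments) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  obs <- matrix$observations
  n_patients <- length(matrix$patients)
  missing_keys <- setdiff(obs$variant_key, assignments$variant_key)
  if (length(missing_keys) > 0) {
    stop("assignments missing for observed variant(s): ",
         paste(head(missing_keys, 5), collapse = ", "), call. = FALSE)
  }
  flagged <- assignments[assignments$status %in% c("category_Ip", "category_IIp"), ]
  per_gene <- flagged |>
    dplyr::count(.data$gene, .data$status) |>
    tidyr_pivot(n_genes = TRUE)
  obs_cls <- dplyr::inner_join(obs, flagged[, c("variant_key", "status")],
                               by = "variant_key")
  count_class <- function(st) {
    sub <- obs_cls[obs_cls$status == st, ]
    per_patient <- table(sub$patient)
    list(
      occurrences = nrow(sub),
      carriers = length(per_patient),
      multi = sum(per_patient >= 2)
    )
  }
  ip <- count_class("category_Ip")
  iip <- count_class("category_IIp")
  carriers_any <- length(unique(obs_cls$patient))
  structure(
    list(
      per_gene = per_gene,
      n_genes_hit = nrow(per_gene),
      n_variants_Ip = sum(flagged$status == "category_Ip"),
      n_variants_IIp = sum(flagged$status == "category_IIp"),
      occurrences_Ip = ip$occurrences,
      occurrences_IIp = iip$occurrences,
      carriers_Ip = ip$carriers,
      carriers_IIp = iip$carriers,
      carriers_any = carriers_any,
      multi_variant_carriers_Ip = ip$multi,
      multi_variant_carriers_IIp = iip$multi,
      n_patients = n_patients,
      prevalence_any = if (n_patients == 0) 0 else carriers_any / n_patients
    ),
    class = "cohort_summary"
  )
}

# Minimal wide pivot of the per-gene status counts (avoids a tidyr dependency
# for one reshape).
tidyr_pivot <- function(counts, n_genes = FALSE) {
  genes <- sort(unique(counts$gene))
  out <- tibble::tibble(
    gene = genes,
    n_Ip = vapply(genes, function(g) {
      sum(counts$n[counts$gene == g & counts$status == "category_Ip"])
    }, numeric(1)),
    n_IIp = vapply(genes, function(g) {
      sum(counts$n[counts$gene == g & counts$status == "category_IIp"])
    }, numeric(1))
  )
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  patients:                 %d\n", x$n_patients))
  cat(sprintf("  genes with Ip/IIp hits:   %d\n", x$n_genes_hit))
  cat(sprintf("  Ip variants / occ / carr: %d / %d / %d\n",
              x$n_variants_Ip, x$occurrences_Ip, x$carriers_Ip))
  cat(sprintf("  IIp variants / occ / carr:%d / %d / %d\n",
              x$n_variants_IIp, x$occurrences_IIp, x$carriers_IIp))
  cat(sprintf("  carriers (any):           %d (prevalence %.1f%%)\n",
              x$carriers_any, 100 * x$prevalence_any))
  invisible(x)
}

#' Gene-level carrier frequency
#'
#' Fraction of cohort patients carrying at least one known-mutation (Ip) or
#' potential-mutation (IIp) variant in the given gene.
#'
#' @param matrix A [cohort_matrix()].
#' @param assignments Tibble from [classify_variants()].
#' @param gene Gene symbol.
#' @param panel Optional [panel_definition()]; when given, the gene must be on
#'   it.
#' @return A fraction in `[0, 1]`.
#' @export
gene_carrier_frequency <- function(matrix, assignments, gene, panel = NULL) {
  stopifnot(inherits(matrix, "cohort_matrix"), length(gene) == 1L)
  if (!is.null(panel) && !gene %in% panel$genes) {
    stop("gene '", gene, "' is not in the configured panel", call. = FALSE)
  }
  n_patients <- length(matrix$patients)
  if (n_patients == 0) return(0)
  keys <- assignments$variant_key[
    assignments$gene == gene &
      assignments$status %in% c("category_Ip", "category_IIp")]
  obs <- matrix$observations
  carriers <- unique(obs$patient[obs$variant_key %in% keys])
  length(carriers) / n_patients
}

#' Carrier vs non-carrier comparison for a dichotomous covariate
#'
#' Pearson chi-squared test on the 2x2 carrier-by-covariate contingency table.
#' No continuity correction is applied by default; set `correct = TRUE` for
#' the Yates-corrected statistic.
#'
#' @param clinical Data frame of per-patient clinical covariates.
#' @param carrier Logical vector, one element per patient: does the patient
#'   carry at least one Ip/IIp variant?
#' @param covariate Name of a logical (or two-level) column of `clinical`.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A list with `chi_square`, `df`, `p`.
#' @export
compare_groups_categorical <- function(clinical, carrier, covariate,
                                       correct = FALSE) {
  stopifnot(is.data.frame(clinical), nrow(clinical) == length(carrier))
  x <- clinical[[covariate]]
  if (is.null(x)) stop("covariate '", covariate, "' not found", call. = FALSE)
  if (length(unique(stats::na.omit(x))) != 2) {
    stop("covariate '", covariate, "' is not dichotomous", call. = FALSE)
  }
  carrier <- as.logical(carrier)
  if (!any(carrier) || all(carrier)) {
    stop("both carrier groups must be non-empty", call. = FALSE)
  }
  tab <- table(carrier = carrier, covariate = x)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: an empty margin", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chi_square = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Carrier vs non-carrier comparison of age
#'
#' One-way ANOVA of age across the carrier and non-carrier groups. With two
#' groups the F statistic equals the square of the pooled-variance t
#' statistic.
#'
#' @param clinical Data frame with a numeric `age` column.
#' @param carrier Logical vector, one element per patient.
#' @return A list with `F`, `df_between`, `df_within`, `p`.
#' @export
compare_groups_age <- function(clinical, carrier) {
  stopifnot(is.data.frame(clinical), "age" %in% names(clinical),
            nrow(clinical) == length(carrier))
  if (min(table(carrier)) < 2 || length(unique(carrier)) < 2) {
    stop("each carrier group needs at least 2 patients", call. = FALSE)
  }
  fit <- aov(age ~ group, data = data.frame(age = clinical$age,
                                            group = factor(carrier)))
  tab <- anova(fit)
  list(
    F = tab[["F value"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    p = tab[["Pr(>F)"]][1]
  )
}
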