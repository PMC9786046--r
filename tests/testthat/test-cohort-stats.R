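# Cohort aggregation, carrier frequencies and group comparisons.

# a 3-patient toy cohort: A carries two known mutations, B one potential, C none
toy_cohort <- function() {
  variants <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "LDLR", hgmd_described = TRUE,
            hgmd_phenotype = "Hypercholesterolaemia"),
    ann_row(pos = 2L, gene = "APOB", hgmd_described = TRUE,
            hgmd_phenotype = "Dyslipidaemia"),
    do.call(ann_row, c(list(pos = 3L, gene = "PCSK9"), pp_labels(4)))
  )
  assignments <- run_cascade(variants)$assignments
  obs <- tibble::tibble(
    patient = c("A", "A", "B"),
    variant_key = c("1:1:A:G", "1:2:A:G", "1:3:A:G"))
  list(matrix = cohort_matrix(c("A", "B", "C"), obs), assignments = assignments)
}

test_that("cohort summary counts carriers, occurrences and multi-carriers", {
  tc <- toy_cohort()
  s <- summarize_cohort(tc$matrix, tc$assignments)
  expect_equal(s$carriers_any, 2)
  expect_equal(s$prevalence_any, 2 / 3)
  expect_equal(s$carriers_Ip, 1)
  expect_equal(s$multi_variant_carriers_Ip, 1)
  expect_equal(s$carriers_IIp, 1)
  expect_equal(s$occurrences_Ip, 2)
  expect_equal(s$n_genes_hit, 3)
  expect_gte(s$occurrences_Ip, s$carriers_Ip)
  # empty matrix
  s0 <- summarize_cohort(cohort_matrix(character(0),
                                       tibble::tibble(patient = character(),
                                                      variant_key = character())),
                         tc$assignments)
  expect_equal(s0$carriers_any, 0)
  expect_equal(s0$prevalence_any, 0)
  # missing assignment for an observed variant is an error
  bad <- cohort_matrix("A", tibble::tibble(patient = "A",
                                           variant_key = "9:9:A:C"))
  expect_error(summarize_cohort(bad, tc$assignments), "missing")
})

test_that("carrier counting uses presence semantics and is monotone", {
  tc <- toy_cohort()
  # duplicating observations changes nothing
  dup <- cohort_matrix(c("A", "B", "C"),
                       dplyr::bind_rows(tc$matrix$observations,
                                        tc$matrix$observations))
  expect_equal(summarize_cohort(dup, tc$assignments)$carriers_any,
               summarize_cohort(tc$matrix, tc$assignments)$carriers_any)
  # forcing a variant out of the flagged set never raises prevalence
  shrunk <- tc$assignments
  shrunk$status[shrunk$status == "category_IIp"] <- "category_II"
  expect_lte(summarize_cohort(tc$matrix, shrunk)$prevalence_any,
             summarize_cohort(tc$matrix, tc$assignments)$prevalence_any)
})

test_that("gene carrier frequency reproduces direct carrier ratios", {
  tc <- toy_cohort()
  expect_equal(gene_carrier_frequency(tc$matrix, tc$assignments, "LDLR"), 1 / 3)
  expect_equal(gene_carrier_frequency(tc$matrix, tc$assignments, "ABCA1"), 0)
  panel <- panel_definition(c("LDLR", "APOB", "PCSK9"))
  expect_error(gene_carrier_frequency(tc$matrix, tc$assignments, "TP53",
                                      panel = panel), "panel")
})

test_that("chi-squared comparison matches the hand-computed Pearson form", {
  # closed-form oracle for a 2x2 table, no continuity correction
  pearson <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  counts <- matrix(c(30, 10, 20, 20), nrow = 2, byrow = TRUE)
  clinical <- data.frame(
    dyslipidemia = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(30, 10, 20, 20)))
  carrier <- rep(c(TRUE, FALSE), times = c(40, 40))
  r <- compare_groups_categorical(clinical, carrier, "dyslipidemia")
  expect_equal(r$chi_square, pearson(counts), tolerance = 1e-12)
  expect_equal(r$df, 1)
  # identical proportions give statistic 0, p 1
  clinical2 <- data.frame(sex = rep(c("M", "F"), 20))
  carrier2 <- rep(c(TRUE, FALSE), each = 20)
  r2 <- compare_groups_categorical(clinical2, carrier2, "sex")
  expect_equal(r2$chi_square, 0)
  expect_equal(r2$p, 1)
  # swapping rows and columns leaves the statistic unchanged
  r3 <- compare_groups_categorical(
    data.frame(flag = carrier), clinical$dyslipidemia, "flag")
  expect_equal(r3$chi_square, r$chi_square, tolerance = 1e-12)
  # degenerate margins error
  expect_error(compare_groups_categorical(
    data.frame(x = rep(TRUE, 10)), rep(c(TRUE, FALSE), 5), "x"),
    "dichotomous|degenerate")
  expect_error(compare_groups_categorical(clinical, rep(TRUE, 80),
                                          "dyslipidemia"), "non-empty")
})

test_that("age ANOVA matches the closed-form decomposition and F = t^2", {
  clinical <- data.frame(age = c(50, 55, 60, 70, 75, 80))
  carrier <- rep(c(TRUE, FALSE), each = 3)
  r <- compare_groups_age(clinical, carrier)
  # hand decomposition: SSB = 600, SSW = 100, F = 600 / (100/4) = 24
  expect_equal(r$F, 24, tolerance = 1e-12)
  expect_equal(r$df_between, 1)
  expect_equal(r$df_within, 4)
  expect_equal(r$p, stats::pf(24, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # F equals the squared pooled-variance t statistic
  tt <- stats::t.test(age ~ carrier, data = cbind(clinical, carrier),
                      var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-9)
  # equal means give F = 0
  same <- data.frame(age = c(50, 60, 50, 60))
  expect_equal(compare_groups_age(same, c(TRUE, TRUE, FALSE, FALSE))$F, 0)
  expect_error(compare_groups_age(clinical, c(TRUE, rep(FALSE, 5))),
               "at least 2")
})
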