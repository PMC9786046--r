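# The synthetic-cohort generator: seeded determinism, composition, planting,
# and end-to-end recovery of the planted truth.

test_that("the same seed yields byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- small_sim_config(3)
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  for (f in c("cohort.vcf", "annotation.tsv", "clinical.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # and a different seed does not
  d3 <- tempfile()
  generate_cohort(small_sim_config(4), dir = d3)
  expect_false(identical(readLines(file.path(d1, "cohort.vcf")),
                         readLines(file.path(d3, "cohort.vcf"))))
})

test_that("generated files are parseable by the package's own readers", {
  d <- tempfile()
  g <- generate_cohort(small_sim_config(5), dir = d)
  ann <- read_annotation_table(file.path(d, "annotation.tsv"))
  expect_equal(nrow(ann), nrow(g$annotation))
  m <- read_cohort_vcf(file.path(d, "cohort.vcf"), min_depth = 0, min_qual = 0)
  expect_setequal(m$patients, g$matrix$patients)
  expect_setequal(paste(m$observations$patient, m$observations$variant_key),
                  paste(g$matrix$observations$patient,
                        g$matrix$observations$variant_key))
})

test_that("pool composition follows the configured fractions", {
  cfg <- simulation_config(seed = 8)
  g <- generate_cohort(cfg)
  tab <- table(g$truth$truth_status)
  expect_equal(sum(tab), 474)
  expect_equal(unname(tab["filtered_common"]), 259)
  expect_equal(unname(tab["filtered_consequence"]), 86)
  expect_equal(unname(tab["category_Ip"]), 37)
  expect_equal(unname(tab["category_I"]), 6)
  expect_equal(unname(tab["category_IIp"]), 43)
  expect_equal(unname(tab["category_II"]), 43)
  # infeasible pools are rejected up front
  expect_error(simulation_config(n_unique_variants = 50,
                                 known_pathogenic_pool = 40,
                                 known_lipid_pool = 30,
                                 novel_pathogenic_pool = 40),
               "infeasible")
})

test_that("zero carrier probability yields zero prevalence", {
  cfg <- small_sim_config(6, carrier_prob_Ip = 0, carrier_prob_IIp = 0,
                          p_rare_background = 0)
  g <- generate_cohort(cfg)
  casc <- run_cascade(g$annotation)
  s <- summarize_cohort(g$matrix, casc$assignments)
  expect_equal(s$prevalence_any, 0)
})

test_that("an all-common pool leaves nothing after the cascade", {
  cfg <- simulation_config(n_patients = 10, n_unique_variants = 50,
                           common_fraction = 1, known_pathogenic_pool = 0,
                           known_lipid_pool = 0, novel_pathogenic_pool = 0,
                           seed = 10)
  g <- generate_cohort(cfg)
  r <- run_cascade(g$annotation)$report
  expect_equal(r$n_retained, 0)
  expect_equal(r$n_filtered_common, 50)
})

test_that("deterministic planting recovers the exact carrier count", {
  cfg <- simulation_config(seed = 12, p_rare_background = 0)
  g <- generate_cohort(cfg, plant_exact_carriers = 63)
  casc <- run_cascade(g$annotation)
  s <- summarize_cohort(g$matrix, casc$assignments)
  expect_equal(s$carriers_any, 63)
  expect_equal(s$prevalence_any, 0.6)
})

test_that("with no label noise the classifier recovers the truth exactly", {
  rec <- recovery_experiment(small_sim_config(20), n_replicates = 5)
  expect_equal(rec$mean_agreement, 1)
  expect_true(all(rec$per_replicate$agreement == 1))
  m <- rec$class_metrics
  expect_true(all(m$sensitivity[m$class %in% c("category_Ip", "category_IIp")] == 1))
})

test_that("label noise degrades agreement but never touches planted variants", {
  rec <- recovery_experiment(small_sim_config(21, score_noise = 0.5),
                             n_replicates = 3)
  expect_lt(rec$mean_agreement, 1)
  m <- rec$class_metrics
  # planted known and novel pathogenic variants are still fully recovered
  expect_equal(m$sensitivity[m$class == "category_Ip"], 1)
  expect_equal(m$sensitivity[m$class == "category_IIp"], 1)
})
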