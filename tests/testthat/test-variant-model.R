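# The category decision tree and its component rules.

test_that("known-database categorization follows the phenotype keyword rule", {
  expect_identical(categorize_known(TRUE, "Hypercholesterolaemia")$category,
                   "category_Ip")
  expect_identical(categorize_known(TRUE, "Niemann-Pick disease, type C2")$category,
                   "category_Ip")
  expect_identical(categorize_known(TRUE, "CD36 deficiency")$category,
                   "category_Ip")
  expect_identical(categorize_known(FALSE, NA)$category, "not_known")
  # described with an unrelated phenotype stays plain category I
  expect_identical(categorize_known(TRUE, "Retinitis pigmentosa")$category,
                   "category_I")
  # described without a phenotype string: category I with a warning rationale
  res <- categorize_known(TRUE, NA)
  expect_identical(res$category, "category_I")
  expect_true("phenotype_unavailable" %in% res$rationale)
})

test_that("missense consensus counts pathogenic calls over available tools", {
  cfg <- classification_config()
  # three of five pathogenic meets the threshold
  r <- missense_consensus(c("benign", "pathogenic", "pathogenic", "pathogenic",
                            "benign"), cfg)
  expect_equal(r$pathogenic_count, 3)
  expect_true(r$met)
  # a missing tool never counts either way; threshold stays absolute
  r <- missense_consensus(c("pathogenic", "pathogenic", "missing", "pathogenic",
                            "benign"), cfg)
  expect_equal(r$pathogenic_count, 3)
  expect_equal(r$available_count, 4)
  expect_true(r$met)
  r <- missense_consensus(rep("benign", 5), cfg)
  expect_equal(r$pathogenic_count, 0)
  expect_false(r$met)
  r <- missense_consensus(rep("missing", 5), cfg)
  expect_false(r$met)
  expect_identical(r$rationale, "no_predictions")
})

test_that("consensus agrees with a brute-force oracle on all 243 label vectors", {
  cfg <- classification_config()
  grid <- expand.grid(rep(list(c("pathogenic", "benign", "missing")), 5),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    labels <- unlist(grid[i, ], use.names = FALSE)
    # independent oracle: explicit enumeration of the five tool slots
    n_path <- 0L
    for (lab in labels) if (identical(lab, "pathogenic")) n_path <- n_path + 1L
    oracle_met <- n_path >= 3L
    r <- missense_consensus(labels, cfg)
    expect_equal(r$pathogenic_count, n_path)
    expect_identical(r$met, oracle_met)
    # the splice consensus shares the counting contract
    expect_identical(splice_consensus(labels, cfg)$met, oracle_met)
  }
})

test_that("consensus is monotone and missing labels are neutral", {
  cfg <- classification_config()
  set.seed(42)
  for (i in 1:50) {
    labels <- sample(c("pathogenic", "benign", "missing"), 5, replace = TRUE)
    base <- missense_consensus(labels, cfg)
    for (j in 1:5) {
      if (labels[j] == "benign") {
        up <- replace(labels, j, "pathogenic")
        expect_true(missense_consensus(up, cfg)$met >= base$met)
      }
      dropped <- replace(labels, j, "missing")
      expect_lte(missense_consensus(dropped, cfg)$pathogenic_count,
                 base$pathogenic_count)
    }
  }
})

test_that("splice score-delta rule uses a 20% inclusive boundary", {
  cfg <- classification_config()
  expect_identical(splice_delta_call(100, 75.76, cfg), "pathogenic") # 24.24%
  expect_identical(splice_delta_call(100, 88.94, cfg), "benign")     # 11.06%
  expect_identical(splice_delta_call(100, 80, cfg), "pathogenic")    # exactly 20%
  # complete site loss is pathogenic
  expect_identical(splice_delta_call(0.8, 0, cfg), "pathogenic")
  expect_identical(splice_delta_call(0.8, NA, cfg), "pathogenic")
  # undetected reference site: the tool must be treated as missing
  expect_error(splice_delta_call(0, 0.5, cfg), "undefined")
})

test_that("published splice rows reach the consensus through the delta rule", {
  cfg <- classification_config()
  t3 <- load_fixture_table3()
  # canonical +5 intronic variant: three deltas and CADD-Splice over the line
  row <- t3[t3$chgvs == "c.818+5G>A", ]
  r <- classify_variant(row, cfg)
  expect_identical(r$status, "category_IIp")
  expect_true("splice_branch" %in% r$rationale)
  # lower-bound deltas (">20") and a missing tool still meet the threshold
  row <- t3[t3$chgvs == "c.4631+1G>A", ]
  expect_identical(classify_variant(row, cfg)$status, "category_IIp")
})

test_that("the decision tree fires branches in the documented order", {
  cfg <- classification_config()
  # database precedence: a described truncating variant is Ip, not IIp
  v <- ann_row(hgmd_described = TRUE, hgmd_phenotype = "Phytosterolaemia",
               consequence = "stop_gained")
  r <- classify_variant(v, cfg)
  expect_identical(r$status, "category_Ip")
  expect_true("hgmd_described" %in% r$rationale)
  expect_false("truncating" %in% r$rationale)
  # a not-described stop gain is auto-IIp
  r <- classify_variant(ann_row(consequence = "stop_gained"), cfg)
  expect_identical(r$status, "category_IIp")
  expect_true("truncating" %in% r$rationale)
  # a frameshift with no tool output is auto-IIp too
  r <- classify_variant(ann_row(consequence = "frameshift"), cfg)
  expect_identical(r$status, "category_IIp")
  # below-threshold missense stays plain category II
  v <- do.call(ann_row, pp_labels(2))
  expect_identical(classify_variant(v, cfg)$status, "category_II")
  # synonymous inside the window routes to the splice branch, not discard
  v <- ann_row(consequence = "synonymous", splice_distance = 3L,
               mt_label = "PP", bdgp_delta = "25", netgene2_delta = "30",
               cadd_splice = 22)
  r <- classify_variant(v, cfg)
  expect_identical(r$status, "category_IIp")
  expect_true("splice_branch" %in% r$rationale)
})

test_that("classification is deterministic and partitions the status space", {
  cfg <- classification_config()
  set.seed(7)
  for (i in 1:40) {
    v <- ann_row(
      pos = 1000L + i,
      consequence = sample(c("missense", "synonymous", "intronic",
                             "stop_gained", "inframe_indel"), 1),
      splice_distance = sample(1:10, 1),
      gnomad_af = sample(c(NA, 0.001, 0.5), 1),
      hgmd_described = sample(c(TRUE, FALSE), 1))
    if (v$hgmd_described) v$hgmd_phenotype <- "Dyslipidaemia"
    r1 <- classify_variant(v, cfg)
    r2 <- classify_variant(v, cfg)
    expect_identical(r1, r2)
    expect_length(r1$status, 1)
    expect_true(r1$status %in% c("filtered_common", "filtered_consequence",
                                 "category_I", "category_Ip",
                                 "category_II", "category_IIp"))
    expect_gt(length(r1$rationale), 0)
    # a described variant never lands in category II
    if (v$hgmd_described && r1$status %in% c("category_II", "category_IIp")) {
      fail("described variant reached the prediction branch")
    }
  }
})

test_that("classification rejects out-of-panel genes and bad inputs", {
  panel <- panel_definition(c("LDLR", "APOB"))
  expect_error(classify_variant(ann_row(gene = "TP53"), panel = panel),
               "not in the configured panel")
  expect_error(classify_variant(ann_row(consequence = "intronic")),
               "splice_distance")
  expect_error(classify_variant(ann_row(gnomad_af = 1.5)), "frequency")
})
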