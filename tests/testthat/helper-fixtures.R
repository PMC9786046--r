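# Builders for in-code fixtures: single annotation rows, a hand-enumerable
# ten-variant cascade set, and tiny VCF files.

ann_row <- function(chrom = "1", pos = 1000L, ref = "A", alt = "G",
                    gene = "PCSK9", consequence = "missense",
                    splice_distance = NA_integer_,
                    gnomad_af = NA_real_, dbsnp_af = NA_real_,
                    hgmd_described = FALSE, hgmd_phenotype = NA_character_,
                    mt_label = NA_character_, snap2_label = NA_character_,
                    sift_label = NA_character_, pp2_label = NA_character_,
                    phdsnp_label = NA_character_,
                    bdgp_delta = NA_character_, netgene2_delta = NA_character_,
                    assp_delta = NA_character_, cadd_splice = NA_real_) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    consequence = consequence, splice_distance = as.integer(splice_distance),
    chgvs = sprintf("c.%d%s>%s", pos, ref, alt), phgvs = NA_character_,
    dbsnp_id = NA_character_, gnomad_af = gnomad_af, dbsnp_af = dbsnp_af,
    hgmd_described = hgmd_described, hgmd_phenotype = hgmd_phenotype,
    mt_label = mt_label, mt_score = NA_real_,
    snap2_label = snap2_label, snap2_score = NA_real_,
    sift_label = sift_label, sift_score = NA_real_,
    pp2_label = pp2_label, pp2_score = NA_real_,
    phdsnp_label = phdsnp_label, phdsnp_score = NA_real_,
    bdgp_delta = bdgp_delta, netgene2_delta = netgene2_delta,
    assp_delta = assp_delta, cadd_splice = cadd_splice
  )
}

# pp(k): a missense label set with k pathogenic calls out of five available
pp_labels <- function(k) {
  labs <- c(rep("PP", k), rep("NPP", 5 - k))
  list(mt_label = labs[1], snap2_label = labs[2], sift_label = labs[3],
       pp2_label = labs[4], phdsnp_label = labs[5])
}

# Ten variants whose cascade outcome is enumerable by hand:
# 4 common (AF > 0.01), 2 deep intronic, 2 described with lipid phenotypes,
# 1 novel missense with 5 pathogenic calls, 1 novel missense with none.
ten_variant_fixture <- function() {
  dplyr::bind_rows(
    ann_row(pos = 101L, gnomad_af = 0.05),
    ann_row(pos = 102L, dbsnp_af = 0.30),
    ann_row(pos = 103L, gnomad_af = 0.011),
    ann_row(pos = 104L, gnomad_af = 0.25, dbsnp_af = 0.25),
    ann_row(pos = 105L, consequence = "intronic", splice_distance = 7L),
    ann_row(pos = 106L, consequence = "synonymous", splice_distance = 9L),
    ann_row(pos = 107L, hgmd_described = TRUE,
            hgmd_phenotype = "Hypercholesterolaemia"),
    ann_row(pos = 108L, hgmd_described = TRUE, hgmd_phenotype = "Tangier disease"),
    do.call(ann_row, c(list(pos = 109L), pp_labels(5))),
    do.call(ann_row, c(list(pos = 110L), pp_labels(0)))
  )
}

# Write a small VCF by hand (text fixture built in code).
write_test_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

small_sim_config <- function(seed, ...) {
  args <- modifyList(
    list(n_patients = 12L, n_unique_variants = 60L,
         common_fraction = 0.5, syn_deepintronic_fraction = 0.4,
         known_pathogenic_pool = 6L, known_lipid_pool = 5L,
         novel_pathogenic_pool = 6L, mean_variants_per_patient = 20,
         carrier_prob_Ip = 0.2, carrier_prob_IIp = 0.15, seed = seed),
    list(...)
  )
  do.call(simulation_config, args)
}
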