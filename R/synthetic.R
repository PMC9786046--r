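# Seeded synthetic-cohort generator: emulates the statistical structure of a
# targeted-panel STEMI cohort (unique-variant pool composition, per-patient
# variant burden, planted known/novel pathogenic variants) and carries
# ground-truth labels so every pipeline stage can be validated end to end.

LIPID_PHENOTYPES <- c(
  "Hypercholesterolaemia", "Hypertriglyceridaemia", "Familial hypercholesterolemia",
  "Hypobetalipoproteinaemia", "Tangier disease", "HDL deficiency",
  "Dyslipidaemia", "Sitosterolaemia", "Cerebrotendinous xanthomatosis",
  "Increased risk of ischemic heart disease", "Apolipoprotein C2 deficiency",
  "Niemann-Pick disease, type C2", "Lower plasma triglyceride level"
)

# Described phenotypes unrelated to lipid metabolism or cardiopathy: these
# variants stay plain category I.
OTHER_PHENOTYPES <- c(
  "Retinitis pigmentosa", "Nonsyndromic hearing loss",
  "Polycystic kidney disease", "Amelogenesis imperfecta",
  "Congenital cataract", "Primary ciliary dyskinesia"
)

#' Simulation configuration
#'
#' Defaults emulate the cohort structure the pipeline targets: 105 patients,
#' a pool of 474 unique panel variants of which 259 are common (population
#' frequency above 0.01), 86 of the 215 rare variants are synonymous or
#' deep-intronic, 43 of the 129 retained variants are database-described (37
#' with a lipid/cardiac phenotype), 43 are planted novel damaging variants,
#' and the per-patient burden averages about 83 variants (common variants
#' dominate the observations).
#'
#' @param n_patients Cohort size. Default 105.
#' @param n_unique_variants Unique variant pool size. Default 474.
#' @param common_fraction Fraction of unique variants with population
#'   frequency above the MAF threshold. Default 259/474.
#' @param syn_deepintronic_fraction Fraction of rare variants that are
#'   synonymous or deep-intronic (filtered by consequence). Default 86/215.
#' @param known_pathogenic_pool Number of database-described variants among
#'   the retained rare variants. Default 43.
#' @param known_lipid_pool How many of the described variants carry a
#'   lipid/cardiac phenotype (planted category Ip). Default 37.
#' @param novel_pathogenic_pool Number of planted not-described variants whose
#'   prediction profiles satisfy the consensus/truncating/splice rules
#'   (planted category IIp). Default 43.
#' @param mean_variants_per_patient Target expected number of observed panel
#'   variants per patient; the common-variant carry probability is derived
#'   from it. Default 83.
#' @param p_rare_background Per-patient carry probability for rare non-planted
#'   variants. Default 0.03.
#' @param carrier_prob_Ip,carrier_prob_IIp Independent per-patient carrier
#'   probability of each planted known / novel pathogenic variant. Defaults
#'   0.013 and 0.010 (chosen so planted occurrence counts land near 50 and 44
#'   over the default pools and cohort size).
#' @param score_noise Per-tool label flip probability applied to the
#'   prediction profiles of non-planted retained variants. Default 0.
#' @param mean_depth,sd_depth Per-call sequencing depth distribution written
#'   to the VCF. Defaults 117 and 22.
#' @param seed Integer seed; reproducibility is mandatory whenever set.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_patients = 105L,
                              n_unique_variants = 474L,
                              common_fraction = 259 / 474,
                              syn_deepintronic_fraction = 86 / 215,
                              known_pathogenic_pool = 43L,
                              known_lipid_pool = 37L,
                              novel_pathogenic_pool = 43L,
                              mean_variants_per_patient = 83,
                              p_rare_background = 0.03,
                              carrier_prob_Ip = 0.013,
                              carrier_prob_IIp = 0.010,
                              score_noise = 0,
                              mean_depth = 117,
                              sd_depth = 22,
                              seed = NULL) {
  stopifnot(
    n_patients >= 0, n_unique_variants >= 0,
    common_fraction >= 0, common_fraction <= 1,
    syn_deepintronic_fraction >= 0, syn_deepintronic_fraction <= 1,
    known_pathogenic_pool >= 0, novel_pathogenic_pool >= 0,
    known_lipid_pool >= 0, known_lipid_pool <= known_pathogenic_pool,
    p_rare_background >= 0, p_rare_background <= 1,
    carrier_prob_Ip >= 0, carrier_prob_Ip <= 1,
    carrier_prob_IIp >= 0, carrier_prob_IIp <= 1,
    score_noise >= 0, score_noise <= 1
  )
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_unique_variants = as.integer(n_unique_variants),
    common_fraction = common_fraction,
    syn_deepintronic_fraction = syn_deepintronic_fraction,
    known_pathogenic_pool = as.integer(known_pathogenic_pool),
    known_lipid_pool = as.integer(known_lipid_pool),
    novel_pathogenic_pool = as.integer(novel_pathogenic_pool),
    mean_variants_per_patient = mean_variants_per_patient,
    p_rare_background = p_rare_background,
    carrier_prob_Ip = carrier_prob_Ip,
    carrier_prob_IIp = carrier_prob_IIp,
    score_noise = score_noise,
    mean_depth = mean_depth,
    sd_depth = sd_depth,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  comp <- pool_composition(cfg)
  if (comp$n_plain < 0) {
    stop("infeasible configuration: planted pools exceed the retained ",
         "rare-variant count (", comp$n_retained, ")", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

pool_composition <- function(cfg) {
  n_common <- round(cfg$n_unique_variants * cfg$common_fraction)
  n_rare <- cfg$n_unique_variants - n_common
  n_deep <- round(n_rare * cfg$syn_deepintronic_fraction)
  n_retained <- n_rare - n_deep
  n_plain <- n_retained - cfg$known_pathogenic_pool - cfg$novel_pathogenic_pool
  list(n_common = n_common, n_rare = n_rare, n_deep = n_deep,
       n_retained = n_retained, n_plain = n_plain)
}

# Derive the per-patient carry probability of a common variant from the
# target mean burden, given the expected rare-variant contribution.
common_carry_prob <- function(cfg, comp) {
  if (comp$n_common == 0) return(0)
  rare_expect <- (comp$n_deep + max(comp$n_plain, 0)) * cfg$p_rare_background +
    cfg$known_pathogenic_pool * cfg$carrier_prob_Ip +
    cfg$novel_pathogenic_pool * cfg$carrier_prob_IIp
  min(1, max(0, (cfg$mean_variants_per_patient - rare_expect) / comp$n_common))
}

# Synthetic per-gene intervals (0-based half-open) used when a panel carries
# no regions: 100 kb per gene, laid out on chromosomes 1..22.
synthetic_panel_regions <- function(panel) {
  n <- length(panel$genes)
  tibble::tibble(
    gene = panel$genes,
    chrom = as.character(rep_len(1:22, n)),
    start = 1e6 * seq_len(n),
    end = 1e6 * seq_len(n) + 1e5
  )
}

#' Generate a synthetic cohort with ground-truth labels
#'
#' Draws a unique-variant pool with the configured composition, assigns each
#' variant a gene, synthetic coordinates and an annotation row consistent with
#' its intended classification (planted novel damaging variants receive
#' prediction profiles that satisfy the consensus, splice-delta or truncating
#' rules; plain category II variants receive at most two pathogenic calls),
#' then draws per-patient observations by independent carries. Outputs are
#' parseable by the package's own readers.
#'
#' @param config A [simulation_config()].
#' @param panel A [panel_definition()]; synthetic regions are created when the
#'   panel has none.
#' @param dir Optional output directory; when given, writes `cohort.vcf`,
#'   `annotation.tsv`, `clinical.tsv`, `truth.tsv` and `panel_genes.txt`.
#' @param plant_exact_carriers Optional integer: deterministic planting mode.
#'   Planted pathogenic observations are reassigned so that exactly this many
#'   patients carry at least one planted Ip/IIp variant (for exact-recovery
#'   tests).
#' @return A list with `annotation` (tibble), `matrix` (a [cohort_matrix()]),
#'   `clinical` (tibble), `truth` (tibble `variant_key`, `truth_status`),
#'   `config`, and `paths` when `dir` was given.
#' @export
generate_cohort <- function(config = simulation_config(),
                            panel = default_panel(),
                            dir = NULL,
                            plant_exact_carriers = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "panel_definition"))
  run <- function() {
    out <- generate_cohort_impl(config, panel, plant_exact_carriers)
    # file writing draws depths/genotype phases, so it stays inside the
    # seeded block: the same seed yields byte-identical outputs
    if (!is.null(dir)) out$paths <- write_cohort(out, dir)
    out
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

generate_cohort_impl <- function(cfg, panel, plant_exact_carriers) {
  comp <- pool_composition(cfg)
  n <- cfg$n_unique_variants
  regions <- panel$regions %||% synthetic_panel_regions(panel)
  patients <- sprintf("P%03d", seq_len(cfg$n_patients))

  truth_status <- rep(c("filtered_common", "filtered_consequence",
                        "category_Ip", "category_I", "category_IIp",
                        "category_II"),
                      times = c(comp$n_common, comp$n_deep,
                                cfg$known_lipid_pool,
                                cfg$known_pathogenic_pool - cfg$known_lipid_pool,
                                cfg$novel_pathogenic_pool, comp$n_plain))
  stopifnot(length(truth_status) == n)

  # coordinates: one unique position per variant, inside its gene's region
  gene_idx <- sample(rep_len(seq_len(nrow(regions)), n))
  pos <- integer(n)
  for (g in unique(gene_idx)) {
    idx <- which(gene_idx == g)
    pos[idx] <- sort(sample(seq.int(regions$start[g] + 1L, regions$end[g]),
                            length(idx)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  ann <- tibble::tibble(
    chrom = regions$chrom[gene_idx], pos = pos, ref = ref, alt = alt,
    gene = regions$gene[gene_idx],
    consequence = NA_character_, splice_distance = NA_integer_,
    chgvs = sprintf("c.%d%s>%s", seq_len(n), ref, alt), phgvs = NA_character_,
    dbsnp_id = NA_character_, gnomad_af = NA_real_, dbsnp_af = NA_real_,
    hgmd_described = FALSE, hgmd_phenotype = NA_character_,
    mt_label = NA_character_, mt_score = NA_real_,
    snap2_label = NA_character_, snap2_score = NA_real_,
    sift_label = NA_character_, sift_score = NA_real_,
    pp2_label = NA_character_, pp2_score = NA_real_,
    phdsnp_label = NA_character_, phdsnp_score = NA_real_,
    bdgp_delta = NA_character_, netgene2_delta = NA_character_,
    assp_delta = NA_character_, cadd_splice = NA_real_
  )

  is_common <- truth_status == "filtered_common"
  is_deep <- truth_status == "filtered_consequence"
  is_known <- truth_status %in% c("category_I", "category_Ip")
  is_iip <- truth_status == "category_IIp"
  is_plain <- truth_status == "category_II"

  # common variants: any consequence mix; the frequency filter removes them
  if (any(is_common)) {
    k <- sum(is_common)
    ann$consequence[is_common] <- sample(c("missense", "synonymous", "intronic"),
                                         k, replace = TRUE, prob = c(.4, .35, .25))
    af <- runif(k, cfg_maf_floor(), 0.5)
    which_db <- sample(1:3, k, replace = TRUE) # gnomAD, dbSNP, or both
    ann$gnomad_af[is_common][which_db != 2] <- af[which_db != 2]
    ann$dbsnp_af[is_common][which_db != 1] <- af[which_db != 1]
  }
  # deep synonymous/intronic: rare, dropped by the consequence filter
  if (any(is_deep)) {
    k <- sum(is_deep)
    ann$consequence[is_deep] <- sample(c("synonymous", "intronic"), k,
                                       replace = TRUE)
    ann$splice_distance[is_deep] <- sample(6:10, k, replace = TRUE)
    ann$gnomad_af[is_deep] <- runif(k, 0, 0.01)
  }
  # splice distances for common syn/intronic rows (any value in the window)
  need_dist <- is.na(ann$splice_distance) &
    ann$consequence %in% c("synonymous", "intronic")
  ann$splice_distance[need_dist] <- sample(1:10, sum(need_dist), replace = TRUE)

  # described variants: known branch, phenotype decides Ip vs I
  if (any(is_known)) {
    k <- sum(is_known)
    ann$consequence[is_known] <- "missense"
    ann$hgmd_described[is_known] <- TRUE
    lipid <- truth_status[is_known] == "category_Ip"
    ann$hgmd_phenotype[is_known][lipid] <-
      sample(LIPID_PHENOTYPES, sum(lipid), replace = TRUE)
    ann$hgmd_phenotype[is_known][!lipid] <-
      sample(OTHER_PHENOTYPES, sum(!lipid), replace = TRUE)
    ann$phgvs[is_known] <- sprintf("p.K%dR", which(is_known))
  }
  # planted novel damaging: profiles that satisfy the category II rules
  if (any(is_iip)) {
    idx <- which(is_iip)
    kind <- sample(c("missense", "truncating", "splice"), length(idx),
                   replace = TRUE, prob = c(.8, .1, .1))
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (kind[j] == "missense") {
        ann$consequence[i] <- "missense"
        n_path <- sample(3:5, 1)
        labels <- sample(c(rep("PP", n_path), rep("NPP", 5 - n_path)))
        ann[i, c("mt_label", "snap2_label", "sift_label", "pp2_label",
                 "phdsnp_label")] <- as.list(labels)
      } else if (kind[j] == "truncating") {
        ann$consequence[i] <- sample(c("stop_gained", "frameshift"), 1)
        ann$mt_label[i] <- "PP"
      } else {
        ann$consequence[i] <- sample(c("splice_donor", "splice_acceptor",
                                       "intronic"), 1)
        ann$splice_distance[i] <- sample(1:5, 1)
        ann$mt_label[i] <- "PP"
        ann$bdgp_delta[i] <- sprintf("%.2f", runif(1, 25, 60))
        ann$netgene2_delta[i] <- sprintf("%.2f", runif(1, 25, 60))
        ann$assp_delta[i] <- sprintf("%.2f", runif(1, 0, 15))
        ann$cadd_splice[i] <- runif(1, 21, 35)
      }
    }
  }
  # plain category II: missense with at most two pathogenic calls
  if (any(is_plain)) {
    idx <- which(is_plain)
    ann$consequence[idx] <- "missense"
    for (i in idx) {
      n_path <- sample(0:2, 1)
      labels <- sample(c(rep("PP", n_path), rep("NPP", 5 - n_path)))
      ann[i, c("mt_label", "snap2_label", "sift_label", "pp2_label",
               "phdsnp_label")] <- as.list(labels)
    }
  }
  # label-flip noise on non-planted retained variants
  if (cfg$score_noise > 0 && any(is_plain)) {
    cols <- c("mt_label", "snap2_label", "sift_label", "pp2_label", "phdsnp_label")
    for (col in cols) {
      i <- which(is_plain & runif(nrow(ann)) < cfg$score_noise)
      ann[[col]][i] <- ifelse(ann[[col]][i] == "PP", "NPP", "PP")
    }
  }

  key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  carry_prob <- numeric(n)
  carry_prob[is_common] <- common_carry_prob(cfg, comp)
  carry_prob[is_deep | is_plain] <- cfg$p_rare_background
  carry_prob[is_known] <- cfg$carrier_prob_Ip
  carry_prob[is_iip] <- cfg$carrier_prob_IIp

  carries <- matrix(rbinom(n * cfg$n_patients, 1,
                           rep(carry_prob, cfg$n_patients)) == 1,
                    nrow = n, ncol = cfg$n_patients)
  planted <- is_known | is_iip
  if (!is.null(plant_exact_carriers)) {
    k <- as.integer(plant_exact_carriers)
    if (k > cfg$n_patients) stop("cannot plant more carriers than patients",
                                 call. = FALSE)
    planted_ids <- which(planted & truth_status %in%
                           c("category_Ip", "category_IIp"))
    if (length(planted_ids) == 0 && k > 0) {
      stop("deterministic planting requires a non-empty planted pool",
           call. = FALSE)
    }
    carries[planted, ] <- FALSE
    chosen <- sample(cfg$n_patients, k)
    for (j in seq_along(chosen)) {
      v <- planted_ids[((j - 1L) %% length(planted_ids)) + 1L]
      carries[v, chosen[j]] <- TRUE
    }
  }

  obs_idx <- which(carries, arr.ind = TRUE)
  observations <- tibble::tibble(
    patient = patients[obs_idx[, 2]],
    variant_key = key[obs_idx[, 1]],
    chrom = ann$chrom[obs_idx[, 1]],
    pos = ann$pos[obs_idx[, 1]],
    ref = ann$ref[obs_idx[, 1]],
    alt = ann$alt[obs_idx[, 1]]
  )
  observations <- observations[order(match(observations$patient, patients),
                                     observations$pos), ]

  clinical <- tibble::tibble(
    patient = patients,
    age = round(rnorm(cfg$n_patients, 57.89, 12.12), 1),
    sex = ifelse(runif(cfg$n_patients) < 0.80, "M", "F"),
    dyslipidemia = runif(cfg$n_patients) < 0.505,
    hypertension = runif(cfg$n_patients) < 0.4666,
    diabetes = runif(cfg$n_patients) < 0.1715,
    tobacco = runif(cfg$n_patients) < 0.6952
  )

  list(
    annotation = tibble::as_tibble(cbind(tibble::tibble(variant_key = key), ann)),
    matrix = cohort_matrix(patients, observations),
    clinical = clinical,
    truth = tibble::tibble(variant_key = key, truth_status = truth_status),
    config = cfg
  )
}

cfg_maf_floor <- function() 0.011 # just above the default common-variant cutoff

#' Write a generated cohort to disk
#'
#' Emits the same formats the readers consume: one multi-sample VCF 4.2 file,
#' the annotation table, the clinical table, the truth labels and the panel
#' gene list.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "truth.tsv"),
    panel = file.path(dir, "panel_genes.txt")
  )
  write_cohort_vcf(cohort, paths[["vcf"]])
  ann <- cohort$annotation
  readr::write_tsv(ann[, setdiff(names(ann), "variant_key")],
                   paths[["annotation"]], progress = FALSE)
  readr::write_tsv(cohort$clinical, paths[["clinical"]], progress = FALSE)
  readr::write_tsv(cohort$truth, paths[["truth"]], progress = FALSE)
  writeLines(unique(cohort$annotation$gene), paths[["panel"]])
  invisible(paths)
}

write_cohort_vcf <- function(cohort, path) {
  patients <- cohort$matrix$patients
  ann <- cohort$annotation
  obs <- cohort$matrix$observations
  cfg <- cohort$config
  ord <- order(suppressWarnings(as.integer(ann$chrom)), ann$chrom, ann$pos)
  ann <- ann[ord, ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cholvar_synthetic_cohort",
    "##reference=GRCh37",
    sprintf("##contig=<ID=%s>", unique(ann$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", patients), collapse = "\t")
  )
  carried <- split(obs$patient, obs$variant_key)
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    who <- carried[[ann$variant_key[i]]] %||% character(0)
    depth <- pmax(30L, round(rnorm(length(patients), cfg$mean_depth, cfg$sd_depth)))
    gt <- ifelse(patients %in% who,
                 ifelse(runif(length(patients)) < 0.1, "1/1", "0/1"),
                 "0/0")
    paste(c(ann$chrom[i], ann$pos[i],
            ifelse(is.na(ann$dbsnp_id[i]), ".", ann$dbsnp_id[i]),
            ann$ref[i], ann$alt[i], "100", "PASS", ".", "GT:DP",
            paste0(gt, ":", depth)), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Replicate recovery experiment
#'
#' Runs generate -> classify -> summarize over independent replicates and
#' reports how well the pipeline recovers the planted truth: exact
#' classification agreement (100% expected when `score_noise = 0`), per-class
#' sensitivity/specificity, and the carrier-prevalence estimate with its
#' standard error against the planted expectation.
#'
#' @param config A [simulation_config()]; its seed (default 1 when unset)
#'   anchors the replicate seeds.
#' @param n_replicates Number of replicates (>= 2).
#' @param panel A [panel_definition()].
#' @param class_config A [classification_config()] used for classification.
#' @return A list with `per_replicate` (tibble: replicate, agreement,
#'   prevalence_est, prevalence_truth), `mean_agreement`,
#'   `mean_estimated_prevalence`, `stderr_prevalence`, `expected_prevalence`
#'   (the planted binomial expectation) and `class_metrics` (tibble with
#'   per-class sensitivity and specificity pooled over replicates).
#' @export
recovery_experiment <- function(config = simulation_config(),
                                n_replicates = 10L,
                                panel = default_panel(),
                                class_config = classification_config()) {
  stopifnot(n_replicates >= 2)
  base_seed <- config$seed %||% 1L
  res <- vector("list", n_replicates)
  pooled <- list()
  for (r in seq_len(n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- base_seed + r
    gen <- generate_cohort(cfg_r, panel = panel)
    casc <- run_cascade(gen$annotation, config = class_config)
    joined <- dplyr::inner_join(casc$assignments, gen$truth, by = "variant_key")
    agreement <- mean(joined$status == joined$truth_status)
    summ <- summarize_cohort(gen$matrix, casc$assignments)
    truth_flag <- gen$truth$truth_status %in% c("category_Ip", "category_IIp")
    truth_keys <- gen$truth$variant_key[truth_flag]
    obs <- gen$matrix$observations
    prevalence_truth <- if (length(gen$matrix$patients) == 0) 0 else
      length(unique(obs$patient[obs$variant_key %in% truth_keys])) /
      length(gen$matrix$patients)
    pooled[[r]] <- joined[, c("status", "truth_status")]
    res[[r]] <- tibble::tibble(replicate = r, agreement = agreement,
                               prevalence_est = summ$prevalence_any,
                               prevalence_truth = prevalence_truth)
  }
  per_replicate <- dplyr::bind_rows(res)
  pooled <- dplyr::bind_rows(pooled)
  class_metrics <- dplyr::bind_rows(lapply(
    c("category_Ip", "category_IIp", "category_I", "category_II"),
    function(cl) {
      tp <- sum(pooled$status == cl & pooled$truth_status == cl)
      fn <- sum(pooled$status != cl & pooled$truth_status == cl)
      fp <- sum(pooled$status == cl & pooled$truth_status != cl)
      tn <- sum(pooled$status != cl & pooled$truth_status != cl)
      tibble::tibble(
        class = cl,
        sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
        specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
      )
    }))
  expected_prevalence <- 1 -
    (1 - config$carrier_prob_Ip)^config$known_lipid_pool *
    (1 - config$carrier_prob_IIp)^config$novel_pathogenic_pool
  list(
    per_replicate = per_replicate,
    mean_agreement = mean(per_replicate$agreement),
    mean_estimated_prevalence = mean(per_replicate$prevalence_est),
    stderr_prevalence = stats::sd(per_replicate$prevalence_est) /
      sqrt(n_replicates),
    expected_prevalence = expected_prevalence,
    class_metrics = class_metrics
  )
}
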