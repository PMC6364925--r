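#' Simulation configuration for a synthetic revascularization cohort
#'
#' Bundles and validates every knob of the synthetic genotype–phenotype
#' generator. Defaults emulate the structure of a 1,599-patient clinical
#' angiography cohort: 67 CAD and 58 LDL-C score SNPs (9 shared between the
#' two panels, giving weighted scores an expected correlation near 0.14),
#' 3 proxy-substituted SNPs per panel, Hardy-Weinberg genotypes at uniform
#' allele frequencies, GWAS-scale effect sizes, onset ages linear in the
#' standardized true scores plus sex, familial-CAD and Gaussian noise
#' (SD 11 years, the scale implied by per-SD regression CIs of roughly
#' +/-0.55 years at n ~ 1,600), age-dependent binary covariates and an
#' age-dependent four-category clinical presentation. Onset ages are
#' truncated to 29–96 years.
#'
#' @param n_subjects Cohort size.
#' @param n_snps_cad,n_snps_ldl SNPs per score panel.
#' @param n_shared SNPs shared between the two panels.
#' @param n_proxy_cad,n_proxy_ldl SNPs per panel carried by a proxy variant
#'   (LD r^2 > 0.8) instead of the index SNP.
#' @param n_imputed_cad,n_imputed_ldl SNPs per panel flagged as imputed
#'   (their VCF records carry a DS field); proxies count among these.
#' @param freq_range Allele-frequency law: uniform on this interval.
#' @param beta_mean,beta_sd Effect-size law: `|Normal(beta_mean, beta_sd)|`.
#' @param gamma_cad,gamma_ldl True onset-age effects, years per SD of the
#'   true weighted CAD / LDL-C score.
#' @param gamma_fam True familial-CAD effect (years).
#' @param gamma_sex True female - male onset-age difference (years).
#' @param interaction_smoking Extra years per SD of the LDL-C score in
#'   smokers (0 = no effect modification).
#' @param mu Baseline mean onset age (years) for a male non-familial subject.
#' @param noise_sd Residual SD of onset age (years).
#' @param frac_female Fraction of women.
#' @param fam_prevalence Familial-CAD prevalence (independent of the scores).
#' @param missing_rate Per-cell genotype missingness rate in the emitted VCF.
#' @param swap_rate Fraction of variants written with ref/alt swapped
#'   (effect allele as REF), exercising orientation.
#' @param age_range Truncation bounds for onset age (years).
#' @param seed Integer seed; identical configs give identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1599,
                       n_snps_cad = 67, n_snps_ldl = 58, n_shared = 9,
                       n_proxy_cad = 3, n_proxy_ldl = 3,
                       n_imputed_cad = 16, n_imputed_ldl = 11,
                       freq_range = c(0.05, 0.95),
                       beta_mean = 0.08, beta_sd = 0.05,
                       gamma_cad = -0.51, gamma_ldl = -0.70,
                       gamma_fam = -3.2, gamma_sex = 9,
                       interaction_smoking = 0,
                       mu = 62.8, noise_sd = 11,
                       frac_female = 0.28, fam_prevalence = 0.41,
                       missing_rate = 0, swap_rate = 0,
                       age_range = c(29, 96),
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_snps_cad = as.integer(n_snps_cad),
              n_snps_ldl = as.integer(n_snps_ldl),
              n_shared = as.integer(n_shared),
              n_proxy_cad = as.integer(n_proxy_cad),
              n_proxy_ldl = as.integer(n_proxy_ldl),
              n_imputed_cad = as.integer(n_imputed_cad),
              n_imputed_ldl = as.integer(n_imputed_ldl),
              freq_range = as.numeric(freq_range),
              beta_mean = beta_mean, beta_sd = beta_sd,
              gamma_cad = gamma_cad, gamma_ldl = gamma_ldl,
              gamma_fam = gamma_fam, gamma_sex = gamma_sex,
              interaction_smoking = interaction_smoking,
              mu = mu, noise_sd = noise_sd,
              frac_female = frac_female, fam_prevalence = fam_prevalence,
              missing_rate = missing_rate, swap_rate = swap_rate,
              age_range = as.numeric(age_range),
              seed = as.integer(seed))
  if (cfg$n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (cfg$n_snps_cad < 1L || cfg$n_snps_ldl < 1L) {
    stop("each score needs at least 1 SNP", call. = FALSE)
  }
  if (cfg$n_shared > min(cfg$n_snps_cad, cfg$n_snps_ldl)) {
    stop("n_shared cannot exceed the smaller panel", call. = FALSE)
  }
  for (r in c("frac_female", "fam_prevalence", "missing_rate", "swap_rate")) {
    if (is.na(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop("rate ", r, " = ", cfg[[r]], " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$freq_range[1] <= 0 || cfg$freq_range[2] >= 1 ||
      cfg$freq_range[1] > cfg$freq_range[2]) {
    stop("freq_range must be an interval inside (0, 1)", call. = FALSE)
  }
  if (cfg$n_proxy_cad + cfg$n_shared > cfg$n_snps_cad ||
      cfg$n_proxy_ldl + cfg$n_shared > cfg$n_snps_ldl) {
    stop("proxy and shared SNP counts exceed panel size", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate the two synthetic SNP weight tables
#'
#' Draws rsIDs, allele pairs and positive effect sizes for the CAD and LDL-C
#' panels. The first `n_shared` SNPs are common to both panels (same rsID and
#' alleles, independently drawn betas), which is what gives the two weighted
#' scores their weak positive correlation. The last `n_proxy_*` SNPs of each
#' panel carry a `proxy_rsid` with `proxy_r2` in (0.8, 1).
#'
#' @param config A [sim_config()].
#' @return List with `cad` and `ldl` — two `grs_weights` tibbles.
#' @export
generate_weights <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  n_unique <- config$n_snps_cad + config$n_snps_ldl - config$n_shared
  n_proxy <- config$n_proxy_cad + config$n_proxy_ldl
  ids <- paste0("rs", sample(1e6:9e6, n_unique + n_proxy))
  snp_ids <- ids[seq_len(n_unique)]
  proxy_pool <- ids[n_unique + seq_len(n_proxy)]

  draw_pair <- function(n) {
    bases <- c("A", "C", "G", "T")
    t(vapply(seq_len(n), function(i) sample(bases, 2), character(2)))
  }
  pairs <- draw_pair(n_unique)

  # panel index into the unique SNP pool: shared first, then panel-specific
  idx_cad <- c(seq_len(config$n_shared),
               config$n_shared + seq_len(config$n_snps_cad - config$n_shared))
  idx_ldl <- c(seq_len(config$n_shared),
               config$n_snps_cad + seq_len(config$n_snps_ldl - config$n_shared))

  build <- function(idx, n_proxy_panel, proxy_ids, trait) {
    n <- length(idx)
    tbl <- tibble::tibble(
      rsid = snp_ids[idx],
      effect_allele = pairs[idx, 1],
      other_allele = pairs[idx, 2],
      beta = abs(stats::rnorm(n, config$beta_mean, config$beta_sd)),
      proxy_rsid = NA_character_,
      proxy_r2 = NA_real_
    )
    if (n_proxy_panel > 0L) {
      tail_rows <- n - n_proxy_panel + seq_len(n_proxy_panel)
      tbl$proxy_rsid[tail_rows] <- proxy_ids
      tbl$proxy_r2[tail_rows] <- stats::runif(n_proxy_panel, 0.81, 0.99)
    }
    new_grs_weights(tbl, trait)
  }
  list(
    cad = build(idx_cad, config$n_proxy_cad,
                proxy_pool[seq_len(config$n_proxy_cad)], "CAD"),
    ldl = build(idx_ldl, config$n_proxy_ldl,
                proxy_pool[config$n_proxy_cad + seq_len(config$n_proxy_ldl)],
                "LDL-C")
  )
}

#' Generate Hardy-Weinberg genotypes for the score SNPs
#'
#' For each variant an allele frequency is drawn from the configured uniform
#' law and genotypes are Binomial(2, p) effect-allele counts (Hardy-Weinberg
#' equilibrium, no LD between SNPs). Proxy-carried SNPs appear in the
#' genotype data under their proxy rsID (the index rsID is absent); proxies
#' are carried as perfect surrogates of their index SNP. A configurable
#' fraction of variants is encoded with ref/alt swapped (effect allele as
#' REF) and per-cell missingness is injected, both only in the *observed*
#' genotypes — the returned truth matrix is artifact-free.
#'
#' @param config A [sim_config()].
#' @param weights Weight-table pair from [generate_weights()].
#' @return A list of class `sim_genotypes`:
#'   * `truth`: subjects x variants matrix of effect-allele counts (no
#'     missingness), columns named by the genotyped (VCF) variant ID;
#'   * `observed`: `truth` with missing cells `NA` (still effect-oriented);
#'   * `variants`: tibble `chrom`, `pos`, `id`, `ref`, `alt`, `freq`,
#'     `swapped`, `imputed`;
#'   * `id_map`: list of tibbles (`cad`, `ldl`) mapping each weight-table
#'     `rsid` to its `vcf_id`.
#' @export
generate_genotypes <- function(config, weights) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  panel <- function(w) {
    tibble::tibble(rsid = w$rsid,
                   vcf_id = ifelse(is.na(w$proxy_rsid), w$rsid, w$proxy_rsid),
                   effect_allele = w$effect_allele,
                   other_allele = w$other_allele)
  }
  map_cad <- panel(weights$cad)
  map_ldl <- panel(weights$ldl)
  all_var <- dplyr::distinct(dplyr::bind_rows(map_cad, map_ldl),
                             .data$vcf_id, .keep_all = TRUE)
  v <- nrow(all_var)
  n <- config$n_subjects

  freq <- stats::runif(v, config$freq_range[1], config$freq_range[2])
  truth <- matrix(stats::rbinom(n * v, 2L, rep(freq, each = n)),
                  nrow = n, ncol = v)
  subjects <- sprintf("S%05d", seq_len(n))
  rownames(truth) <- subjects
  colnames(truth) <- all_var$vcf_id

  swapped <- stats::runif(v) < config$swap_rate
  imputed <- rep(FALSE, v)
  flag_imputed <- function(map, n_imputed) {
    ids <- utils::tail(map$vcf_id, n_imputed)
    imputed[match(ids, all_var$vcf_id)] <<- TRUE
  }
  flag_imputed(map_cad, config$n_imputed_cad)
  flag_imputed(map_ldl, config$n_imputed_ldl)

  observed <- truth
  if (config$missing_rate > 0) {
    observed[stats::runif(n * v) < config$missing_rate] <- NA_real_
  }

  variants <- tibble::tibble(
    chrom = as.character(sample(1:22, v, replace = TRUE)),
    pos = sample(1e4:1e8, v),
    id = all_var$vcf_id,
    ref = ifelse(swapped, all_var$effect_allele, all_var$other_allele),
    alt = ifelse(swapped, all_var$other_allele, all_var$effect_allele),
    freq = freq, swapped = swapped, imputed = imputed
  )
  structure(list(truth = truth, observed = observed, variants = variants,
                 id_map = list(cad = map_cad, ldl = map_ldl)),
            class = "sim_genotypes")
}

# True standardized weighted/unweighted scores from the truth matrix,
# using the same formulas as the scoring module.
sim_true_scores <- function(truth, weights, id_map) {
  mat <- truth[, id_map$vcf_id, drop = FALSE]
  colnames(mat) <- id_map$rsid
  dm <- dosage_matrix(mat, oriented = TRUE)
  compute_scores(dm, weights)
}

#' Extract one panel's oriented dosage matrix from simulated genotypes
#'
#' Convenience accessor for in-memory simulation studies: pulls the observed
#' effect-allele dosages of one score panel out of a `sim_genotypes` bundle
#' (resolving proxy columns back to their index rsIDs) as an oriented
#' [dosage_matrix()] ready for [compute_scores()].
#'
#' @param genotypes A `sim_genotypes` bundle ([generate_genotypes()]).
#' @param panel `"cad"` or `"ldl"`.
#' @return An oriented [dosage_matrix()] with columns named by index rsID.
#' @export
panel_dosage <- function(genotypes, panel = c("cad", "ldl")) {
  panel <- match.arg(panel)
  stopifnot(inherits(genotypes, "sim_genotypes"))
  map <- genotypes$id_map[[panel]]
  mat <- genotypes$observed[, map$vcf_id, drop = FALSE]
  colnames(mat) <- map$rsid
  dosage_matrix(mat, oriented = TRUE)
}
#' Generate phenotypes from the genotype truth
#'
#' Onset age is linear in the standardized true weighted scores plus sex,
#' familial-CAD and Gaussian noise, truncated to the configured range:
#' `age = mu + gamma_sex*female + gamma_fam*famCAD + gamma_cad*z_CAD +
#' gamma_ldl*z_LDL (+ interaction) + e`. Familial CAD is drawn independently
#' of the scores. The binary covariates (smoking, diabetes, hypertension,
#' known high cholesterol), BMI and the four-category clinical presentation
#' are drawn with prevalences depending on the NON-genetic part of onset age,
#' so they show realistic age gradients (younger patients smoke more and
#' present more often with STEMI; diabetes, hypertension and recognized high
#' cholesterol rise with age) while remaining independent of the genetic
#' scores. PCs are standard normal.
#'
#' @param config A [sim_config()].
#' @param genotypes A `sim_genotypes` bundle ([generate_genotypes()]).
#' @param weights Weight-table pair ([generate_weights()]).
#' @return List with `phenotypes` (tibble as [read_phenotypes()] returns) and
#'   `latent` (tibble of per-subject true scores and the pre-truncation age).
#' @export
generate_phenotypes <- function(config, genotypes, weights) {
  stopifnot(inherits(config, "sim_config"),
            inherits(genotypes, "sim_genotypes"))
  set.seed(config$seed + 3000L)
  n <- config$n_subjects
  subjects <- rownames(genotypes$truth)

  sc_cad <- sim_true_scores(genotypes$truth, weights$cad,
                            genotypes$id_map$cad)
  sc_ldl <- sim_true_scores(genotypes$truth, weights$ldl,
                            genotypes$id_map$ldl)
  z_cad <- sc_cad$z_wgrs
  z_ldl <- sc_ldl$z_wgrs

  female <- stats::runif(n) < config$frac_female
  fam <- as.integer(stats::runif(n) < config$fam_prevalence)
  eps <- stats::rnorm(n, 0, config$noise_sd)
  base_age <- config$mu + config$gamma_sex * female + config$gamma_fam * fam +
    eps

  # covariates depend on the non-genetic age component only
  a <- base_age - 64
  smoking <- as.integer(stats::runif(n) < stats::plogis(0.30 - 0.035 * a))
  diabetes <- as.integer(stats::runif(n) < stats::plogis(-1.90 + 0.020 * a))
  hypertension <- as.integer(stats::runif(n) < stats::plogis(0.00 + 0.045 * a))
  high_chol <- as.integer(stats::runif(n) < stats::plogis(-0.25 + 0.020 * a))
  bmi <- round(stats::rnorm(n, 27.4 - 0.010 * a, 4.2), 1)

  # presentation: multinomial logits vs SAP, STEMI declining with age
  logits <- cbind(STEMI = 0.42 - 0.045 * a,
                  NSTEMI = -0.91 - 0.020 * a,
                  UAP = -1.56 - 0.020 * a,
                  SAP = 0)
  pr <- exp(logits) / rowSums(exp(logits))
  pres_idx <- vapply(seq_len(n), function(i)
    sample.int(4L, 1L, prob = pr[i, ]), integer(1))
  presentation <- factor(colnames(logits)[pres_idx],
                         levels = c("STEMI", "NSTEMI", "UAP", "SAP"))

  age_raw <- base_age + config$gamma_cad * z_cad + config$gamma_ldl * z_ldl +
    config$interaction_smoking * z_ldl * smoking
  age <- pmin(pmax(age_raw, config$age_range[1]), config$age_range[2])

  phen <- tibble::tibble(
    subject_id = subjects,
    sex = factor(ifelse(female, "female", "male"),
                 levels = c("male", "female")),
    age_onset = round(age, 1),
    familial_cad = fam,
    smoking = smoking,
    diabetes = diabetes,
    hypertension = hypertension,
    high_cholesterol = high_chol,
    bmi = bmi,
    presentation = presentation,
    pc1 = stats::rnorm(n),
    pc2 = stats::rnorm(n)
  )
  latent <- tibble::tibble(
    subject_id = subjects,
    z_cad_true = z_cad, z_ldl_true = z_ldl,
    ugrs_cad_true = sc_cad$ugrs, wgrs_cad_true = sc_cad$wgrs,
    ugrs_ldl_true = sc_ldl$ugrs, wgrs_ldl_true = sc_ldl$wgrs,
    base_age = base_age, age_raw = age_raw
  )
  list(phenotypes = phen, latent = latent)
}

#' Simulate a complete cohort file bundle
#'
#' Runs [generate_weights()], [generate_genotypes()] and
#' [generate_phenotypes()] and writes the file bundle the pipeline consumes:
#' a VCF of genotypes (with DS fields on imputed records), the two weight
#' TSVs, the phenotype TSV and a `truth.json` recording every generator
#' parameter and per-subject latent values.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   `weights`, `genotypes`, `phenotypes` and `latent` objects.
#' @export
simulate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  weights <- generate_weights(config)
  genotypes <- generate_genotypes(config, weights)
  phen <- generate_phenotypes(config, genotypes, weights)

  # observed ALT counts: swapped variants are encoded on the other allele
  gt_alt <- genotypes$observed
  sw <- genotypes$variants$swapped
  gt_alt[, sw] <- 2 - gt_alt[, sw, drop = FALSE]

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    weights_cad = file.path(dir, "weights_cad.tsv"),
    weights_ldl = file.path(dir, "weights_ldl.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(genotypes$variants[, c("chrom", "pos", "id", "ref", "alt")],
            gt_alt, paths$vcf, imputed = genotypes$variants$imputed)
  write_weight_table(weights$cad, paths$weights_cad)
  write_weight_table(weights$ldl, paths$weights_ldl)
  readr::write_tsv(phen$phenotypes, paths$phenotypes, progress = FALSE)
  truth_doc <- list(
    config = unclass(config),
    variants = genotypes$variants,
    subjects = phen$latent
  )
  jsonlite::write_json(truth_doc, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, config = config, weights = weights,
                 genotypes = genotypes, phenotypes = phen$phenotypes,
                 latent = phen$latent))
}
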