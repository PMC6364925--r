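test_that("config validation enforces rates, sizes and panel arithmetic", {
  cfg <- sim_config()
  expect_equal(cfg$n_snps_cad, 67L)
  expect_equal(cfg$n_snps_ldl, 58L)
  expect_error(sim_config(n_subjects = 1), "n_subjects")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_snps_cad = 0), "at least 1")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_shared = 60), "smaller panel")
})

test_that("weight generation honours panel sizes, proxies and sharing", {
  cfg <- sim_config(seed = 3)
  w <- generate_weights(cfg)
  expect_equal(nrow(w$cad), 67)
  expect_equal(nrow(w$ldl), 58)
  expect_equal(sum(!is.na(w$cad$proxy_rsid)), 3)
  expect_equal(sum(!is.na(w$ldl$proxy_rsid)), 3)
  expect_true(all(w$cad$proxy_r2[!is.na(w$cad$proxy_rsid)] > 0.8))
  expect_true(all(w$cad$beta >= 0))
  expect_length(intersect(w$cad$rsid, w$ldl$rsid), 9)

  # determinism: same seed, identical tables
  w2 <- generate_weights(sim_config(seed = 3))
  expect_identical(tibble::as_tibble(w$cad), tibble::as_tibble(w2$cad))

  w0 <- generate_weights(sim_config(n_shared = 0, seed = 4))
  expect_length(intersect(w0$cad$rsid, w0$ldl$rsid), 0)
})

test_that("genotypes follow Hardy-Weinberg at the configured frequencies", {
  cfg <- sim_config(n_subjects = 10000, n_snps_cad = 6, n_snps_ldl = 4,
                    n_shared = 0, n_proxy_cad = 0, n_proxy_ldl = 0,
                    n_imputed_cad = 0, n_imputed_ldl = 0, seed = 5)
  w <- generate_weights(cfg)
  g <- generate_genotypes(cfg, w)
  for (j in seq_len(ncol(g$truth))) {
    p <- g$variants$freq[j]
    obs_freq <- mean(g$truth[, j]) / 2
    expect_lt(abs(obs_freq - p), 0.015)
    obs_geno <- tabulate(g$truth[, j] + 1L, 3L)
    exp_geno <- 10000 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    chi2 <- sum((obs_geno - exp_geno)^2 / exp_geno)
    expect_lt(chi2, qchisq(0.999, df = 2))
  }
})

test_that("swap and missing rates show up in the observed encoding only", {
  cfg <- sim_config(n_subjects = 300, swap_rate = 0.3, missing_rate = 0.05,
                    seed = 6)
  w <- generate_weights(cfg)
  g <- generate_genotypes(cfg, w)
  v <- nrow(g$variants)
  expect_gt(sum(g$variants$swapped), v * 0.15)
  expect_lt(sum(g$variants$swapped), v * 0.45)
  expect_false(anyNA(g$truth))
  miss <- mean(is.na(g$observed))
  expect_lt(abs(miss - 0.05), 0.02)
  # harmonization should flip exactly the swapped variants
  d <- tempfile(); b <- simulate_cohort(cfg, d)
  geno <- read_vcf(b$paths$vcf)
  h <- suppressWarnings(harmonize(geno$dosage, geno$variants, b$weights$cad))
  swapped_ids <- g$variants$id[g$variants$swapped]
  cad_ids <- b$genotypes$id_map$cad$vcf_id
  expect_equal(h$report$flipped, length(intersect(swapped_ids, cad_ids)))
  unlink(d, recursive = TRUE)
})

test_that("pipeline scores equal generator-truth scores on clean data", {
  cfg <- sim_config(n_subjects = 120, seed = 8)
  d <- tempfile()
  b <- simulate_cohort(cfg, d)
  geno <- read_vcf(b$paths$vcf)
  for (trait in c("cad", "ldl")) {
    w <- read_weight_table(b$paths[[paste0("weights_", trait)]],
                           trait = toupper(trait))
    h <- suppressWarnings(harmonize(geno$dosage, geno$variants, w))
    expect_equal(h$report$dropped, 0L)
    expect_equal(h$report$proxied, 3L)
    sc <- compute_scores(h$dosage, h$weights)
    truth_sc <- grsonset:::sim_true_scores(b$genotypes$truth,
                                           b$weights[[trait]],
                                           b$genotypes$id_map[[trait]])
    expect_equal(sc$ugrs, truth_sc$ugrs, tolerance = 1e-10)
    expect_equal(sc$wgrs, truth_sc$wgrs, tolerance = 1e-10)
  }
  unlink(d, recursive = TRUE)
})

test_that("phenotypes reproduce the configured onset-age model", {
  # no noise, no effects: every age equals the baseline
  cfg0 <- sim_config(n_subjects = 50, gamma_cad = 0, gamma_ldl = 0,
                     gamma_fam = 0, gamma_sex = 0, noise_sd = 1e-9,
                     mu = 63, seed = 9)
  w0 <- generate_weights(cfg0)
  g0 <- generate_genotypes(cfg0, w0)
  ph0 <- generate_phenotypes(cfg0, g0, w0)
  expect_true(all(abs(ph0$phenotypes$age_onset - 63) <= 0.11))

  # large-sample recovery of the LDL score effect from the truth scores
  cfg <- sim_config(n_subjects = 4000, seed = 10)
  w <- generate_weights(cfg)
  g <- generate_genotypes(cfg, w)
  ph <- generate_phenotypes(cfg, g, w)
  d <- dplyr::inner_join(ph$phenotypes, ph$latent, by = "subject_id")
  d$age_exact <- d$age_raw  # pre-truncation, pre-rounding response
  fit <- fit_ols(d, "age_exact",
                 c("z_ldl_true", "z_cad_true", "sex", "familial_cad"))
  tab <- tidy(fit)
  expect_lt(abs(tab$estimate[tab$term == "z_ldl_true"] - cfg$gamma_ldl),
            3 * tab$se[tab$term == "z_ldl_true"])
  expect_lt(abs(tab$estimate[tab$term == "familial_cad"] - cfg$gamma_fam),
            3 * tab$se[tab$term == "familial_cad"])
  expect_true(all(ph$phenotypes$age_onset >= 29 &
                    ph$phenotypes$age_onset <= 96))
})

test_that("the full bundle is deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 60, missing_rate = 0.02, swap_rate = 0.1,
                    seed = 12)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in c("cohort.vcf", "weights_cad.tsv", "weights_ldl.tsv",
              "phenotypes.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
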