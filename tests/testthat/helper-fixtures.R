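# In-code fixture builders shared across test files.

make_weights <- function(n = 4, betas = NULL, trait = "CAD",
                         rsids = NULL, effect = NULL, other = NULL,
                         proxy_rsid = NULL, proxy_r2 = NULL) {
  if (is.null(rsids)) rsids <- paste0("rs", seq_len(n))
  if (is.null(betas)) betas <- seq(0.05, by = 0.01, length.out = n)
  if (is.null(effect)) effect <- rep(c("A", "C"), length.out = n)
  if (is.null(other)) other <- rep(c("G", "T"), length.out = n)
  tbl <- tibble::tibble(rsid = rsids, effect_allele = effect,
                        other_allele = other, beta = betas,
                        proxy_rsid = proxy_rsid %||% NA_character_,
                        proxy_r2 = proxy_r2 %||% NA_real_)
  grsonset:::new_grs_weights(tbl, trait)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_dosage <- function(mat, oriented = TRUE,
                        subjects = NULL, variants = NULL) {
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(mat)))
  if (is.null(variants)) variants <- paste0("rs", seq_len(ncol(mat)))
  dimnames(mat) <- list(subjects, variants)
  dosage_matrix(mat, oriented = oriented)
}

write_weights_file <- function(weights, path = tempfile(fileext = ".tsv")) {
  write_weight_table(weights, path)
  path
}

# a small phenotype + score cohort with known structure, for model tests
make_cohort <- function(n = 400, seed = 1, gamma_ldl = 0, gamma_fam = 0,
                        noise_sd = 5) {
  set.seed(seed)
  z_cad <- rnorm(n); z_ldl <- rnorm(n)
  fam <- rbinom(n, 1, 0.4)
  female <- rbinom(n, 1, 0.3)
  age <- 63 + 8 * female + gamma_fam * fam + gamma_ldl * z_ldl +
    rnorm(n, 0, noise_sd)
  tibble::tibble(
    subject_id = paste0("S", seq_len(n)),
    sex = factor(ifelse(female == 1, "female", "male"),
                 levels = c("male", "female")),
    age_onset = age,
    familial_cad = fam,
    smoking = rbinom(n, 1, 0.5),
    diabetes = rbinom(n, 1, 0.15),
    hypertension = rbinom(n, 1, 0.5),
    high_cholesterol = rbinom(n, 1, 0.4),
    bmi = rnorm(n, 27, 4),
    presentation = factor(sample(c("STEMI", "NSTEMI", "UAP", "SAP"), n,
                                 replace = TRUE),
                          levels = c("STEMI", "NSTEMI", "UAP", "SAP")),
    pc1 = rnorm(n), pc2 = rnorm(n),
    ugrs_cad = 67 + 4 * z_cad, wgrs_cad = 67 + 4 * z_cad,
    z_ugrs_cad = z_cad, z_wgrs_cad = z_cad,
    ugrs_ldl = 58 + 4 * z_ldl, wgrs_ldl = 58 + 4 * z_ldl,
    z_ugrs_ldl = z_ldl, z_wgrs_ldl = z_ldl
  )
}
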