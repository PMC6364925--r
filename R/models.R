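#' Join trait score sets onto a phenotype table
#'
#' @param phenotypes Phenotype tibble ([read_phenotypes()]).
#' @param cad_scores,ldl_scores `grs_scores` tibbles for the CAD and LDL-C
#'   scores ([compute_scores()]).
#' @return The phenotype tibble with columns `ugrs_cad`, `wgrs_cad`,
#'   `z_ugrs_cad`, `z_wgrs_cad` and the `_ldl` counterparts, joined by
#'   `subject_id` (inner join).
#' @export
join_scores <- function(phenotypes, cad_scores, ldl_scores) {
  suffix_scores <- function(s, sfx) {
    s <- tibble::as_tibble(s)[, c("subject_id", "ugrs", "wgrs",
                                  "z_ugrs", "z_wgrs")]
    names(s)[-1] <- paste0(names(s)[-1], "_", sfx)
    s
  }
  out <- dplyr::inner_join(phenotypes, suffix_scores(cad_scores, "cad"),
                           by = "subject_id")
  out <- dplyr::inner_join(out, suffix_scores(ldl_scores, "ldl"),
                           by = "subject_id")
  if (nrow(out) == 0L) {
    stop("joining scores to phenotypes produced 0 subjects", call. = FALSE)
  }
  out
}

grs_score_cols <- c("z_wgrs_cad", "z_ugrs_cad", "z_wgrs_ldl", "z_ugrs_ldl")

full_covariates <- c("sex", "pc1", "pc2", "familial_cad", "smoking", "bmi",
                     "diabetes", "hypertension", "high_cholesterol")

#' Age-at-onset regression models
#'
#' Fits the study's two families of linear models of age at first
#' revascularization:
#' * sex-adjusted models — one per factor (familial CAD, smoking, diabetes,
#'   hypertension, known high cholesterol, BMI, and each standardized GRS),
#'   adjusted for sex; GRS models are additionally adjusted for genetic
#'   principal components 1 and 2;
#' * multivariable models 2–5 — one per standardized score (weighted CAD,
#'   unweighted CAD, weighted LDL-C, unweighted LDL-C), adjusted for sex,
#'   PC1, PC2, familial CAD, smoking, BMI, diabetes, hypertension and known
#'   high cholesterol.
#'
#' GRS coefficients read as years of earlier/later onset per 1 SD of the
#' score. Each model is fitted on complete cases for its own columns; a model
#' whose factor is entirely missing is skipped with a message.
#'
#' @param cohort Phenotypes joined with both score sets ([join_scores()]).
#' @return Tibble of coefficient rows (columns as [tidy.grs_fit()] plus
#'   `focal` marking each model's factor of interest).
#' @export
grs_age_models <- function(cohort) {
  stopifnot("age_onset" %in% names(cohort))
  fits <- list()

  sex_adj_factors <- c("familial_cad", "smoking", "diabetes", "hypertension",
                       "high_cholesterol", "bmi")
  for (f in sex_adj_factors) {
    if (!f %in% names(cohort) || all(is.na(cohort[[f]]))) {
      message("skipping sex-adjusted model for ", f, ": no data")
      next
    }
    fits[[paste0("sex_adjusted_", f)]] <-
      fit_ols(cohort, "age_onset", c(f, "sex"),
              model = paste0("sex_adjusted_", f))
  }
  for (s in grs_score_cols) {
    if (!s %in% names(cohort) || all(is.na(cohort[[s]]))) next
    fits[[paste0("sex_adjusted_", s)]] <-
      fit_ols(cohort, "age_onset", c(s, "sex", "pc1", "pc2"),
              model = paste0("sex_adjusted_", s))
  }

  multi_labels <- c(z_wgrs_cad = "model2_wgrs_cad", z_ugrs_cad = "model3_ugrs_cad",
                    z_wgrs_ldl = "model4_wgrs_ldl", z_ugrs_ldl = "model5_ugrs_ldl")
  for (s in names(multi_labels)) {
    if (!s %in% names(cohort) || all(is.na(cohort[[s]]))) next
    covs <- intersect(full_covariates, names(cohort))
    covs <- covs[vapply(covs, function(v) !all(is.na(cohort[[v]])), logical(1))]
    fits[[multi_labels[[s]]]] <-
      fit_ols(cohort, "age_onset", c(s, covs), model = multi_labels[[s]])
  }

  out <- dplyr::bind_rows(purrr::map(fits, function(f) {
    tab <- tidy(f)
    tab$term <- gsub("`", "", tab$term, fixed = TRUE)
    tab$focal <- tab$term == f$terms[1]  # each model's factor of interest
    tab
  }))
  out
}

#' Effect-modification (interaction) test
#'
#' Augments a multivariable age-at-onset model with a product term between a
#' standardized score and a candidate modifier (e.g. smoking, familial CAD,
#' BMI or sex) and reports the product-term estimate and p-value.
#'
#' @param cohort Phenotypes joined with scores ([join_scores()]).
#' @param score Name of the standardized score column, e.g. `"z_wgrs_ldl"`.
#' @param modifier Name of the modifier column.
#' @return A `grs_fit`; the product term is named `score:modifier`.
#' @export
interaction_test <- function(cohort, score, modifier) {
  stopifnot(score %in% names(cohort), modifier %in% names(cohort))
  d <- cohort
  if (is.factor(d[[modifier]])) d[[modifier]] <- as.numeric(d[[modifier]]) - 1
  d$.interaction <- d[[score]] * d[[modifier]]
  covs <- intersect(full_covariates, names(d))
  covs <- covs[vapply(covs, function(v) !all(is.na(d[[v]])), logical(1))]
  terms <- unique(c(score, modifier, covs, ".interaction"))
  fit <- fit_ols(d, "age_onset", terms,
                 model = paste0("interaction_", score, "_x_", modifier))
  fit$tidy$term[fit$tidy$term == ".interaction"] <-
    paste0(score, ":", modifier)
  fit
}
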