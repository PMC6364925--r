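#' Apply a missing-genotype policy to an oriented dosage matrix
#'
#' `mean_impute` replaces each missing cell by the in-sample mean dosage of
#' that variant (keeping the effective SNP count constant across subjects);
#' `rescale` leaves cells missing — the score functions then let missing
#' cells contribute 0 and rescale each subject's score to the full SNP count
#' (uGRS: multiply by N / n_used; wGRS: multiply by the ratio of total to
#' observed beta sum).
#'
#' @param dosage An oriented [dosage_matrix()].
#' @param policy `"mean_impute"` or `"rescale"`.
#' @return A [dosage_matrix()]; completed under `mean_impute`, unchanged under
#'   `rescale`.
#' @export
apply_missing_policy <- function(dosage, policy = c("mean_impute", "rescale")) {
  policy <- match.arg(policy)
  stopifnot(inherits(dosage, "dosage_matrix"))
  mat <- dosage$dosages
  if (policy == "rescale" || !anyNA(mat)) return(dosage)
  mu <- colMeans(mat, na.rm = TRUE)
  if (anyNA(mu) || any(!is.finite(mu))) {
    stop("variant(s) missing in all subjects cannot be mean-imputed: ",
         paste(colnames(mat)[!is.finite(mu)], collapse = ", "), call. = FALSE)
  }
  idx <- which(is.na(mat), arr.ind = TRUE)
  mat[idx] <- mu[idx[, 2]]
  dosage_matrix(mat, oriented = dosage$oriented)
}

#' Unweighted genetic risk score
#'
#' One point per risk-increasing allele under an additive model: the score of
#' subject i is the row sum of effect-allele dosages, `sum_j s_ij`.
#'
#' @param dosage An oriented [dosage_matrix()].
#' @param policy Missing-genotype policy, see [apply_missing_policy()].
#' @return Named numeric vector of per-subject scores. Subjects with all
#'   variants missing get `NA` with a warning.
#' @export
compute_ugrs <- function(dosage, policy = c("mean_impute", "rescale")) {
  policy <- match.arg(policy)
  check_oriented(dosage)
  n_snp <- ncol(dosage$dosages)
  n_used <- rowSums(!is.na(dosage$dosages))
  if (policy == "mean_impute") {
    mat <- apply_missing_policy(dosage, "mean_impute")$dosages
    score <- rowSums(mat)
  } else {
    score <- rowSums(dosage$dosages, na.rm = TRUE) * n_snp / n_used
  }
  score[n_used == 0L] <- NA_real_
  if (any(n_used == 0L)) {
    warning(sum(n_used == 0L),
            " subject(s) with no genotyped score variants; score set to NA",
            call. = FALSE)
  }
  score
}

#' Weighted genetic risk score
#'
#' Each effect allele is weighted by its GWAS beta and the weighted sum is
#' normalized by the average effect size, keeping the weighted score on the
#' allele-count scale of the unweighted score:
#' `wGRS_i = (N / sum_j beta_j) * sum_j beta_j s_ij`.
#' With all betas equal the weighted and unweighted scores coincide exactly.
#'
#' @param dosage An oriented [dosage_matrix()] whose columns are named by
#'   rsID and covered by `weights`.
#' @param weights A `grs_weights` table; matched to columns by rsID.
#' @param policy Missing-genotype policy, see [apply_missing_policy()].
#' @return Named numeric vector of per-subject scores.
#' @export
compute_wgrs <- function(dosage, weights,
                         policy = c("mean_impute", "rescale")) {
  policy <- match.arg(policy)
  check_oriented(dosage)
  ids <- colnames(dosage$dosages)
  pos <- match(ids, weights$rsid)
  if (anyNA(pos)) {
    stop("dosage columns not present in weight table: ",
         paste(ids[is.na(pos)], collapse = ", "), call. = FALSE)
  }
  beta <- weights$beta[pos]
  n_snp <- length(beta)
  if (any(beta < 0)) {
    warning("negative beta(s) after orientation; check that effect alleles are risk-increasing",
            call. = FALSE)
  }
  total_beta <- sum(beta)
  if (total_beta == 0) {
    stop("sum of effect sizes is zero; average-effect-size normalization undefined",
         call. = FALSE)
  }
  # with all betas equal the normalization cancels algebraically; short-cut
  # so the weighted score equals the unweighted one bit-for-bit
  if (length(unique(beta)) == 1L) {
    beta <- rep(1, n_snp)
    total_beta <- n_snp
  }
  n_used <- rowSums(!is.na(dosage$dosages))
  if (policy == "mean_impute") {
    mat <- apply_missing_policy(dosage, "mean_impute")$dosages
    score <- as.numeric(mat %*% beta) * n_snp / total_beta
  } else {
    mat <- dosage$dosages
    mat[is.na(mat)] <- 0
    obs_beta <- as.numeric((!is.na(dosage$dosages)) %*% beta)
    score <- as.numeric(mat %*% beta) * n_snp / obs_beta
  }
  score[n_used == 0L] <- NA_real_
  if (any(n_used == 0L)) {
    warning(sum(n_used == 0L),
            " subject(s) with no genotyped score variants; score set to NA",
            call. = FALSE)
  }
  names(score) <- rownames(dosage$dosages)
  score
}

#' Standardize a score to mean 0, SD 1
#'
#' Linear rescaling `z = (x - mean(x)) / sd(x)` with the sample (n-1) SD, so
#' downstream regression effects read as years per SD of the score. `NA`s are
#' ignored for the mean/SD and propagated.
#'
#' @param x Numeric vector with at least 2 non-missing values.
#' @return Standardized vector of the same length.
#' @export
standardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values to standardize",
                         call. = FALSE)
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s == 0) {
    stop("zero variance: score cannot be standardized", call. = FALSE)
  }
  (x - mean(x[ok])) / s
}

#' Compute a full score set for one trait
#'
#' Runs the missing policy, the unweighted and weighted scores and their
#' standardizations, and returns everything as one tibble.
#'
#' @inheritParams compute_wgrs
#' @return A tibble of class `grs_scores` with columns `subject_id`, `ugrs`,
#'   `wgrs`, `z_ugrs`, `z_wgrs`, `n_used`, and a `trait` attribute.
#' @export
compute_scores <- function(dosage, weights,
                           policy = c("mean_impute", "rescale")) {
  policy <- match.arg(policy)
  check_oriented(dosage)
  ugrs <- compute_ugrs(dosage, policy)
  wgrs <- compute_wgrs(dosage, weights, policy)
  out <- tibble::tibble(
    subject_id = rownames(dosage$dosages),
    ugrs = unname(ugrs),
    wgrs = unname(wgrs),
    z_ugrs = unname(standardize(ugrs)),
    z_wgrs = unname(standardize(wgrs)),
    n_used = unname(rowSums(!is.na(dosage$dosages)))
  )
  attr(out, "trait") <- attr(weights, "trait")
  class(out) <- c("grs_scores", class(out))
  out
}

#' Write a score set to TSV
#'
#' @param scores A `grs_scores` tibble from [compute_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(tibble::as_tibble(scores), path, progress = FALSE)
  invisible(path)
}

check_oriented <- function(dosage) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  if (!dosage$oriented) {
    stop("dosage matrix is not oriented; run harmonize() first", call. = FALSE)
  }
  invisible(TRUE)
}

#' Score distribution plot
#'
#' Histograms of the unweighted and weighted scores of a score set.
#'
#' @param object A `grs_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grs_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("ugrs", "wgrs"),
                              names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::labs(x = "risk-allele score", y = "subjects",
                  title = attr(object, "trait")) +
    ggplot2::theme_minimal()
}
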