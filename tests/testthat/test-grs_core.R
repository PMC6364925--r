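# Brute-force per-element oracles kept deliberately loop-based and separate
# from the vectorized implementation.
oracle_ugrs <- function(mat) {
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    s <- 0
    for (j in seq_len(ncol(mat))) s <- s + mat[i, j]
    out[i] <- s
  }
  out
}
oracle_wgrs <- function(mat, beta) {
  n_snp <- ncol(mat)
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    s <- 0
    for (j in seq_len(n_snp)) s <- s + beta[j] * mat[i, j]
    out[i] <- s * n_snp / sum(beta)
  }
  out
}

test_that("scores equal the loop oracle on random hard-call instances", {
  set.seed(101)
  for (rep in 1:20) {
    mat <- matrix(sample(0:2, 50 * 67, replace = TRUE), 50, 67)
    beta <- abs(rnorm(67, 0.08, 0.05)) + 1e-4
    w <- make_weights(67, betas = beta)
    dm <- make_dosage(mat, variants = w$rsid)
    expect_equal(unname(compute_ugrs(dm)), oracle_ugrs(mat),
                 tolerance = 1e-10)
    expect_equal(unname(compute_wgrs(dm, w)), oracle_wgrs(mat, beta),
                 tolerance = 1e-10)
  }
})

test_that("worked weighted-score example and equal-beta equivalence hold", {
  w <- make_weights(3, betas = c(0.1, 0.2, 0.3))
  dm <- make_dosage(matrix(c(1, 2, 0), 1, 3), variants = w$rsid)
  # sum(beta*s) = 0.5, mean beta = 0.2 -> 2.5
  expect_equal(unname(compute_wgrs(dm, w)), 2.5)

  set.seed(5)
  mat <- matrix(sample(0:2, 20 * 7, replace = TRUE), 20, 7)
  weq <- make_weights(7, betas = rep(0.37, 7))
  dmr <- make_dosage(mat, variants = weq$rsid)
  expect_identical(unname(compute_wgrs(dmr, weq)),
                   unname(compute_ugrs(dmr)))
})

test_that("score bounds and single-allele monotonicity hold", {
  set.seed(7)
  n_snp <- 12
  w <- make_weights(n_snp, betas = abs(rnorm(n_snp, 0.08, 0.05)) + 1e-4)
  mat <- matrix(sample(0:2, 25 * n_snp, replace = TRUE), 25, n_snp)
  dm <- make_dosage(mat, variants = w$rsid)
  u <- compute_ugrs(dm)
  expect_true(all(u >= 0 & u <= 2 * n_snp))

  ij <- which(mat < 2, arr.ind = TRUE)[1, ]
  i <- ij[["row"]]; j <- ij[["col"]]
  mat2 <- mat; mat2[i, j] <- mat2[i, j] + 1
  dm2 <- make_dosage(mat2, variants = w$rsid)
  expect_equal(unname(compute_ugrs(dm2)[i] - u[i]), 1)
  expect_equal(unname(compute_wgrs(dm2, w)[[i]] - compute_wgrs(dm, w)[[i]]),
               n_snp * w$beta[j] / sum(w$beta))
})

test_that("weighted and unweighted scores share their expectation", {
  # with betas drawn independently of the allele frequencies,
  # E[wGRS] = E[uGRS]; checked over replicate (beta, freq) draws
  set.seed(9)
  n <- 200; n_snp <- 20
  diffs <- replicate(200, {
    w <- make_weights(n_snp, betas = abs(rnorm(n_snp, 0.08, 0.05)) + 1e-4)
    p <- runif(n_snp, 0.1, 0.9)
    mat <- matrix(rbinom(n * n_snp, 2, rep(p, each = n)), n, n_snp)
    dm <- make_dosage(mat, variants = w$rsid)
    mean(compute_wgrs(dm, w)) - mean(compute_ugrs(dm))
  })
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})

test_that("unoriented input, zero beta sum and misaligned columns are fatal", {
  w <- make_weights(2)
  dm_un <- make_dosage(matrix(1, 2, 2), oriented = FALSE,
                       variants = w$rsid)
  expect_error(compute_ugrs(dm_un), "not oriented")
  w0 <- make_weights(2, betas = c(0.3, -0.3))
  dm <- make_dosage(matrix(1, 2, 2), variants = w0$rsid)
  expect_warning(expect_error(compute_wgrs(dm, w0), "zero"), "negative beta")
  dm_bad <- make_dosage(matrix(1, 2, 2), variants = c("rsX", "rsY"))
  expect_error(compute_wgrs(dm_bad, w), "not present in weight table")
})

test_that("standardization matches the two-point case and is idempotent", {
  z <- standardize(c(1, 3))
  expect_equal(z, c(-1, 1) / sqrt(2))
  set.seed(3)
  x <- rnorm(50, 10, 4)
  z1 <- standardize(x)
  expect_lt(abs(mean(z1)), 1e-10)
  expect_lt(abs(sd(z1) - 1), 1e-10)
  expect_equal(standardize(z1), z1)
  expect_error(standardize(rep(2, 5)), "zero variance")
})

test_that("missing policies impute or rescale as specified", {
  w <- make_weights(3, betas = c(0.1, 0.2, 0.3))
  mat <- rbind(c(0, 1, 2), c(1, NA, 2), c(2, 1, 0), c(NA, NA, NA))
  dm <- make_dosage(mat, variants = w$rsid)

  imp <- apply_missing_policy(dm, "mean_impute")
  # variant 2 is observed as (1, 1) in the other subjects -> imputed 1.0
  expect_equal(imp$dosages[2, 2], 1)

  expect_warning(u_resc <- compute_ugrs(dm, policy = "rescale"),
                 "no genotyped")
  expect_equal(unname(u_resc[2]), (1 + 2) * 3 / 2)
  expect_true(is.na(u_resc[4]))
  expect_warning(w_resc <- compute_wgrs(dm, w, policy = "rescale"),
                 "no genotyped")
  expect_equal(unname(w_resc[2]), (0.1 * 1 + 0.3 * 2) * 3 / (0.1 + 0.3))

  # a variant missing everywhere cannot be mean-imputed
  mat_all <- rbind(c(0, NA, 2), c(1, NA, 2))
  expect_error(apply_missing_policy(make_dosage(mat_all), "mean_impute"),
               "missing in all subjects")
})

test_that("the two missing policies agree in rank on a noisy cohort", {
  set.seed(77)
  n <- 500; n_snp <- 30
  w <- make_weights(n_snp, betas = abs(rnorm(n_snp, 0.08, 0.05)) + 1e-4)
  p <- runif(n_snp, 0.1, 0.9)
  mat <- matrix(rbinom(n * n_snp, 2, rep(p, each = n)), n, n_snp)
  mat[runif(n * n_snp) < 0.10] <- NA
  dm <- make_dosage(mat, variants = w$rsid)
  a <- compute_wgrs(dm, w, policy = "mean_impute")
  b <- compute_wgrs(dm, w, policy = "rescale")
  expect_gt(cor(a, b, method = "spearman", use = "complete.obs"), 0.95)
})

test_that("compute_scores assembles a standardized, bookkept tibble", {
  set.seed(8)
  w <- make_weights(10, betas = abs(rnorm(10, 0.08, 0.05)) + 1e-4)
  mat <- matrix(sample(0:2, 40 * 10, replace = TRUE), 40, 10)
  mat[1, 3] <- NA
  dm <- make_dosage(mat, variants = w$rsid)
  sc <- compute_scores(dm, w)
  expect_s3_class(sc, "grs_scores")
  expect_equal(sc$n_used, c(9, rep(10, 39)))
  expect_lt(abs(mean(sc$z_ugrs)), 1e-10)
  expect_lt(abs(sd(sc$z_wgrs) - 1), 1e-10)
})
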