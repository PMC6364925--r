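test_that("age strata use the sex-specific cutoffs, closed on the right", {
  expect_equal(as.character(assign_age_group("male", 36.9)), "very_young")
  expect_equal(as.character(assign_age_group("female", 45.5)), "very_young")
  expect_equal(as.character(assign_age_group(
    rep("male", 4), c(40, 40.01, 55, 70.5))),
    c("very_young", "young", "young", "old"))
  expect_equal(as.character(assign_age_group(
    rep("female", 4), c(50, 50.1, 80, 80.1))),
    c("very_young", "young", "intermediate", "old"))
  expect_true(is.na(assign_age_group("male", NA)))
})

test_that("premature disease uses strict sex-specific age thresholds", {
  expect_true(flag_premature("male", 54.9))
  expect_false(flag_premature("male", 55.0))
  expect_true(flag_premature("female", 64.9))
  expect_false(flag_premature("female", 65.0))
})

test_that("Cochran-Armitage test is null at equal proportions and detects the smoking gradient", {
  null <- cochran_armitage_trend(c(5, 50, 25), c(10, 100, 50))
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)

  # age-declining smoking in men: 70%, 59.3%, 55.7%, 40.6%
  smoking <- cochran_armitage_trend(c(7, 176, 299, 125),
                                    c(10, 297, 537, 308))
  expect_lt(smoking$p, 0.001)
  expect_lt(smoking$statistic, 0)

  expect_warning(dg <- cochran_armitage_trend(c(0, 0), c(5, 5)),
                 "degenerate")
  expect_equal(dg$p, 1)
  expect_error(cochran_armitage_trend(c(1, 0), c(5, 0)), "positive")
})

test_that("CA statistic is invariant to affine score changes and matches prop.trend.test", {
  set.seed(21)
  for (i in 1:10) {
    tot <- sample(30:120, 4)
    suc <- rbinom(4, tot, runif(1, 0.2, 0.8))
    if (sum(suc) == 0 || sum(suc) == sum(tot)) next
    a <- cochran_armitage_trend(suc, tot)
    b <- cochran_armitage_trend(suc, tot, scores = 10 + 5 * (1:4))
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
    # independent reference: the score chi-square test (Z^2 = X^2)
    ref <- suppressWarnings(stats::prop.trend.test(suc, tot))
    expect_equal(a$statistic^2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(a$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("CA p-values agree with a permutation null on a small table", {
  set.seed(31)
  tot <- c(40, 40, 40, 40)
  suc <- c(10, 14, 17, 23)
  obs <- cochran_armitage_trend(suc, tot)
  # permute group labels of the individual outcomes
  y <- rep(rep(c(1, 0), 4), c(rbind(suc, tot - suc)))
  g <- rep(1:4, tot)
  stat_of <- function(yy) {
    s <- tapply(yy, g, sum)
    cochran_armitage_trend(as.integer(s), tot)$statistic
  }
  perm <- replicate(4000, stat_of(sample(y)))
  p_perm <- mean(abs(perm) >= abs(obs$statistic))
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(obs$p - p_perm), 4 * se + 0.005)
})

test_that("continuous trend test recovers exact and null slopes", {
  g <- rep(1:4, each = 10)
  exact <- suppressWarnings(continuous_trend_test(2 + 3 * g, g))
  expect_equal(exact$slope, 3, tolerance = 1e-10)
  expect_lt(exact$p, 1e-12)

  flat <- continuous_trend_test(rep(c(5, 5, 5, 5), each = 10) +
                                  rep(c(-1, 1), 20), g)
  expect_equal(flat$slope, 0, tolerance = 1e-10)

  expect_warning(idn <- continuous_trend_test(rep(2, 40), g), "identical")
  expect_equal(idn$p, 1)
})

test_that("trend tests keep their nominal type-I error under the null", {
  set.seed(41)
  n_rep <- 400
  rej_ca <- rej_lm <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    tot <- rep(60, 4)
    suc <- rbinom(4, tot, 0.4)
    rej_ca[r] <- if (sum(suc) %in% c(0, sum(tot))) FALSE else
      cochran_armitage_trend(suc, tot)$p < 0.05
    y <- rnorm(240, 50, 5)
    rej_lm[r] <- continuous_trend_test(y, rep(1:4, each = 60))$p < 0.05
  }
  expect_lt(abs(mean(rej_ca) - 0.05), 0.03)
  expect_lt(abs(mean(rej_lm) - 0.05), 0.03)
})

test_that("Pearson correlation matches a hand-computed small example", {
  x <- c(1, 2, 4, 5, 7)
  y <- c(1, 3, 4, 4, 8)
  # hand computation of r and the t-based p
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  res <- pearson_correlation(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p.value, p_hand, tolerance = 1e-12)

  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")

  set.seed(51)
  small <- replicate(100, abs(pearson_correlation(rnorm(1000),
                                                  rnorm(1000))$r) < 0.1)
  expect_gte(mean(small), 0.95)
})

test_that("fit_ols reproduces exact fits and a pseudo-inverse oracle", {
  d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
  f <- suppressWarnings(fit_ols(d, "y", "x"))
  expect_equal(tidy(f)$estimate, c(2, 3), tolerance = 1e-10)
  expect_lt(suppressWarnings(glance(f))$sigma, 1e-10)

  set.seed(61)
  n <- 200
  d2 <- tibble::tibble(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                       c = rnorm(n), e = rnorm(n))
  f2 <- fit_ols(d2, "y", c("a", "b", "c", "e"))
  X <- cbind(1, d2$a, d2$b, d2$c, d2$e)
  # SVD pseudo-inverse, independent of lm's QR path
  sv <- svd(X)
  beta_or <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) %*% d2$y
  expect_equal(tidy(f2)$estimate, as.numeric(beta_or), tolerance = 1e-8)
  res <- d2$y - X %*% beta_or
  sigma2 <- sum(res^2) / (n - 5)
  se_or <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_equal(tidy(f2)$se, se_or, tolerance = 1e-8)

  d2$dup <- d2$a
  expect_error(fit_ols(d2, "y", c("a", "dup")), "collinear")
  expect_error(fit_ols(d2[1:3, ], "y", c("a", "b", "c", "e")),
               "too few complete cases")
})

test_that("OLS confidence intervals cover the truth at the nominal rate", {
  set.seed(71)
  n_rep <- 400
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 60
    d <- tibble::tibble(x = rnorm(n), z = rnorm(n))
    d$y <- 1 + 0.5 * d$x - 0.3 * d$z + rnorm(n, 0, 2)
    tab <- tidy(fit_ols(d, "y", c("x", "z")))
    cover[r] <- tab$ci_low[2] <= 0.5 && tab$ci_high[2] >= 0.5
  }
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})
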