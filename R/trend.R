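#' Cochran-Armitage trend test
#'
#' Tests for a linear trend in binomial proportions across K ordered groups.
#' With group scores w_k (centered at their count-weighted mean) the
#' statistic is
#' \deqn{Z = \frac{\sum_k w_k (r_k - n_k \bar p)}{\sqrt{\bar p (1-\bar p)
#'   \left[\sum_k n_k w_k^2 - (\sum_k n_k w_k)^2 / N\right]}}}
#' referred to the standard normal, two-sided, without continuity
#' correction. Default scores are the equally spaced 1..K; the statistic is
#' invariant to affine transformations of the scores.
#'
#' @param successes Integer vector of event counts per group.
#' @param totals Integer vector of group sizes.
#' @param scores Optional numeric group scores (default `1:K`).
#' @return A `grs_trend` object with `statistic` (Z), `p` (two-sided),
#'   `totals`, `successes`, `scores` and `method`.
#' @examples
#' cochran_armitage_trend(c(7, 176, 299, 125), c(10, 297, 537, 308))
#' @export
cochran_armitage_trend <- function(successes, totals, scores = NULL) {
  k <- length(totals)
  stopifnot(length(successes) == k, k >= 2L)
  if (any(totals <= 0)) stop("every group total must be positive", call. = FALSE)
  if (any(successes < 0) || any(successes > totals)) {
    stop("successes must satisfy 0 <= successes <= totals", call. = FALSE)
  }
  if (is.null(scores)) scores <- seq_len(k)
  n_tot <- sum(totals)
  p_bar <- sum(successes) / n_tot
  if (p_bar %in% c(0, 1)) {
    warning("degenerate table (pooled proportion 0 or 1); p set to 1",
            call. = FALSE)
    z <- 0
    p <- 1
  } else {
    w <- scores - sum(totals * scores) / n_tot
    num <- sum(w * (successes - totals * p_bar))
    den <- sqrt(p_bar * (1 - p_bar) *
                  (sum(totals * w^2) - sum(totals * w)^2 / n_tot))
    z <- num / den
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(statistic = z, p = p, successes = successes,
                 totals = totals, scores = scores,
                 method = "Cochran-Armitage trend test"),
            class = "grs_trend")
}

#' Linear trend test for a continuous variable across ordered groups
#'
#' Ordinary least squares of the values on the (1..K) group index, as used
#' for "P for trend" of continuous characteristics across age strata.
#'
#' @param values Numeric vector.
#' @param group Group membership: an ordered factor or integer index per
#'   observation.
#' @return A `grs_trend` object with `statistic` (the slope t statistic),
#'   `p`, `slope`, `se` and `method`.
#' @export
continuous_trend_test <- function(values, group) {
  stopifnot(length(values) == length(group))
  idx <- if (is.factor(group)) as.integer(group) else as.integer(group)
  ok <- !is.na(values) & !is.na(idx)
  values <- values[ok]; idx <- idx[ok]
  if (length(unique(idx)) < 2L) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    warning("all values identical; trend p set to 1", call. = FALSE)
    return(structure(list(statistic = 0, p = 1, slope = 0, se = NA_real_,
                          method = "linear trend (OLS on group index)"),
                     class = "grs_trend"))
  }
  fit <- stats::lm(values ~ idx)
  cf <- summary(fit)$coefficients
  structure(list(statistic = cf["idx", "t value"],
                 p = cf["idx", "Pr(>|t|)"],
                 slope = cf["idx", "Estimate"],
                 se = cf["idx", "Std. Error"],
                 method = "linear trend (OLS on group index)"),
            class = "grs_trend")
}

#' @export
print.grs_trend <- function(x, ...) {
  cat("<grs_trend> ", x$method, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format.pval(x$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a trend test
#' @param x A `grs_trend` object.
#' @param ... Unused.
#' @return One-row tibble with `method`, `statistic`, `p.value` and, for the
#'   continuous test, `slope` and `se`.
#' @exportS3Method generics::tidy
tidy.grs_trend <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, p.value = x$p,
                 slope = if (!is.null(x$slope)) x$slope else NA_real_,
                 se = if (!is.null(x$se)) x$se else NA_real_)
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation of two score vectors, with the usual two-sided
#' p-value from `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return One-row tibble with `r`, `p.value` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
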