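#' Fit an ordinary least-squares model and tabulate the estimates
#'
#' Data-frame-first wrapper around [stats::lm()] that returns coefficient
#' estimates with standard errors, 95% t-based confidence intervals and
#' two-sided p-values, after complete-case restriction to the model columns.
#' Rank-deficient designs are a fatal error naming the collinear terms
#' rather than silently dropping them.
#'
#' @param data A data frame holding the response and the predictors.
#' @param response Name of the response column (string).
#' @param terms Character vector of predictor column names.
#' @param model Model label carried into the output.
#' @return An object of class `grs_fit`; see [tidy.grs_fit()] and
#'   [glance.grs_fit()].
#' @export
fit_ols <- function(data, response, terms, model = "model") {
  stopifnot(is.data.frame(data), is.character(response), is.character(terms))
  cols <- c(response, terms)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0L) {
    stop("column(s) not in data: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  form <- stats::as.formula(
    paste(sprintf("`%s`", response), "~",
          paste(sprintf("`%s`", terms), collapse = " + ")))
  n <- nrow(d)
  fit <- stats::lm(form, data = d)
  p <- length(stats::coef(fit))
  if (n <= p) {
    stop("too few complete cases (n = ", n, ") for ", p, " coefficients",
         call. = FALSE)
  }
  cf_all <- stats::coef(fit)
  if (anyNA(cf_all) || fit$rank < p) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf_all)[is.na(cf_all)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  tcrit <- stats::qt(0.975, df = n - p)
  est <- unname(sm[, "Estimate"])
  se <- unname(sm[, "Std. Error"])
  tab <- tibble::tibble(
    model = model,
    term = rownames(sm),
    estimate = est,
    se = se,
    ci_low = est - tcrit * se,
    ci_high = est + tcrit * se,
    p = unname(sm[, "Pr(>|t|)"]),
    n = n
  )
  structure(list(tidy = tab, fit = fit, n = n, model = model,
                 response = response, terms = terms),
            class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, ...) {
  cat("<grs_fit> ", x$model, ": ", x$response, " ~ ",
      paste(x$terms, collapse = " + "), "  (n = ", x$n, ")\n", sep = "")
  print(x$tidy)
  invisible(x)
}

#' Coefficient table of a fitted model
#'
#' @param x A `grs_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `model`, `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @exportS3Method generics::tidy
tidy.grs_fit <- function(x, ...) x$tidy

#' One-row model summary
#'
#' @param x A `grs_fit` object.
#' @param ... Unused.
#' @return Tibble with `model`, `n`, `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`.
#' @exportS3Method generics::glance
glance.grs_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(model = x$model, n = x$n, r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared, sigma = sm$sigma,
                 df.residual = x$fit$df.residual)
}

#' Forest plot of model estimates
#'
#' Plots estimates and 95% confidence intervals from one or more tidied
#' model tables (rows of [tidy.grs_fit()] output), e.g. the focal GRS terms
#' across models.
#'
#' @param estimates Tibble with columns `term`, `estimate`, `ci_low`,
#'   `ci_high` and optionally `model`.
#' @return A ggplot object.
#' @export
plot_model_estimates <- function(estimates) {
  stopifnot(all(c("term", "estimate", "ci_low", "ci_high") %in%
                  names(estimates)))
  lab <- if ("model" %in% names(estimates)) {
    paste(estimates$model, estimates$term, sep = ": ")
  } else estimates$term
  d <- dplyr::mutate(estimates, label = factor(lab, levels = rev(unique(lab))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "years below/above mean age at onset", y = NULL) +
    ggplot2::theme_minimal()
}
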