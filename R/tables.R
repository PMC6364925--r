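#' Age-stratified characteristics table for one sex
#'
#' Summarizes a cohort by the four sex-specific age strata: n per stratum,
#' mean (SD) for continuous characteristics, count (%) for binary ones and
#' the four clinical presentations, with a "P for trend" across strata — a
#' Cochran-Armitage trend test for binary rows and an OLS trend on the group
#' index for continuous rows.
#'
#' @param cohort Phenotype tibble, optionally with joined score columns
#'   ([join_scores()]).
#' @param sex `"male"` or `"female"`.
#' @return A list of class `grs_characteristics`: `summary` (long tibble with
#'   `variable`, `age_group`, `n`, `mean`, `sd`, `count`, `pct`) and `trend`
#'   (tibble `variable`, `p_trend`). Empty strata appear with `n = 0` and are
#'   excluded from the tests.
#' @export
characteristics_table <- function(cohort, sex = c("male", "female")) {
  sex <- match.arg(sex)
  d <- cohort[!is.na(cohort$sex) & cohort$sex == sex &
                !is.na(cohort$age_onset), , drop = FALSE]
  d$age_group <- assign_age_group(d$sex, d$age_onset)
  groups <- levels(d$age_group)
  n_by <- vapply(groups, function(g) sum(d$age_group == g), integer(1))

  cont_vars <- intersect(c("age_onset", "bmi", "ugrs_cad", "wgrs_cad",
                           "ugrs_ldl", "wgrs_ldl"), names(d))
  bin_vars <- intersect(c("smoking", "diabetes", "hypertension",
                          "high_cholesterol", "familial_cad"), names(d))
  pres_levels <- c("STEMI", "NSTEMI", "UAP", "SAP")

  rows <- list()
  trend <- list()

  for (v in cont_vars) {
    rows[[v]] <- tibble::tibble(
      variable = v, age_group = groups, n = n_by,
      mean = vapply(groups, function(g)
        mean(d[[v]][d$age_group == g], na.rm = TRUE), numeric(1)),
      sd = vapply(groups, function(g)
        stats::sd(d[[v]][d$age_group == g], na.rm = TRUE), numeric(1)),
      count = NA_real_, pct = NA_real_)
    ok <- !is.na(d[[v]])
    p <- if (v == "age_onset") NA_real_ else if (sum(ok) > 2)
      continuous_trend_test(d[[v]][ok], d$age_group[ok])$p else NA_real_
    trend[[v]] <- tibble::tibble(variable = v, p_trend = p)
  }

  bin_row <- function(v, value_by_group) {
    cnt <- vapply(groups, function(g)
      sum(value_by_group[d$age_group == g], na.rm = TRUE), numeric(1))
    tot <- vapply(groups, function(g)
      sum(!is.na(value_by_group[d$age_group == g])), numeric(1))
    rows[[v]] <<- tibble::tibble(
      variable = v, age_group = groups, n = n_by,
      mean = NA_real_, sd = NA_real_, count = cnt,
      pct = ifelse(tot > 0, 100 * cnt / tot, NA_real_))
    nonempty <- tot > 0
    p <- if (sum(nonempty) >= 2 && sum(cnt) > 0 && sum(cnt) < sum(tot))
      cochran_armitage_trend(cnt[nonempty], tot[nonempty],
                             scores = which(nonempty))$p else NA_real_
    trend[[v]] <<- tibble::tibble(variable = v, p_trend = p)
  }
  for (v in bin_vars) bin_row(v, d[[v]])
  if ("presentation" %in% names(d) && !all(is.na(d$presentation))) {
    for (lv in pres_levels) {
      bin_row(lv, as.integer(d$presentation == lv))
    }
  }

  summary <- dplyr::bind_rows(rows)
  summary[] <- lapply(summary, unname)
  structure(list(sex = sex,
                 summary = summary,
                 trend = dplyr::bind_rows(trend),
                 n_total = nrow(d)),
            class = "grs_characteristics")
}

#' @export
print.grs_characteristics <- function(x, ...) {
  cat("<grs_characteristics> sex:", x$sex, "- n =", x$n_total, "\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' Score and familial-CAD summary by clinical presentation
#'
#' Per presentation category (STEMI, NSTEMI, UAP, SAP): mean (SD) of the four
#' genetic risk scores and count (%) with familial CAD, plus a "P for
#' difference" — one-way ANOVA F-test for the score means and a Pearson
#' chi-square (no continuity correction) for familial CAD.
#'
#' @param cohort Phenotypes joined with scores ([join_scores()]); subjects
#'   with missing presentation are excluded.
#' @return A list of class `grs_presentation`: `summary` (tibble `variable`,
#'   `presentation`, `n`, `mean`, `sd`, `count`, `pct`) and `tests` (tibble
#'   `variable`, `p_difference`). Absent categories are omitted with a
#'   warning.
#' @export
presentation_summary <- function(cohort) {
  d <- cohort[!is.na(cohort$presentation), , drop = FALSE]
  if (nrow(d) == 0L) stop("no subjects with non-missing presentation",
                          call. = FALSE)
  present <- levels(droplevels(d$presentation))
  absent <- setdiff(levels(d$presentation), present)
  if (length(absent) > 0L) {
    warning("presentation category(ies) absent: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  d$presentation <- droplevels(d$presentation)
  score_vars <- intersect(c("ugrs_cad", "wgrs_cad", "ugrs_ldl", "wgrs_ldl"),
                          names(d))
  rows <- list(); tests <- list()
  n_by <- vapply(present, function(g)
    sum(d$presentation == g), integer(1))
  for (v in score_vars) {
    rows[[v]] <- tibble::tibble(
      variable = v, presentation = present, n = n_by,
      mean = vapply(present, function(g)
        mean(d[[v]][d$presentation == g], na.rm = TRUE), numeric(1)),
      sd = vapply(present, function(g)
        stats::sd(d[[v]][d$presentation == g], na.rm = TRUE), numeric(1)),
      count = NA_real_, pct = NA_real_)
    p <- if (length(present) >= 2) {
      av <- stats::aov(d[[v]] ~ d$presentation)
      summary(av)[[1]][["Pr(>F)"]][1]
    } else NA_real_
    tests[[v]] <- tibble::tibble(variable = v, p_difference = p)
  }
  if ("familial_cad" %in% names(d) && !all(is.na(d$familial_cad))) {
    cnt <- vapply(present, function(g)
      sum(d$familial_cad[d$presentation == g], na.rm = TRUE), numeric(1))
    tot <- vapply(present, function(g)
      sum(!is.na(d$familial_cad[d$presentation == g])), numeric(1))
    rows$familial_cad <- tibble::tibble(
      variable = "familial_cad", presentation = present, n = n_by,
      mean = NA_real_, sd = NA_real_, count = cnt,
      pct = ifelse(tot > 0, 100 * cnt / tot, NA_real_))
    p <- if (length(present) >= 2) {
      tabm <- rbind(cnt, tot - cnt)
      stats::chisq.test(tabm, correct = FALSE)$p.value
    } else NA_real_
    tests$familial_cad <- tibble::tibble(variable = "familial_cad",
                                         p_difference = p)
  }
  summary <- dplyr::bind_rows(rows)
  summary[] <- lapply(summary, unname)
  structure(list(summary = summary,
                 tests = dplyr::bind_rows(tests)),
            class = "grs_presentation")
}

#' @export
print.grs_presentation <- function(x, ...) {
  cat("<grs_presentation>\n")
  print(x$summary, n = 25)
  print(x$tests)
  invisible(x)
}

#' Pool sex-by-age stratum summaries into overall cohort figures
#'
#' Given stratum-level summaries (one row per sex-by-age-group stratum with
#' its size `n`, `mean_age`, and count columns for binary characteristics),
#' computes the overall cohort summary: pooled mean age as the n-weighted
#' average of stratum means, the percentage of women, and a pooled
#' percentage for every count column.
#'
#' @param strata Tibble with columns `sex`, `n`, `mean_age` and any number of
#'   count columns (e.g. `familial_cad`, `smoking`, `stemi`, ...).
#' @return One-row tibble: `n_total`, `mean_age`, `pct_women`, and `pct_<col>`
#'   for each count column.
#' @examples
#' strata <- tibble::tibble(sex = c("male", "female"), n = c(100, 50),
#'                          mean_age = c(60, 70), familial_cad = c(40, 20))
#' derived_overall_summary(strata)
#' @export
derived_overall_summary <- function(strata) {
  stopifnot(all(c("sex", "n", "mean_age") %in% names(strata)))
  if (anyNA(strata$n)) stop("stratum n missing", call. = FALSE)
  n_total <- sum(strata$n)
  out <- tibble::tibble(
    n_total = n_total,
    mean_age = sum(strata$n * strata$mean_age) / n_total,
    pct_women = 100 * sum(strata$n[tolower(strata$sex) == "female"]) / n_total
  )
  count_cols <- setdiff(names(strata),
                        c("sex", "age_group", "n", "mean_age", "sd_age"))
  for (v in count_cols) {
    out[[paste0("pct_", v)]] <- 100 * sum(strata[[v]]) / n_total
  }
  out
}

#' Pool presentation-specific counts over stratum presentation totals
#'
#' Combines per-presentation event counts (e.g. subjects with familial CAD in
#' each presentation category) with presentation totals summed from the
#' sex-by-age stratum table, yielding the percentage with the characteristic
#' in each presentation category.
#'
#' @param strata Stratum tibble with count columns `stemi`, `nstemi`, `uap`,
#'   `sap`.
#' @param presentation_counts Tibble with columns `presentation` and `count`.
#' @return Tibble `presentation`, `count`, `total`, `pct`.
#' @export
pool_presentation_counts <- function(strata, presentation_counts) {
  need <- c("stemi", "nstemi", "uap", "sap")
  stopifnot(all(need %in% names(strata)),
            all(c("presentation", "count") %in% names(presentation_counts)))
  totals <- tibble::tibble(
    presentation = toupper(need),
    total = vapply(need, function(v) sum(strata[[v]]), numeric(1),
                   USE.NAMES = FALSE)
  )
  out <- dplyr::inner_join(
    dplyr::mutate(presentation_counts,
                  presentation = toupper(.data$presentation)),
    totals, by = "presentation")
  dplyr::mutate(out, pct = 100 * .data$count / .data$total)
}
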