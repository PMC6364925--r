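#' Assign sex-specific age-at-onset strata
#'
#' Four ordered strata with sex-specific cutoffs, closed on the upper end:
#' men — very_young (<=40), young (>40–55), intermediate (>55–70), old (>70);
#' women — very_young (<=50), young (>50–65), intermediate (>65–80),
#' old (>80).
#'
#' @param sex Character or factor vector, `"male"`/`"female"`.
#' @param age_onset Numeric vector of ages (years) at first
#'   revascularization.
#' @return Ordered factor with levels `very_young`, `young`, `intermediate`,
#'   `old`; `NA` where sex or age is missing.
#' @examples
#' assign_age_group(c("male", "male", "female"), c(40, 40.01, 45.5))
#' @export
assign_age_group <- function(sex, age_onset) {
  sex <- tolower(as.character(sex))
  age_onset <- as.numeric(age_onset)
  stopifnot(length(sex) == length(age_onset))
  cuts_m <- c(-Inf, 40, 55, 70, Inf)
  cuts_f <- c(-Inf, 50, 65, 80, Inf)
  labs <- c("very_young", "young", "intermediate", "old")
  out <- rep(NA_character_, length(sex))
  m <- !is.na(sex) & sex == "male" & !is.na(age_onset)
  f <- !is.na(sex) & sex == "female" & !is.na(age_onset)
  out[m] <- labs[cut(age_onset[m], cuts_m, labels = FALSE, right = TRUE)]
  out[f] <- labs[cut(age_onset[f], cuts_f, labels = FALSE, right = TRUE)]
  factor(out, levels = labs, ordered = TRUE)
}

#' Flag premature coronary artery disease
#'
#' Premature CAD is a first event strictly before age 55 in men and 65 in
#' women.
#'
#' @inheritParams assign_age_group
#' @return Logical vector; `NA` where sex or age is missing.
#' @export
flag_premature <- function(sex, age_onset) {
  sex <- tolower(as.character(sex))
  stopifnot(length(sex) == length(age_onset))
  ifelse(sex == "male", age_onset < 55,
         ifelse(sex == "female", age_onset < 65, NA))
}
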