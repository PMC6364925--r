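#' Read a subject phenotype table
#'
#' Reads the per-subject phenotype/covariate file. Required columns:
#' `subject_id`, `sex` (male/female), `age_onset` (years at first
#' revascularization). Optional columns: `familial_cad`, `smoking`,
#' `diabetes`, `hypertension`, `high_cholesterol` (0/1), `bmi` (kg/m^2),
#' `presentation` (STEMI, NSTEMI, UAP or SAP), `pc1`, `pc2` (genetic
#' principal components).
#'
#' @param path Path to a TSV or CSV file with a header.
#' @return A tibble with typed columns; `presentation` is a factor with
#'   levels STEMI, NSTEMI, UAP, SAP.
#' @export
read_phenotypes <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("subject_id", "sex", "age_onset")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0L) {
    stop("phenotype file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sex <- tolower(as.character(raw$sex))
  bad_sex <- which(!sex %in% c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("invalid sex value at row(s) ", paste(bad_sex, collapse = ", "),
         " (expected male/female)", call. = FALSE)
  }
  age <- as.numeric(raw$age_onset)
  bad_age <- which(is.na(age) | age <= 0 | age > 120)
  if (length(bad_age) > 0L) {
    stop("invalid age_onset at row(s) ", paste(bad_age, collapse = ", "),
         " (must be in (0, 120])", call. = FALSE)
  }
  opt_binary <- function(col) {
    if (!col %in% names(raw)) return(rep(NA_integer_, nrow(raw)))
    v <- raw[[col]]
    out <- as.integer(v)
    bad <- which(!is.na(out) & !out %in% c(0L, 1L))
    if (length(bad) > 0L) {
      stop("column ", col, " must be 0/1; bad row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out
  }
  pres_levels <- c("STEMI", "NSTEMI", "UAP", "SAP")
  if ("presentation" %in% names(raw)) {
    pres_chr <- toupper(as.character(raw$presentation))
    pres_chr[!is.na(pres_chr) & pres_chr == ""] <- NA_character_
    bad <- which(!is.na(pres_chr) & !pres_chr %in% pres_levels)
    if (length(bad) > 0L) {
      stop("invalid presentation value at row(s) ",
           paste(bad, collapse = ", "), " (allowed: ",
           paste(pres_levels, collapse = ", "), ")", call. = FALSE)
    }
    pres <- factor(pres_chr, levels = pres_levels)
  } else {
    pres <- factor(rep(NA_character_, nrow(raw)), levels = pres_levels)
  }
  opt_num <- function(col) {
    if (col %in% names(raw)) as.numeric(raw[[col]]) else rep(NA_real_, nrow(raw))
  }
  tibble::tibble(
    subject_id = as.character(raw$subject_id),
    sex = factor(sex, levels = c("male", "female")),
    age_onset = age,
    familial_cad = opt_binary("familial_cad"),
    smoking = opt_binary("smoking"),
    diabetes = opt_binary("diabetes"),
    hypertension = opt_binary("hypertension"),
    high_cholesterol = opt_binary("high_cholesterol"),
    bmi = opt_num("bmi"),
    presentation = pres,
    pc1 = opt_num("pc1"),
    pc2 = opt_num("pc2")
  )
}
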