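#' Subjects-by-variants dosage matrix
#'
#' A thin container around a numeric matrix of risk-allele (or, before
#' harmonization, ALT-allele) dosages. Rows are subjects, columns variants;
#' values lie in `[0, 2]` (hard genotype calls are 0/1/2, imputed dosages may
#' be fractional) and `NA` marks a missing genotype. The `oriented` flag
#' records whether columns already count effect (risk-increasing) alleles.
#'
#' @param dosages Numeric matrix with rownames (subject IDs) and colnames
#'   (variant IDs).
#' @param oriented Logical; `TRUE` once dosages count effect alleles.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosages, oriented = FALSE) {
  stopifnot(is.matrix(dosages), is.numeric(dosages))
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages)) || is.null(colnames(dosages))) {
    stop("dosage matrix needs subject rownames and variant colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate subject IDs in dosage matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(dosages))) {
    stop("duplicate variant IDs in dosage matrix", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  structure(list(dosages = dosages, oriented = isTRUE(oriented)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("<dosage_matrix> ", nrow(x$dosages), " subjects x ", ncol(x$dosages),
      " variants, oriented = ", x$oriented, ", ",
      sum(is.na(x$dosages)), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Subject IDs of a dosage matrix
#' @param x A `dosage_matrix`.
#' @return Character vector of subject IDs.
#' @export
subject_ids <- function(x) rownames(x$dosages)

#' Variant IDs of a dosage matrix
#' @param x A `dosage_matrix`.
#' @return Character vector of variant IDs.
#' @export
variant_ids <- function(x) colnames(x$dosages)
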