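#' Read a SNP effect-weight table
#'
#' Reads the tab- or comma-separated weight file for one trait score. The file
#' must have a header with columns `rsid`, `effect_allele`, `other_allele` and
#' `beta`; the optional columns `proxy_rsid` and `proxy_r2` designate a
#' substitute variant in high linkage disequilibrium (r^2 > 0.8) to be used
#' when the index SNP is absent from the genotype data.
#'
#' @param path Path to the weight file (TSV or CSV, header required).
#' @param trait Trait label for the score, e.g. `"CAD"` or `"LDL-C"`.
#' @return A tibble of class `grs_weights` with one row per SNP, columns
#'   `rsid`, `effect_allele`, `other_allele`, `beta`, `proxy_rsid`,
#'   `proxy_r2`, and a `trait` attribute. Row order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\teffect_allele\tother_allele\tbeta",
#'              "rs1\tA\tG\t0.12", "rs2\tC\tT\t0.05"), tf)
#' read_weight_table(tf, trait = "CAD")
#' @export
read_weight_table <- function(path, trait) {
  stopifnot(is.character(path), length(path) == 1L)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  required <- c("rsid", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("weight table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    rsid = as.character(raw$rsid),
    effect_allele = toupper(as.character(raw$effect_allele)),
    other_allele = toupper(as.character(raw$other_allele)),
    beta = as.numeric(raw$beta),
    proxy_rsid = if ("proxy_rsid" %in% names(raw))
      as.character(raw$proxy_rsid) else NA_character_,
    proxy_r2 = if ("proxy_r2" %in% names(raw))
      as.numeric(raw$proxy_r2) else NA_real_
  )
  tbl$proxy_rsid[!is.na(tbl$proxy_rsid) & tbl$proxy_rsid == ""] <- NA_character_
  new_grs_weights(tbl, trait)
}

#' Construct and validate a weight table
#'
#' @param tbl Tibble with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta` and optionally `proxy_rsid`, `proxy_r2`.
#' @param trait Trait label.
#' @return Validated `grs_weights` tibble.
#' @keywords internal
new_grs_weights <- function(tbl, trait) {
  if (!"proxy_rsid" %in% names(tbl)) tbl$proxy_rsid <- NA_character_
  if (!"proxy_r2" %in% names(tbl)) tbl$proxy_r2 <- NA_real_
  dup <- tbl$rsid[duplicated(tbl$rsid)]
  if (length(dup) > 0L) {
    stop("duplicate rsID(s) in weight table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (anyNA(tbl$beta) || any(!is.finite(tbl$beta))) {
    stop("non-finite beta in weight table (rows ",
         paste(which(!is.finite(tbl$beta)), collapse = ", "), ")",
         call. = FALSE)
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- !ok_allele(tbl$effect_allele) | !ok_allele(tbl$other_allele)
  if (any(bad)) {
    stop("unknown allele character at rsID(s): ",
         paste(tbl$rsid[bad], collapse = ", "),
         " (SNP alleles must be one of A, C, G, T)", call. = FALSE)
  }
  if (any(tbl$effect_allele == tbl$other_allele)) {
    stop("effect allele equals other allele at rsID(s): ",
         paste(tbl$rsid[tbl$effect_allele == tbl$other_allele], collapse = ", "),
         call. = FALSE)
  }
  has_proxy <- !is.na(tbl$proxy_rsid)
  if (any(has_proxy & (is.na(tbl$proxy_r2) | tbl$proxy_r2 <= 0.8))) {
    stop("proxy variants require proxy_r2 > 0.8", call. = FALSE)
  }
  attr(tbl, "trait") <- trait
  class(tbl) <- c("grs_weights", class(tbl))
  tbl
}

#' Write a weight table to TSV
#'
#' @param weights A `grs_weights` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path) {
  out <- tibble::as_tibble(weights)[, c("rsid", "effect_allele", "other_allele",
                                        "beta", "proxy_rsid", "proxy_r2")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.grs_weights <- function(x, ...) {
  cat("<grs_weights> trait:", attr(x, "trait"), "-", nrow(x), "SNPs,",
      sum(!is.na(x$proxy_rsid)), "with proxies\n")
  NextMethod()
}
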