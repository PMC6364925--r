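#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF v4.x file and returns ALT-allele dosages per subject per
#' variant together with the variant keys. Only biallelic SNP records are
#' kept; multiallelic or indel records are rejected with a warning giving the
#' count. The returned matrix is unoriented: dosages count ALT alleles, not
#' (yet) effect alleles — see [harmonize()].
#'
#' @param path Path to a VCF file with per-sample `GT` and optionally `DS`
#'   fields.
#' @param prefer_dosage If `TRUE` and a `DS` (imputed dosage) field is present
#'   for a record, use it instead of the hard `GT` allele count.
#' @return A list with `dosage` (a [dosage_matrix()] with `oriented = FALSE`;
#'   missing genotypes `./.` become `NA`) and `variants` (tibble with columns
#'   `chrom`, `pos`, `id`, `ref`, `alt`).
#' @export
read_vcf <- function(path, prefer_dosage = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  check_vcf_structure(path)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }

  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_bad <- sum(!is_snp)
  if (n_bad > 0L) {
    warning(n_bad, " non-biallelic-SNP record(s) rejected", call. = FALSE)
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path, call. = FALSE)

  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  dose <- gt_to_dosage(gt_chr)
  if (prefer_dosage && grepl("ID=DS", paste(vcf@meta, collapse = " "))) {
    ds <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE))
    use <- !is.na(ds)
    dose[use] <- ds[use]
  }
  dose <- dose[is_snp, , drop = FALSE]

  variants <- tibble::tibble(
    chrom = as.character(fix[is_snp, "CHROM"]),
    pos = as.integer(fix[is_snp, "POS"]),
    id = as.character(fix[is_snp, "ID"]),
    ref = ref[is_snp],
    alt = alt[is_snp]
  )
  mat <- t(dose)
  rownames(mat) <- samples
  colnames(mat) <- variants$id
  list(dosage = dosage_matrix(mat, oriented = FALSE), variants = variants)
}

# ALT allele count from GT strings ("0/1", "1|1", "./." -> NA)
gt_to_dosage <- function(gt_chr) {
  out <- matrix(NA_real_, nrow = nrow(gt_chr), ncol = ncol(gt_chr),
                dimnames = dimnames(gt_chr))
  known <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
             "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2)
  idx <- match(gt_chr, names(known))
  out[] <- known[idx]
  out[is.na(gt_chr) | gt_chr %in% c("./.", ".|.", ".")] <- NA_real_
  out
}

# Minimal structural validation so malformed files fail with a line number
# (the field counts of every data line must match the #CHROM header).
check_vcf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L) {
    stop("malformed VCF ", path, ": expected exactly one #CHROM header line",
         call. = FALSE)
  }
  if (!grepl("^##fileformat=VCF", lines[1])) {
    stop("malformed VCF ", path, ": line 1 is not a ##fileformat declaration",
         call. = FALSE)
  }
  n_fields <- lengths(strsplit(lines[hdr], "\t", fixed = TRUE))
  body <- seq(hdr + 1L, length.out = length(lines) - hdr)
  for (i in body) {
    if (!nzchar(lines[i])) next
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf != n_fields) {
      stop("malformed VCF ", path, ": line ", i, " has ", nf,
           " fields, expected ", n_fields, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write hard-call genotypes (and optional dosages) to a VCF file
#'
#' Writes a minimal VCF v4.2 with per-sample `GT` fields, and a `DS` field on
#' records flagged as imputed. Used by the synthetic-cohort generator; the
#' dialect written is the one [read_vcf()] reads.
#'
#' @param variants Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param gt Subjects-by-variants matrix of ALT-allele hard calls (0/1/2, `NA`
#'   for missing), rownames are subject IDs.
#' @param path Output path.
#' @param imputed Optional logical vector per variant; imputed records carry a
#'   `DS` field equal to the ALT dosage.
#' @param ds Optional subjects-by-variants matrix of fractional ALT dosages to
#'   write as `DS` for imputed records (defaults to `gt`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, gt, path, imputed = NULL, ds = NULL) {
  stopifnot(nrow(variants) == ncol(gt))
  if (is.null(imputed)) imputed <- rep(FALSE, nrow(variants))
  if (is.null(ds)) ds <- gt
  subjects <- rownames(gt)
  gt_code <- function(x) {
    out <- rep("./.", length(x))
    out[!is.na(x) & x == 0] <- "0/0"
    out[!is.na(x) & x == 1] <- "0/1"
    out[!is.na(x) & x == 2] <- "1/1"
    out
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=grsonset synthetic cohort generator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated ALT dose\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(j) {
    codes <- gt_code(gt[, j])
    if (imputed[j]) {
      dsj <- ifelse(is.na(ds[, j]), ".", format(ds[, j], trim = TRUE))
      codes <- paste(codes, dsj, sep = ":")
      fmt <- "GT:DS"
    } else {
      fmt <- "GT"
    }
    paste(c(variants$chrom[j], variants$pos[j], variants$id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", fmt, codes),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
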