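#' Orient dosages to count risk-increasing alleles
#'
#' Matches each SNP of a weight table to a genotyped variant and re-orients
#' dosages so that every column counts the effect (risk-increasing) allele,
#' i.e. the effect allele takes the role of the alternative allele regardless
#' of how the VCF happened to encode ref/alt. Matching is by rsID; when the
#' index rsID is absent but the weight entry names a proxy variant (LD
#' r^2 > 0.8), the proxy column is used in its place. Variants whose allele
#' pair does not match the weight entry's `{effect, other}` pair are dropped.
#'
#' Strand-ambiguous SNPs (A/T or C/G allele pairs) cannot be disambiguated
#' from allele labels alone; `strand_policy = "keep"` (default, appropriate
#' for single-platform data with consistent strand) keeps them with a warning,
#' `"drop"` removes them.
#'
#' @param dosage An unoriented [dosage_matrix()] of ALT-allele dosages.
#' @param variants Variant key tibble from [read_vcf()] (`chrom`, `pos`, `id`,
#'   `ref`, `alt`).
#' @param weights A `grs_weights` table ([read_weight_table()]).
#' @param strand_policy `"keep"` or `"drop"` for strand-ambiguous SNPs.
#' @return A list with:
#'   * `dosage`: oriented [dosage_matrix()] whose columns follow the weight
#'     table order (matched entries only), named by the index rsID;
#'   * `weights`: the matched subset of `weights`, aligned to the columns;
#'   * `report`: a `harmonization_report` — counts of `matched`, `proxied`,
#'     `flipped`, `dropped`, `ambiguous_kept` plus a per-entry `detail`
#'     tibble. Always `matched + dropped = nrow(weights)`.
#' @export
harmonize <- function(dosage, variants, weights,
                      strand_policy = c("keep", "drop")) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(inherits(dosage, "dosage_matrix"))
  if (dosage$oriented) {
    stop("dosage matrix is already oriented; harmonize() must not be applied twice",
         call. = FALSE)
  }
  mat <- dosage$dosages
  # rsID is the primary key; chrom:pos disambiguates colliding IDs
  vid <- variants$id
  if (anyDuplicated(vid)) {
    keyed <- paste(variants$chrom, variants$pos, sep = ":")
    vid[duplicated(vid) | duplicated(vid, fromLast = TRUE)] <-
      paste0(vid, "@", keyed)[duplicated(vid) | duplicated(vid, fromLast = TRUE)]
  }

  n <- nrow(weights)
  detail <- tibble::tibble(
    rsid = weights$rsid,
    matched_id = NA_character_,
    action = character(n),
    note = NA_character_
  )
  cols <- integer(0)
  flip <- logical(0)
  keep_entry <- logical(n)
  n_proxied <- 0L
  n_ambiguous <- 0L

  is_ambiguous <- function(a, b) {
    p <- paste(sort(c(a, b)), collapse = "/")
    p %in% c("A/T", "C/G")
  }

  for (k in seq_len(n)) {
    w <- weights[k, ]
    j <- match(w$rsid, vid)
    used_proxy <- FALSE
    if (is.na(j) && !is.na(w$proxy_rsid)) {
      j <- match(w$proxy_rsid, vid)
      used_proxy <- !is.na(j)
    }
    if (is.na(j)) {
      detail$action[k] <- "dropped"
      detail$note[k] <- "absent from genotypes"
      next
    }
    detail$matched_id[k] <- variants$id[j]
    ref <- variants$ref[j]
    alt <- variants$alt[j]
    if (is_ambiguous(w$effect_allele, w$other_allele) &&
        strand_policy == "drop") {
      detail$action[k] <- "dropped"
      detail$note[k] <- "strand-ambiguous (policy drop)"
      next
    }
    if (w$effect_allele == alt && w$other_allele == ref) {
      do_flip <- FALSE
    } else if (w$effect_allele == ref && w$other_allele == alt) {
      do_flip <- TRUE
    } else {
      detail$action[k] <- "dropped"
      detail$note[k] <- sprintf("allele mismatch (%s/%s vs %s/%s)",
                                w$effect_allele, w$other_allele, ref, alt)
      next
    }
    if (is_ambiguous(w$effect_allele, w$other_allele)) {
      n_ambiguous <- n_ambiguous + 1L
      detail$note[k] <- "strand-ambiguous (kept)"
    }
    detail$action[k] <- if (do_flip) "flipped" else "kept"
    if (used_proxy) {
      n_proxied <- n_proxied + 1L
      detail$note[k] <- paste0("proxy ", w$proxy_rsid,
                               if (!is.na(detail$note[k])) paste0("; ", detail$note[k]) else "")
    }
    keep_entry[k] <- TRUE
    cols <- c(cols, j)
    flip <- c(flip, do_flip)
  }

  if (!any(keep_entry)) {
    stop("no weight-table variants could be matched to the genotype data",
         call. = FALSE)
  }
  if (n_ambiguous > 0L) {
    warning(n_ambiguous, " strand-ambiguous SNP(s) kept (strand_policy = \"keep\")",
            call. = FALSE)
  }

  out <- mat[, cols, drop = FALSE]
  if (any(flip)) {
    out[, flip] <- 2 - out[, flip, drop = FALSE]  # NA stays NA
  }
  colnames(out) <- weights$rsid[keep_entry]

  report <- structure(list(
    matched = sum(keep_entry),
    proxied = n_proxied,
    flipped = sum(flip),
    dropped = n - sum(keep_entry),
    ambiguous_kept = n_ambiguous,
    detail = detail
  ), class = "harmonization_report")

  matched_weights <- weights[keep_entry, ]
  attr(matched_weights, "trait") <- attr(weights, "trait")

  list(dosage = dosage_matrix(out, oriented = TRUE),
       weights = matched_weights,
       report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report>\n",
      "  matched: ", x$matched, " (", x$proxied, " via proxy, ",
      x$flipped, " flipped, ", x$ambiguous_kept, " strand-ambiguous kept)\n",
      "  dropped: ", x$dropped, "\n", sep = "")
  invisible(x)
}

#' Tidy a harmonization report
#'
#' @param x A `harmonization_report`.
#' @param ... Unused.
#' @return The per-entry detail tibble (`rsid`, `matched_id`, `action`,
#'   `note`).
#' @exportS3Method generics::tidy
tidy.harmonization_report <- function(x, ...) x$detail
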