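#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are a
#' fatal error naming the key. Numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @param allowed Character vector of allowed keys (defaults to the
#'   simulation and run parameters).
#' @return Named list of values.
#' @export
read_run_config <- function(path, allowed = NULL) {
  if (is.null(allowed)) {
    allowed <- unique(c(names(formals(sim_config)),
                        c("vcf", "weights_cad", "weights_ldl", "phenotypes",
                          "scores_cad", "scores_ldl", "out",
                          "missing_policy", "strand_policy",
                          "prefer_dosage", "seed")))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% allowed) stop("unknown config key: ", key, call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

write_manifest <- function(dir, inputs, outputs, seed = NA, extra = list()) {
  files <- c(inputs, outputs)
  files <- files[vapply(files, file.exists, logical(1))]
  manifest <- c(list(
    package = "grsonset",
    version = as.character(utils::packageVersion("grsonset")),
    seed = seed,
    inputs = as.list(inputs),
    checksums = as.list(tools::md5sum(unlist(files)))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a cohort bundle from a configuration
#'
#' Entry point behind the `simulate` subcommand: builds a [sim_config()]
#' (overriding defaults with any keys in `config`), writes the full file
#' bundle via [simulate_cohort()] plus a log of every parameter used.
#'
#' @param out Output directory.
#' @param config Named list of [sim_config()] overrides (e.g. from
#'   [read_run_config()]).
#' @param seed Seed overriding `config$seed` if non-`NULL`.
#' @return Invisibly, the [simulate_cohort()] bundle.
#' @export
run_simulate <- function(out, config = list(), seed = NULL) {
  config <- config[names(config) %in% names(formals(sim_config))]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cfg <- do.call(sim_config, config)
  bundle <- simulate_cohort(cfg, out)
  log_lines <- c("simulate: parameters used",
                 paste0(names(unclass(cfg)), " = ",
                        vapply(unclass(cfg), function(x)
                          paste(format(x), collapse = ","), character(1))))
  writeLines(log_lines, file.path(out, "simulate.log"))
  write_manifest(out, inputs = character(0),
                 outputs = unlist(bundle$paths), seed = cfg$seed)
  invisible(bundle)
}

#' Score a cohort: read, harmonize, compute and standardize both GRS
#'
#' Entry point behind the `score` subcommand: reads the VCF and both weight
#' tables, orients dosages to count risk alleles (with proxy substitution),
#' applies the missing-genotype policy, computes unweighted and weighted
#' scores and their standardized versions, and writes per-trait score TSVs
#' plus harmonization reports.
#'
#' @param vcf Path to the genotype VCF.
#' @param weights_cad,weights_ldl Paths to the CAD and LDL-C weight tables.
#' @param out Output directory.
#' @param missing_policy `"mean_impute"` or `"rescale"`.
#' @param strand_policy `"keep"` or `"drop"` for strand-ambiguous SNPs.
#' @param prefer_dosage Use DS fields when present.
#' @return Invisibly, a list with `scores` (list of `grs_scores`), `reports`
#'   (harmonization reports) and output `paths`.
#' @export
run_score <- function(vcf, weights_cad, weights_ldl, out,
                      missing_policy = c("mean_impute", "rescale"),
                      strand_policy = c("keep", "drop"),
                      prefer_dosage = FALSE) {
  missing_policy <- match.arg(missing_policy)
  strand_policy <- match.arg(strand_policy)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  geno <- read_vcf(vcf, prefer_dosage = prefer_dosage)
  w <- list(cad = read_weight_table(weights_cad, trait = "CAD"),
            ldl = read_weight_table(weights_ldl, trait = "LDL-C"))
  scores <- list(); reports <- list(); paths <- list()
  for (trait in c("cad", "ldl")) {
    h <- harmonize(geno$dosage, geno$variants, w[[trait]],
                   strand_policy = strand_policy)
    sc <- compute_scores(h$dosage, h$weights, policy = missing_policy)
    scores[[trait]] <- sc
    reports[[trait]] <- h$report
    paths[[paste0("scores_", trait)]] <-
      write_scores(sc, file.path(out, paste0("scores_", trait, ".tsv")))
    rep_path <- file.path(out, paste0("harmonization_", trait, ".tsv"))
    readr::write_tsv(h$report$detail, rep_path, progress = FALSE)
    paths[[paste0("harmonization_", trait)]] <- rep_path
    counts_path <- file.path(out, paste0("harmonization_", trait,
                                         "_counts.tsv"))
    readr::write_tsv(tibble::tibble(
      matched = h$report$matched, proxied = h$report$proxied,
      flipped = h$report$flipped, dropped = h$report$dropped,
      ambiguous_kept = h$report$ambiguous_kept), counts_path,
      progress = FALSE)
    paths[[paste0("harmonization_", trait, "_counts")]] <- counts_path
  }
  write_manifest(out,
                 inputs = c(vcf = vcf, weights_cad = weights_cad,
                            weights_ldl = weights_ldl),
                 outputs = unlist(paths),
                 extra = list(missing_policy = missing_policy,
                              strand_policy = strand_policy,
                              prefer_dosage = prefer_dosage))
  invisible(list(scores = scores, reports = reports, paths = paths))
}

#' Analyze a scored cohort: strata tables, trends, models, interactions
#'
#' Entry point behind the `analyze` subcommand: joins scores to phenotypes
#' and emits the age-stratified characteristics tables per sex (with trend
#' tests), the clinical-presentation summary (with difference tests), the
#' sex-adjusted and multivariable age-at-onset models, the unweighted and
#' weighted between-score correlations, the GRS-by-modifier interaction
#' tests, and a plain-text report; every number in the report comes from one
#' of the TSVs written alongside it.
#'
#' @param scores_cad,scores_ldl Paths to score TSVs from [run_score()].
#' @param phenotypes Path to the phenotype TSV.
#' @param out Output directory.
#' @return Invisibly, a list with the result objects and output `paths`.
#' @export
run_analyze <- function(scores_cad, scores_ldl, phenotypes, out) {
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  read_sc <- function(path) {
    readr::read_tsv(path, col_types = readr::cols(
      subject_id = readr::col_character()), progress = FALSE,
      show_col_types = FALSE)
  }
  phen <- read_phenotypes(phenotypes)
  cohort <- join_scores(phen, read_sc(scores_cad), read_sc(scores_ldl))
  if (nrow(cohort) == 0L) stop("score/phenotype join is empty", call. = FALSE)

  paths <- list()
  results <- list()
  emit <- function(obj, name) {
    p <- file.path(out, paste0(name, ".tsv"))
    readr::write_tsv(obj, p, progress = FALSE)
    paths[[name]] <<- p
  }

  for (sx in c("male", "female")) {
    if (!any(cohort$sex == sx, na.rm = TRUE)) {
      warning("no ", sx, " subjects; table omitted", call. = FALSE)
      next
    }
    tab <- characteristics_table(cohort, sx)
    results[[paste0("characteristics_", sx)]] <- tab
    emit(tab$summary, paste0("characteristics_", sx))
    emit(tab$trend, paste0("characteristics_", sx, "_trend"))
  }

  if (!all(is.na(cohort$presentation))) {
    pres <- presentation_summary(cohort)
    results$presentation <- pres
    emit(pres$summary, "presentation_summary")
    emit(pres$tests, "presentation_tests")
  }

  models <- grs_age_models(cohort)
  results$models <- models
  emit(models, "models")

  correlations <- dplyr::bind_rows(
    dplyr::mutate(pearson_correlation(cohort$ugrs_cad, cohort$ugrs_ldl),
                  pair = "ugrs_cad~ugrs_ldl"),
    dplyr::mutate(pearson_correlation(cohort$wgrs_cad, cohort$wgrs_ldl),
                  pair = "wgrs_cad~wgrs_ldl"))
  results$correlations <- correlations
  emit(correlations, "correlations")

  interactions <- list()
  for (s in c("z_wgrs_cad", "z_wgrs_ldl")) {
    for (m in c("smoking", "familial_cad", "bmi", "sex")) {
      if (all(is.na(cohort[[m]]))) next
      f <- interaction_test(cohort, s, m)
      interactions[[paste(s, m, sep = "_x_")]] <-
        f$tidy[f$tidy$term == paste0(s, ":", m), ]
    }
  }
  if (length(interactions) > 0L) {
    itab <- dplyr::bind_rows(interactions)
    results$interactions <- itab
    emit(itab, "interactions")
  }

  report_path <- file.path(out, "report.txt")
  writeLines(render_report(results, nrow(cohort)), report_path)
  paths$report <- report_path

  write_manifest(out,
                 inputs = c(scores_cad = scores_cad, scores_ldl = scores_ldl,
                            phenotypes = phenotypes),
                 outputs = unlist(paths))
  invisible(c(results, list(paths = paths, cohort = cohort)))
}

render_report <- function(results, n) {
  fmt <- function(x, d = 2) formatC(x, digits = d, format = "f")
  out <- c("Genetic risk scores and age at onset: analysis report",
           paste0("subjects analyzed: ", n), "")
  for (sx in c("male", "female")) {
    tab <- results[[paste0("characteristics_", sx)]]
    if (is.null(tab)) next
    out <- c(out, paste0("== Characteristics by age group (", sx, ") =="))
    age <- tab$summary[tab$summary$variable == "age_onset", ]
    out <- c(out, paste0("  n per group: ",
                         paste(age$age_group, age$n, sep = "=",
                               collapse = ", ")))
    for (v in unique(tab$summary$variable)) {
      rowv <- tab$summary[tab$summary$variable == v, ]
      pv <- tab$trend$p_trend[tab$trend$variable == v]
      cells <- if (all(is.na(rowv$mean))) {
        paste0(rowv$count, " (", fmt(rowv$pct, 1), "%)")
      } else {
        paste0(fmt(rowv$mean, 1), " (", fmt(rowv$sd, 1), ")")
      }
      out <- c(out, paste0("  ", format(v, width = 18), " ",
                           paste(cells, collapse = " | "),
                           "  p_trend=", ifelse(is.na(pv), "NA",
                                                format.pval(pv, digits = 3))))
    }
    out <- c(out, "")
  }
  if (!is.null(results$presentation)) {
    out <- c(out, "== Scores and familial CAD by clinical presentation ==")
    ps <- results$presentation
    for (v in unique(ps$summary$variable)) {
      rowv <- ps$summary[ps$summary$variable == v, ]
      pv <- ps$tests$p_difference[ps$tests$variable == v]
      cells <- if (all(is.na(rowv$mean))) {
        paste0(rowv$count, " (", fmt(rowv$pct, 1), "%)")
      } else {
        paste0(fmt(rowv$mean, 1), " (", fmt(rowv$sd, 1), ")")
      }
      out <- c(out, paste0("  ", format(v, width = 18), " ",
                           paste(cells, collapse = " | "),
                           "  p_diff=", format.pval(pv, digits = 3)))
    }
    out <- c(out, "")
  }
  if (!is.null(results$models)) {
    out <- c(out, "== Age-at-onset models (focal terms) ==")
    foc <- results$models[results$models$focal, ]
    out <- c(out, vapply(seq_len(nrow(foc)), function(i) {
      paste0("  ", format(foc$model[i], width = 28), " ",
             format(foc$term[i], width = 18), " ",
             fmt(foc$estimate[i]), " (", fmt(foc$ci_low[i]), ", ",
             fmt(foc$ci_high[i]), ") p=",
             format.pval(foc$p[i], digits = 3), " n=", foc$n[i])
    }, character(1)), "")
  }
  if (!is.null(results$correlations)) {
    out <- c(out, "== Between-score correlations ==",
             vapply(seq_len(nrow(results$correlations)), function(i) {
               paste0("  ", results$correlations$pair[i], ": r = ",
                      fmt(results$correlations$r[i]), ", p = ",
                      format.pval(results$correlations$p.value[i],
                                  digits = 3))
             }, character(1)), "")
  }
  if (!is.null(results$interactions)) {
    it <- results$interactions
    out <- c(out, "== Effect-modification tests (product terms) ==",
             vapply(seq_len(nrow(it)), function(i) {
               paste0("  ", format(it$term[i], width = 30), " ",
                      fmt(it$estimate[i]), " p = ",
                      format.pval(it$p[i], digits = 3))
             }, character(1)))
  }
  out
}
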