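#' Run configuration for the end-to-end pipeline
#'
#' A run is described by a plain list (built here, or read from JSON/YAML
#' with [read_run_config()]) with fields:
#'
#' * `reference`: path to the reference FASTA.
#' * `samples`: path to a sample-sheet TSV (`sample`, `vcf`, `group` with
#'   groups `control`/`exposed`), or an equivalent data frame.
#' * `catalog`: optional path to a signature-catalogue TSV used for
#'   ranking and exposure fitting.
#' * `bed`, `expression`: optional gene footprints (BED4) and per-gene
#'   expression TSV for the selection analysis.
#' * parameters: `mode` (signature derivation), `n_bins`, `x_mode`,
#'   `effective_genome_bp`, `alpha`, `keep_all_filters`, `subset`,
#'   `selection_group`, `out` (output directory).
#'
#' @param config A configuration list.
#' @param need Character vector of required fields.
#' @return The validated config (paths checked, sample sheet loaded).
#' @export
validate_run_config <- function(config, need = c("reference", "samples")) {
  for (f in need)
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
  for (f in intersect(c("reference", "catalog", "bed", "expression"),
                      names(config))) {
    if (is.character(config[[f]]) && !file.exists(config[[f]]))
      stop("config path '", f, "' does not exist: ", config[[f]])
  }
  if (!is.null(config$samples)) {
    if (is.character(config$samples)) {
      if (!file.exists(config$samples))
        stop("sample sheet not found: ", config$samples)
      sheet_dir <- dirname(config$samples)
      config$samples <- utils::read.table(config$samples, header = TRUE,
                                          sep = "\t", stringsAsFactors = FALSE)
      # VCF paths in a sheet may be relative to the sheet's directory
      rel <- !file.exists(config$samples$vcf) &
        file.exists(file.path(sheet_dir, config$samples$vcf))
      config$samples$vcf[rel] <- file.path(sheet_dir,
                                           config$samples$vcf[rel])
    }
    req <- c("sample", "vcf")
    if (!all(req %in% names(config$samples)))
      stop("sample sheet needs columns: ", paste(req, collapse = ", "))
    missing_vcf <- !file.exists(config$samples$vcf)
    if (any(missing_vcf))
      stop("VCF not found for sample ",
           config$samples$sample[missing_vcf][1], ": ",
           config$samples$vcf[missing_vcf][1])
  }
  config
}

#' @rdname validate_run_config
#' @param path Path to a JSON or YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    cfg <- yaml::read_yaml(path)
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg
}

load_samples <- function(config, genome) {
  sheet <- config$samples
  keep_all <- isTRUE(config$keep_all_filters)
  records <- list(); qc <- list()
  for (i in seq_len(nrow(sheet))) {
    r <- withCallingHandlers(
      read_vcf(sheet$vcf[i], sheet$sample[i], genome = genome,
               keep_all_filters = keep_all),
      warning = function(w) invokeRestart("muffleWarning"))
    records[[sheet$sample[i]]] <- r
    qc[[sheet$sample[i]]] <- attr(r, "skipped")
  }
  list(records = do.call(rbind, records), qc = qc)
}

#' Build all catalogues for a set of clone VCFs
#'
#' Reads the reference and every sample's VCF, merges adjacent SNVs into
#' doublets, classifies all records, and builds the SBS96, DBS78 and ID
#' catalogues plus the six-class summary with its one-way ANOVA and
#' Tukey post-hoc report. With `config$out` set, catalogue TSVs, the
#' class summary, and a QC log (records in, classified, skipped, per
#' sample) are written there.
#'
#' @param config See [validate_run_config()].
#' @return A list with `catalogs` (named list of `mutation_catalog`),
#'   `class_summary`, `anova`, `records` and `qc`.
#' @export
run_catalog <- function(config) {
  config <- validate_run_config(config)
  genome <- load_reference(config$reference)
  inputs <- load_samples(config, genome)
  records <- merge_adjacent_snvs(inputs$records)
  sample_ids <- config$samples$sample

  catalogs <- list(); skipped_n <- list()
  for (scheme in c("SBS96", "DBS78", "ID")) {
    cl <- withCallingHandlers(
      classify_mutations(records, genome, scheme),
      warning = function(w) invokeRestart("muffleWarning"))
    catalogs[[scheme]] <- build_catalog(cl, scheme, sample_ids = sample_ids)
    skipped_n[[scheme]] <- catalogs[[scheme]]$skipped
  }

  summary <- NULL; anova <- NULL
  if (all(rowSums(catalogs$SBS96$counts) > 0)) {
    summary <- class_percentages(catalogs$SBS96)
    if (length(sample_ids) >= 2) anova <- class_anova(summary)
  }

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    for (scheme in names(catalogs))
      write_catalog(catalogs[[scheme]],
                    file.path(config$out, paste0("catalog_", scheme, ".tsv")))
    if (!is.null(summary)) {
      utils::write.table(
        data.frame(sample = summary$sample_ids, summary$percentages,
                   check.names = FALSE),
        file.path(config$out, "class_percentages.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    qc_lines <- c(
      sprintf("stage=read_vcf sample=%s filtered=%d symbolic=%d complex=%d",
              names(inputs$qc), vapply(inputs$qc, `[[`, 0L, "filtered"),
              vapply(inputs$qc, `[[`, 0L, "symbolic"),
              vapply(inputs$qc, `[[`, 0L, "complex")),
      sprintf("stage=classify scheme=%s classified=%d skipped=%d",
              names(catalogs),
              vapply(catalogs, function(x) sum(x$counts), 0L),
              vapply(skipped_n, sum, 0L)))
    writeLines(qc_lines, file.path(config$out, "qc.log"))
  }
  invisible(list(catalogs = catalogs, class_summary = summary, anova = anova,
                 records = records, qc = inputs$qc))
}

#' Derive exposure signatures and compare them to a catalogue
#'
#' Splits the samples into control and exposed groups, derives the SBS,
#' DBS and ID exposure profiles by control normalisation, and (when a
#' signature catalogue is supplied) ranks every catalogue signature by
#' cosine similarity and refits the profile as a non-negative
#' combination. A failure in one scheme (e.g. no exposure-attributable
#' excess) is reported and the run continues with the remaining schemes.
#'
#' @param config See [validate_run_config()]; `samples` must carry a
#'   `group` column covering both `control` and `exposed`.
#' @return A list with `profiles`, `reports`, `fits` and `errors`
#'   (per-scheme error messages), plus the `catalogs` used.
#' @export
run_signature <- function(config) {
  config <- validate_run_config(config)
  if (is.null(config$samples$group) ||
      !all(c("control", "exposed") %in% config$samples$group))
    stop("signature derivation needs samples in both 'control' and 'exposed' groups")
  built <- run_catalog(config)
  sheet <- config$samples
  catalog_tsv <- if (!is.null(config$catalog))
    read_signature_catalog(config$catalog) else NULL

  profiles <- list(); reports <- list(); fits <- list(); errors <- list()
  for (scheme in names(built$catalogs)) {
    cat_all <- built$catalogs[[scheme]]
    sub_cat <- function(group) {
      ids <- sheet$sample[sheet$group == group]
      structure(list(scheme_id = scheme, sample_ids = ids,
                     counts = cat_all$counts[ids, , drop = FALSE],
                     skipped = cat_all$skipped[ids]),
                class = "mutation_catalog")
    }
    res <- tryCatch(
      derive_exposure_signature(sub_cat("exposed"), sub_cat("control"),
                                mode = config$mode %||n% "mean-subtract",
                                name = paste0("derived_", scheme)),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[scheme]] <- conditionMessage(res)
      next
    }
    profiles[[scheme]] <- res
    if (!is.null(catalog_tsv) && catalog_tsv$scheme_id == scheme) {
      cmp <- catalog_tsv
      if (!is.null(config$subset))
        cmp <- signature_catalog(scheme,
                                 cmp$signatures[, config$subset, drop = FALSE])
      reports[[scheme]] <- rank_matches(res, cmp)
      fits[[scheme]] <- fit_exposures(res, cmp)
    }
  }
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    for (scheme in names(profiles))
      write_signature_catalog(profiles[[scheme]],
                              file.path(config$out,
                                        paste0("profile_", scheme, ".tsv")))
    for (scheme in names(reports))
      export_report(reports[[scheme]],
                    file.path(config$out, paste0("ranking_", scheme, ".tsv")))
    for (scheme in names(fits))
      export_report(fits[[scheme]],
                    file.path(config$out, paste0("fit_", scheme, ".json")))
  }
  invisible(list(profiles = profiles, reports = reports, fits = fits,
                 errors = errors, catalogs = built$catalogs))
}

`%||n%` <- function(a, b) if (is.null(a)) b else a

#' Gene-level selection analysis
#'
#' Counts mutations in gene footprints, tests each gene for over- and
#' under-mutation against uniform random placement (FDR-controlled calls
#' at `alpha`), and, when expression values are available, regresses
#' binned mutation rate on expression. Without an expression file the
#' regression is skipped with a notice.
#'
#' @param config See [validate_run_config()]; `bed` is required.
#' @return A list with `enrichment` (data frame in the shape gene,
#'   observed, expected, p_over, p_under, q_over, q_under, call) and
#'   `regression` (a `rate_regression` or the string `"skipped"`).
#' @export
run_selection <- function(config) {
  config <- validate_run_config(config, need = c("reference", "samples", "bed"))
  genome <- load_reference(config$reference)
  inputs <- load_samples(config, genome)
  records <- inputs$records
  group <- config$selection_group %||n% "exposed"
  if (!is.null(config$samples$group) && group %in% config$samples$group) {
    ids <- config$samples$sample[config$samples$group == group]
    records <- records[records$sample_id %in% ids, , drop = FALSE]
  }
  genes <- read_gene_models(config$bed, config$expression)
  observed <- count_gene_mutations(records, genes)
  enrichment <- gene_enrichment_test(
    observed, total_mutations = nrow(records),
    footprint_bp = genes$table$footprint_bp,
    effective_genome_bp = config$effective_genome_bp %||n% sum(genome$lengths),
    model = config$model %||n% "poisson")
  enrichment <- call_enrichment(enrichment, alpha = config$alpha %||n% 0.05)

  regression <- "skipped"
  if (!is.null(config$expression) && any(!is.na(genes$table$expression))) {
    regression <- expression_rate_regression(
      records, genes, n_bins = config$n_bins %||n% 10,
      x_mode = config$x_mode %||n% "midrank")
  }
  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(enrichment, file.path(config$out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reg_json <- if (identical(regression, "skipped"))
      list(status = "skipped") else
      list(status = "ok", slope = regression$slope,
           intercept = regression$intercept, p_value = regression$p_value,
           r_squared = regression$r_squared, bins = regression$bins)
    jsonlite::write_json(reg_json, file.path(config$out, "regression.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(list(enrichment = enrichment, regression = regression))
}

#' Run the complete analysis
#'
#' [run_catalog()], [run_signature()] and (when a BED file is supplied)
#' [run_selection()] in sequence, sharing one configuration.
#'
#' @param config See [validate_run_config()].
#' @return A list with components `catalog`, `signature`, `selection`.
#' @export
run_all <- function(config) {
  out <- list()
  out$signature <- run_signature(config)  # includes catalogue building
  out$catalog <- list(catalogs = out$signature$catalogs)
  if (!is.null(config$bed)) out$selection <- run_selection(config)
  invisible(out)
}
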