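#' Build a per-sample mutation catalogue
#'
#' Tallies classified mutations into a samples x channels count matrix
#' over the full canonical channel set (channels with no mutations are
#' zero columns). Row sums equal the number of classified records per
#' sample; per-sample skipped-record counts can be attached for QC.
#'
#' @param classified Output of [classify_mutations()] (the list, or just
#'   its `classified` data frame).
#' @param scheme_id Channel scheme; must match the classified records.
#' @param sample_ids Optional ordered sample set (so samples with zero
#'   mutations still get a row); defaults to the samples present.
#' @return A `mutation_catalog`: list with `scheme_id`, `sample_ids`,
#'   `counts` (integer matrix, samples x channels) and `skipped` (named
#'   integer vector per sample).
#' @export
build_catalog <- function(classified, scheme_id, sample_ids = NULL) {
  skipped_df <- NULL
  if (is.list(classified) && !is.data.frame(classified) &&
      !is.null(classified$classified)) {
    skipped_df <- classified$skipped
    classified <- classified$classified
  }
  if (nrow(classified) && !all(classified$scheme_id == scheme_id))
    stop("mixed or mismatched channel schemes in classified records")
  labels <- channel_scheme(scheme_id)$labels
  if (is.null(sample_ids))
    sample_ids <- sort(unique(classified$sample_id))
  counts <- table(
    factor(classified$sample_id, levels = sample_ids),
    factor(classified$channel, levels = labels)
  )
  counts <- matrix(as.integer(counts), nrow = length(sample_ids),
                   dimnames = list(sample_ids, labels))
  skipped <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (!is.null(skipped_df) && nrow(skipped_df)) {
    tab <- table(factor(skipped_df$sample_id, levels = sample_ids))
    skipped[] <- as.integer(tab)
  }
  structure(list(scheme_id = scheme_id, sample_ids = sample_ids,
                 counts = counts, skipped = skipped),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("<mutation_catalog %s: %d sample(s), %d mutations>\n",
              x$scheme_id, length(x$sample_ids), sum(x$counts)))
  invisible(x)
}

#' Collapse an SBS96 catalogue to the six substitution classes
#'
#' Per sample, the 96 channels are summed into their central substitution
#' classes (C>A, C>G, C>T, T>A, T>C, T>G) and expressed as percentages of
#' that sample's total; the cross-sample mean and standard deviation
#' (n - 1 denominator, clones treated as replicates) are attached.
#'
#' @param catalog An SBS96 `mutation_catalog` with >= 1 mutation per sample.
#' @return A `class_summary`: list with `sample_ids`, `class_labels`,
#'   `percentages` (samples x 6), `mean` and `sd` (length-6 vectors, %).
#' @export
class_percentages <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (catalog$scheme_id != "SBS96")
    stop("class percentages are defined for SBS96 catalogues")
  totals <- rowSums(catalog$counts)
  if (any(totals == 0))
    stop("sample(s) with no classified mutations: ",
         paste(catalog$sample_ids[totals == 0], collapse = ", "))
  cls <- sbs_class_of(colnames(catalog$counts))
  class_counts <- t(rowsum(t(catalog$counts), cls))  # samples x 6
  class_counts <- class_counts[, SBS_CLASSES, drop = FALSE]
  pct <- sweep(class_counts, 1, totals, "/") * 100
  structure(list(
    sample_ids = catalog$sample_ids,
    class_labels = SBS_CLASSES,
    percentages = pct,
    mean = colMeans(pct),
    sd = apply(pct, 2, stats::sd)
  ), class = "class_summary")
}

#' One-way ANOVA across substitution classes
#'
#' Tests whether the six class percentages differ, with clones as
#' replicates (one observation per sample per class), followed by Tukey's
#' HSD over all 15 class pairs.
#'
#' @param summary A `class_summary` from [class_percentages()], built from
#'   >= 2 samples.
#' @return A list with `f_statistic`, `p_value`, `tukey` (data frame:
#'   pair, diff, p_adj) and the underlying `aov` fit.
#' @export
class_anova <- function(summary) {
  stopifnot(inherits(summary, "class_summary"))
  if (length(summary$sample_ids) < 2)
    stop("ANOVA needs at least 2 samples")
  df <- data.frame(
    pct = as.vector(summary$percentages),
    class = factor(rep(summary$class_labels,
                       each = length(summary$sample_ids)),
                   levels = summary$class_labels)
  )
  fit <- stats::aov(pct ~ class, data = df)
  tab <- summary(fit)[[1]]
  f <- tab["class", "F value"]
  p <- tab["class", "Pr(>F)"]
  ss_class <- tab["class", "Sum Sq"]
  if (ss_class < 1e-12) {          # no between-class variation at all
    f <- 0; p <- 1
  } else if (!is.finite(f) || p == 0) {
    # zero residual variance: p is below the representable threshold
    f <- Inf
    p <- .Machine$double.xmin
  }
  tk <- stats::TukeyHSD(fit)$class
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(f_statistic = unname(f), p_value = unname(p), tukey = tukey, fit = fit)
}

#' Write / read a mutation catalogue as TSV
#'
#' The exported orientation is channels as rows (canonical order) and
#' samples as columns, header `Type<TAB>sample...`. On read, a transposed
#' file (samples as rows) is auto-detected from the label column.
#'
#' @param catalog A `mutation_catalog`.
#' @param path TSV path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog`
#'   returns a `mutation_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(Type = colnames(catalog$counts), t(catalog$counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  first <- as.character(df[[1]])
  scheme_of <- function(labs) {
    for (s in c("SBS96", "DBS78", "ID"))
      if (all(labs %in% channel_scheme(s)$labels)) return(s)
    NULL
  }
  scheme <- scheme_of(first)
  if (!is.null(scheme)) {         # channels as rows
    counts <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(counts) <- first
  } else {                        # transposed orientation: samples as rows
    scheme <- scheme_of(colnames(df)[-1])
    if (is.null(scheme)) stop("cannot recognise channel labels in ", path)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- first
  }
  labels <- channel_scheme(scheme)$labels
  if (!setequal(colnames(counts), labels))
    stop("incomplete channel set in ", path)
  counts <- counts[, labels, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(scheme_id = scheme, sample_ids = rownames(counts),
                 counts = counts,
                 skipped = stats::setNames(integer(nrow(counts)),
                                           rownames(counts))),
            class = "mutation_catalog")
}
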