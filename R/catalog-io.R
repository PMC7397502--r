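#' Read a signature catalogue from TSV
#'
#' Expects a header line `Type<TAB>sig1<TAB>sig2...`, one row per channel
#' label and one column per signature. The channel scheme (SBS96, DBS78 or
#' ID) is recognised from the label set; labels must match the canonical
#' set exactly (any unknown, missing or duplicated label is fatal). Rows
#' are reordered to canonical channel order and each signature column is
#' renormalised to sum to one.
#'
#' @param path Path to the TSV file.
#' @return A `signature_catalog`: list with `scheme_id`, `channel_labels`
#'   and `signatures` (numeric matrix, channels x signatures).
#' @export
read_signature_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("catalogue needs a label column plus >=1 signature column")
  labels <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric signature entries in ", path)
  if (any(mat < 0)) stop("negative signature entry in ", path)
  if (anyDuplicated(labels))
    stop("duplicated channel label: ", labels[duplicated(labels)][1])

  scheme <- NULL
  for (s in c("SBS96", "DBS78", "ID")) {
    canon <- channel_scheme(s)$labels
    if (all(labels %in% canon)) { scheme <- s; break }
  }
  if (is.null(scheme))
    stop("unknown channel label(s): ",
         paste(utils::head(setdiff(labels, c(sbs96_labels(), dbs78_labels(),
                                             id83_labels())), 3),
               collapse = ", "))
  canon <- channel_scheme(scheme)$labels
  missing <- setdiff(canon, labels)
  if (length(missing))
    stop("missing channel(s) for scheme ", scheme, ": ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ..." else "")
  mat <- mat[match(canon, labels), , drop = FALSE]
  rownames(mat) <- canon
  sums <- colSums(mat)
  if (any(sums <= 0)) stop("all-zero signature column: ",
                           colnames(mat)[sums <= 0][1])
  mat <- sweep(mat, 2, sums, "/")
  structure(list(scheme_id = scheme, channel_labels = canon, signatures = mat),
            class = "signature_catalog")
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("<signature_catalog %s: %d signature(s)>\n",
              x$scheme_id, ncol(x$signatures)))
  invisible(x)
}

#' Build a signature catalogue in memory
#'
#' @param scheme_id Channel scheme id.
#' @param signatures Numeric matrix (channels x signatures) with column
#'   names; rows must follow canonical channel order.
#' @return A `signature_catalog`.
#' @export
signature_catalog <- function(scheme_id, signatures) {
  canon <- channel_scheme(scheme_id)$labels
  stopifnot(nrow(signatures) == length(canon), !is.null(colnames(signatures)),
            all(signatures >= 0))
  rownames(signatures) <- canon
  signatures <- sweep(signatures, 2, colSums(signatures), "/")
  structure(list(scheme_id = scheme_id, channel_labels = canon,
                 signatures = signatures),
            class = "signature_catalog")
}

#' Write a signature catalogue (or single profile) to TSV
#'
#' @param catalog A `signature_catalog` or `signature_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature_catalog <- function(catalog, path) {
  if (inherits(catalog, "signature_profile")) {
    mat <- matrix(catalog$weights, ncol = 1,
                  dimnames = list(names(catalog$weights), catalog$name))
    catalog <- signature_catalog(catalog$scheme_id, mat)
  }
  df <- data.frame(Type = catalog$channel_labels,
                   catalog$signatures, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED (plus optional expression TSV)
#'
#' The BED file is 0-based half-open with a name field (BED4). Intervals
#' sharing a name are merged when overlapping; the footprint is the total
#' merged length. Expression values are attached by gene name from a
#' two-column TSV (`gene<TAB>value`); genes without a value get `NA`, and
#' expression rows naming unknown genes produce a warning.
#'
#' @param bed_path Path to the BED4 file.
#' @param expression_path Optional path to the expression TSV.
#' @return A `gene_models` object: list with `granges` (1-based GRanges,
#'   one range per merged interval, `name` metadata column) and `table`
#'   (data.frame: name, footprint_bp, expression).
#' @export
read_gene_models <- function(bed_path, expression_path = NULL) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("contig", "start", "end", "name"),
                           colClasses = c("character", "integer", "integer",
                                          "character"))
  if (any(bed$end <= bed$start))
    stop("BED interval with end <= start for gene ",
         bed$name[bed$end <= bed$start][1])
  gr <- GenomicRanges::GRanges(bed$contig,
                               IRanges::IRanges(bed$start + 1L, bed$end))
  gr$name <- bed$name
  gene_models_from_granges(gr, expression_path)
}

#' Build gene models from a GRanges object
#'
#' Programmatic counterpart of [read_gene_models()]: intervals sharing a
#' `name` are merged, footprints computed, and expression attached either
#' from a TSV path or a named numeric vector.
#'
#' @param gr A `GRanges` (1-based) with a `name` metadata column.
#' @param expression_path Optional expression TSV path.
#' @param expression Optional named numeric vector of expression values.
#' @return A `gene_models` object.
#' @export
gene_models_from_granges <- function(gr, expression_path = NULL,
                                     expression = NULL) {
  merged <- unlist(GenomicRanges::reduce(GenomicRanges::split(gr, gr$name)))
  merged$name <- names(merged)
  names(merged) <- NULL
  fp <- tapply(GenomicRanges::width(merged), merged$name, sum)
  tab <- data.frame(name = names(fp), footprint_bp = as.integer(fp),
                    expression = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(expression_path)) {
    expr <- tryCatch(
      utils::read.table(expression_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE),
      error = function(e) data.frame(gene = character(0), value = numeric(0)))
    if (nrow(expr)) {
      unknown <- setdiff(expr[[1]], tab$name)
      if (length(unknown))
        warning("expression value(s) for unknown gene(s): ",
                paste(utils::head(unknown, 3), collapse = ", "))
      m <- match(tab$name, expr[[1]])
      tab$expression <- as.numeric(expr[[2]])[m]
    }
  } else if (!is.null(expression)) {
    tab$expression <- as.numeric(expression[tab$name])
  }
  structure(list(granges = merged, table = tab), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models: %d gene(s), %d bp total footprint>\n",
              nrow(x$table), sum(x$table$footprint_bp)))
  invisible(x)
}

#' Write gene models to BED4 (and expression to TSV)
#' @param genes A `gene_models` object.
#' @param bed_path Output BED path.
#' @param expression_path Optional output TSV path for expression values.
#' @return Invisibly, `bed_path`.
#' @export
write_gene_models <- function(genes, bed_path, expression_path = NULL) {
  gr <- genes$granges
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
                   gr$name)
  utils::write.table(df, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(expression_path)) {
    keep <- !is.na(genes$table$expression)
    utils::write.table(
      data.frame(gene = genes$table$name[keep],
                 value = genes$table$expression[keep]),
      expression_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_path)
}
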