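#' Count mutations falling in gene footprints
#'
#' A mutation counts for a gene iff the 1-based position of its first
#' altered reference base lies inside any of the gene's merged intervals;
#' a mutation inside two overlapping genes counts for both. For indels the
#' first altered base is the base after the VCF anchor.
#'
#' @param records A `mutation_records` data frame.
#' @param genes A `gene_models` object.
#' @return Named integer vector of observed counts, one per gene.
#' @export
count_gene_mutations <- function(records, genes) {
  pos <- records$pos + ifelse(records$kind %in% c("INS", "DEL"), 1L, 0L)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(records$contig, IRanges::IRanges(pos, pos)),
    genes$granges)
  hit_names <- genes$granges$name[S4Vectors::subjectHits(hits)]
  tab <- table(factor(hit_names, levels = genes$table$name))
  stats::setNames(as.integer(tab), genes$table$name)
}

#' Gene-level overmutation / protection test
#'
#' Under a null of uniform random placement over an effective genome, the
#' expected mutation count for a gene is
#' `lambda = total_mutations * footprint_bp / effective_genome_bp`.
#' Upper- (`p_over = P(X >= obs)`) and lower-tail (`p_under = P(X <= obs)`)
#' probabilities are computed with `X ~ Poisson(lambda)` (default) or
#' `X ~ Binomial(total, footprint/genome)` (`model = "binomial"`).
#'
#' @param observed Integer vector of observed per-gene counts (named).
#' @param total_mutations Total mutations placed on the genome.
#' @param footprint_bp Integer vector of gene footprints (bp).
#' @param effective_genome_bp Effective genome length (bp).
#' @param model `"poisson"` (default) or `"binomial"`.
#' @return Data frame with columns gene, observed, expected, p_over,
#'   p_under (no multiplicity adjustment; see [call_enrichment()]).
#' @export
gene_enrichment_test <- function(observed, total_mutations, footprint_bp,
                                 effective_genome_bp,
                                 model = c("poisson", "binomial")) {
  model <- match.arg(model)
  stopifnot(all(observed >= 0), all(observed <= total_mutations),
            all(footprint_bp > 0))
  if (any(footprint_bp > effective_genome_bp))
    stop("gene footprint exceeds effective genome length")
  lambda <- total_mutations * footprint_bp / effective_genome_bp
  if (model == "poisson") {
    p_over <- stats::ppois(observed - 1, lambda, lower.tail = FALSE)
    p_under <- stats::ppois(observed, lambda)
  } else {
    pr <- footprint_bp / effective_genome_bp
    p_over <- stats::pbinom(observed - 1, total_mutations, pr,
                            lower.tail = FALSE)
    p_under <- stats::pbinom(observed, total_mutations, pr)
  }
  data.frame(
    gene = if (!is.null(names(observed))) names(observed) else
      paste0("gene", seq_along(observed)),
    observed = as.integer(observed),
    expected = lambda,
    p_over = p_over,
    p_under = p_under,
    stringsAsFactors = FALSE
  )
}

#' Context-adjusted footprints for the enrichment null
#'
#' The default null places mutations uniformly per base pair. When the
#' mutational process has strong sequence-context preferences (e.g. C>A
#' concentrated at particular trinucleotides), a gene rich in favoured
#' contexts is expected to collect more mutations than its raw footprint
#' suggests. This helper reweights each gene's footprint by the SBS96
#' signature: every genomic position contributes the total signature
#' weight of its (strand-collapsed) trinucleotide context. The returned
#' weights can be passed to [gene_enrichment_test()] as `footprint_bp`
#' together with `genome_weight` as `effective_genome_bp`, since only the
#' ratio enters the expected count.
#'
#' @param genome A `reference_genome`.
#' @param genes A `gene_models` object.
#' @param profile An SBS96 `signature_profile` describing the process.
#' @return List with `gene_weight` (named numeric) and `genome_weight`.
#' @export
context_weighted_footprint <- function(genome, genes, profile) {
  stopifnot(inherits(profile, "signature_profile"),
            profile$scheme_id == "SBS96")
  labs <- sbs96_labels()
  # per-trinucleotide weight: sum of the three channels centred on it,
  # plus the three centred on its reverse complement
  tri_of <- paste0(substr(labs, 1, 1), substr(labs, 3, 3), substr(labs, 7, 7))
  w_pyr <- tapply(profile$weights, tri_of, sum)
  tri_weight <- function(tri) {
    out <- numeric(length(tri))
    hit <- tri %in% names(w_pyr)
    out[hit] <- w_pyr[tri[hit]]
    rc <- revcomp_chr(tri[!hit])
    ok <- rc %in% names(w_pyr)
    out[!hit][ok] <- w_pyr[rc[ok]]
    out
  }
  genome_weight <- 0
  gene_weight <- stats::setNames(numeric(nrow(genes$table)),
                                 genes$table$name)
  for (ctg in names(genome$contigs)) {
    s <- genome$contigs[[ctg]]
    L <- nchar(s)
    if (L < 3) next
    ch <- strsplit(s, "")[[1]]
    tris <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
    wpos <- c(0, tri_weight(tris), 0)   # centre positions 2..L-1
    genome_weight <- genome_weight + sum(wpos)
    gr <- genes$granges
    on_ctg <- as.character(GenomicRanges::seqnames(gr)) == ctg
    cum <- cumsum(wpos)
    for (i in which(on_ctg)) {
      a <- GenomicRanges::start(gr)[i]; b <- GenomicRanges::end(gr)[i]
      nm <- gr$name[i]
      gene_weight[nm] <- gene_weight[nm] + cum[min(b, L)] -
        (if (a > 1) cum[a - 1] else 0)
    }
  }
  list(gene_weight = gene_weight, genome_weight = genome_weight)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")`, kept as a named step so
#' the multiplicity control used for the over/under calls is explicit.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Call genes overmutated / protected / consistent
#'
#' Over- and under-mutation are treated as two separate one-sided
#' families, each FDR-controlled at `alpha`: q_over and q_under are BH
#' adjustments of p_over and p_under across genes.
#'
#' @param enrichment Data frame from [gene_enrichment_test()].
#' @param alpha FDR level (default 0.05).
#' @return The data frame with q_over, q_under and call columns added.
#' @export
call_enrichment <- function(enrichment, alpha = 0.05) {
  enrichment$q_over <- fdr_adjust(enrichment$p_over)
  enrichment$q_under <- fdr_adjust(enrichment$p_under)
  enrichment$call <- ifelse(enrichment$q_over < alpha, "overmutated",
                            ifelse(enrichment$q_under < alpha, "protected",
                                   "consistent"))
  enrichment
}

#' Mutation rate versus gene expression regression
#'
#' Genes with expression values are ranked by expression and split into
#' `n_bins` equal-size bins; each bin's mutation rate is the number of
#' mutations in the bin's footprints divided by the bin footprint in Mb.
#' Ordinary least squares then regresses bin rate on the bin's expression
#' midrank (default), mean expression, or mean log-expression.
#'
#' @param records A `mutation_records` data frame.
#' @param genes A `gene_models` object with expression values.
#' @param n_bins Number of expression bins (>= 3; default 10, deciles).
#' @param x_mode Regressor: `"midrank"`, `"mean_expression"` or
#'   `"mean_log_expression"`.
#' @return A `rate_regression`: list with `bins` (data frame: bin, x,
#'   n_genes, footprint_mb, mutations, rate_per_mb), `slope`, `intercept`,
#'   `p_value`, `r_squared` and the `lm` fit.
#' @export
expression_rate_regression <- function(records, genes, n_bins = 10,
                                       x_mode = c("midrank",
                                                  "mean_expression",
                                                  "mean_log_expression")) {
  x_mode <- match.arg(x_mode)
  if (n_bins < 3) stop("need at least 3 bins")
  tab <- genes$table[!is.na(genes$table$expression), , drop = FALSE]
  if (nrow(tab) < n_bins)
    stop("fewer genes with expression (", nrow(tab), ") than bins (", n_bins, ")")
  per_gene <- count_gene_mutations(records, genes)[tab$name]
  ord <- order(tab$expression, tab$name)  # name breaks expression ties
  tab <- tab[ord, , drop = FALSE]
  per_gene <- per_gene[ord]
  bin <- ceiling(seq_len(nrow(tab)) * n_bins / nrow(tab))
  fp_mb <- tapply(tab$footprint_bp, bin, sum) / 1e6
  if (any(fp_mb == 0)) stop("empty bin footprint")
  muts <- tapply(per_gene, bin, sum)
  x <- switch(x_mode,
    midrank = tapply(seq_len(nrow(tab)), bin, mean),
    mean_expression = tapply(tab$expression, bin, mean),
    mean_log_expression = tapply(log1p(tab$expression), bin, mean))
  bins <- data.frame(bin = as.integer(names(fp_mb)), x = as.numeric(x),
                     n_genes = as.integer(table(bin)),
                     footprint_mb = as.numeric(fp_mb),
                     mutations = as.integer(muts),
                     rate_per_mb = as.numeric(muts / fp_mb))
  fit <- stats::lm(rate_per_mb ~ x, data = bins)
  sm <- suppressWarnings(summary(fit))  # perfect fits are handled below
  r2 <- sm$r.squared
  p <- sm$coefficients["x", "Pr(>|t|)"]
  slope <- unname(stats::coef(fit)[2])
  # constant response: no explainable variance, nothing to reject
  y <- bins$rate_per_mb
  if (!is.finite(r2) || sum((y - mean(y))^2) <= 1e-9 * (1 + mean(y)^2)) {
    r2 <- 0; p <- 1; slope <- 0
  }
  if (!is.finite(p)) p <- 1
  structure(list(
    bins = bins,
    slope = slope,
    slope_se = sm$coefficients["x", "Std. Error"],
    intercept = unname(stats::coef(fit)[1]),
    p_value = p,
    r_squared = r2,
    x_mode = x_mode,
    fit = fit
  ), class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf(
    "<rate_regression (%d bins, x = %s): slope %.4g/Mb per unit, p = %.3g, R2 = %.3f>\n",
    nrow(x$bins), x$x_mode, x$slope, x$p_value, x$r_squared))
  invisible(x)
}
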