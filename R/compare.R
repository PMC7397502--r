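#' Cosine similarity between two non-negative profile vectors
#'
#' `dot(a, b) / (||a|| * ||b||)`, clamped to [0, 1] for non-negative
#' input (floating-point round-off can push the raw value marginally
#' outside). Scale-invariant and symmetric.
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return A scalar in [0, 1].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector in cosine similarity")
  min(max(sum(a * b) / (na * nb), 0), 1)
}

#' Rank catalogue signatures by cosine similarity to a query profile
#'
#' @param profile A `signature_profile`.
#' @param catalog A `signature_catalog` on the same scheme.
#' @return A `similarity_report`: list with `query`, `scheme_id` and
#'   `ranking` (data frame: rank, signature, cosine), sorted
#'   non-increasing with ties preserving catalogue column order.
#' @export
rank_matches <- function(profile, catalog) {
  stopifnot(inherits(profile, "signature_profile"),
            inherits(catalog, "signature_catalog"))
  if (profile$scheme_id != catalog$scheme_id)
    stop("profile scheme ", profile$scheme_id,
         " does not match catalogue scheme ", catalog$scheme_id)
  scores <- apply(catalog$signatures, 2, cosine_similarity, a = profile$weights)
  ord <- order(-scores)  # stable: ties keep catalogue order
  structure(list(
    query = profile$name,
    scheme_id = profile$scheme_id,
    ranking = data.frame(rank = seq_along(ord),
                         signature = colnames(catalog$signatures)[ord],
                         cosine = unname(scores[ord]))
  ), class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("<similarity_report for '%s' (%s)>\n", x$query, x$scheme_id))
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Refit a profile as a non-negative combination of catalogue signatures
#'
#' Solves the non-negative least-squares problem
#' `min ||query - S w||_2, w >= 0` over the catalogue matrix `S`
#' (active-set NNLS via [pracma::lsqnonneg()]), and reports the residual
#' norm and the cosine between the query and its reconstruction.
#'
#' @param profile A `signature_profile`.
#' @param catalog A `signature_catalog` on the same scheme.
#' @param subset Optional character vector restricting the catalogue to
#'   named signatures.
#' @return An `exposure_fit`: list with `query`, `exposures` (named
#'   non-negative weights), `residual_norm` and `reconstruction_cosine`.
#' @export
fit_exposures <- function(profile, catalog, subset = NULL) {
  stopifnot(inherits(profile, "signature_profile"),
            inherits(catalog, "signature_catalog"))
  if (profile$scheme_id != catalog$scheme_id)
    stop("profile and catalogue schemes differ")
  S <- catalog$signatures
  if (!is.null(subset)) {
    missing <- setdiff(subset, colnames(S))
    if (length(missing)) stop("signature(s) not in catalogue: ",
                              paste(missing, collapse = ", "))
    S <- S[, subset, drop = FALSE]
  }
  if (any(colSums(S) == 0)) stop("degenerate (all-zero) catalogue signature")
  fit <- pracma::lsqnonneg(S, as.numeric(profile$weights))
  w <- stats::setNames(fit$x, colnames(S))
  recon <- as.numeric(S %*% w)
  rc <- if (sum(recon) > 0) cosine_similarity(profile$weights, recon) else NA_real_
  structure(list(query = profile$name, exposures = w,
                 residual_norm = sqrt(sum((profile$weights - recon)^2)),
                 reconstruction_cosine = rc),
            class = "exposure_fit")
}

#' @export
print.exposure_fit <- function(x, ...) {
  nz <- x$exposures[x$exposures > 1e-8]
  cat(sprintf("<exposure_fit for '%s': %d active signature(s), residual %.4g>\n",
              x$query, length(nz), x$residual_norm))
  print(round(sort(nz, decreasing = TRUE), 4))
  invisible(x)
}

#' Export a similarity report or exposure fit
#'
#' Reports go to TSV (rank, signature, cosine); fits to JSON (exposures,
#' residual norm, reconstruction cosine).
#'
#' @param x A `similarity_report` or `exposure_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_report <- function(x, path) {
  if (inherits(x, "similarity_report")) {
    utils::write.table(x$ranking, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "exposure_fit")) {
    jsonlite::write_json(
      list(query = x$query, exposures = as.list(x$exposures),
           residual_norm = x$residual_norm,
           reconstruction_cosine = x$reconstruction_cosine),
      path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported report type")
  invisible(path)
}
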