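#' Derive an exposure signature by control normalisation
#'
#' Estimates the mutational profile attributable to an exposure by
#' subtracting the control clones' channel counts from the exposed
#' clones': in the default `"mean-subtract"` mode the per-channel mean
#' count across exposed clones minus the per-channel mean across control
#' clones, with negative excesses floored at zero and the result
#' renormalised to sum to one. `"pooled"` mode pools counts within each
#' group (scaled to a common per-clone basis by dividing by the group
#' size) before subtracting; with equal weighting per clone the two agree,
#' so the pooled variant is kept as a sensitivity check. An optional
#' pseudocount (default 0) can be added to every channel of both groups
#' before subtraction.
#'
#' @param exposed,control `mutation_catalog` objects on the same scheme.
#' @param mode `"mean-subtract"` (default) or `"pooled"`.
#' @param pseudocount Non-negative count added to each channel mean.
#' @param name Name recorded on the resulting profile.
#' @return A `signature_profile`: list with `scheme_id`, `name`, `weights`
#'   (named, non-negative, sums to 1), `support` (rounded total positive
#'   excess) and `provenance` (derivation parameters).
#' @export
derive_exposure_signature <- function(exposed, control,
                                      mode = c("mean-subtract", "pooled"),
                                      pseudocount = 0, name = "exposure") {
  mode <- match.arg(mode)
  stopifnot(inherits(exposed, "mutation_catalog"),
            inherits(control, "mutation_catalog"))
  if (exposed$scheme_id != control$scheme_id)
    stop("exposed and control catalogues are on different schemes")
  if (nrow(exposed$counts) < 1 || nrow(control$counts) < 1)
    stop("need at least one sample per group")
  if (mode == "mean-subtract") {
    exp_mean <- colMeans(exposed$counts)
    ctl_mean <- colMeans(control$counts)
  } else {
    exp_mean <- colSums(exposed$counts) / nrow(exposed$counts)
    ctl_mean <- colSums(control$counts) / nrow(control$counts)
  }
  excess <- pmax((exp_mean + pseudocount) - (ctl_mean + pseudocount), 0)
  total <- sum(excess)
  if (total <= 0)
    stop("no exposure-attributable excess: exposed counts do not exceed controls")
  signature_profile(exposed$scheme_id, excess / total, name = name,
                    support = round(total),
                    provenance = list(mode = mode, pseudocount = pseudocount,
                                      n_exposed = nrow(exposed$counts),
                                      n_control = nrow(control$counts)))
}

#' Construct a signature profile
#'
#' @param scheme_id Channel scheme id.
#' @param weights Non-negative numeric vector over the scheme's channels
#'   (canonical order; names optional, set from the scheme).
#' @param name Profile name.
#' @param support Number of contributing mutations (optional).
#' @param provenance List of derivation parameters (optional).
#' @return A `signature_profile` with weights renormalised to sum to 1.
#' @export
signature_profile <- function(scheme_id, weights, name = "profile",
                              support = NA_real_, provenance = list()) {
  scheme <- channel_scheme(scheme_id)
  if (length(weights) != scheme$size)
    stop("expected ", scheme$size, " weights for ", scheme_id,
         ", got ", length(weights))
  if (any(weights < 0)) stop("negative signature weight")
  s <- sum(weights)
  if (s <= 0) stop("all-zero signature")
  structure(list(scheme_id = scheme_id, name = name,
                 weights = stats::setNames(as.numeric(weights) / s,
                                           scheme$labels),
                 support = support, provenance = provenance),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  top <- sort(x$weights, decreasing = TRUE)[1:3]
  cat(sprintf("<signature_profile '%s' (%s); top channels: %s>\n",
              x$name, x$scheme_id,
              paste(sprintf("%s %.1f%%", names(top), 100 * top),
                    collapse = ", ")))
  invisible(x)
}

#' Express a signature profile in percent
#'
#' @param profile A `signature_profile`.
#' @return Named numeric vector summing to 100.
#' @export
profile_percentages <- function(profile) {
  stopifnot(inherits(profile, "signature_profile"))
  profile$weights * 100
}
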