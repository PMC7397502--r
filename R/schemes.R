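#' Channel schemes for mutational signature analysis
#'
#' A channel scheme is a fixed, ordered set of mutation-type labels over
#' which catalogues and signatures are defined. Three schemes are provided:
#'
#' * `SBS96`: single-base substitutions, 6 pyrimidine-centred substitution
#'   classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 16 possible
#'   5'/3' flanking-base pairs; labels have the form `"A[C>A]G"`.
#' * `DBS78`: doublet-base substitutions, strand-agnostic, collapsed onto
#'   10 canonical reference doublets; labels have the form `"CC>AA"`.
#' * `ID`: the 83-channel small insertion/deletion scheme: 1-bp events by
#'   pyrimidine-collapsed base (C or T) and homopolymer run length, longer
#'   events by length and repeat-unit count, with microhomology
#'   sub-classification for deletions at non-repetitive sites.
#'
#' Label order is canonical and normative: catalogue matrices, signature
#' vectors and exported TSVs all follow it bit-exactly. The same tables are
#' shipped as TSV fixtures under `inst/extdata/`.
#'
#' @param scheme_id One of `"SBS96"`, `"DBS78"`, `"ID"`.
#' @return `channel_scheme()` returns an object of class `channel_scheme`
#'   with fields `scheme_id`, `labels` and `size`.
#' @examples
#' channel_scheme("SBS96")$size  # 96
#' @export
channel_scheme <- function(scheme_id = c("SBS96", "DBS78", "ID")) {
  scheme_id <- match.arg(scheme_id)
  labels <- switch(scheme_id,
    SBS96 = sbs96_labels(),
    DBS78 = dbs78_labels(),
    ID    = id83_labels()
  )
  structure(
    list(scheme_id = scheme_id, labels = labels, size = length(labels)),
    class = "channel_scheme"
  )
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("<channel_scheme %s: %d channels>\n", x$scheme_id, x$size))
  invisible(x)
}

BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' @rdname channel_scheme
#' @export
sbs96_labels <- function() {
  # COSMIC order: grouped by substitution class, then 5' flank, then 3' flank
  unlist(lapply(SBS_CLASSES, function(cls) {
    as.vector(t(outer(BASES, BASES, function(p5, p3)
      paste0(p5, "[", cls, "]", p3))))
  }))
}

# The 10 canonical reference doublets; AT, CG, GC, TA are their own
# reverse complements, so their alt doublets also collapse.
DBS_CANONICAL_REF <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")

#' @rdname channel_scheme
#' @export
dbs78_labels <- function() {
  # COSMIC DBS78 order. For palindromic refs the canonical alt of each
  # {alt, revcomp(alt)} pair is fixed by this table, which is normative.
  c(
    "AC>CA", "AC>CG", "AC>CT", "AC>GA", "AC>GG", "AC>GT", "AC>TA", "AC>TG", "AC>TT",
    "AT>CA", "AT>CC", "AT>CG", "AT>GA", "AT>GC", "AT>TA",
    "CC>AA", "CC>AG", "CC>AT", "CC>GA", "CC>GG", "CC>GT", "CC>TA", "CC>TG", "CC>TT",
    "CG>AT", "CG>GC", "CG>GT", "CG>TA", "CG>TC", "CG>TT",
    "CT>AA", "CT>AC", "CT>AG", "CT>GA", "CT>GC", "CT>GG", "CT>TA", "CT>TC", "CT>TG",
    "GC>AA", "GC>AG", "GC>AT", "GC>CA", "GC>CG", "GC>TA",
    "TA>AT", "TA>CG", "TA>CT", "TA>GC", "TA>GG", "TA>GT",
    "TC>AA", "TC>AG", "TC>AT", "TC>CA", "TC>CG", "TC>CT", "TC>GA", "TC>GG", "TC>GT",
    "TG>AA", "TG>AC", "TG>AT", "TG>CA", "TG>CC", "TG>CT", "TG>GA", "TG>GC", "TG>GT",
    "TT>AA", "TT>AC", "TT>AG", "TT>CA", "TT>CC", "TT>CG", "TT>GA", "TT>GC", "TT>GG"
  )
}

#' @rdname channel_scheme
#' @export
id83_labels <- function() {
  c(
    # 1-bp deletions: homopolymer run length includes the deleted base
    paste0("DEL.C.1.", c(1:5, "6+")),
    paste0("DEL.T.1.", c(1:5, "6+")),
    # 1-bp insertions: run length of reference bases matching the inserted base
    paste0("INS.C.1.", c(0:4, "5+")),
    paste0("INS.T.1.", c(0:4, "5+")),
    # >=2 bp deletions at repeats: repeat-unit count includes the deleted copy
    unlist(lapply(c(2:4, "5+"), function(L) paste0("DEL.R.", L, ".", c(1:5, "6+")))),
    # >=2 bp insertions at repeats: count of pre-existing copies in the reference
    unlist(lapply(c(2:4, "5+"), function(L) paste0("INS.R.", L, ".", c(0:4, "5+")))),
    # deletions at non-repetitive sites with flanking microhomology
    "DEL.MH.2.1",
    paste0("DEL.MH.3.", 1:2),
    paste0("DEL.MH.4.", 1:3),
    paste0("DEL.MH.5+.", c(1:4, "5+"))
  )
}

#' Reverse complement of character vectors of DNA strings
#'
#' @param x Character vector over the alphabet A, C, G, T, N.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract the central substitution class from SBS96 labels
#' @param labels Character vector of SBS96 labels such as "A[C>A]G".
#' @return Character vector of classes such as "C>A".
#' @export
sbs_class_of <- function(labels) {
  sub("^.\\[(.>.)\\].$", "\\1", labels)
}

#' Write the canonical channel tables as TSV fixtures
#'
#' Used to (re)generate the tables under `inst/extdata/`; they are shipped
#' with the package and a unit test pins the code to the shipped files.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @keywords internal
write_scheme_fixtures <- function(dir) {
  paths <- vapply(c("SBS96", "DBS78", "ID"), function(s) {
    p <- file.path(dir, paste0("scheme_", s, ".tsv"))
    utils::write.table(
      data.frame(index = seq_along(channel_scheme(s)$labels),
                 label = channel_scheme(s)$labels),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
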