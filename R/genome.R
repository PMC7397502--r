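#' Reference genomes and sequence context
#'
#' A `reference_genome` holds contig sequences as uppercase character
#' strings over the alphabet {A,C,G,T,N}. Sequences are stored in memory
#' (the intended scale is simulated or subset genomes, not a full human
#' reference); FASTA I/O goes through Biostrings.
#'
#' @name reference_genome
NULL

new_reference_genome <- function(contigs) {
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    offending <- regmatches(contigs[bad][1],
                            regexpr("[^ACGTN]", contigs[bad][1]))
    stop("reference contains non-ACGTN character '", offending,
         "' in contig ", names(contigs)[bad][1])
  }
  structure(
    list(contigs = contigs, lengths = nchar(contigs)),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome: %d contig(s), %d bp total>\n",
              length(x$contigs), sum(x$lengths)))
  invisible(x)
}

#' Load a reference genome from FASTA
#'
#' Sequences are case-folded to uppercase; any character outside
#' {A,C,G,T,N} (including IUPAC ambiguity codes) is an error.
#'
#' @param path Path to a FASTA file.
#' @return A `reference_genome`.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  contigs <- toupper(as.character(seqs))
  # keep only the first word of each FASTA header, as aligners do
  names(contigs) <- sub("\\s.*$", "", names(seqs))
  new_reference_genome(contigs)
}

#' Construct a reference genome from in-memory sequences
#'
#' @param contigs Named character vector of contig sequences.
#' @return A `reference_genome`.
#' @export
reference_from_strings <- function(contigs) {
  new_reference_genome(toupper(contigs))
}

#' Write a reference genome to FASTA
#'
#' @param genome A `reference_genome`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), path,
                              width = 70L)
  invisible(path)
}

#' Sequence context around genomic positions
#'
#' Returns the (2*flank+1)-mer centred on each position; positions whose
#' window extends past a contig end are padded with `N`. `contig`, `pos`
#' may be vectors (recycled against each other).
#'
#' @param genome A `reference_genome`.
#' @param contig Contig name(s).
#' @param pos 1-based position(s) of the central base.
#' @param flank Number of flanking bases on each side (>= 0).
#' @return Character vector of context strings.
#' @export
context <- function(genome, contig, pos, flank = 1L) {
  stopifnot(flank >= 0)
  n <- max(length(contig), length(pos))
  contig <- rep_len(contig, n)
  pos <- rep_len(as.integer(pos), n)
  unknown <- setdiff(unique(contig), names(genome$contigs))
  if (length(unknown)) stop("unknown contig(s): ", paste(unknown, collapse = ", "))
  len <- genome$lengths[contig]
  if (any(pos < 1L | pos > len)) {
    stop("position out of bounds on contig ",
         contig[which(pos < 1L | pos > len)[1]])
  }
  out <- character(n)
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    s <- genome$contigs[[ctg]]
    L <- nchar(s)
    start <- pos[i] - flank
    end <- pos[i] + flank
    core <- substring(s, pmax(start, 1L), pmin(end, L))
    left <- strrep("N", pmax(1L - start, 0L))
    right <- strrep("N", pmax(end - L, 0L))
    out[i] <- paste0(left, core, right)
  }
  out
}
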