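#' Somatic mutation records
#'
#' Mutations are held in an ordinary data frame with one row per event and
#' columns `sample_id`, `contig`, `pos` (1-based position of the first
#' reference base), `ref`, `alt` and `kind` (one of `SNV`, `DBS`, `INS`,
#' `DEL`). Indels follow the VCF anchor convention: ref and alt share a
#' single leading anchor base and exactly one of them has further bases.
#'
#' @param sample_id,contig,ref,alt Character vectors.
#' @param pos Integer vector, 1-based.
#' @param kind Optional; inferred from ref/alt when omitted.
#' @return A validated data frame of class `mutation_records`.
#' @export
mutation_records <- function(sample_id, contig, pos, ref, alt, kind = NULL) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    contig = as.character(contig),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    stringsAsFactors = FALSE
  )
  df$kind <- if (is.null(kind)) infer_kind(df$ref, df$alt) else as.character(kind)
  validate_mutation_records(df)
  class(df) <- c("mutation_records", "data.frame")
  df
}

#' Classify ref/alt pairs as SNV, DBS, INS, DEL or NA (unsupported)
#' @keywords internal
infer_kind <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  kind <- rep(NA_character_, length(ref))
  kind[nr == 1L & na == 1L & ref != alt] <- "SNV"
  kind[nr == 2L & na == 2L & ref != alt] <- "DBS"
  ins <- nr == 1L & na > 1L & substr(alt, 1L, 1L) == ref
  del <- na == 1L & nr > 1L & substr(ref, 1L, 1L) == alt
  kind[ins] <- "INS"
  kind[del] <- "DEL"
  kind
}

validate_mutation_records <- function(df) {
  with(df, {
    if (any(is.na(kind))) stop("unsupported ref/alt combination at row ",
                               which(is.na(kind))[1])
    snv <- kind == "SNV"
    if (any(snv & (nchar(ref) != 1L | nchar(alt) != 1L | ref == alt)))
      stop("invalid SNV record")
    dbs <- kind == "DBS"
    if (any(dbs & (nchar(ref) != 2L | nchar(alt) != 2L | ref == alt)))
      stop("invalid DBS record")
    indel <- kind %in% c("INS", "DEL")
    anchored <- substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &
      (nchar(ref) == 1L | nchar(alt) == 1L) & nchar(ref) != nchar(alt)
    if (any(indel & !anchored)) stop("indel record violates anchor convention")
  })
  invisible(df)
}

#' Read somatic mutations from a VCF file
#'
#' Parses a VCF v4.2 file into a `mutation_records` data frame. By default
#' only records whose FILTER is `PASS` or `.` are kept. Multi-allelic
#' records are split into one record per alternate allele. Records with
#' symbolic or breakend alleles, or substitutions longer than two bases,
#' are skipped with a warning and counted in the `skipped` attribute.
#' Length-2 substitutions that differ at only one position are demoted to
#' the underlying SNV.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param sample_id Sample label attached to every record.
#' @param genome Optional `reference_genome`; when supplied, indels are
#'   left-aligned against it (see [left_align_indels()]).
#' @param keep_all_filters Keep records regardless of FILTER status.
#' @return A `mutation_records` data frame with attribute `skipped`
#'   (named integer: filtered, symbolic, complex).
#' @export
read_vcf <- function(path, sample_id, genome = NULL, keep_all_filters = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  skipped <- c(filtered = 0L, symbolic = 0L, complex = 0L)
  if (nrow(fix) == 0) {
    out <- empty_records()
    attr(out, "skipped") <- skipped
    return(out)
  }
  filt_ok <- keep_all_filters | is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  skipped["filtered"] <- sum(!filt_ok)
  fix <- fix[filt_ok, , drop = FALSE]

  # split multi-allelic records
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  df <- data.frame(
    contig = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = toupper(fix$REF[idx]),
    alt = toupper(unlist(alts)),
    stringsAsFactors = FALSE
  )

  # symbolic (<DEL>), breakend (with [ or ]) and spanning (*) alleles
  symbolic <- grepl("[^ACGTN]", df$alt)
  skipped["symbolic"] <- sum(symbolic)
  if (any(symbolic)) warning(sum(symbolic), " symbolic/breakend allele(s) skipped")
  df <- df[!symbolic, , drop = FALSE]

  # demote length-2 substitutions differing at a single position to SNVs
  len2 <- nchar(df$ref) == 2L & nchar(df$alt) == 2L
  if (any(len2)) {
    d1 <- substr(df$ref, 1, 1) != substr(df$alt, 1, 1)
    d2 <- substr(df$ref, 2, 2) != substr(df$alt, 2, 2)
    only2 <- len2 & !d1 & d2
    only1 <- len2 & d1 & !d2
    df$pos[only2] <- df$pos[only2] + 1L
    df$ref[only2] <- substr(df$ref[only2], 2, 2)
    df$alt[only2] <- substr(df$alt[only2], 2, 2)
    df$ref[only1] <- substr(df$ref[only1], 1, 1)
    df$alt[only1] <- substr(df$alt[only1], 1, 1)
  }

  kind <- infer_kind(df$ref, df$alt)
  complex <- is.na(kind)
  skipped["complex"] <- sum(complex)
  if (any(complex)) warning(sum(complex), " complex/unsupported record(s) skipped")
  df <- df[!complex, , drop = FALSE]

  out <- mutation_records(sample_id, df$contig, df$pos, df$ref, df$alt)
  if (!is.null(genome)) out <- left_align_indels(out, genome)
  attr(out, "skipped") <- skipped
  out
}

empty_records <- function() {
  mutation_records(character(0), character(0), integer(0),
                   character(0), character(0))
}

#' Left-align indels against the reference
#'
#' Shifts each insertion/deletion maximally 5'-ward: while the base
#' immediately before the event equals the last base of the
#' inserted/deleted sequence, the event slides one base left. This gives
#' every indel in a repeat tract a canonical placement, which the
#' homopolymer-run classification relies on. SNV/DBS records pass through
#' unchanged.
#'
#' @param records A `mutation_records` data frame.
#' @param genome A `reference_genome`.
#' @return The records with indels left-aligned (anchor convention kept).
#' @export
left_align_indels <- function(records, genome) {
  idx <- which(records$kind %in% c("INS", "DEL"))
  for (i in idx) {
    ctg <- genome$contigs[[records$contig[i]]]
    if (is.null(ctg)) stop("unknown contig: ", records$contig[i])
    pos <- records$pos[i]
    if (records$kind[i] == "DEL") {
      seq <- substr(records$ref[i], 2L, nchar(records$ref[i]))
    } else {
      seq <- substr(records$alt[i], 2L, nchar(records$alt[i]))
    }
    k <- nchar(seq)
    # slide while base at anchor equals last base of the event sequence
    while (pos >= 1L && substr(ctg, pos, pos) == substr(seq, k, k)) {
      seq <- paste0(substr(ctg, pos, pos), substr(seq, 1L, k - 1L))
      pos <- pos - 1L
    }
    if (pos < 1L) { # ran off the contig start; keep original placement
      next
    }
    anchor <- substr(ctg, pos, pos)
    records$pos[i] <- pos
    if (records$kind[i] == "DEL") {
      records$ref[i] <- paste0(anchor, seq)
      records$alt[i] <- anchor
    } else {
      records$ref[i] <- anchor
      records$alt[i] <- paste0(anchor, seq)
    }
  }
  records
}

#' Write mutation records to a VCF v4.2 file
#'
#' Produces a minimal sites-only VCF (CHROM..INFO, FILTER = PASS) that
#' round-trips through [read_vcf()] field-for-field. Records are sorted by
#' contig (order of appearance in `genome` if given, else alphabetical)
#' and position.
#'
#' @param records A `mutation_records` data frame (single sample).
#' @param path Output path.
#' @param genome Optional `reference_genome` used for contig header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=exposig")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$contigs), genome$lengths))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ctg_levels <- if (!is.null(genome)) names(genome$contigs) else
    sort(unique(records$contig))
  ord <- order(match(records$contig, ctg_levels), records$pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  records$contig[ord], records$pos[ord],
                  records$ref[ord], records$alt[ord])
  writeLines(c(hdr, body), path)
  invisible(path)
}
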