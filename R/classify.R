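#' Classify mutations into signature channels
#'
#' Each somatic mutation is mapped to its canonical channel in one of the
#' three schemes. Single-base substitutions use the pyrimidine convention:
#' a mutation whose reference base is A or G is reported on the opposite
#' strand (ref/alt complemented, flanks reverse-complemented), so every
#' channel has a C or T centre. Doublet substitutions are collapsed onto
#' the 10 canonical reference doublets by reverse complementation. Indels
#' are classified by type, length and sequence context (homopolymer run,
#' repeat-unit count, microhomology); records must be left-aligned (see
#' [left_align_indels()]).
#'
#' Records touching an `N` base in the evaluated window are not assigned a
#' channel: they come back in the `skipped` component with a reason, and a
#' warning reports the count.
#'
#' @param records A `mutation_records` data frame.
#' @param genome A `reference_genome`.
#' @return A list with `classified` (the records plus `scheme_id`,
#'   `channel` and `channel_index` columns) and `skipped` (records that
#'   could not be classified, with a `reason` column).
#' @name classify
NULL

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

#' @rdname classify
#' @export
classify_sbs <- function(records, genome) {
  records <- records[records$kind == "SNV", , drop = FALSE]
  if (nrow(records) == 0) return(classified_empty(records, "SBS96"))
  tri <- context(genome, records$contig, records$pos, 1L)
  centre <- substr(tri, 2L, 2L)
  mism <- centre != records$ref & centre != "N"
  if (any(mism))
    stop("reference allele mismatch at ", records$contig[mism][1], ":",
         records$pos[mism][1], " (VCF says ", records$ref[mism][1],
         ", reference has ", centre[mism][1], ")")
  has_n <- grepl("N", tri, fixed = TRUE)

  pyr <- records$ref %in% c("C", "T")
  tri_use <- ifelse(pyr, tri, revcomp_chr(tri))
  ref_use <- ifelse(pyr, records$ref, comp_base(records$ref))
  alt_use <- ifelse(pyr, records$alt, comp_base(records$alt))
  channel <- paste0(substr(tri_use, 1L, 1L), "[", ref_use, ">", alt_use, "]",
                    substr(tri_use, 3L, 3L))
  finish_classification(records, channel, has_n, "SBS96",
                        reason = "N in trinucleotide")
}

#' @rdname classify
#' @export
classify_dbs <- function(records, genome = NULL) {
  records <- records[records$kind == "DBS", , drop = FALSE]
  if (nrow(records) == 0) return(classified_empty(records, "DBS78"))
  if (any(records$ref == records$alt)) stop("DBS with ref == alt is not a substitution")
  labs <- dbs78_labels()
  cand1 <- paste0(records$ref, ">", records$alt)
  cand2 <- paste0(revcomp_chr(records$ref), ">", revcomp_chr(records$alt))
  channel <- ifelse(cand1 %in% labs, cand1,
                    ifelse(cand2 %in% labs, cand2, NA_character_))
  # doublets that change only one base have no DBS channel
  finish_classification(records, channel, is.na(channel), "DBS78",
                        reason = "no DBS78 channel (single-base doublet or N)")
}

#' @rdname classify
#' @export
classify_indel <- function(records, genome) {
  records <- records[records$kind %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(records) == 0) return(classified_empty(records, "ID"))
  n <- nrow(records)
  channel <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    channel[i] <- indel_channel(
      genome$contigs[[records$contig[i]]], records$pos[i],
      records$ref[i], records$alt[i], records$kind[i])
  }
  finish_classification(records, channel, is.na(channel), "ID",
                        reason = "N in evaluated window")
}

# channel for one left-aligned indel; NA when the window touches an N
indel_channel <- function(ctg, pos, ref, alt, kind) {
  if (kind == "DEL") {
    seq <- substr(ref, 2L, nchar(ref))
  } else {
    seq <- substr(alt, 2L, nchar(alt))
  }
  L <- nchar(seq)
  if (grepl("N", seq, fixed = TRUE)) return(NA_character_)

  if (L == 1L) {
    run <- homopolymer_run(ctg, pos, seq, include_event = kind == "DEL",
                           event_len = if (kind == "DEL") 1L else 0L)
    if (is.na(run)) return(NA_character_)
    base <- if (seq %in% c("C", "G")) "C" else "T"
    if (kind == "DEL") {
      bin <- if (run >= 6L) "6+" else as.character(run)
      return(paste0("DEL.", base, ".1.", bin))
    } else {
      bin <- if (run >= 5L) "5+" else as.character(run)
      return(paste0("INS.", base, ".1.", bin))
    }
  }

  lbin <- if (L >= 5L) "5+" else as.character(L)
  if (kind == "DEL") {
    cnt <- repeat_copies(ctg, pos, seq, deleted = TRUE)
    if (is.na(cnt)) return(NA_character_)
    if (cnt >= 2L) {
      rbin <- if (cnt >= 6L) "6+" else as.character(cnt)
      return(paste0("DEL.R.", lbin, ".", rbin))
    }
    mh <- microhomology_len(ctg, pos, seq)
    if (is.na(mh)) return(NA_character_)
    if (mh >= 1L) {
      mbin <- if (L >= 5L && mh >= 5L) "5+" else as.character(min(mh, L - 1L))
      return(paste0("DEL.MH.", lbin, ".", mbin))
    }
    return(paste0("DEL.R.", lbin, ".1"))
  } else {
    cnt <- repeat_copies(ctg, pos, seq, deleted = FALSE)
    if (is.na(cnt)) return(NA_character_)
    rbin <- if (cnt >= 5L) "5+" else as.character(cnt)
    return(paste0("INS.R.", lbin, ".", rbin))
  }
}

`%||%` <- function(a, b) if (length(a)) a else b

# total run of `base` contiguous with the event site, scanning both
# directions; includes the deleted base itself for deletions
homopolymer_run <- function(ctg, pos, base, include_event, event_len) {
  L <- nchar(ctg)
  run <- if (include_event) 1L else 0L
  i <- pos + 1L + event_len  # first reference base right of the event
  while (i <= L) {
    b <- substr(ctg, i, i)
    if (b == "N") return(NA_integer_)
    if (b != base) break
    run <- run + 1L; i <- i + 1L
  }
  i <- pos  # anchor base and leftwards
  while (i >= 1L) {
    b <- substr(ctg, i, i)
    if (b == "N") return(NA_integer_)
    if (b != base) break
    run <- run + 1L; i <- i - 1L
  }
  run
}

# number of tandem copies of `seq` at the event site (both directions);
# for deletions the deleted copy itself is counted
repeat_copies <- function(ctg, pos, seq, deleted) {
  L <- nchar(seq); G <- nchar(ctg)
  cnt <- if (deleted) 1L else 0L
  i <- pos + 1L + (if (deleted) L else 0L)  # right flank
  while (i + L - 1L <= G) {
    s <- substr(ctg, i, i + L - 1L)
    if (grepl("N", s, fixed = TRUE)) return(NA_integer_)
    if (s != seq) break
    cnt <- cnt + 1L; i <- i + L
  }
  i <- pos - L + 1L  # left flank (ends at the anchor base)
  while (i >= 1L) {
    s <- substr(ctg, i, i + L - 1L)
    if (grepl("N", s, fixed = TRUE)) return(NA_integer_)
    if (s != seq) break
    cnt <- cnt + 1L; i <- i - L
  }
  cnt
}

# longest flanking microhomology: prefix of the deleted sequence matching
# immediately 3' of the deletion, or suffix matching immediately 5'
microhomology_len <- function(ctg, pos, seq) {
  L <- nchar(seq); G <- nchar(ctg)
  fwd <- 0L
  for (k in seq_len(L - 1L)) {
    j <- pos + L + k
    if (j > G) break
    b <- substr(ctg, j, j)
    if (b == "N") return(NA_integer_)
    if (b != substr(seq, k, k)) break
    fwd <- k
  }
  bwd <- 0L
  for (k in seq_len(L - 1L)) {
    j <- pos - k + 1L
    if (j < 1L) break
    b <- substr(ctg, j, j)
    if (b == "N") return(NA_integer_)
    if (b != substr(seq, L - k + 1L, L - k + 1L)) break
    bwd <- k
  }
  max(fwd, bwd)
}

revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  revcomp(x)
}

finish_classification <- function(records, channel, skip, scheme_id, reason) {
  labels <- channel_scheme(scheme_id)$labels
  skipped <- records[skip, , drop = FALSE]
  if (nrow(skipped)) {
    skipped$reason <- reason
    warning(nrow(skipped), " record(s) skipped: ", reason)
  }
  out <- records[!skip, , drop = FALSE]
  out$scheme_id <- rep_len(scheme_id, nrow(out))
  out$channel <- channel[!skip]
  out$channel_index <- match(out$channel, labels)
  stopifnot(!anyNA(out$channel_index))
  list(classified = out, skipped = skipped)
}

classified_empty <- function(records, scheme_id) {
  out <- records
  out$scheme_id <- character(0)
  out$channel <- character(0)
  out$channel_index <- integer(0)
  skipped <- records
  skipped$reason <- character(0)
  list(classified = out, skipped = skipped)
}

#' Merge adjacent same-sample SNVs into doublet substitutions
#'
#' Two SNVs from the same sample at consecutive positions on one contig
#' are replaced by a single DBS record (variant callers frequently emit
#' doublets as two adjacent SNV lines). Runs of three or more consecutive
#' SNVs fit neither the SBS nor the DBS scheme: they are kept as SNVs but
#' marked `TRUE` in the returned `flag_multibase` column, and downstream
#' catalogue building excludes flagged rows.
#'
#' @param records A `mutation_records` data frame.
#' @return The records with adjacent SNV pairs merged and a
#'   `flag_multibase` logical column added.
#' @export
merge_adjacent_snvs <- function(records) {
  ord <- order(records$sample_id, records$contig, records$pos)
  records <- records[ord, , drop = FALSE]
  records$flag_multibase <- FALSE
  snv <- which(records$kind == "SNV")
  if (length(snv) < 2) return(records)

  same_run <- records$sample_id[snv[-1]] == records$sample_id[snv[-length(snv)]] &
    records$contig[snv[-1]] == records$contig[snv[-length(snv)]] &
    records$pos[snv[-1]] == records$pos[snv[-length(snv)]] + 1L
  run_id <- cumsum(c(TRUE, !same_run))
  runs <- split(snv, run_id)

  drop <- integer(0)
  for (r in runs) {
    if (length(r) == 2L) {
      i <- r[1]; j <- r[2]
      records$ref[i] <- paste0(records$ref[i], records$ref[j])
      records$alt[i] <- paste0(records$alt[i], records$alt[j])
      records$kind[i] <- "DBS"
      drop <- c(drop, j)
    } else if (length(r) >= 3L) {
      records$flag_multibase[r] <- TRUE
    }
  }
  if (length(drop)) records <- records[-drop, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Classify all mutation records for one scheme
#'
#' Dispatches records of the matching kind to [classify_sbs()],
#' [classify_dbs()] or [classify_indel()]. Rows flagged `flag_multibase`
#' (runs of adjacent SNVs, see [merge_adjacent_snvs()]) are routed to
#' `skipped`.
#'
#' @inheritParams classify
#' @param scheme_id One of `"SBS96"`, `"DBS78"`, `"ID"`.
#' @return As [classify_sbs()].
#' @export
classify_mutations <- function(records, genome,
                               scheme_id = c("SBS96", "DBS78", "ID")) {
  scheme_id <- match.arg(scheme_id)
  flagged <- if (is.null(records$flag_multibase)) rep(FALSE, nrow(records)) else
    records$flag_multibase
  keep <- records[!flagged, , drop = FALSE]
  res <- switch(scheme_id,
    SBS96 = classify_sbs(keep, genome),
    DBS78 = classify_dbs(keep, genome),
    ID    = classify_indel(keep, genome))
  flagged_rows <- records[flagged & records$kind == "SNV", , drop = FALSE]
  if (nrow(flagged_rows) && scheme_id %in% c("SBS96", "DBS78")) {
    flagged_rows$reason <- "multi-base run (>= 3 adjacent SNVs)"
    common <- intersect(names(res$skipped), names(flagged_rows))
    res$skipped <- rbind(res$skipped[common], flagged_rows[common])
  }
  res
}
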