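test_that("SBS classification follows the pyrimidine convention", {
  g <- make_genome(chr1 = "TACCA")        # context at pos 3 is "ACC"
  r <- classify_sbs(mutation_records("s", "chr1", 3L, "C", "A"), g)
  expect_equal(r$classified$channel, "A[C>A]C")

  g <- make_genome(chr1 = "TAGCA")        # context "AGC": purine centre
  r <- classify_sbs(mutation_records("s", "chr1", 3L, "G", "T"), g)
  expect_equal(r$classified$channel, "G[C>A]T")

  g <- make_genome(chr1 = "TATGA")        # context "ATG"
  r <- classify_sbs(mutation_records("s", "chr1", 3L, "T", "C"), g)
  expect_equal(r$classified$channel, "A[T>C]G")
  expect_equal(r$classified$channel_index,
               match("A[T>C]G", sbs96_labels()))
})

test_that("SBS classification skips N contexts and catches ref mismatches", {
  g <- make_genome(chr1 = "ACGTA")
  expect_warning(
    r <- classify_sbs(mutation_records("s", "chr1", 1L, "A", "T"), g),
    "skipped")
  expect_equal(nrow(r$classified), 0L)
  expect_equal(nrow(r$skipped), 1L)
  expect_error(
    classify_sbs(mutation_records("s", "chr1", 2L, "G", "T"), g),
    "mismatch")
})

test_that("DBS classification collapses reverse complements onto canonical doublets", {
  ex <- list(c("CC", "AA", "CC>AA"),
             c("GG", "TT", "CC>AA"),
             c("CA", "TG", "TG>CA"),
             c("AT", "GC", "AT>GC"),
             c("TA", "CG", "TA>CG"))
  for (e in ex) {
    r <- classify_dbs(mutation_records("s", "chr1", 1L, e[1], e[2]))
    expect_equal(r$classified$channel, e[3])
  }
  degenerate <- mutation_records("s", "chr1", 1L, "CC", "AA")
  degenerate$alt <- "CC"   # bypass the constructor to hit the classifier check
  expect_error(classify_dbs(degenerate), "not a substitution")
})

test_that("adjacent SNV pairs merge to DBS; longer runs are flagged", {
  r <- merge_adjacent_snvs(mutation_records(
    "s", rep("chr1", 2), c(5L, 6L), c("C", "C"), c("A", "A")))
  expect_equal(nrow(r), 1L)
  expect_equal(r$kind, "DBS")
  expect_equal(r$ref, "CC")
  expect_equal(r$alt, "AA")

  r <- merge_adjacent_snvs(mutation_records(
    "s", rep("chr1", 2), c(5L, 7L), c("C", "C"), c("A", "A")))
  expect_equal(r$kind, c("SNV", "SNV"))

  r <- merge_adjacent_snvs(mutation_records(
    "s", rep("chr1", 3), 5:7, c("C", "C", "C"), c("A", "A", "A")))
  expect_equal(nrow(r), 3L)
  expect_true(all(r$flag_multibase))
  expect_true(all(r$kind == "SNV"))

  # different samples never merge
  r <- merge_adjacent_snvs(mutation_records(
    c("a", "b"), rep("chr1", 2), c(5L, 6L), c("C", "C"), c("A", "A")))
  expect_equal(nrow(r), 2L)
})

test_that("1-bp indel channels encode base and homopolymer run length", {
  #                 123456789
  g <- make_genome(chr1 = "ATCCCATTA")
  # deletion of one C from the CCC run (left-aligned anchor at pos 2)
  r <- classify_indel(mutation_records("s", "chr1", 2L, "TC", "T"), g)
  expect_equal(r$classified$channel, "DEL.C.1.3")

  g <- make_genome(chr1 = "ATGGATTA")
  r <- classify_indel(mutation_records("s", "chr1", 2L, "TG", "T"), g)
  expect_equal(r$classified$channel, "DEL.C.1.2")

  g <- make_genome(chr1 = "CATTTTTTGC")
  # insertion of one T adjacent to a 6-T run: capped at 5+
  r <- classify_indel(mutation_records("s", "chr1", 2L, "A", "AT"), g)
  expect_equal(r$classified$channel, "INS.T.1.5+")

  # insertion where neither neighbour matches: run 0
  g <- make_genome(chr1 = "ACGAG")
  r <- classify_indel(mutation_records("s", "chr1", 2L, "C", "CT"), g)
  expect_equal(r$classified$channel, "INS.T.1.0")
})

test_that("longer indels split into repeat and microhomology channels", {
  # "AT" deleted from a 3-copy tandem repeat: repeat count includes the
  # deleted copy
  g <- make_genome(chr1 = "GCATATATGC")
  r <- classify_indel(mutation_records("s", "chr1", 2L, "CAT", "C"), g)
  expect_equal(r$classified$channel, "DEL.R.2.3")

  # deleting TAG from ...G|TAG|TA...: left-alignment slides it into the
  # GTA x 2 tandem, so this is a 2-copy repeat deletion
  g <- make_genome(chr1 = "GGTAGTACCC")
  r <- classify_indel(left_align_indels(
    mutation_records("s", "chr1", 2L, "GTAG", "G"), g), g)
  expect_equal(r$classified$channel, "DEL.R.3.2")

  # non-repetitive deletion whose 3' flank repeats the first two deleted
  # bases: microhomology of length 2
  g <- make_genome(chr1 = "GGTAGCTATTT")
  r <- classify_indel(mutation_records("s", "chr1", 2L, "GTAGC", "G"), g)
  expect_equal(r$classified$channel, "DEL.MH.4.2")

  # deletion with no repeat copy and no flanking homology
  g <- make_genome(chr1 = "GCTAGCCACT")
  r <- classify_indel(mutation_records("s", "chr1", 2L, "CTAG", "C"), g)
  expect_equal(r$classified$channel, "DEL.R.3.1")

  # tandem duplication insertion: one pre-existing copy in the reference
  g <- make_genome(chr1 = "GGTAGCCACT")
  r <- classify_indel(left_align_indels(
    mutation_records("s", "chr1", 5L, "G", "GTAG"), g), g)
  expect_equal(r$classified$channel, "INS.R.3.1")
})

test_that("indel run length agrees with a brute-force reference scan", {
  g <- random_genome(20000, seed = 21)
  s <- g$contigs[["chr1"]]
  ch <- strsplit(s, "")[[1]]
  set.seed(22)
  pos <- sample(10:19990, 1200, replace = FALSE)
  # brute force: run of the base at p, scanning left and right in the string
  brute_run <- function(p) {
    b <- ch[p]
    i <- p; while (i > 1 && ch[i - 1] == b) i <- i - 1
    j <- p; while (j < length(ch) && ch[j + 1] == b) j <- j + 1
    j - i + 1
  }
  recs <- mutation_records("s", "chr1", pos - 1L,
                           paste0(ch[pos - 1], ch[pos]), ch[pos - 1])
  recs <- left_align_indels(recs, g)
  res <- classify_indel(recs, g)
  expect_equal(nrow(res$classified), 1200L)
  expected_bin <- vapply(pos, function(p) {
    run <- brute_run(p)
    base <- if (ch[p] %in% c("C", "G")) "C" else "T"
    paste0("DEL.", base, ".1.", if (run >= 6) "6+" else run)
  }, character(1))
  # left-alignment does not change the run, so channels must agree
  expect_equal(res$classified$channel, expected_bin)
})

test_that("classification is strand-symmetric for all three schemes", {
  g <- random_genome(4000, seed = 31)
  L <- g$lengths[["chr1"]]
  rg <- make_genome(chr1 = exposig:::revcomp_chr(g$contigs[["chr1"]]))
  set.seed(32)

  # SNVs
  pos <- sample(2:(L - 1), 800)
  ref <- substring(g$contigs[["chr1"]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  fwd <- classify_sbs(mutation_records("s", "chr1", pos, ref, alt), g)
  rev <- classify_sbs(mutation_records("s", "chr1", L - pos + 1L,
                                       exposig:::comp_base(ref),
                                       exposig:::comp_base(alt)), rg)
  expect_equal(rev$classified$channel, fwd$classified$channel)

  # DBS
  pos <- sample(2:(L - 2), 400)
  ref2 <- substring(g$contigs[["chr1"]], pos, pos + 1)
  alt2 <- exposig:::revcomp_chr(ref2)  # guaranteed to differ at both bases?
  ok <- substr(ref2, 1, 1) != substr(alt2, 1, 1) &
    substr(ref2, 2, 2) != substr(alt2, 2, 2)
  pos <- pos[ok]; ref2 <- ref2[ok]; alt2 <- alt2[ok]
  fwd <- classify_dbs(mutation_records("s", "chr1", pos, ref2, alt2))
  rev <- classify_dbs(mutation_records("s", "chr1", L - pos,
                                       exposig:::revcomp_chr(ref2),
                                       exposig:::revcomp_chr(alt2)))
  expect_equal(rev$classified$channel, fwd$classified$channel)

  # 1-bp deletions
  pos <- sample(5:(L - 5), 300)
  anchor <- substring(g$contigs[["chr1"]], pos - 1, pos - 1)
  del_base <- substring(g$contigs[["chr1"]], pos, pos)
  fwd_rec <- left_align_indels(
    mutation_records("s", "chr1", pos - 1L, paste0(anchor, del_base), anchor),
    g)
  fwd <- classify_indel(fwd_rec, g)
  rpos <- L - pos + 1L   # deleted base position in the reversed genome
  ranchor <- substring(rg$contigs[["chr1"]], rpos - 1, rpos - 1)
  rev_rec <- left_align_indels(
    mutation_records("s", "chr1", rpos - 1L,
                     paste0(ranchor, exposig:::comp_base(del_base)), ranchor),
    rg)
  rev <- classify_indel(rev_rec, rg)
  expect_equal(rev$classified$channel, fwd$classified$channel)
})
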