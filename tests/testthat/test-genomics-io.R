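test_that("FASTA round-trip preserves sequence and case-folds to uppercase", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), fa)
  g <- load_reference(fa)
  expect_equal(g$lengths[["chr1"]], 4L)
  expect_equal(g$contigs[["chr1"]], "ACGT")

  writeLines(c(">chr1 description text", "acgt"), fa)
  g <- load_reference(fa)
  expect_equal(g$contigs[["chr1"]], "ACGT")
  expect_named(g$contigs, "chr1")

  g2 <- make_genome(chr1 = "ACGTACGT", chr2 = "TTTT")
  out <- tempfile(fileext = ".fa")
  write_reference(g2, out)
  expect_equal(load_reference(out)$contigs, g2$contigs)
})

test_that("IUPAC ambiguity codes in the reference are rejected by name", {
  expect_error(make_genome(chr1 = "ACGRT"), "R")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGRT"), fa)
  expect_error(load_reference(fa), "R")
  writeLines(character(0), fa)
  expect_error(load_reference(fa), "empty|malformed")
})

test_that("context returns centred k-mers with N fill at contig edges", {
  g <- make_genome(chr1 = "ACGTA")
  expect_equal(context(g, "chr1", 3, 1), "CGT")
  expect_equal(context(g, "chr1", 1, 1), "NAC")
  expect_equal(context(g, "chr1", 3, 0), "G")
  expect_equal(context(g, "chr1", 5, 2), "GTANN")
  expect_error(context(g, "chrX", 1, 1), "unknown contig")
  expect_error(context(g, "chr1", 6, 0), "out of bounds")
})

test_that("context agrees with direct string slicing on random positions", {
  g <- random_genome(3000, seed = 11)
  s <- g$contigs[["chr1"]]
  set.seed(12)
  pos <- sample(2:2999, 1200, replace = TRUE)
  expect_equal(context(g, "chr1", pos, 1),
               substring(s, pos - 1, pos + 1))
  inner <- pos[pos >= 6 & pos <= 2995]
  expect_equal(context(g, "chr1", inner, 5),
               substring(s, inner - 5, inner + 5))
})

test_that("read_vcf types SNV, DBS and anchored indels", {
  vcf <- write_temp_vcf(c(
    "chr1\t5\t.\tC\tA\t.\tPASS\t.",
    "chr1\t9\t.\tCC\tAA\t.\tPASS\t.",
    "chr1\t14\t.\tAC\tA\t.\tPASS\t.",
    "chr1\t20\t.\tA\tAGG\t.\tPASS\t."))
  r <- read_vcf(vcf, "s1")
  expect_equal(r$kind, c("SNV", "DBS", "DEL", "INS"))
  expect_equal(r$pos, c(5L, 9L, 14L, 20L))
  expect_equal(r$sample_id, rep("s1", 4))
})

test_that("FILTER handling keeps PASS/. by default and everything on request", {
  vcf <- write_temp_vcf(c(
    "chr1\t5\t.\tC\tA\t.\tPASS\t.",
    "chr1\t6\t.\tC\tA\t.\t.\t.",
    "chr1\t7\t.\tC\tA\t.\tlowqual\t."))
  r <- read_vcf(vcf, "s")
  expect_equal(r$pos, c(5L, 6L))
  expect_equal(attr(r, "skipped")[["filtered"]], 1L)
  r_all <- read_vcf(vcf, "s", keep_all_filters = TRUE)
  expect_equal(nrow(r_all), 3L)
})

test_that("multi-allelic records split and symbolic alleles are skipped with a count", {
  vcf <- write_temp_vcf(c(
    "chr1\t5\t.\tC\tA,T\t.\tPASS\t.",
    "chr1\t9\t.\tC\t<DEL>\t.\tPASS\t.",
    "chr1\t12\t.\tCG\tCA\t.\tPASS\t."))   # MNV differing at one base -> SNV
  expect_warning(r <- read_vcf(vcf, "s"), "symbolic")
  expect_equal(nrow(r), 3L)
  expect_equal(r$alt[r$pos == 5L], c("A", "T"))
  expect_equal(attr(r, "skipped")[["symbolic"]], 1L)
  demoted <- r[r$pos == 13L, ]
  expect_equal(demoted$kind, "SNV")
  expect_equal(demoted$ref, "G")
  expect_equal(demoted$alt, "A")
})

test_that("VCF round-trip reproduces records field-for-field", {
  recs <- mutation_records(
    "clone1", rep("chr1", 5), c(3L, 10L, 20L, 30L, 40L),
    c("C", "GG", "AC", "T", "ATT"),
    c("A", "TT", "A", "TCC", "A"))
  path <- tempfile(fileext = ".vcf")
  write_vcf(recs, path)
  back <- read_vcf(path, "clone1")
  expect_equal(back[names(recs)], recs[names(recs)],
               ignore_attr = TRUE)
})

test_that("indels are left-aligned into repeat tracts at load", {
  #        1234567890
  g <- make_genome(chr1 = "ATCCCCGATT")
  # deletion of one C written at the right end of the C run
  vcf <- write_temp_vcf("chr1\t5\t.\tCC\tC\t.\tPASS\t.")
  r <- read_vcf(vcf, "s", genome = g)
  expect_equal(r$pos, 2L)   # anchored at the T before the run
  expect_equal(r$ref, "TC")
  expect_equal(r$alt, "T")
  # insertion of a C inside the run shifts to the run start too
  vcf <- write_temp_vcf("chr1\t6\t.\tC\tCC\t.\tPASS\t.")
  r <- read_vcf(vcf, "s", genome = g)
  expect_equal(r$pos, 2L)
  expect_equal(r$alt, "TC")
})

test_that("signature catalogue TSVs are validated and renormalised on read", {
  labs <- sbs96_labels()
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(Type = labs, sigA = rep(2, 96), sigB = 1:96),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat96 <- read_signature_catalog(path)
  expect_equal(cat96$scheme_id, "SBS96")
  expect_equal(unname(colSums(cat96$signatures)), c(1, 1), tolerance = 1e-12)
  expect_equal(colnames(cat96$signatures), c("sigA", "sigB"))

  d <- dbs78_labels()
  write.table(data.frame(Type = d, s = rep(1, 78)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_equal(read_signature_catalog(path)$scheme_id, "DBS78")

  write.table(data.frame(Type = labs[-96], s = rep(1, 95)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(path), "missing channel")

  write.table(data.frame(Type = c(labs[-1], labs[2]), s = rep(1, 96)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(path), "duplicated")

  neg <- data.frame(Type = labs, s = c(-1, rep(1, 95)))
  write.table(neg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_catalog(path), "negative")
})

test_that("catalogue TSV export round-trips through the reader", {
  prof <- toy_signature("exposure_sbs")
  path <- tempfile(fileext = ".tsv")
  write_signature_catalog(prof, path)
  back <- read_signature_catalog(path)
  expect_equal(unname(back$signatures[, 1]), unname(prof$weights),
               tolerance = 1e-12)
})

test_that("gene models merge overlapping intervals and attach expression", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tKMT2D",
               "chr1\t200\t300\tTP53",
               "chr1\t250\t400\tTP53"), bed)
  g <- read_gene_models(bed)
  expect_equal(g$table$footprint_bp[g$table$name == "KMT2D"], 100L)
  expect_equal(g$table$footprint_bp[g$table$name == "TP53"], 200L)
  expect_true(all(is.na(g$table$expression)))

  expr <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tvalue", "KMT2D\t5.5", "UNKNOWN\t1"), expr)
  expect_warning(g2 <- read_gene_models(bed, expr), "UNKNOWN")
  expect_equal(g2$table$expression[g2$table$name == "KMT2D"], 5.5)
  expect_true(is.na(g2$table$expression[g2$table$name == "TP53"]))

  writeLines("chr1\t100\t100\tBAD", bed)
  expect_error(read_gene_models(bed), "end <= start")
})
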