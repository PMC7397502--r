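simple_genes <- function(starts0, ends0, names = NULL,
                         contig = "chr1", expression = NULL) {
  if (is.null(names)) names <- paste0("g", seq_along(starts0))
  gr <- GenomicRanges::GRanges(contig,
                               IRanges::IRanges(starts0 + 1L, ends0))
  gr$name <- names
  gene_models_from_granges(gr, expression = expression)
}

test_that("gene counting uses 1-based positions against half-open intervals", {
  genes <- simple_genes(0, 100, "KMT2D")
  rec_at <- function(pos) mutation_records("s", "chr1", pos, "C", "A")
  expect_equal(unname(count_gene_mutations(rec_at(50L), genes)), 1L)
  expect_equal(unname(count_gene_mutations(rec_at(100L), genes)), 1L)
  expect_equal(unname(count_gene_mutations(rec_at(101L), genes)), 0L)
  # indels count at the first altered base, one past the anchor
  del <- mutation_records("s", "chr1", 100L, "AC", "A")
  expect_equal(unname(count_gene_mutations(del, genes)), 0L)
  del_in <- mutation_records("s", "chr1", 99L, "AC", "A")
  expect_equal(unname(count_gene_mutations(del_in, genes)), 1L)
  # overlapping genes both count the same mutation
  both <- simple_genes(c(0, 40), c(100, 140), c("a", "b"))
  expect_equal(unname(count_gene_mutations(rec_at(50L), both)), c(1L, 1L))
})

test_that("gene counting agrees with a brute-force double loop", {
  set.seed(71)
  starts <- sort(sample(seq(0, 90000, by = 100), 30))
  genes <- simple_genes(starts, starts + sample(50:400, 30, TRUE))
  pos <- sample.int(95000, 2000, replace = TRUE)
  recs <- mutation_records("s", "chr1", pos, "C", "A")
  fast <- count_gene_mutations(recs, genes)
  gr <- genes$granges
  brute <- vapply(genes$table$name, function(nm) {
    iv <- gr[gr$name == nm]
    sum(vapply(pos, function(p)
      any(p >= GenomicRanges::start(iv) & p <= GenomicRanges::end(iv)),
      logical(1)))
  }, numeric(1))
  expect_equal(unname(fast), unname(brute))
})

test_that("Poisson tail probabilities match closed forms and the pmf oracle", {
  # observed 5, lambda 1: 1 - e^-1 * (1 + 1 + 1/2 + 1/6 + 1/24)
  r <- gene_enrichment_test(5L, 1000L, 1e5, 1e8)
  expect_equal(r$expected, 1)
  expect_equal(r$p_over, 1 - exp(-1) * sum(1 / factorial(0:4)),
               tolerance = 1e-12)
  expect_equal(r$p_over, 0.003660, tolerance = 1e-4)
  # observed 0, lambda 5: p_under = e^-5, p_over = 1
  r <- gene_enrichment_test(0L, 1000L, 5e5, 1e8)
  expect_equal(r$p_under, exp(-5), tolerance = 1e-12)
  expect_equal(r$p_over, 1)

  # pmf-summation oracle across a grid: both tails summed term by term
  for (lambda in c(0.1, 1, 5, 20)) {
    fp <- lambda * 1e8 / 1000
    r <- gene_enrichment_test(0:50, 1000L, rep(fp, 51), 1e8)
    # pmf in log space so large k does not overflow lambda^k
    pmf <- function(k) exp(-lambda + k * log(lambda) - lgamma(k + 1))
    for (obs in c(0L, 1L, 7L, 23L, 50L)) {
      over <- sum(vapply(obs:(obs + 400L), pmf, numeric(1)))
      under <- sum(vapply(0:obs, pmf, numeric(1)))
      expect_lt(abs(r$p_over[obs + 1] - over), 1e-10)
      expect_lt(abs(r$p_under[obs + 1] - under), 1e-10)
    }
  }
  expect_error(gene_enrichment_test(1L, 10L, 2e8, 1e8), "exceeds")
})

test_that("Poisson and exact binomial tails agree for small footprint fractions", {
  for (obs in c(0L, 2L, 8L)) {
    p <- gene_enrichment_test(obs, 10000L, 5e4, 1e8, model = "poisson")
    b <- gene_enrichment_test(obs, 10000L, 5e4, 1e8, model = "binomial")
    expect_lt(abs(p$p_over - b$p_over) / b$p_over, 0.1)
    expect_lt(abs(p$p_under - b$p_under) / b$p_under, 0.1)
  }
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(c(0.001, 0.5)), c(0.002, 0.5))
})

test_that("enrichment calls split into separate one-sided FDR families", {
  set.seed(72)
  obs <- c(60L, rep(10L, 18), 0L)   # one clear excess, one clear deficit
  enr <- gene_enrichment_test(obs, 10000L, rep(1e5, 20), 1e8)
  called <- call_enrichment(enr, alpha = 0.05)
  expect_equal(called$call[1], "overmutated")
  expect_equal(called$call[20], "protected")
  expect_true(all(called$call[2:19] == "consistent"))
})

test_that("rate regression handles flat, perfect-linear and noisy inputs", {
  set.seed(73)
  n_genes <- 40
  starts <- seq(0, by = 20000, length.out = n_genes)
  expr <- seq_len(n_genes)

  # flat: every gene gets the same count over equal footprints
  genes <- simple_genes(starts, starts + 10000,
                        expression = setNames(expr, paste0("g", 1:n_genes)))
  pos <- unlist(lapply(starts, function(s) s + seq(1, 10000, by = 500)))
  recs <- mutation_records("s", "chr1", as.integer(pos), "C", "A")
  flat <- expression_rate_regression(recs, genes, n_bins = 10)
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_equal(flat$r_squared, 0)

  # counts exactly linear in bin index
  per_gene <- rep(c(10, 20, 30, 40), each = 10)
  pos <- unlist(lapply(seq_len(n_genes), function(i)
    starts[i] + seq_len(per_gene[i])))
  recs <- mutation_records("s", "chr1", as.integer(pos), "C", "A")
  lin <- expression_rate_regression(recs, genes, n_bins = 4)
  expect_equal(lin$r_squared, 1, tolerance = 1e-9)
  expect_lt(lin$p_value, 1e-6)
  expect_gt(lin$slope, 0)

  expect_error(expression_rate_regression(recs, genes, n_bins = 2), "3")
  no_expr <- simple_genes(starts, starts + 10000)
  expect_error(expression_rate_regression(recs, no_expr), "expression")
})

test_that("regression recovers a known generating slope from simulation", {
  set.seed(74)
  n_genes <- 100
  starts <- seq(0, by = 15000, length.out = n_genes)
  expr <- rlnorm(n_genes, log(10), 0.8)
  genes <- simple_genes(starts, starts + 10000,
                        expression = setNames(expr, paste0("g", 1:n_genes)))
  slope_true <- 30   # mutations per Mb per expression unit
  r0 <- 100
  counts <- rpois(n_genes, (r0 + slope_true * expr) * 0.01)
  pos <- unlist(lapply(seq_len(n_genes), function(i)
    starts[i] + sample.int(10000, counts[i], replace = TRUE)))
  recs <- mutation_records("s", "chr1", as.integer(pos), "C", "A")
  fit <- expression_rate_regression(recs, genes, n_bins = 10,
                                    x_mode = "mean_expression")
  expect_lt(abs(fit$slope - slope_true), 2 * fit$slope_se)
  expect_lt(fit$p_value, 0.01)
})

test_that("context-weighted footprints reduce to raw footprints for flat signatures", {
  g <- random_genome(20000, seed = 75)
  genes <- simple_genes(c(1000, 6000, 12000), c(3000, 9000, 15000))
  flat <- signature_profile("SBS96", rep(1, 96))
  cw <- context_weighted_footprint(g, genes, flat)
  # every interior position carries the same weight, so gene weights are
  # proportional to footprint and the expected counts match the raw null
  expected_ratio <- genes$table$footprint_bp / sum(genes$table$footprint_bp)
  expect_equal(unname(cw$gene_weight / sum(cw$gene_weight)),
               expected_ratio, tolerance = 1e-3)

  # a one-hot channel weights genes by exact matching-trinucleotide counts
  hot <- one_hot_sbs("A[C>A]A")
  cw1 <- context_weighted_footprint(g, genes, hot)
  s <- g$contigs[["chr1"]]
  count_tri <- function(a, b) {
    n <- 0L
    for (p in a:b) {
      tri <- substr(s, p - 1, p + 1)
      if (tri == "ACA" || tri == "TGT") n <- n + 1L
    }
    n
  }
  brute <- c(count_tri(1001, 3000), count_tri(6001, 9000),
             count_tri(12001, 15000))
  expect_equal(unname(cw1$gene_weight), brute)
  expect_equal(cw1$genome_weight, count_tri(2, 19999))
})
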