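# shared helpers: tiny in-memory genomes, random fixtures, temp files

make_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  reference_from_strings(seqs)
}

random_genome <- function(length_bp = 5000, seed = 1, gc = 0.42,
                          name = "chr1") {
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), length_bp, replace = TRUE,
                    prob = probs), collapse = "")
  make_genome(stats::setNames(s, name))
}

write_temp_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("test", tmpdir = dir, fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               lines), path)
  path
}

# a one-hot SBS96 signature concentrated on a single channel
one_hot_sbs <- function(channel) {
  labs <- sbs96_labels()
  w <- numeric(96)
  w[labs == channel] <- 1
  signature_profile("SBS96", w, name = paste0("onehot_", channel))
}

# a reproducible random signature profile (decoys for ranking tests)
random_profile <- function(scheme_id, seed, concentration = 0.3,
                           name = paste0("decoy", seed)) {
  set.seed(seed)
  n <- channel_scheme(scheme_id)$size
  w <- stats::rgamma(n, shape = concentration)
  signature_profile(scheme_id, w / sum(w), name = name)
}

# catalogue built from a list of signature_profiles
catalog_from_profiles <- function(profiles) {
  mat <- vapply(profiles, function(p) p$weights,
                numeric(length(profiles[[1]]$weights)))
  colnames(mat) <- vapply(profiles, function(p) p$name, character(1))
  signature_catalog(profiles[[1]]$scheme_id, mat)
}
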