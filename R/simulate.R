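#' Simulation configuration for synthetic clone studies
#'
#' Defines the synthetic study: a random reference genome, control clones
#' that accumulate mutations from a background process alone, and exposed
#' clones that accumulate background plus exposure-process mutations.
#' Defaults mirror the design of a clonal carcinogen-exposure experiment:
#' 3 control and 4 exposed clones; a background signature enriched for
#' C>T and T>C transitions; an exposure signature dominated by C>A
#' transversions with CC>AA doublets and single C/G deletions in short
#' homopolymer runs as the accompanying doublet/indel processes.
#'
#' Burdens are expected mutation counts per clone (Poisson means).
#' `dbs_fraction` and `indel_fraction` give the fraction of each
#' process's events emitted as doublet substitutions and indels; the
#' remainder are SNVs.
#'
#' @param seed Integer master seed; per-clone seeds are derived as
#'   `seed * 1000 + clone_index` (clones numbered across both groups).
#' @param n_contigs,contig_length_bp Reference shape (total >= 1000 bp).
#' @param gc_fraction GC content of the i.i.d. reference, in (0, 1).
#' @param n_control_clones,n_exposed_clones Clone counts per group.
#' @param background_signature,exposure_signature SBS96
#'   `signature_profile`s for the two processes.
#' @param background_burden,exposure_burden Expected mutations per clone
#'   contributed by each process.
#' @param dbs_fraction,indel_fraction Per-process event-type fractions.
#' @param background_dbs_signature,exposure_dbs_signature DBS78 profiles.
#' @param background_id_signature,exposure_id_signature ID profiles
#'   (1-bp channels only; the simulator places homopolymer-context
#'   events).
#' @param n_genes,gene_length_bp Optional non-overlapping gene models.
#' @param expression_rate_slope Optional coupling: each gene receives
#'   extra uniformly placed SNVs at `slope * log1p(expression)` mutations
#'   per Mb per clone (the log scale matches how expression effects are
#'   usually modelled for right-skewed expression distributions, and the
#'   regression's log-expression regressor).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_contigs = 1L,
                              contig_length_bp = 1e6,
                              gc_fraction = 0.42,
                              n_control_clones = 3L,
                              n_exposed_clones = 4L,
                              background_signature = toy_signature("background_sbs"),
                              exposure_signature = toy_signature("exposure_sbs"),
                              background_burden = 3000,
                              exposure_burden = 5000,
                              dbs_fraction = 0.01,
                              indel_fraction = 0.02,
                              background_dbs_signature = toy_signature("background_dbs"),
                              exposure_dbs_signature = toy_signature("exposure_dbs"),
                              background_id_signature = toy_signature("background_id"),
                              exposure_id_signature = toy_signature("exposure_id"),
                              n_genes = 0L,
                              gene_length_bp = 10000L,
                              expression_rate_slope = NULL) {
  stopifnot(background_burden >= 0, exposure_burden >= 0,
            dbs_fraction >= 0, dbs_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            dbs_fraction + indel_fraction <= 1,
            gc_fraction > 0, gc_fraction < 1,
            inherits(background_signature, "signature_profile"),
            inherits(exposure_signature, "signature_profile"))
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

#' Built-in toy signatures used by the simulator
#'
#' Read from the TSV fixtures under `inst/extdata/`. `background_sbs` is
#' enriched for C>T and T>C transitions (the spontaneous pattern of
#' untreated clones); `exposure_sbs` concentrates on C>A transversions;
#' `exposure_dbs` is CC>AA-dominated with TG>AT / TG>CA minor channels;
#' `exposure_id` is dominated by single C deletions in homopolymer runs
#' of two to four.
#'
#' @param name One of `"background_sbs"`, `"exposure_sbs"`,
#'   `"background_dbs"`, `"exposure_dbs"`, `"background_id"`,
#'   `"exposure_id"`.
#' @return A `signature_profile`.
#' @export
toy_signature <- function(name) {
  path <- system.file("extdata", paste0("toy_", name, ".tsv"),
                      package = "exposig", mustWork = TRUE)
  cat_ <- read_signature_catalog(path)
  signature_profile(cat_$scheme_id, cat_$signatures[, 1], name = name)
}

#' Simulate a reference genome
#'
#' Bases are i.i.d. at the configured GC fraction (A and T each
#' `(1-gc)/2`, C and G each `gc/2`); a fixed seed gives a byte-identical
#' genome. Contigs are named `chr1`, `chr2`, ...
#'
#' @param config A `simulation_config` (its `seed`, `n_contigs`,
#'   `contig_length_bp` and `gc_fraction` fields are used).
#' @param path Optional FASTA output path.
#' @return A `reference_genome`.
#' @export
simulate_reference <- function(config, path = NULL) {
  if (config$n_contigs * config$contig_length_bp < 1000)
    stop("reference must be at least 1000 bp so contexts have flanks")
  set.seed(config$seed)
  gc <- config$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(BASES, config$contig_length_bp, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  names(contigs) <- paste0("chr", seq_len(config$n_contigs))
  genome <- new_reference_genome(contigs)
  if (!is.null(path)) write_reference(genome, path)
  genome
}

#' Precompute the context index of a genome
#'
#' Positions are indexed by trinucleotide (for SNV placement), by
#' dinucleotide (doublets), and homopolymer runs are tabulated (indels),
#' so mutation sites can be sampled uniformly among positions whose
#' context matches the drawn channel.
#'
#' @param genome A `reference_genome`.
#' @return A `genome_index` list.
#' @export
build_genome_index <- function(genome) {
  tri <- list(); din <- list(); runs <- list()
  for (ctg in names(genome$contigs)) {
    ch <- strsplit(genome$contigs[[ctg]], "")[[1]]
    L <- length(ch)
    tri_str <- paste0(ch[1:(L - 2)], ch[2:(L - 1)], ch[3:L])
    tri[[ctg]] <- split(2:(L - 1), tri_str)
    din_str <- paste0(ch[1:(L - 1)], ch[2:L])
    din[[ctg]] <- split(1:(L - 1), din_str)
    r <- rle(ch)
    ends <- cumsum(r$lengths)
    runs[[ctg]] <- data.frame(base = r$values,
                              start = ends - r$lengths + 1L,
                              len = r$lengths, stringsAsFactors = FALSE)
  }
  structure(list(genome = genome, tri = tri, din = din, runs = runs),
            class = "genome_index")
}

# -- site bookkeeping ---------------------------------------------------
# a claimed site blocks itself plus one base on each side, so no two
# simulated events are ever adjacent (adjacency would corrupt the truth
# channel once adjacent SNVs are merged into doublets)
new_site_ledger <- function(genome) {
  new.env(hash = TRUE, parent = emptyenv())
}

claim_site <- function(ledger, ctg, pos, width) {
  keys <- paste0(ctg, ":", (pos - 1L):(pos + width))
  for (k in keys)
    if (exists(k, envir = ledger, inherits = FALSE)) return(FALSE)
  for (k in keys) assign(k, TRUE, envir = ledger)
  TRUE
}

# sample `k` sites for one channel from candidate (contig, pos) pairs
sample_sites <- function(cands, k, width, ledger, channel) {
  n_cand <- sum(lengths(cands$pos))
  if (n_cand == 0)
    stop("no genomic site matches channel ", channel)
  ctg_vec <- rep(names(cands$pos), lengths(cands$pos))
  pos_vec <- unlist(cands$pos, use.names = FALSE)
  strand_vec <- unlist(cands$strand, use.names = FALSE)
  perm <- sample.int(n_cand)
  out_i <- integer(k); got <- 0L
  for (j in perm) {
    if (claim_site(ledger, ctg_vec[j], pos_vec[j], width)) {
      got <- got + 1L
      out_i[got] <- j
      if (got == k) break
    }
  }
  if (got < k)
    stop("exhausted genomic sites for channel ", channel,
         " (", got, " of ", k, " placed)")
  list(contig = ctg_vec[out_i], pos = pos_vec[out_i],
       strand = strand_vec[out_i])
}

#' Simulate the mutations of one clone
#'
#' For each mutational process, the event count is Poisson with the
#' process burden; events are split into SNV/DBS/indel types at the
#' configured fractions; each event's channel is drawn from the process
#' signature of that type, and a genomic site whose reference context
#' matches the channel (on either strand) is drawn uniformly from the
#' precomputed index. Sites are never reused within a clone and no two
#' events are adjacent.
#'
#' @param index A `genome_index`.
#' @param sample_id Clone label.
#' @param processes List of process descriptors, each a list with
#'   `name`, `burden`, `sbs` (SBS96 profile), and optionally `dbs`, `id`
#'   profiles with `dbs_fraction`, `indel_fraction`.
#' @param seed Integer seed for this clone.
#' @return List with `records` (a `mutation_records` data frame) and
#'   `truth` (data frame: sample_id, contig, pos, ref, alt, kind,
#'   channel, process).
#' @export
simulate_clone <- function(index, sample_id, processes, seed) {
  set.seed(seed)
  genome <- index$genome
  ledger <- new_site_ledger(genome)
  rows <- list()
  for (proc in processes) {
    n <- stats::rpois(1, proc$burden)
    if (n == 0) next
    df <- if (is.null(proc$dbs_fraction) || is.null(proc$dbs)) 0 else
      proc$dbs_fraction
    idf <- if (is.null(proc$indel_fraction) || is.null(proc$id)) 0 else
      proc$indel_fraction
    type_counts <- stats::rmultinom(1, n, c(snv = 1 - df - idf, dbs = df,
                                            indel = idf))[, 1]
    if (type_counts["snv"] > 0)
      rows[[length(rows) + 1L]] <-
        place_snvs(index, ledger, sample_id, proc$sbs, type_counts["snv"],
                   proc$name)
    if (type_counts["dbs"] > 0)
      rows[[length(rows) + 1L]] <-
        place_dbs(index, ledger, sample_id, proc$dbs, type_counts["dbs"],
                  proc$name)
    if (type_counts["indel"] > 0)
      rows[[length(rows) + 1L]] <-
        place_indels(index, ledger, sample_id, proc$id, type_counts["indel"],
                     proc$name)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), contig = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               kind = character(0), channel = character(0),
               process = character(0))
  ord <- order(truth$contig, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  records <- mutation_records(truth$sample_id, truth$contig, truth$pos,
                              truth$ref, truth$alt, truth$kind)
  list(records = records, truth = truth)
}

place_snvs <- function(index, ledger, sample_id, profile, n, process) {
  stopifnot(inherits(profile, "signature_profile"),
            profile$scheme_id == "SBS96")
  per_channel <- stats::rmultinom(1, n, profile$weights)[, 1]
  out <- list()
  for (channel in names(per_channel)[per_channel > 0]) {
    k <- per_channel[[channel]]
    p5 <- substr(channel, 1, 1); ref <- substr(channel, 3, 3)
    alt <- substr(channel, 5, 5); p3 <- substr(channel, 7, 7)
    fwd_tri <- paste0(p5, ref, p3)
    rev_tri <- revcomp(fwd_tri)
    cands <- list(
      pos = lapply(index$tri, function(ix)
        c(ix[[fwd_tri]], ix[[rev_tri]])),
      strand = lapply(index$tri, function(ix)
        rep(c("+", "-"), c(length(ix[[fwd_tri]]), length(ix[[rev_tri]]))))
    )
    s <- sample_sites(cands, k, 1L, ledger, channel)
    rev <- s$strand == "-"
    out[[channel]] <- data.frame(
      sample_id = sample_id, contig = s$contig, pos = s$pos,
      ref = ifelse(rev, comp_base(ref), ref),
      alt = ifelse(rev, comp_base(alt), alt),
      kind = "SNV", channel = channel, process = process,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

place_dbs <- function(index, ledger, sample_id, profile, n, process) {
  stopifnot(inherits(profile, "signature_profile"),
            profile$scheme_id == "DBS78")
  per_channel <- stats::rmultinom(1, n, profile$weights)[, 1]
  out <- list()
  for (channel in names(per_channel)[per_channel > 0]) {
    k <- per_channel[[channel]]
    ref <- substr(channel, 1, 2); alt <- substr(channel, 4, 5)
    rc_ref <- revcomp(ref)
    cands <- list(
      pos = lapply(index$din, function(ix) {
        fwd <- ix[[ref]]
        rev <- if (rc_ref != ref) ix[[rc_ref]] else integer(0)
        c(fwd, rev)
      }),
      strand = lapply(index$din, function(ix) {
        nf <- length(ix[[ref]])
        nr <- if (rc_ref != ref) length(ix[[rc_ref]]) else 0L
        rep(c("+", "-"), c(nf, nr))
      })
    )
    s <- sample_sites(cands, k, 2L, ledger, channel)
    rev <- s$strand == "-"
    out[[channel]] <- data.frame(
      sample_id = sample_id, contig = s$contig, pos = s$pos,
      ref = ifelse(rev, rc_ref, ref),
      alt = ifelse(rev, revcomp(alt), alt),
      kind = "DBS", channel = channel, process = process,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

place_indels <- function(index, ledger, sample_id, profile, n, process) {
  stopifnot(inherits(profile, "signature_profile"), profile$scheme_id == "ID")
  nonzero <- names(profile$weights)[profile$weights > 0]
  bad <- nonzero[!grepl("^(DEL|INS)\\.[CT]\\.1\\.", nonzero)]
  if (length(bad))
    stop("simulator places 1-bp indel channels only; profile has weight on ",
         bad[1])
  per_channel <- stats::rmultinom(1, n, profile$weights)[, 1]
  genome <- index$genome
  out <- list()
  for (channel in names(per_channel)[per_channel > 0]) {
    k <- per_channel[[channel]]
    parts <- strsplit(channel, ".", fixed = TRUE)[[1]]
    type <- parts[1]; base <- parts[2]; runlab <- parts[4]
    bases <- if (base == "C") c("C", "G") else c("T", "A")
    run_min <- as.integer(sub("\\+$", "", runlab))
    exact <- !grepl("\\+$", runlab)
    placed <- 0L
    rows <- vector("list", k)
    if (type == "INS" && runlab == "0") {
      # inserted base must match neither neighbour: rejection-sample sites
      tries <- 0L
      while (placed < k && tries < 1000L * k) {
        tries <- tries + 1L
        ctg <- sample(names(genome$contigs), 1)
        L <- genome$lengths[[ctg]]
        p <- sample.int(L - 2L, 1) + 1L
        b <- sample(bases, 1)
        if (substr(genome$contigs[[ctg]], p, p) == b ||
            substr(genome$contigs[[ctg]], p + 1L, p + 1L) == b) next
        if (!claim_site(ledger, ctg, p, 1L)) next
        placed <- placed + 1L
        anchor <- substr(genome$contigs[[ctg]], p, p)
        rows[[placed]] <- data.frame(
          sample_id = sample_id, contig = ctg, pos = p, ref = anchor,
          alt = paste0(anchor, b), kind = "INS", channel = channel,
          process = process, stringsAsFactors = FALSE)
      }
      if (placed < k) stop("exhausted genomic sites for channel ", channel)
      out[[channel]] <- do.call(rbind, rows)
      next
    }
    # run-based channels: pick a homopolymer run of the right base & length
    cand <- list()
    for (ctg in names(index$runs)) {
      r <- index$runs[[ctg]]
      ok <- r$base %in% bases & r$start > 1L &
        (if (exact) r$len == run_min else r$len >= run_min)
      cand[[ctg]] <- which(ok)
    }
    n_cand <- sum(lengths(cand))
    if (n_cand == 0) stop("no genomic site matches channel ", channel)
    ctg_vec <- rep(names(cand), lengths(cand))
    idx_vec <- unlist(cand, use.names = FALSE)
    perm <- sample.int(n_cand)
    for (j in perm) {
      if (placed == k) break
      ctg <- ctg_vec[j]
      r <- index$runs[[ctg]][idx_vec[j], ]
      width <- r$len + (if (type == "INS") 1L else 0L)
      if (!claim_site(ledger, ctg, r$start - 1L, width)) next
      placed <- placed + 1L
      anchor <- substr(genome$contigs[[ctg]], r$start - 1L, r$start - 1L)
      if (type == "DEL") {
        rows[[placed]] <- data.frame(
          sample_id = sample_id, contig = ctg, pos = r$start - 1L,
          ref = paste0(anchor, r$base), alt = anchor, kind = "DEL",
          channel = channel, process = process, stringsAsFactors = FALSE)
      } else {
        rows[[placed]] <- data.frame(
          sample_id = sample_id, contig = ctg, pos = r$start - 1L,
          ref = anchor, alt = paste0(anchor, r$base), kind = "INS",
          channel = channel, process = process, stringsAsFactors = FALSE)
      }
    }
    if (placed < k)
      stop("exhausted genomic sites for channel ", channel)
    out[[channel]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Simulate a full clonal exposure study
#'
#' Generates the reference, optional non-overlapping gene models with
#' log-normal expression values, and all clones: control clones carry the
#' background process only, exposed clones background plus exposure.
#' When `expression_rate_slope` is set, every clone additionally gains
#' per-gene SNVs at `slope * expression` mutations per Mb of footprint,
#' placed uniformly within the gene. Fully reproducible from
#' `config$seed`; when `dir` is given, the reference FASTA, one VCF per
#' clone, the truth table, gene BED, expression TSV and a sample sheet
#' are written there.
#'
#' @param config A `simulation_config`.
#' @param dir Optional output directory (created if needed).
#' @return A `simulated_study`: list with `genome`, `index`, `clones`
#'   (named list of `mutation_records`), `truth` (combined truth table),
#'   `genes` (`gene_models` or NULL), `sample_sheet` (data frame:
#'   sample, group, vcf) and `config`.
#' @export
simulate_study <- function(config, dir = NULL) {
  genome <- simulate_reference(config)
  index <- build_genome_index(genome)

  set.seed(config$seed * 1000L + 999L)
  genes <- NULL
  if (config$n_genes > 0) {
    genes <- place_genes(genome, config$n_genes, config$gene_length_bp)
    expr <- stats::setNames(
      round(stats::rlnorm(config$n_genes, meanlog = log(10), sdlog = 1), 4),
      genes$table$name)
    genes <- gene_models_from_granges(genes$granges, expression = expr)
  }

  background <- list(name = "background", burden = config$background_burden,
                     sbs = config$background_signature,
                     dbs = config$background_dbs_signature,
                     id = config$background_id_signature,
                     dbs_fraction = config$dbs_fraction,
                     indel_fraction = config$indel_fraction)
  exposure <- list(name = "exposure", burden = config$exposure_burden,
                   sbs = config$exposure_signature,
                   dbs = config$exposure_dbs_signature,
                   id = config$exposure_id_signature,
                   dbs_fraction = config$dbs_fraction,
                   indel_fraction = config$indel_fraction)

  sheet <- data.frame(
    sample = c(paste0("control_", seq_len(config$n_control_clones)),
               paste0("exposed_", seq_len(config$n_exposed_clones))),
    group = rep(c("control", "exposed"),
                c(config$n_control_clones, config$n_exposed_clones)),
    stringsAsFactors = FALSE)

  clones <- list(); truth <- list()
  for (i in seq_len(nrow(sheet))) {
    procs <- if (sheet$group[i] == "control") list(background) else
      list(background, exposure)
    sim <- simulate_clone(index, sheet$sample[i], procs,
                          seed = config$seed * 1000L + i)
    if (!is.null(genes) && !is.null(config$expression_rate_slope)) {
      extra <- expression_coupled_snvs(genome, genes, sheet$sample[i],
                                       config$expression_rate_slope)
      if (nrow(extra)) {
        sim$truth <- rbind(sim$truth, extra)
        sim$records <- mutation_records(sim$truth$sample_id, sim$truth$contig,
                                        sim$truth$pos, sim$truth$ref,
                                        sim$truth$alt, sim$truth$kind)
      }
    }
    clones[[sheet$sample[i]]] <- sim$records
    truth[[sheet$sample[i]]] <- sim$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  study <- structure(list(genome = genome, index = index, clones = clones,
                          truth = truth, genes = genes,
                          sample_sheet = sheet, config = config),
                     class = "simulated_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

# non-overlapping placement: one gene per disjoint slot of twice the
# gene length, at a random offset inside its slot
place_genes <- function(genome, n_genes, gene_length_bp) {
  slot <- 2L * gene_length_bp
  per_ctg <- pmax(genome$lengths %/% slot, 0L)
  if (sum(per_ctg) < n_genes)
    stop("genes do not fit: ", n_genes, " genes of ", gene_length_bp,
         " bp need more than ", sum(genome$lengths), " bp of genome")
  slots <- data.frame(
    contig = rep(names(genome$contigs), per_ctg),
    k = unlist(lapply(per_ctg, seq_len), use.names = FALSE))
  pick <- slots[sort(sample.int(nrow(slots), n_genes)), , drop = FALSE]
  offset <- sample.int(gene_length_bp, n_genes, replace = TRUE) - 1L
  start0 <- (pick$k - 1L) * slot + offset        # 0-based
  gr <- GenomicRanges::GRanges(
    pick$contig, IRanges::IRanges(start0 + 1L, start0 + gene_length_bp))
  gr$name <- sprintf("gene%03d", seq_len(n_genes))
  gene_models_from_granges(gr)
}

expression_coupled_snvs <- function(genome, genes, sample_id, slope) {
  gr <- genes$granges
  tab <- genes$table
  out <- list()
  for (g in seq_len(nrow(tab))) {
    fp_mb <- tab$footprint_bp[g] / 1e6
    n <- stats::rpois(1, slope * log1p(tab$expression[g]) * fp_mb)
    if (n == 0) next
    iv <- gr[gr$name == tab$name[g]]
    # sample positions uniformly over the merged footprint
    w <- GenomicRanges::width(iv)
    which_iv <- sample.int(length(iv), n, replace = TRUE, prob = w)
    pos <- GenomicRanges::start(iv)[which_iv] +
      floor(stats::runif(n) * w[which_iv])
    ctg <- as.character(GenomicRanges::seqnames(iv))[which_iv]
    ref <- substring(genome$contigs[ctg], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                  USE.NAMES = FALSE)
    out[[g]] <- data.frame(sample_id = sample_id, contig = ctg, pos = pos,
                           ref = ref, alt = alt, kind = "SNV",
                           channel = NA_character_,
                           process = "expression_coupled",
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), contig = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      channel = character(0), process = character(0)))
  do.call(rbind, out)
}

#' Write a simulated study to disk
#'
#' @param study A `simulated_study`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(study$genome, file.path(dir, "reference.fa"))
  sheet <- study$sample_sheet
  sheet$vcf <- paste0(sheet$sample, ".vcf")  # relative to the study directory
  for (i in seq_len(nrow(sheet)))
    write_vcf(study$clones[[sheet$sample[i]]],
              file.path(dir, sheet$vcf[i]), genome = study$genome)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$genes))
    write_gene_models(study$genes, file.path(dir, "genes.bed"),
                      file.path(dir, "expression.tsv"))
  invisible(dir)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study: %d clone(s), %d mutations, %d bp genome>\n",
              length(x$clones), nrow(x$truth), sum(x$genome$lengths)))
  invisible(x)
}
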