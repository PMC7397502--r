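---
title: "Methods: from clone VCFs to exposure signatures and selection statistics"
author: "exposig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from clone VCFs to exposure signatures and selection statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental design this package models

A clonal carcinogen-exposure experiment compares somatic mutations in
single-cell-derived clones expanded after an in vitro exposure against
clones from unexposed cultures of the same tissue. Because each clone
amplifies the private mutations of one founding cell to detectable
allele fractions, whole-genome sequencing of a handful of exposed and
control clones yields clean per-clone mutation sets. `exposig` takes the
analysis from there: per-clone VCFs in, mutational signatures, catalogue
comparisons and selection statistics out. A simulator generates
synthetic studies with the same structure so the entire pipeline is
testable without sequencing data.

# Channel schemes and classification conventions

Three standard channel schemes are implemented (`channel_scheme()`), and
their label tables ship as TSV fixtures that tests pin bit-exactly:

* **SBS96** — single-base substitutions in trinucleotide context. Every
  substitution is reported by the pyrimidine of the mutated base pair:
  if the reference base is A or G, the mutation is projected onto the
  opposite strand (ref and alt complemented, flanks
  reverse-complemented and swapped). 6 substitution classes x 16 flank
  pairs = 96 channels, and enumerating all 192 strand-explicit
  (trinucleotide, alt) combinations hits each channel exactly twice —
  a property the test suite asserts.
* **DBS78** — doublet substitutions, collapsed by reverse complement
  onto 10 canonical reference doublets. For the four palindromic
  doublets (AT, CG, GC, TA) the canonical alternate of each
  `{alt, revcomp(alt)}` pair is fixed by the shipped label table; any
  fixed choice is valid provided data and catalogues use the same one,
  which sharing one normative table guarantees. All 144 two-base
  substitutions collapse to exactly 78 channels.
* **ID** — the 83-channel small-indel scheme. 1-bp events are labelled
  by event type, pyrimidine-collapsed base (G counts as C, A as T) and
  homopolymer run length; longer events by length and repeat-unit
  count, with microhomology sub-classification for deletions at
  non-repetitive sites.

Two indel conventions matter and are applied consistently:

* **Left alignment.** Indels are shifted maximally 5'-ward against the
  reference at load (`left_align_indels()`), giving every event in a
  repeat tract one canonical placement. A consequence worth knowing: a
  deletion written inside a partial tandem repeat can slide into the
  repeat's canonical frame, where it is classified as a repeat
  deletion rather than a microhomology deletion — that is the intended
  behaviour, matching how the scheme distinguishes the two.
* **Run length.** For deletions the homopolymer run includes the
  deleted base (deleting one C from `CCC` is `DEL.C.1.3`); for
  insertions it is the run of reference bases matching the inserted
  base. Runs are counted in both directions from the event, which
  makes the classification strand-symmetric — reverse-complementing a
  mutation and its genome never changes its channel, for any scheme.

Adjacent same-clone SNV pairs are merged into doublets before
cataloguing (`merge_adjacent_snvs()`), since callers emit doublets
either way. Runs of three or more adjacent SNVs fit neither scheme;
they are flagged and excluded from SBS and DBS catalogues rather than
silently split, and surface in the skipped-record accounting. Any
channel computation that touches an `N` base skips the record with a
counted warning.

# Catalogues and the class-level summary

`build_catalog()` tallies classified mutations into a samples x
channels count matrix over the full canonical channel set; row sums
always equal the number of classified records, a conservation property
the tests assert against brute-force tallies. For the six-class summary
(`class_percentages()`), percentages are computed **per clone and then
averaged** — clones are biological replicates, so the spread across
clones is the error bar, and the standard deviation uses the n-1
denominator. The accompanying one-way ANOVA (`class_anova()`) treats
the six substitution classes as factor levels with clones as
replicates, followed by Tukey's HSD over all 15 class pairs. Two
degenerate inputs get defined answers: no between-class variation gives
F = 0, p = 1; zero residual variance gives a p reported at the smallest
representable positive value rather than an exact zero.

# Deriving an exposure signature

Exposed clones carry background plus exposure mutations; control clones
background alone. `derive_exposure_signature()` therefore estimates the
exposure process as the per-channel **mean count across exposed clones
minus the mean across control clones**, floors negative excesses at
zero, and renormalises to a probability vector. Subtracting means of
counts (rather than proportions) is the default because all clones
share one genome and comparable coverage in this design, making counts
directly comparable; a `pooled` mode (pool within group, scale to a
per-clone basis) is provided as a sensitivity check and agrees with the
default under equal weighting. No pseudocount is added by default — a
smoothing constant would silently move weight into empty channels of a
sparse catalogue — but a `pseudocount` argument exists for users who
want it. When no channel shows positive excess the function raises an
error rather than returning a zero vector: that situation means the
data contain no exposure-attributable signal and downstream cosine
ranking would be meaningless.

The derived profile records its support (total positive excess, a
measure of how many mutations back the signature) and provenance
(derivation mode and group sizes).

# Comparing against signature catalogues

`cosine_similarity()` is the standard shape comparison for non-negative
profiles; `rank_matches()` scores a derived profile against every
column of a user-supplied catalogue TSV, sorting with a stable tie
rule (catalogue order) so reports are deterministic. `fit_exposures()`
refits the profile as a non-negative combination of catalogue
signatures by active-set NNLS; tests require agreement with a dense
1e-3 grid search on two-signature problems, so the optimiser is
interchangeable as long as it meets that contract. No reference
catalogue is bundled — COSMIC files are ordinary input TSVs — keeping
the package download-free and catalogue-version-agnostic.

# Selection statistics

**Gene over/under-mutation.** The null is uniform random placement over
an effective genome: a gene of footprint `f` in a genome of size `G`
with `N` total mutations expects `lambda = N f / G`. Tail probabilities
use Poisson by default (`p_over = P(X >= obs)`, `p_under = P(X <=
obs)`), with exact binomial as an option; the two agree closely
whenever `f/G` is small. Over- and under-mutation are controlled as
**two separate one-sided FDR families** (Benjamini-Hochberg at 0.05
each), mirroring how overmutated and protected gene lists are reported
separately. For processes with strong context preferences,
`context_weighted_footprint()` reweights footprints by the signature's
trinucleotide composition, giving a context-adjusted null; it is off by
default because the uniform null is the stated baseline.

**Mutation rate versus expression.** Genes with expression values are
ranked and split into equal-size bins (deciles by default); each bin's
rate is mutations per Mb of footprint, regressed by OLS on the bin's
expression midrank (default), mean expression, or mean log1p
expression. The log option exists because expression is right-skewed
in essentially all transcriptome data: on the raw scale the top bin is
simultaneously the highest-leverage and highest-variance point, which
destabilises OLS inference, whereas log-expression spreads bins evenly.

# The synthetic study generator

`simulate_study()` emulates the clonal design: an i.i.d. random genome
at a set GC fraction (default 0.42, a realistic mammalian value), 3
control clones drawn from a background process and 4 exposed clones
from background + exposure (the default group sizes), written as VCFs
with a sample sheet, truth table, gene BED and expression TSV.

* **Burdens** are Poisson per clone per process; defaults of 3000
  background and 5000 exposure mutations per clone represent clones
  with a clearly detectable exposure signal over a realistic
  spontaneous background.
* **Signatures.** The shipped toy background is enriched for C>T and
  T>C transitions (with extra weight at CpG-like contexts), the
  pattern spontaneous tissue-culture backgrounds show; the toy
  exposure concentrates 80% of its weight in C>A transversions with a
  5' preference, with CC>AA-dominated doublets and single-C-deletion
  indels as companion processes. These are deliberately *toy*
  profiles: recognisable, strongly separated, and not copies of any
  reference catalogue entry.
* **Placement honours context.** Mutation channels are drawn from the
  signature, then a genomic site whose trinucleotide (or doublet, or
  homopolymer run) matches the channel on either strand is drawn
  uniformly from a precomputed index. Sites are never reused within a
  clone and claimed sites block their immediate neighbours, so no two
  simulated events are adjacent — which is what lets the truth table
  assert that classification recovers the generating channel for 100%
  of records. Indel placement supports the 1-bp channels, which is
  what the toy indel signatures use; longer-indel channels are
  classified but not simulated.
* **Expression coupling.** With `expression_rate_slope` set, each gene
  receives extra uniformly placed SNVs at `slope * log1p(expression)`
  per Mb per clone. The log-scale coupling matches how expression
  effects are modelled for right-skewed (log-normal) expression and
  keeps bin variances comparable in the recovery analysis.
* **Reproducibility.** One master seed fans out as
  `seed * 1000 + clone_index` per clone (a fixed, documented
  derivation), so studies are byte-identical under a repeated seed and
  clones are individually reproducible.

What the simulator does *not* model: sequencing and calling errors,
subclonal structure, chromatin- or replication-timing-dependent
mutation rates, and real genome composition (repeats, GC
heterogeneity). Passing recovery tests therefore demonstrates the
pipeline's correctness on clean clonal data, not robustness to caller
artefacts.

# Verification problem sizes and numerical choices

The test suite and the acceptance script verify the pipeline at these
sizes, chosen to make the statistical checks well-powered while the
checks stay comfortably reproducible on a single CPU:

* Signature recovery: 10 studies of 3+4 clones on a 1 Mb genome,
  background 3000 / exposure 5000 per clone; recovery cosine vs the
  generating signature (observed ~0.999, required >= 0.95) and
  top-rank identification among 9 random decoys.
* Null calibration: 200 genes with log-normal lengths (median 10 kb) on
  a ~2.5 Mb gene-dense genome, 50,000 uniform mutations, 20 replicates.
  The mutation count is set so per-gene expectations are large (~200),
  keeping the discrete Poisson p-value distribution close to uniform;
  with small expectations the attainable test levels sit visibly below
  nominal and calibration checks would conflate discreteness with
  miscalibration.
* Regression recovery: 120 genes of 10 kb on a 3 Mb genome, 20 bins,
  true slope 300 mutations/Mb per log-expression unit against a
  background of 4000 mutations per clone; the fitted slope is required
  to land within 2 standard errors of truth in >= 9/10 seeds. The
  matching log-scale regressor keeps residuals near-homoscedastic, and
  20 bins give the SE estimate enough degrees of freedom that +-2 SE
  has close to its nominal coverage.
* Oracle agreements (Poisson tails vs direct pmf summation at 1e-10;
  NNLS vs 1e-3 grid search) run on fixed small grids in seconds.

Other numerical choices: signature vectors are renormalised to sum to
one at load with a 1e-6 tolerance on the input; cosine values are
clamped to [0, 1] against round-off; ranking ties preserve catalogue
order; the ANOVA and regression degenerate cases are pinned to defined
values as described above.

# Known limitations

* The control-normalisation arithmetic (mean-subtract with zero floor)
  is the simplest estimator consistent with the exposed-vs-control
  design; it ignores per-clone coverage differences, which real data
  may need (a rate-per-Mb variant would slot into the same interface).
* The ID scheme's longer-indel channels are classified but not
  exercised by the simulator, so their coverage comes from constructed
  unit tests only.
* The effective genome size for the enrichment null defaults to the
  full reference length; for real genomes the callable fraction should
  be supplied instead.
* De novo signature extraction (NMF across cohorts) is out of scope by
  design: the package derives signatures by control subtraction and
  compares them to catalogues by refitting.
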