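---
title: "Annotation depth artifacts in TPM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation depth artifacts in TPM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcripts-per-million is a *relative* abundance measure,

$$tpm_i = 10^6\,\frac{x_i / y_i}{\sum_{j=1}^{n} x_j / y_j},$$

with $x_i$ the reads mapped to transcript $i$, $y_i$ its length, and the
denominator $S = \sum_j x_j/y_j$ running over every transcript *annotated in
the reference used for quantification*. Because tpm always sums to one
million per sample, the value assigned to any one gene depends on how many
other transcripts were annotated and how many reads they absorbed. Reference
transcriptomes for pre-clinical species (cynomolgus monkey, dog, rat, mouse)
annotate far fewer transcripts per gene than the human reference — roughly
20–75% as many — so a human sample and a species sample quantified against
their own references are not on the same scale, even for one-to-one
orthologous genes. `tpmdepth` builds a fully synthetic, seed-reproducible
world in which every ingredient of this confounding is explicit and
measurable, and implements the correction that restores comparability
(TMM rescaling of tpm over expressed orthologs).

Three mechanisms are modelled separately:

1. **Denominator shrinkage.** Removing annotated transcripts that carried
   reads shrinks $S$; every surviving tpm is multiplied by exactly
   $S/S'$ when counts are unchanged. This is the closed-form "removal law"
   asserted to 1e-9 in the tests.
2. **Read-map competition.** A read compatible with several transcripts is
   assigned fractionally; when a competitor (a paralog, or a sibling
   isoform) is missing from the annotation, its share of the ambiguous
   reads migrates to the transcripts that remain. This inflates mapped
   reads — not just tpm — for low-expression genes whose competitors are
   poorly annotated.
3. **Length drift.** Historically over-estimated gene lengths depress the
   per-length rate $x/y$ without adding reads, deflating tpm by a closed
   form of the same equation.

## The synthetic world

### Transcriptomes

`forge_transcriptome()` builds genes from abstract *blocks* (sequence
segments). Reads are never nucleotide strings: a read records the
transcript it came from and the block it covers, and its compatibility set
against any annotation is the set of transcripts containing that block.
This is deliberately the coarsest model that still produces the read
competition mechanism; base-level alignment, error models, strandedness and
fragment-length distributions add nothing to the mechanism under study and
are out of scope.

Defaults (all overridable through `experiment_config()`):

* **Isoform counts**: zero-truncated negative binomial, truncated mean 7
  (human-like) with dispersion 2; species profiles use truncated means of
  about 1.5–5, which lands transcripts-per-gene ratios in the observed
  20–75% band. Real per-species isoform-count distributions are only
  summarized in the source material, so these are stated, configurable
  placeholders.
* **Backbone lengths**: lognormal with median 2.5 kb (sdlog 0.6), a
  reasonable mRNA length scale. The first isoform carries all blocks of
  its gene; later isoforms keep the gene core block plus a random subset
  (p = 0.6), so all isoforms of a gene compete for core reads.
* **Paralog families**: 20% of genes, family sizes 2–6, with family-shared
  blocks covering a per-family fraction of 30–70% of each member's
  backbone. Shared blocks are the only cross-gene homology, so block
  sharing across genes occurs within families only — an invariant the
  `annotation()` validator enforces.

### Expression and reads

`simulate_expression()` draws gene weights log-uniformly over
`dynamic_range_log10` decades (default 4.5) and splits them across isoforms
with a symmetric Dirichlet. Two genes are pinned to the ends of the range
so the realized span equals the request exactly, and on a 500-gene forge
the full-annotation gene tpm populates every log10 bin between 0.5 and 4.5
— the binning used to pick stratified control genes. `simulate_reads()`
samples an origin transcript with probability proportional to
$\theta_i \times y_i$ (longer transcripts shed more fragments, the standard
generative model implied by the per-length rate in the tpm equation), then
a block position uniform along the transcript. `thin_reads()` models
sequencing-depth disparity as independent Bernoulli retention.

What a green test does *not* establish: the generator has no sequence
errors, no positional bias, no multi-sample biological variability, and a
log-uniform expression law rather than an empirical one. Effect sizes
measured here (e.g. the magnitude of depth-driven median shifts) are
properties of this stated world, not estimates of any real dataset's
values; only the directions and the algebraic identities transfer.

## Quantification

`assign_reads()` is a desk-scale stand-in for a lightweight quantifier.
Reads are grouped into equivalence classes by compatibility set; uniquely
compatible reads count 1.0; ambiguous reads are split by EM. Because the
covered block is observed, the within-class posterior is proportional to
$\theta_t$ alone (the length terms cancel against the uniform position
density), and the M-step is the classic $\theta_t \propto x_t / y_t$
update. Defaults: 1000 iterations, tolerance 1e-8 on the maximum absolute
abundance change; fully symmetric transcripts stay at the equal-split fixed
point of the uniform initialisation. The tests verify EM against an
exhaustive grid-search maximiser of the observed-data likelihood on small
instances.

Numerical notes:

* Unmapped reads (empty compatibility against the quantified annotation)
  are excluded from counts, from $S$, and from `n_mapped` — this exclusion
  *is* the denominator-shrinkage mechanism.
* tpm uses the raw transcript length as printed in the defining equation;
  no effective-length correction exists because there is no fragment-length
  machinery. This changes absolute tpm but none of the depth artifacts.
* Gene values are plain sums of member-transcript counts and tpm
  (abundance summation); no count re-scaling from abundances.
* Equivalence-class allocations are fractional doubles; "counts equal"
  assertions in degenerate constructions hold to 1e-9–1e-12, while
  EM-adjacent comparisons use the convergence tolerance.

## Annotation experiments

* `subsample_sweep()` re-creates the subsampling protocol: control
  transcripts are removed from the pool first and re-inserted into every
  subsample; subsample sizes are round-half-up of fraction × pool (minimum
  1). At protocol scale (1–99% × 100) it emits exactly 9,900 annotations.
  The control set is an arbitrary transcript set; by default the experiment
  runner uses the complete isoform sets of the 10 stratified control genes,
  since the protocol's per-gene framing requires the genes to be fully
  represented everywhere.
* `preclinicalize()` reduces every ortholog gene to its species-level
  transcript count. "Random with replacement" is interpreted as independent
  re-draws *across* replicates with within-replicate sampling without
  replacement — duplicate transcript ids inside one annotation are
  ill-defined.
* `remove_paralogs()` deletes cross-gene family competitors of target
  genes, the operation that reduces (but does not eliminate) tpm
  multi-modality across sweep replicates.
* `vary_gene_lengths()` emulates historical length drift parametrically.
  Padding appends never-expressed, never-mappable blocks (length grows,
  counts cannot); trimming removes whole tail blocks, so the realized
  factor is block-granular. Replaying real historical releases is out of
  scope.

## Statistics

`inflation_significance()` runs Kruskal–Wallis across fraction groups of
the per-gene log10 tpm differences, then Dunn's post hoc (hand-rolled
rank-sum z statistics with tie correction — no Dunn implementation ships
with the pre-installed stack) of each fraction against the largest
fraction, with Benjamini–Hochberg adjustment at $\alpha = 0.05$. The
reference-group design matches the framing of divergence from the
fully-described annotation; an all-pairs mode is available. Genes absent or
unexpressed in a subsample are excluded from the test and tallied in a
dropout report — the source protocol does not state a zero-handling rule.
The Kruskal–Wallis grouping unit pools all control-gene differences per
fraction (per-replicate means would also be defensible; pooling is the
default for power at desk scale).

`characterize_inflated_genes()` flags genes whose mean log10 tpm difference
across pre-clinicalized replicates exceeds 0.1 with a positive mean reads
difference, then locates the flagged set's mean expression within 1000
equal-size random gene draws. The 0.1 threshold and the 5th-percentile
reading are artifact conventions (the source identifies such genes
graphically); both are exposed in the configuration.

## TMM correction

`tmm_factor()` is implemented from the trimmed-mean-of-M-values definition:
library-size (column-sum) normalization, M and A on log2 scale, double
trimming (30% of M and 5% of A, each tail, edgeR-style rank cutoffs), and a
precision-weighted mean of the surviving M. One deliberate deviation from
the count-based formulation: the delta-method precision weights are
computed on the *proportion* scale, $(1-p)/p$ summed over the two samples,
not $(N-x)/(Nx)$. This makes the factor exactly invariant to rescaling
either input — an invariant worth having when the inputs are tpm, which
are compositions, not counts — and coincides with the count-based weights
whenever the two column sums are equal (as they are for tpm tables), which
is why the implementation agrees with edgeR's TMM to 1e-8 on tpm-style
input in the test suite.

`normalize_cross_species()` applies the workflow: restrict to one-to-one
orthologs, keep genes strictly above 1 tpm in *both* members of a compared
pair, choose the human reference sample by the upper-quartile convention,
and rescale each sample by `(lib_ref / lib_sample) / factor` — a single
multiplier per sample, so within-sample rank order is exactly preserved.
The reported TMM factor itself is 1 for a pure depth change (library-size
normalization absorbs global multipliers); the depth disparity is carried
by the library-size ratio over the filtered ortholog set, and the TMM
factor corrects the residual composition shift. TMM is computed per tissue
by default ("within organ" medians imply per-tissue framing); passing no
tissue labels treats all samples as one tissue. Diagnostics fix the gene
set at the pre-correction stage so the pre and post medians are computed
over identical genes.

## Known limitations

* Reads are block-resolution; sub-block homology (partial overlaps) cannot
  be expressed.
* The EM likelihood is exact for this generative model but simpler than a
  real quantifier's (no positional/fragment bias, no effective lengths).
* Trimmed-mode length drift is block-granular.
* Real-data magnitudes (the 65% significance boundary, ortholog counts,
  per-tissue medians) are not reproduced and are not targets; the package
  demonstrates mechanisms and directions at desk scale.

## Worked example

```{r}
library(tpmdepth)

ann   <- forge_transcriptome(500, seed = 1)
truth <- simulate_expression(ann, seed = 2)
reads <- simulate_reads(truth, ann, 1e5, seed = 3)

full_q <- quantify_sample(reads, ann)
full_g <- summarize_to_gene(full_q, ann, ann)

ctrl <- stratified_select_genes(full_g, 10, seed = 4)
keep <- ann$transcripts$transcript_id[ann$transcripts$gene_id %in% ctrl]
sch  <- sweep_scheme(fractions = seq(10, 90, 10), reps_per_fraction = 20,
                     keep_set = keep, seed = 5)
anns <- subsample_sweep(ann, sch)
gq   <- lapply(anns, function(a)
  summarize_to_gene(quantify_sample(reads, a), a, ann))
attr(gq, "manifest") <- attr(anns, "manifest")

res <- build_sweep_result(gq, full_g, ctrl)
inflation_significance(res)
```
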