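---
title: "Weighted multimapped quantification of repetitive histone transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multimapped quantification of repetitive histone transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

## The problem

Replication-dependent ("canonical") histone genes occur in dense clusters
of near-identical copies. Two consequences matter for RNA-seq analysis.
First, reads from these genes multimap: a standard pipeline that keeps
only uniquely mapping reads reports little or no coverage for most family
members, not because the transcripts are absent but because no single
locus can claim their reads. Second, canonical histone mRNAs normally end
in a stem-loop instead of a poly(A) tail, so in a poly(A)-selected library
their apparent expression measures how much of the transcript pool has
been aberrantly polyadenylated. A gene-set increase of canonical histones
in such data is therefore evidence of disturbed 3' end processing, and
quantifying it requires rescuing the multimapped reads.

`histoquant` packages the full procedure and enough scaffolding to verify
every stage on synthetic data with known truth.

## The procedure

For one sample, every alignment record carries the total number of loci
`n` its read mapped to. Records with `n` above the cap (default 10) are
discarded; each surviving record adds `1/n` to every gene whose flattened
exon union it overlaps by at least one base. Summed over a read whose
mappings are all exonic, the contributions are exactly 1, so a gene
family's total weighted count equals its total read count however the
reads are distributed among copies — the property that makes family-level
fold changes estimable even when no individual read can be placed.

Normalization is anchored to references chosen from the data: genes whose
adjusted differential-expression p-value exceeds 0.5 ("unchanging") and
whose counts are positive in every sample (a geometric mean with a zero
factor is undefined). Exactly 50 are drawn uniformly at random under a
required, logged seed — the random draw is otherwise unreproducible. Each
sample's factor is the geometric mean of its reference counts divided by
the mean of the control samples' geometric means, so control factors
average exactly 1 and normalized values stay on the control scale.

Histone counts are floored before division: entries that are exactly zero
("no coverage") become 0.1, the smallest observable coverage; positive
entries below 0.1 are left untouched. The order is fixed — floor first,
then divide — so a zero entry becomes `0.1 / factor`, not 0.1.

Each sample is then collapsed to the geometric mean of its normalized
canonical (or variant) histone counts. The reported fold change is the
ratio of the case and control group means of these per-sample values, and
the p-value a two-sided two-sample t-test on the same values. The test and
the fold change deliberately use the same per-sample summaries: eight
numbers carry the entire inference, as in the underlying 4 vs 4 design.

### Choices the procedure leaves open

Three details are not forced by the description above; the package picks
one behaviour and exposes the alternative behind a flag.

- *Fold change*: ratio of arithmetic group means of the per-sample
  geometric means (default) or ratio of their geometric means
  (`fold_change = "geometric"`). The arithmetic version pairs naturally
  with the t-test performed on the same values.
- *t-test flavour*: Welch (default) or pooled-variance Student
  (`var_equal = TRUE`). With 4 samples per group, Welch costs little and
  guards against unequal variances.
- *RPM boundary*: the expression filter keeps a gene at **exactly** 10
  reads per million ("meeting a minimum threshold" reads most naturally as
  inclusive). The RPM denominator is the per-sample total of assigned
  counts in the matrix being filtered.

Two further interpretations are worth stating. Reads above the cap are
discarded entirely rather than truncated to their best 10 loci — the cap
describes an aligner's reporting limit, and discarding is the conservative
reproduction. A mapping overlapping the exons of two genes contributes its
weight to both; no ambiguity rule is imposed, matching simple coverage
counting. Gene-level "coverage" is interpreted throughout as weighted read
count per gene, not per-base depth, which is what a count-based DE
workflow consumes.

## The synthetic generator

`sim_config()` describes a toy study; `build_toy_genome()`,
`simulate_alignments()`, `simulate_clip_peaks()` and `simulate_ct_table()`
realise it deterministically from a master seed (per-stage and per-sample
substreams are derived by fixed offsets, so samples are independent but
every run is reproducible).

The packaged Scenario S1 encodes the reference design: 4 expressing vs 4
control samples; 34 canonical histone-like genes in families of 2–10
structurally identical copies, true fold change 2.12; 15 unique variant
histone genes, true fold change 0.841; 200 non-differential reference
candidates; 100 other DE genes split half up (fold change 2) and half down
(0.5). Multimapping is modelled at the family level: a read from any copy
is emitted once at every copy with `n` equal to the family size. This
sidesteps sequence-level alignment entirely — the procedure consumes
mapping multiplicities, never sequences — and makes family membership the
exact ground truth for the ambiguity structure.

Counts are negative-binomial with a shared dispersion of 0.05, a typical
replicate-level value for inbred-mouse tissue RNA-seq. No baseline
expression is implied by the design itself, so the generator draws
per-gene baselines lognormally (sdlog 0.8) around a mean of 100 expected
reads per gene — moderate coverage with a realistic spread, including
occasional weakly covered histone genes. These are free choices,
documented here once and not tuned. Polyadenylation-dependent
detectability is modelled simply as the case-group fold change itself:
downstream computation only ever sees counts, so a separate latent
polyadenylation variable would be invisible.

What the generator does **not** emulate: sequence content, quality scores,
positional or GC bias, splicing variation, partially homologous copies
(family copies are all-or-nothing multimappers), or library-size variation
beyond what the count model induces. Passing recovery tests therefore
demonstrates the estimator's correctness under the stated ambiguity and
noise structure, not robustness to alignment artefacts of real repetitive
loci.

## The DE substitute and composition

`de_lite()` is plumbing: group means and Welch t-tests on
`log2(RPM + 0.5)`, BH-adjusted. It stands in for a count-model DE analysis
at desk scale and claims no equivalence with one.

One genuine subtlety deserves its own paragraph. With total-count (RPM)
scaling, a genuine increase of an abundant gene set makes every *other*
gene appear slightly down-regulated — the composition effect. In this
pipeline that matters at the eligibility step: "unchanging" genes are
defined by a large adjusted p-value, and under a composition-shifted
effect estimate that definition selects genes whose counts happened to
drift *with* the shift, biasing the normalization factors and with them
both histone fold changes. Count-model DE tools avoid this by
median-of-ratios scaling, which is robust to a minority of changing
genes. `de_lite()` therefore offers
`normalization = c("total", "median_ratio")`; the pipeline uses
`"median_ratio"` for the eligibility table, and
`median_ratio_size_factors()` is exported. The default remains `"total"`
so the documented RPM contract holds when the function is used directly.

## Numerical choices

- Geometric means are computed in the log domain, `exp(mean(log(x)))`,
  never as `prod(x)^(1/n)`: the direct product overflows past a few dozen
  large counts. Tests pin the two routes against each other where the
  product is finite.
- Zero-variance t-tests (both groups constant) return p = 1 with a warning
  when the groups are equal, and NA with a warning otherwise; `de_lite()`
  sets degenerate genes to p = 1 with a warning count.
- All intervals are 0-based half-open internally (the GTF-lite reader
  converts from 1-based inclusive on input); interval algebra never emits
  zero-length intervals, and UTRs are annotation-provided, never inferred.
- Coverage arithmetic ignores strand; the covered proportion of a feature
  class uses the union of cluster∩feature bases, so it is invariant to
  splitting a cluster into abutting pieces (hit counts are not — both
  behaviours are tested).
- Enrichment of binding among a gene set uses a one-sided Fisher exact
  test on presence/absence, reported with the sample cross-product odds
  ratio. This is a minimal defensible choice for "enrichment", labelled as
  an interpretation in outputs, not a reproduction of any particular
  published test.

## Problem sizes

The recovery checks run Scenario S1 across 20 master seeds (each run: 349
genes, 8 samples, roughly 300k alignment records), chosen so the
across-seed mean fold changes are estimated to about one percent while a
full check completes in about a minute on a laptop core. Null-calibration
checks use 2,000 all-null genes for the type-I rate and two independent
5,000-gene experiments for the concordance null; oracle comparisons
(Benjamini–Hochberg, Fisher, covered-bases, geometric mean) use hundreds
of random small instances.

## Limitations

The package quantifies; it does not align, call peaks, or model
polyadenylation biochemically. The DE substitute is not a count-model
method and should not be used for real inference. Single-isoform flattened
gene models are assumed (exon-union counting); overlapping annotations are
handled by double-assignment, which a practitioner may wish to log and
inspect. Real histone loci include partially homologous copies and
cross-family homology that the all-or-nothing family model does not
represent.
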