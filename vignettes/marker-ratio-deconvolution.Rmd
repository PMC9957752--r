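---
title: "Marker-ratio deconvolution of whole-liver transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-ratio deconvolution of whole-liver transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatodecon)
```

## The estimand and the estimator

Within one RNA-seq library, each transcript `t` is a fraction of the total
transcriptome `T`.  Consider a whole-liver library (subscript L) and a pure
cell-type library (subscript C).  For a gene expressed in exactly one cell
type, the ratio

$$\hat f_c = \frac{t_L / T_L}{t_C / T_C}$$

equals the fraction of that cell type's transcriptome within the whole-liver
transcriptome.  Both numerator and denominator are fractions of their own
library totals, so any linear rescaling of either library cancels; this is
why only *linear* normalizations (to the library total, or to the library
median) are applied upstream — they leave within-library proportions, and
hence the estimator, untouched.

A single marker is noisy, so the ratio is computed for a set of
cell-type-exclusive markers and averaged (`estimate_cell_fraction()`, mean by
default, median available).  The per-type estimates of all nonparenchymal
cell (NPC) types are summed and the hepatocyte fraction is obtained by
subtraction from the whole (`estimate_npc_and_hepatocyte()`).  Hepatocytes
are deliberately *not* estimated from their own markers: isolated-hepatocyte
libraries are unreliable references, both because isolation strongly induces
reactive genes and because hepatocyte preparations retain NPC contamination.
The subtraction route needs no hepatocyte reference at all.

Note the estimand is the cell-type **transcriptome** fraction, not the cell
**number** fraction — cell types differ in transcripts per cell, so a type
contributing 1% of transcripts may be far more than 1% of cells.

With the per-type fractions in hand, a gene expressed in several cell types
is apportioned (`apportion_gene()`): type `c` contributes
$f_c \cdot \mathrm{frac}_c(g) / \mathrm{frac}_L(g)$ of the gene's
whole-tissue expression, the unattributed remainder is the residual, and the
residual can be credited to hepatocytes when no hepatocyte reference profile
exists.  Contributions plus residual sum to 1 by construction; a sum of
contributions exceeding 1 by more than 0.05 is surfaced as a
model-inconsistency warning, never silently corrected, because no sum-to-one
constraint is imposed across cell types.

## Preprocessing

The pipeline order is: remove extraneous biotypes, collapse isoforms,
convert reads to molecule counts, then renormalize.

* `filter_extraneous()` removes ribosomal RNA, mitochondrial RNA and small
  RNA classes.  The default exclusion set is `{rRNA, Mt_rRNA, Mt_tRNA,
  miRNA, snoRNA, snRNA}`; the exact list is configurable because annotation
  vocabularies differ.
* `collapse_isoforms()` keeps, per gene, the isoform with the largest raw
  count in that library.  Ties are broken by the lexicographically smallest
  transcript id purely for determinism.
* `to_molecule_counts()` divides read counts by transcript length in kb.
  Reads are proportional to transcript length at equal molarity, so
  reads/kb is the molecule-count proxy on which transcriptome fractions are
  defined.
* `renormalize()` offers `total` (fractions; idempotent) and `median`
  scaling.  The median is taken over genes with *nonzero* expression only —
  the median of a zero-inflated vector is frequently 0, which would be a
  useless divisor.  Zero-count genes are retained with fraction 0 rather
  than dropped, so gene universes stay aligned across libraries.

Because the estimator depends only on within-library fractions, the choice
between raw molecule counts, total-, or median-normalized inputs does not
change any estimated fraction; this invariance is asserted in the test
suite.

## Marker derivation and surrogate references

`find_cell_specific_genes()` declares gene `g` a marker of type `c` when its
fraction in `c` is at least `min_own_fraction` (default `1e-5`, a solidly
detected transcript in a deep library) and its fraction in every other type
is at most `max_other_relative` (default 0.05) times the own-type fraction.
"Uniquely expressed" has no single canonical operationalization; these two
thresholds make the rule explicit and reproducible, and both are arguments.
A type ending up with fewer than `min_markers` (default 5) markers is an
error rather than a silent degradation, because the averaged ratio needs
several markers for stability.

For cell types without a tissue-derived reference,
`select_surrogate_library()` ranks candidate libraries from other sources by
Pearson correlation with the whole-tissue profile and proposes the best one
as surrogate.  By default the correlation is computed on
`log2(1 + 1e6 * fraction)` values: linear-scale Pearson between RNA-seq
libraries is dominated by a handful of extremely abundant genes, so the
log scale gives a more informative ranking; `log_transform = FALSE`
restores the plain linear correlation.

## Signature scoring and staging

`de_rank()` ranks genes between two conditions by a Welch t-test per gene on
`log2(CPM + 1)` values with Benjamini–Hochberg q-values.  This is a simple
location test that keeps the synthetic pipeline closed and calibrated (its
type-I error is verified at the 5% level in the suite); it is not a
negative-binomial count model, and for real count data a dedicated
differential-expression package is the right engine for this one stage.

`derive_signature()` keeps genes up in the reference condition at
`log2FC >= 1` and `q <= 0.05` (both arguments), ordered by ascending q then
descending fold change, optionally truncated to `top_k`.
`score_samples()` summarizes a signature per sample as the mean across
signature genes of the gene's z-scored `log2(x + 1)` expression across
samples.  This deliberately simple module score is fully specified and easy
to reason about; `method = "rank"` (mean within-sample percentile rank)
is provided as a sensitivity check.  Since the z-score is taken across
samples, the matrix must be comparable across samples already; a guard warns
when sample totals differ by more than 10-fold.

`stage_trend()` tests for a monotone decline of score across ordinal stages
with Spearman's rho against the stage index and a two-sided permutation
p-value.  When the multiset of stage labels admits at most `n_perm` distinct
assignments the null is enumerated exhaustively and the p-value is exact;
otherwise `n_perm` random permutations are drawn with the add-one
correction.  With tied stage ranks (several samples per stage) the
attainable |rho| is bounded below 1; perfect ordering attains the extreme of
the enumerated null rather than exactly ±1.

`stage_classifier()` reproduces the single-gene staging protocol: select two
stage groups, reserve about one quarter of the samples (stratified,
largest-remainder allocation so the training size is `round(f*n)` and each
class quota is within one sample of proportionality) for fitting a
univariate logistic regression, and compute the ROC on the held-out three
quarters.  The AUC is integrated by the trapezoidal rule with half credit
for ties, so it equals the scaled Mann–Whitney U statistic.  Because a
univariate logistic model is a monotone transform of its input, the model
AUC equals the raw-expression AUC (up to slope orientation); both are
reported to expose the equivalence.

## Overlap statistics

`fisher_overlap()` computes the one-sided enrichment p-value of the overlap
of two gene sets as the hypergeometric upper tail of the 2x2 table, with the
sample odds ratio (no continuity correction).  The universe is an explicit
argument — the single biggest lever on overlap p-values — and defaults to
nothing: the caller must say what "detected in both datasets" means.
`pearson_concordance()` correlates matched per-gene vectors, by default
after `log2(x + 1)`.

## What the synthetic generator emulates — and what it does not

`make_reference_set()` builds per-type profiles with log-normal expression
(meanlog 2, sdlog 1 on the reads/kb scale) for genes shared by all types,
and exclusive markers drawn at meanlog 4 — markers model abundant
cell-identity genes, which in real references sit in the upper expression
tail.  Transcript lengths are uniform in [0.5, 10] kb so the reads/kb
conversion is nontrivial.  `mix_whole_tissue()` forms exact convex
combinations of the reference fraction vectors and either returns expected
counts (`noise = "none"`, for closed-form identity checks) or Poisson
resamples (`noise = "poisson"`).  `make_two_condition_matrix()` plants genes
at an exact expected log2 fold change in Poisson counts with log-normal
baselines (meanlog 4 ≈ median 55 counts, a realistic bulk depth per gene).
`make_staged_cohort()` imposes a linear per-stage decrement on the log2
mean of signature genes and one sentinel biomarker gene.

Deliberately not modelled: negative-binomial overdispersion (Poisson only),
batch effects across reference sources, UMI/read-level structure, doublets,
and cross-species ortholog mapping noise.  Passing tests therefore
demonstrate correctness of the estimators under their own model — exact
recovery in the noise-free limit, consistency under Poisson noise,
calibration under the null — not robustness to every artifact of real
libraries.  In particular the real-data caveat that reference libraries come
from heterogeneous sources (and that some immune subtypes cannot be
distinguished in normal tissue) is out of the generator's scope; each
provided library is treated as one cell type.

## Numerical choices and problem sizes

All generators take an explicit integer seed and are bit-reproducible; no
wall-clock seeding anywhere.  Degenerate inputs fail fast with named genes
(nonpositive lengths, all-zero libraries, markers unexpressed in their own
type); a marker with zero *tissue* expression contributes a valid ratio of 0
(the cell type may be absent from the tissue).  Estimated fractions are
clipped to [0, 1] with a warning, and the unclipped per-marker ratios are
always preserved.  The logistic fit runs IRLS to a deviance tolerance of
1e-10 with at most 100 iterations and flags (quasi-)separation rather than
failing.

The validation suite uses panels of 3–6 cell types with 1000–1500 genes and
20 markers per type, Poisson depths of 1e4–1e6 with 50 replicate seeds,
cohorts of 200 samples over 4 stages, and 20-seed null calibrations —
sizes at which the closed-form identities are exercised exactly and the
Monte-Carlo checks have comfortable margins while the whole suite runs in
well under a minute.
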