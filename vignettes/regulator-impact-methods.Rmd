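---
title: "Regulatory impact factors with geometric co-expression metrics: models and methods"
author: "georif authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory impact factors with geometric co-expression metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(georif)
```

## The problem

Diseases such as cancer reshape gene expression, and a central question is
which *regulators* — transcription factors (TFs), epigenetic factors (EFs),
long non-coding RNAs (lncRNAs) — drive those changes. Raw co-expression
networks conflate direct regulation, regulatory cascades and shared
upstream causes. The Regulatory Impact Factor (RIF) approach narrows the
question: given a set of candidate regulators and the genes that are
differentially expressed (DE) between two conditions (e.g. tumor versus
normal tissue), score each regulator by how strongly its *co-expression
with the DE genes changes* between the conditions ("differential wiring").
`georif` implements this scoring under four interchangeable co-expression
measures — Pearson, Spearman, the Fisher information metric, and a Sobolev
metric — and assembles the top-scoring regulators into an interaction
network filtered by the PCIT (Partial Correlation and Information Theory)
algorithm.

## Pipeline and models

### Normalization and differential expression

Counts are normalized with trimmed-mean-of-M-values (TMM) factors: for each
sample against a reference, the weighted mean of log2 expression ratios
after trimming 30% of M-values and 5% of A-values from each tail, weights
being the inverse delta-method variance of M; factors are rescaled to
geometric mean 1. Expression is summarized as
`log2((count + c) / (lib_size * factor) * 1e6)` with pseudocount `c = 0.5`
(configurable). Genes with zero counts in every sample are dropped up
front, with a logged count.

DE genes are called with a deliberately *simplified* negative-binomial
exact test. The NB mean-variance law is `v = mu + alpha * mu^2`. The
common dispersion maximizes the conditional NB log-likelihood given the
per-condition totals (which removes the mean parameter), summed over genes,
on counts rescaled to a common effective library size (rounded half to
even); the maximization is one-dimensional on `alpha` in `[1e-6, 10]` with
tolerance `1e-6`. Tagwise dispersions shrink per-gene conditional-ML
estimates toward the common value with a fixed prior weight of 10
pseudo-samples, `alpha_g = (w*alpha_c + n*alpha_hat_g)/(w + n)` — a
fixed-weight stand-in for full empirical-Bayes weighting, which is out of
scope; a common-only mode is exposed. The exact test conditions the
group-1 total on the grand total, treating the total over `n_k` samples as
NB with dispersion `alpha_g / n_k`, and sums the probabilities of all
splits at most as likely as the observed one (two-sided, capped at 1);
with `alpha = 0` it reduces to the exact binomial conditional of two
Poisson totals. P-values are adjusted by Benjamini-Hochberg, and the DE
call is strict: a gene with FDR exactly at the cutoff is not DE. The
default cutoff is 0.05 and configurable, since published analyses rarely
state it.

A limitation stated up front: the test is *unpaired*. Donor/pair labels
are carried through the containers but not used by the exact test, which
conditions only on group totals.

### Co-expression metrics

For a regulator `j` and DE gene `i`, associations `r1_ij` and `r2_ij` are
computed separately from the samples of each condition, on log2-CPM
profiles.

* **Pearson / Spearman** — sample correlation (Spearman: Pearson on
  mid-ranks). Zero-variance profiles yield a defined association of 0 with
  a warning.
* **Fisher information metric** — profiles are embedded on the probability
  simplex (`to_simplex`: shift by `-min + delta`, `delta = 1e-8 * range`,
  then divide by the sum; a constant profile maps to the uniform point),
  and the Fisher-Rao geodesic is `d(p, q) = arccos(sum_i sqrt(p_i q_i))`.
  We use the convention *without* the leading factor 2, so the range is
  `[0, pi/2]`; the factor only rescales distances and cancels in the
  association mapping. The Bhattacharyya coefficient is evaluated in
  Hellinger form, `1 - 0.5 * sum((sqrt(p) - sqrt(q))^2)`, which is exactly
  1 at `p = q` and avoids cancellation near the minimum.
* **Sobolev metric** — with `w = p - q`, order-`k` distance
  `d^2 = sum_{j=0..k} ||D^j w||^2` where `D` is the *circular* first
  difference; `k = 0` is Euclidean and the default is `k = 1`. The
  circular boundary makes the finite-difference form exactly equal, by
  Parseval, to the spectral form
  `(1/n) * sum_t (1 + |1 - e^{2 pi i t/n}|^2) |w_hat_t|^2`, which the test
  suite uses as an independent oracle. Because a discrete "derivative"
  depends on coordinate order, profiles use the input sample order of the
  count matrix, identically in both conditions; reordering samples changes
  Sobolev distances. This is a prominent, documented property of the
  metric.

Geometric distances become associations by `a = 1 - d / d_max`, strictly
decreasing, with `d_max = pi/2` for Fisher (the theoretical maximum) and,
for Sobolev, the largest distance observed over all regulator-gene pairs in
*both* conditions of the current run (recorded in the result for
reproducibility). The mapping is a declared convention of this package:
the distance-to-correlation mapping used by the original analyses was
never published. Geometric associations are unsigned (`[0, 1]`) by
default; `signed_geometric = TRUE` multiplies each by the sign of the
pairwise Pearson correlation. Log2-CPM was chosen as the common input
scale for all four metrics (raw counts and linear CPM were considered; the
log scale keeps the statistical and geometric branches comparable and is
robust to single extreme samples).

### RIF scores

With `e1_i`, `e2_i` the mean log2-CPM of DE gene `i` per condition:

* Phenotype impact factor: `PIF_i = (e1_i^2 - e2_i^2) / 2` — large for
  abundant, strongly shifted genes.
* Differential wiring: `DW_ij = r1_ij - r2_ij`.
* `RIF1_j = mean_i(PIF_i * DW_ij^2)` — differential wiring to
  high-impact genes. The square on DW follows the original formulation of
  the score; a linear-DW variant is exposed (`rif1_linear_dw`).
* `RIF2_j = mean_i((e1_i * r1_ij)^2 - (e2_i * r2_ij)^2)` — change in
  correlation-weighted predicted abundance.

Both scores are z-standardized across regulators within each metric, and
regulators are ranked by |z| (dense ranks). "Top" regulators are the
union of the top-k by |RIF1 z| and top-k by |RIF2 z| (default k = 10).
Ranking by magnitude, not signed score, reflects that both strongly
positive and strongly negative regulatory impact are reportable; signed
variants are available (`select = "positive"` / `"negative"`). Ties in the
ranking criterion fall back on the raw score (the extreme raw value wins)
and then on the gene identifier, so selection is deterministic.

Relabelling the conditions negates PIF, DW, RIF1 and RIF2 exactly and
leaves |z| ranks and the selected set unchanged; the condition orientation
is therefore an explicit configuration field (`condition1`), never
inferred.

### Regulator network (PCIT)

Direct correlations between selected regulators are pooled-sample Pearson
correlations of log2-CPM over both conditions — PCIT is defined on Pearson
correlations regardless of which association metric produced the ranking
(an option allows the run's own metric instead). For every node pair
(x, y) and every third node z, the three first-order partial correlations
are computed and a trio tolerance `eps` is the mean of the absolute
partial-to-direct ratios (terms with |direct| < 1e-12 are skipped, as are
trios with degenerate conditioning). The edge (x, y) is eliminated if some
z satisfies `|r_xy| <= eps*|r_xz|` and `|r_xy| <= eps*|r_yz|`. Retained
edges must also have |direct correlation| at or above the edge threshold
(default 0.90, read as "survive PCIT AND strong direct correlation"; a
stricter minimum-partial rule is optional). Isolated nodes stay in the
node table, and edge lists are written with lexicographically ordered
endpoints so outputs are byte-stable.

A property of the trio-tolerance rule worth knowing: a *strong* perfectly
mediated edge (say r_xy = 0.81 with r_xz = r_yz = 0.9) is **kept**,
because its vanishing partial correlation drags the trio tolerance down
(`eps = mean(0, 0.743, 0.743) = 0.496` and `0.81 > 0.496 * 0.9`). The
filter prunes edges that are weak relative to their trio — e.g. r_xy =
0.25 via two links of 0.5 is eliminated — not every edge whose partial
vanishes. This follows directly from the published definition and is
asserted by the test suite against a from-the-definition triple-loop
oracle.

## The synthetic-data generator

`generate_null` draws NB counts per gene (log-uniform baseline means,
default range 10-1000; default dispersion 0.1, typical of biological
replicates; 20 + 20 paired samples; Poisson at dispersion 0).
`generate_wired` additionally multiplies planted DE genes' means by their
fold-change in condition 1 and implants differential wiring on the latent
log-mean: a wired regulator shares a per-sample lognormal factor (sd 1 on
the natural-log scale, mean-corrected — chosen once as typical
co-regulated-module variability) with its targets, mixed with weight `rho`
against independent noise, *in condition 1 only*. Counts are Poisson-gamma
around the exponentiated latent. Wiring on the latent scale keeps the
induced correlation controllable; with `rho = 0` no factor is injected and
the output reduces exactly to null-plus-fold-changes. The planted targets
form a coherent up-regulated module (a regulon activated in condition 1),
while background DE genes alternate direction; with alternating target
directions the PIF-weighted RIF1 contributions would cancel by
construction and the fixture could not exercise recovery.

What the generator does *not* emulate: donor effects (pair labels are
structural only), gene length and GC biases, count outliers, and
correlation among background genes. Passing tests on this generator
demonstrate the statistical machinery under its stated model, not
performance on real tissue data.

### Study sizes and what the simulations show

The recovery benchmark (`rif_recovery_run`) uses 300 genes, 20 + 20
samples, dispersion 0.1, 100 planted DE genes at 4-fold change, one wired
regulator (`rho = 0.9`, 20 targets) against 50 decoys. Calibration runs
(`null_calibration_run`) use 2000 null genes, 10 + 10 samples, dispersion
0.4. These sizes keep a full multi-seed study within minutes on one core
while leaving enough genes for the FDR machinery to be meaningful.

Measured behavior at those defaults (100 seeds): the planted regulator
reaches RIF1 rank <= 3 among 51 regulators in about 94% of runs for
Pearson and Spearman and enters the network node set in essentially all
runs; the *geometric* metrics recover it less reliably (Fisher about 63%,
Sobolev about 38% for rank <= 3). The cause is structural, not a bug: a
decoy's own count noise perturbs its distances to *every* DE gene
coherently, a regulator-level random effect that does not average out
across DE genes, whereas correlation-based associations center it away.
Under the unsigned distance-to-association convention this caps
geometric-metric recovery well below the statistical metrics on data where
count noise is comparable to the planted biological factor. Low-noise
fixtures (dispersion 0.02, high baseline means, small background DE set)
let every metric detect the wiring, which is what the unit suite asserts.

## Numerical choices

* BH adjustment via `p.adjust`; validated inputs (p outside [0, 1] error).
* `optimize()` tolerances: 1e-6 for the common dispersion (the quantity
  that matters downstream), 1e-4 for per-gene ML estimates that are then
  shrunk heavily.
* Exact-test ties: outcomes with probability within a relative 1e-10 of
  the observed split count as "at most as likely".
* Fisher `arccos` argument clipped to [-1, 1]; Hellinger-form evaluation
  for accuracy near 0.
* `d_max` guard: an all-identical Sobolev run uses machine epsilon to
  avoid 0/0.
* Equal-library rescaling before the exact test rounds half to even
  (R's `round`).
* All floats are written with `%.17g`, so text round trips are exact to
  well below 1e-9 and reruns are byte-identical.

## Known limitations

* The exact test ignores pairing; a paired design loses power here.
* Tagwise shrinkage uses a fixed prior weight, not estimated.
* The geometric association mapping (`1 - d/d_max`) is this package's
  convention; the original analyses' mapping was not published, so
  numerical RIF values under Fisher/Sobolev are not comparable across
  implementations, though ranks within a run are well-defined.
* The Sobolev metric depends on sample order (see above).
* PCIT keeps strong mediated edges by construction of the trio tolerance.
* Real-data regulator lists must use the same gene identifiers as the
  count matrix; no ID mapping is performed.
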