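---
title: "The scoring card method: model, optimization and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scoring card method: model, optimization and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmseq)
```

## The model

The scoring card method (SCM) classifies protein sequences into two classes
using nothing but dipeptide composition. A *scoring card* assigns each of the
400 ordered dipeptides a propensity score $S_i \in [0, 1000]$; a sequence $P$
of length $L$ is scored as the weighted sum

$$S(P) = \sum_{i=1}^{400} w_i S_i,$$

where $w_i$ is the frequency of dipeptide $i$ among the $L-1$ overlapping
adjacent pairs of $P$. Because the $w_i$ sum to one, $S(P)$ is a convex
combination of card scores and always lies in $[0, 1000]$. Classification is
a strict threshold rule: $P$ is called positive iff $S(P)$ *exceeds* the
threshold.

The initial card (`build_initial_card()`) is purely statistical: the raw
score of dipeptide $i$ is its content in the positive class minus its
content in the negative class, linearly min-max mapped onto $[0, 1000]$.
Class content is computed from **pooled** counts over all class sequences
(not the mean of per-sequence fractions), matching how compositions are
conventionally reported over total residue counts; the per-sequence-averaged
variant is available via `pooled_dipeptide_composition(method = "mean")`.
If every raw difference is equal — possible only in degenerate inputs — all
scores map to the midpoint 500 so that $S(P)$ stays defined.

Amino-acid propensities are derived from the card by averaging, for each
residue $X$, the "40" dipeptide scores that contain $X$: the 20 with $X$
leading plus the 20 with $X$ trailing, so the homodipeptide $XX$ is counted
twice. Only 39 of those dipeptides are distinct; we take the stated count of
40 literally by default and expose the 39-distinct variant
(`derive_aa_propensities(method = "distinct39")`). The two differ by a small
per-residue reweighting and are nearly perfectly correlated in practice.

## Optimization

The card is optimized by an *intelligent genetic algorithm* (IGA) maximizing

$$\mathrm{Fit}(\mathrm{card}) = W_1 \cdot \mathrm{AUC} + W_2 \cdot R,
\qquad W_1 = 0.9,\; W_2 = 0.1,$$

where AUC is the mean rank-based ROC AUC over stratified 10-fold splits of
the training data scored with the candidate card, and $R$ is the Pearson
correlation between the candidate's derived amino-acid propensities and
those of the frozen initial card. The $R$ term is a regularizer: it anchors
the optimized card to the interpretable composition-difference statistics
instead of letting the search drift to an arbitrary high-AUC corner of the
400-dimensional cube.

The IGA operator set is a reconstruction from the orthogonal-experimental-
design GA literature — population size 20, 50 generations, per-gene mutation
probability 0.02 with uniform step ±100, initial population seeded with the
initial card plus uniform ±50 noise, elitism 2 — chosen for observable
optimization gain within seconds on one CPU. None of these values is a
published constant; all are exposed in `iga_config()`. The distinctive
operator is `oa_crossover()`: the 400 genes are partitioned into $k = 15$
contiguous groups and a two-level $L_{16}$ orthogonal array samples 16
balanced group-wise recombinations of the two parents. All 16 rows plus the
second parent are evaluated; the best evaluated candidate becomes one child
(by construction never worse than either parent), and a second child is
composed from the per-factor main-effect analysis of the array. Scores are
clamped to $[0, 1000]$ after every variation step.

Fold assignment is stratified, shuffled once from the CV seed, and then
frozen for the whole run, making fitness a deterministic function of the
chromosome — required both for bit-reproducibility under a fixed seed and
for the monotone best-ever fitness that elitism guarantees.

Two design points were genuinely open and decided as follows:

* **Default threshold of an unoptimized card.** Nothing prescribes one
  before threshold selection; the median of the 400 scores is used as a
  defined placeholder and replaced by `select_threshold()` (exhaustive scan
  of midpoints between adjacent distinct scores, ties broken toward balanced
  sensitivity/specificity, then the smaller threshold) whenever labels are
  available.
* **Subset-selection accuracy.** In the negative-pool resampling protocol
  (`train_with_negative_resampling()`, ten balanced candidate datasets by
  default) the "training accuracy" used to pick the best subset is
  resubstitution accuracy at the selected threshold, since nothing fixes the
  alternative; the per-subset report also carries the CV AUC so users can
  rank by either.

## What the fitness's "cross-validation" does and does not do

The CV inside the fitness restrains the GA from chasing per-fold noise, but
it is **not** an unbiased skill estimate: the initial card is built from all
training sequences and the GA maximizes the fold AUCs directly, so training
data leak into the evaluation through both routes. With 400 free scores and
400 training sequences the leakage is large — on pure-noise data the initial
card alone reaches an in-sample CV AUC near 0.93 and the GA pushes it close
to 1. This is intrinsic to the SCM design, and is why honest performance
claims must come from sequences held out from the whole pipeline. The test
suite therefore measures *skill* on independent draws of the generating
process: at enrichment $\beta = 0$ the held-out AUC of a trained card is
statistically indistinguishable from 0.5 (no signal, no skill), while the
in-sample figure would pass 0.9.

## The synthetic stated world

`generate_dataset()` emulates two sequence classes that differ only by
dipeptide enrichment. Negatives are i.i.d. draws from a background residue
distribution (uniform 0.05 by default, so null behavior is analytically
obvious; a natural-frequency preset is provided). Positives use the same
emission process except that at each position, with probability $\beta$, one
of the enriched dipeptides is emitted as the next two residues. Defaults —
200 positive and 200 negative sequences of length 300, five enriched
dipeptides (`CP`, `CH`, `FF`, `WH`, `PM`, echoing cysteine-proline /
cysteine-histidine heme-coordination motifs), $\beta = 0.05$ — are the
stated benchmark world. Enrichment by *insertion* rather than by shifting
single-residue frequencies makes the signal genuinely dipeptide-level, so a
card must resolve pair order to find it.

What a green test on this world establishes: the pipeline detects planted
pair-level enrichment at a realistic strength, the optimizer improves the
Eq.-style fitness monotonically, and every enriched dipeptide lands in the
top 5% of optimized scores. What it does not establish: performance on real
proteins, whose families, length distributions, and homology structure the
generator deliberately does not attempt to simulate.

## Numerical choices

* AUC is the rank statistic (concordant + half of tied pairs), exact under
  ties; it is checked against an $O(n^2)$ pair-counting oracle.
* The Mann-Whitney p-value is exact (shift-algorithm enumeration over
  doubled midranks, valid under ties) whenever $n_a n_b \le 200$, and a
  tie-corrected normal approximation without continuity correction
  otherwise; the exact branch is checked against full enumeration.
* Matthews correlation with any zero marginal is reported as 0 and flagged.
* Correlations against the packaged published tables use the printed values
  exactly as printed (2-4 significant figures); the ±0.01 test tolerance
  absorbs printing-precision rounding.
* Amino-acid join order is fixed alphabetical by one-letter code everywhere;
  AAindex records (canonical A/R/N/D/... value order) are re-indexed on
  load.
* Card files round-trip at full double precision (`%.17g`); two-decimal
  rendering is display-only.

## Limitations

* The expert second step of the property analysis — choosing *informative*
  properties among the $|R| > 0.5$ candidates — is knowledge-based by
  design and not automated; the package emits the ranked candidate list.
* Headline accuracies published for real heme-binding-protein data are not
  reproducible here: they require the original curated sequence datasets.
  The packaged tables support exact reproduction of every quantity
  computable from printed values, nothing more.
* B-factors are consumed as given in the packaged table; no structure
  parsing is attempted.
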