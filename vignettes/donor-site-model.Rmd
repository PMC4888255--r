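---
title: "Donor splice-site prediction: model, features and evaluation protocol"
author: "spliceSVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Donor splice-site prediction: model, features and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceSVM)
```

## The problem and the unit of analysis

Exon–intron boundaries (donor, or 5′, splice sites) almost always start
the intron with the dinucleotide GT, but genes contain far more GT
dimers than real splice junctions, so the dimer by itself carries
almost no specificity. The unit of analysis in this package is the
**splice window**: a fixed-length nucleotide string with the conserved
GT at a declared offset. The default geometry is 15 nt with GT at
positions 9–10 — eight exonic positions, the dimer, and five intronic
positions. This short window was chosen deliberately: the feature count
below is invariant in the window length, and a 15 nt motif is short
enough to be scored inside NGS short reads. Loaders cut this window out
of the longer records of common benchmark formats (140 nt with GT at
71–72; 38 nt with GT at 9–10), which fixes the exon/intron split of the
15-mer at 8 + 7 — the split forced by the 15 nt benchmark geometry and
adopted here for every input profile.

Windows are held in a `SpliceWindowSet` (a `DNAStringSet` plus labels,
source ids and coordinates) whose validity enforces three invariants:
equal widths, pure A/C/G/T content, and the GT dimer at the geometry
offset. Coordinates are 1-based inclusive on the forward strand
everywhere in user-facing output; re-slicing a source sequence at a
window's `sourceCoord` reproduces the window exactly (this is
property-tested). Records violating any invariant are rejected with a
reason and surfaced through `rejections()`; nothing is dropped
silently, and ambiguity codes are never imputed. Reverse-strand
scanning is available but opt-in (`scanCandidates(..., reverseStrand =
TRUE)`), reporting windows in the reverse-complement frame.

## Frequency models

Two classes of probability models are estimated per label class from
training windows only:

* the **positional model** `p(α at i)`, a 4 × L frequency matrix with
  its extremal sums `M = Σ_i max_α p(α_i)` and `N = Σ_i min_α p(α_i)`;
* the **dependency model** `q(α at i | β at j)` over all `L(L−1)`
  ordered position pairs.

Both use additive smoothing at count level,
`(count + κ) / (n + 4κ)`, with κ = 1 by default. The log-score
features below are undefined at zero frequencies, so the default κ
keeps every score finite; κ = 0 recovers the raw relative-frequency
matrices and is used in the degenerate-case tests. When a conditioning
base was never observed (and κ = 0) the conditional is defined as the
uniform 1/4 — the maximum-entropy convention, which again keeps logs
finite and adds no directional information. The conserved GT columns
are retained in all sums: under a pseudocount-0 model they contribute
`log₂ 1 = 0` to the log scores and symmetric `max = min = 1` amounts
to M and N, so including them is harmless and keeps the bookkeeping
uniform.

## The feature map

Each window maps to up to 344 named features:

| block | features | definition |
|---|---|---|
| positional | `wmm_true`, `wmm_diff` | weight-matrix log score `Σ log₂ p^t(α_i)`; its difference against the false-class model |
| | `ss_true`, `ss_diff` | min–max normalised positional score `100 (Σ p(α_i) − M)/(M − N)`; its class difference |
| dependency | `wam_true`, `wam_diff` | weight-array log score `Σ_{i≠j} log₂ q^t(α_i|β_j)`; its class difference |
| | `sae_true`, `sae_diff` | `2L(L−1) − 2 Σ q^t`; `2Σ q^f − 2Σ q^t` |
| compositional | `di_*`, `tri_*`, `tetra_*` | overlapping k-mer frequencies `n(m)/(L−k+1)`, k = 2, 3, 4 |

The k-mer denominator is the number of overlapping windows `L − k + 1`,
so each k-mer block is a probability vector (each block sums to 1; this
is property-tested). Feature order is fixed by the manifest — model
scores first, then k-mers in lexicographic A<C<G<T order — so feature
matrices are reproducible column-for-column.

The `ss_*` scores as implemented are **deviation-form**: 0 for a window
matching the per-position consensus and negative otherwise. The
classical Shapiro–Senapathy form, `100 (Σp − N)/(M − N)` (100 at
consensus, 0 at anti-consensus), differs only by a constant shift of
100 and is available via `ssVariant = "classical"`. Which form to make
the default was a genuinely open choice; the deviation form is what the
rest of the package (and its frozen feature set) is calibrated to, and
because the two differ by an affine map the downstream SVM with
z-scored features is indifferent between them.

## Feature selection and the frozen 49-feature set

Features are ranked by the F-score
`F(j) = |(x̄_j⁺ − x̄_j⁻)/(s̄_j⁺ − s̄_j⁻)|`, using sample (n−1)
standard deviations — the convention of the feature-selection
literature this statistic comes from; the estimator choice is not
dictated by the formula itself. The selection rule is inclusive:
`F ≥ 1.25`. This ratio form degenerates when the two class spreads
coincide: with equal means it is 0, with unequal means it is undefined
and `fScore()` returns the sentinel `Inf`. Sentinels rank above every
finite score but are never auto-selected — `selectFeatures()` flags
them with a warning and leaves the decision to the analyst, since an
infinite ratio usually signals a degenerate feature rather than a
supremely informative one. The **Chen–Lin F-score** (between-class
squared deviation over summed within-class variances), a natural
alternative reading of the same statistic, is available as
`variant = "classical"`; both variants are affine-invariant and
permutation-invariant (property-tested).

The package ships a frozen manifest, `selected49`, holding the 49
features retained at threshold 1.25 on the human HS3D donor benchmark:
all eight model scores plus 14 di-, 15 tri- and 12 tetramer
compositions. Freezing the list reproduces the cross-species protocol
— selection is done once on human data and the same features are
reused for other species — and makes predictions reproducible without
re-running selection, which would require the original benchmark.

## Classifier

The SVM is `e1071::svm` — the standard R implementation of
C-classification SVMs — with an RBF kernel at γ = 0.2, the operating
point where held-out AUC-ROC stabilises for this feature map, and
probability output via internally cross-validated sigmoid calibration
(seeded through `svmConfig(seed =)`, so training is deterministic).
Two parameters are deliberate package choices where the method leaves
them open:

* **cost C = 1**: the soft-margin cost is not part of the published
  operating point; 1 is the library default and is exposed in
  `svmConfig()`.
* **feature scaling**: z-scoring fitted on the training split is the
  default, because the feature blocks live on wildly different scales
  (log scores in the tens to hundreds, compositions in [0, 1]) and an
  RBF kernel otherwise lets the large-magnitude block dominate the
  distance. `scaling = "none"` preserves the literal unscaled reading.
  Constant features pass through unscaled with a warning rather than
  producing divisions by zero.

A binary call uses the probability threshold 0.5.

## Evaluation protocol

`assembleEvalSets()` draws `nSets` independent data sets by seeded
sampling without replacement at an **exact** true:false ratio (sizes
are maximal under the ratio given the available pools), then partitions
each set into class-stratified folds so every fold preserves the set's
ratio and every window is tested exactly once per set. A 10-set ×
fivefold design yields exactly 50 per-fold (AUC-ROC, AUC-PR) pairs and
their arithmetic means. Inside cross-validation the default
`modelScope = "fold"` re-estimates the frequency models and the feature
scaler from the training folds only — the leakage-safe reading; whether
the original protocol refit the models per fold cannot be determined,
so the pooled behaviour is available as `modelScope = "global"` for
comparison, and the two are not interchangeable in results.

Both areas are computed exactly, sweeping the distinct observed scores
as thresholds (instances sharing a score change classification
together — the exact version of a sweep over probability thresholds,
valid for non-probability scores too):

* **AUC-ROC** is the trapezoid sum over the sweep,
  `Σ { tpr·Δfpr + ½ Δtpr·Δfpr }`, which equals the Mann–Whitney
  pair statistic with ties counted ½ (tested to 1e−9 against a
  brute-force pair-counting oracle).
* **AUC-PR** uses Davis–Goadrich interpolation: between adjacent
  achievable points true positives are stepped with proportionally
  growing false positives, so precision follows
  `x/(x + FP_a + s(x − TP_a))` rather than a straight line. The area
  is integrated in closed form per segment (the integrand is
  `x/(ax + c)`), so no grid error enters; the test oracle is an
  independent fine-grid trapezoid interpolation. The curve is anchored
  at `TP = FP = 0`, which makes the all-tied-scores curve the constant
  at class prevalence; TP = 0 points themselves are excluded from the
  reported curve because precision is undefined there.

AUC-PR is the imbalance-sensitive of the two: on balanced designs it
sits at or above AUC-ROC, while under 1:5 imbalance it drops below —
the qualitative signature the acceptance tests reproduce on the
synthetic benchmark.

## The synthetic generator

`generateWindows()` draws true sites position-independently from a PWM
that places probability `conservation` on the consensus base at every
non-GT position (remainder split over the other bases per the
background distribution), and false sites from the background alone,
with GT forced at the offset in both classes — emulating the partial
conservation around real splice junctions on one side and the
arbitrary genomic context of non-functional GT dimers on the other.
Defaults, fixed once as the package's study conditions:

* `conservation = 0.85` — a strongly conserved donor motif, giving a
  clearly learnable but not trivial signal;
* consensus embedding the canonical donor context `...CAG | GTAAGT...`
  at the geometry's offsets;
* uniform background;
* exact class counts (the ratio is deterministic, not stochastic).

At `conservation = 0.25` with uniform background the two classes are
identical in law — the null case, where the whole pipeline must score
at chance. An optional `dependentPair` mode copies the base at one
position to another with a set probability in true sites only, planting
a pairwise dependency that only the `wam_*`/`sae_*` features can see.

What the generator does **not** emulate matters for interpreting green
tests: real donor sites have position-specific (not uniform)
conservation profiles, composition biases shared between classes,
neighbouring-position dependencies, and false sites drawn from real
exonic/intronic background rather than an i.i.d. model. Passing the
synthetic suite therefore demonstrates that the machinery is correct
and well-calibrated (chance at the null, signal recovery, monotone
response in conservation, the balanced/imbalanced AUC-PR pattern) — it
does not certify the accuracy figures achievable on real benchmark
data, which require the external datasets this package only provides
loaders for.

## Problem sizes and numerical choices

The test suite and the acceptance script run the protocol at reduced
but statistically meaningful sizes, chosen as the package's own
benchmark conditions: 1000 windows/class with one fivefold set for the
null and signal-recovery checks and for the conservation sweep
{0.4, 0.6, 0.8, 0.95}; 500 true sites with two fivefold sets for the
balanced (1:1) and imbalanced (1:5) comparisons; 50/class with ten
sets for the protocol-shape check. Tolerances: frequency-model columns
sum to 1 within 1e−9; AUC-ROC matches its pair-count oracle within
1e−9; AUC-PR matches its grid oracle within 1e−4; the null AUC band is
0.5 ± 0.05 (the sampling width at these sizes); empirical consensus
frequencies are checked at binomial 3σ.

Degenerate inputs are errors, not silent results: empty or mixed-length
training sets, single-class training or test partitions (flagged and
excluded from cross-validation means with a warning), positional
models with `M = N`, zero frequencies reaching a log (the error advises
refitting with a positive pseudocount), and geometry mismatches at
prediction time.

## Limitations

* Donor sites only; acceptor (AG) geometry is out of scope.
* Forward-strand semantics by default; reverse-complement scanning is
  opt-in and reports coordinates in the reverse-complement frame.
* The frozen `selected49` manifest reflects selection on a human donor
  benchmark; for distant genomes re-running `selectFeatures()` on local
  data and passing the resulting manifest is the supported path.
* Model archives are R serialisations (`saveModel()`/`loadModel()`);
  the plain-text interchange formats cover frequency models, manifests,
  feature matrices, curves and evaluation tables, but not the fitted
  SVM state itself.
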