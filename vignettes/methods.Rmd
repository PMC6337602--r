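---
title: "Positional-influence encodings and flexible neural trees for acetylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional-influence encodings and flexible neural trees for acetylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetree)
```

## The problem

Lysine acetylation is identified experimentally at a small fraction of the
lysines a proteome contains, and sequence predictors fill the gap. The
standard formulation treats each lysine-centered peptide window of
`2n + 1` residues as one sample: positive if the central lysine has a
proven acetylation site, negative otherwise. `acetree` implements the full
pipeline for this formulation. This vignette is the package's account of
the model, its assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## Window extraction

Windows are extracted for every `K` in a protein; windows that overrun a
terminus are padded with `X`. Padding keeps feature dimensionality fixed —
the dominant convention among PTM predictors — and is neutral by
construction, since every encoder assigns `X` the property value zero.
Annotations are 1-based residue indices; internally offsets run `-n..n`
with the lysine at 0. An annotation pointing at a non-lysine is rejected by
default (listing the offenders) because it almost always indicates an
off-by-one or a stale sequence version; a skip-with-warning mode exists for
deliberately messy inputs.

Real acetylation corpora are heavily imbalanced (of order 15 negatives per
positive), so `build_dataset()` subsamples negatives to a configurable
ratio (default 1:1, seeded, without replacement). Unannotated lysines are
all treated as negative candidates — an unavoidable label-noise assumption
shared by the field, discussed under limitations. Redundancy reduction is
out of scope: inputs are expected to be pre-filtered (e.g. CD-HIT at 40%
identity), since homologous windows otherwise leak between CV folds.

## Positional-influence encoding

The influence of a neighbor at signed offset `k` is an even function of
`k`: constant `c1`; square-root `a1·|k|^(1/2) + b1`; quadratic
`a2·k² + b2`. Evenness is required because the two flanks play symmetric
roles around the modified residue; the square-root family is evaluated on
`|k|` — the only reading under which it is an even function on `[-n, n]`.

How an influence profile "enriches" a property profile is an open design
point; we use the elementwise product, feature `(p, k) =
influence[k] × property[p, residue_k]`, concatenated property-major. The
rationale is that it reduces exactly to the unweighted property profile
under a constant influence of 1, and (via the pooled variant below) to
weighted amino-acid composition — the special cases the construction is
expected to contain. Two layouts are exposed:

* `reduce = "none"` (default): per-position features, `P × (2n+1)` values.
* `reduce = "sum"`: pooled per property, `Σ_k influence[k] ×
  property[p, residue_k]`, `P` values. Here the influence profile acts as
  a positional matched filter.

Properties default to 13 AAIndex entries (charge, hydrophobicity, surface
accessibility, flexibility, mutability, helix propensities) assembled at
run time from the AAIndex copy in seqinr, and are z-scored per property
across the 20 residues (default on) so that no entry dominates by raw
scale. Rare/ambiguous residues (B, Z, U, O, …) are mapped to `X` on
ingest. Default family coefficients (`c = 57.6`, `a1 = 4.1`, `b1 = 27.1`,
`a2 = −2.7`, `b2 = 67.1`) are values that performed well when tuned on
acetylation benchmarks; the conventional search ranges are `a ∈ [−10, 10]`
and `b, c ∈ [−100, 100]`.

One identifiability caveat motivates several defaults below: any
classifier that normalizes features per column erases positional
weighting entirely (each weight is absorbed into the column's scale), and
a global rescaling absorbs an overall factor. Consequently (i) the
pipeline normalizes features with a *single* global center/scale, never
per column; (ii) configuration scans use the pooled `"sum"` reduction,
where the influence *shape* genuinely changes the information content;
(iii) for the constant family only the sign of `c1` matters, so its grid
in `search_params()` ties — reported as such, not hidden.

## The flexible neural tree

Leaves emit raw feature values; a function node computes
`net = Σ_j w_j·y_j` over its children and emits
`exp(−((net − m)/n_act)²)`. We adopt this scaled-Gaussian reading of the
flexible activation — center `m`, width `n_act` — because both are named
node parameters of the model family; an unscaled reading would leave the
width parameter meaningless. `|n_act|` is clamped to at least `1e-6`
during evaluation to avoid division blow-ups. Scores therefore lie in
`(0, 1]`; classification uses a fixed 0.5 threshold (a score exactly at
the threshold is positive — documented boundary convention), and AUC is
computed from raw scores, so the threshold choice does not affect it.

No optimizer is canonical for FNTs, so the package uses the classical
pairing: genetic programming for structure (tournament size 3, subtree
crossover, subtree/point mutation, elitism; offspring violating the depth
cap fall back to their parent) and particle swarm optimization for the
continuous parameters of the incumbent best tree (constricted swarm,
inertia 0.729, cognitive/social 1.49445, positions clamped to `[−5, 5]`;
the incumbent parameters seed one particle, so PSO never returns a worse
tree). Fitness defaults to RMSE of the score against the 0/1 label;
`1 − AUC` is available for imbalanced data. The master seed is split into
named substreams (initialization, per-generation evolution, per-generation
swarm, CV folds), making each stage independently reproducible.

Default budgets — population 20, 8 generations, 15 particles × 20
iterations, depth ≤ 3, arities {2, 3} — were chosen as the smallest
configuration that reliably drives the synthetic benchmarks below to their
expected operating points on one CPU in seconds; all are tunable through
`train_config()`.

## The synthetic benchmark

`generate_dataset()` emulates exactly the structure the encoders assume: a
position-dependent physico-chemical difference between classes. Negatives
draw residues i.i.d. from a background (default uniform over 20);
positives draw, at offset `k`, from the background tilted by
`exp(effect_size · g(k) · z(residue) / noise_sd)`, where `z` is the
standardized profile of a chosen signal property (default net charge,
apt because acetylation neutralizes the lysine charge) and `g` is the
family profile normalized to maximum 1, optionally truncated at
`signal_span` to create planted-bandwidth problems. Both classes carry a
forced central `K`. Tilted sampling (rather than additive noise on
features) keeps generated windows valid sequences consumable by every
encoder, including one-hot and composition. Ground truth (family, effect,
property, span) is attached to the dataset so recovery experiments are
self-contained.

What the generator does *not* emulate: motif grammars, phylogenetic
redundancy, proteome-realistic background composition, annotation noise,
and class imbalance beyond the configured ratio. Passing tests therefore
demonstrate that the pipeline's machinery is correct and can recover a
planted signal of the assumed form — not that any particular accuracy will
transfer to real proteomes.

Experiment operating points (used by the validation suite, all on one
CPU): learnability uses `n = 12`, 250 + 250 windows, effect 3 (strong —
held-out AUC ≥ 0.9) and effect 0 (chance band). Family recovery uses
effect 1 with 250 + 250 and 4-fold CV: a *moderate* effect is essential,
because at strong effects every family saturates at AUC 1 and the ranking
degenerates to ties; below the ceiling the matched quadratic filter wins
the ranking in ≥ 8/10 seeded replicates. Planted-bandwidth recovery uses
windows of `n = 15` whose signal spans only `|k| ≤ 10` (effect 1,
200 + 200, 2-fold CV): widths beyond the span add amplified noise, so the
scan's best `n` returns to 10. Exact AUC ties in the scan break toward
the smaller window, which is also the cheaper feature set.

## Metrics

Both metric formulations are implemented from their own formulas and
property-tested for equality under the count mapping
(`TP = N+ − N−+`, `TN = N− − N+−`, `FP = N+−`, `FN = N−+`) — the
cross-check that guards each against transcription error. Numerical
conventions: MCC is 0 when its denominator vanishes (any all-one-class
prediction); metrics requiring both classes raise errors rather than
returning NaN; AUC is the Mann–Whitney pair statistic with half credit
for ties, identical to the trapezoidal area under the swept ROC and
invariant under monotone score transforms. Cross-validation folds are
stratified (per-fold class counts within one of each other) because of
the field's class imbalance, with every sample tested exactly once.

## Known limitations

* Negative labels are only "not yet proven positive"; reported
  specificity on real data is optimistic in an unquantified way.
* The FNT objective is non-convex and the search heuristic; different
  seeds give different trees, and only the seeded pipeline — not any
  single tree — is reproducible.
* Per-position encodings at large `n` (325+ features) dilute the GP's
  leaf sampling; the pooled reduction is recommended when `P` properties
  suffice to carry the signal.
* The parameter grid in `search_params()` scores shape, not scale;
  coefficient pairs with equal ratio are equivalent by design.
* Sequences are handled in memory; the package targets benchmark-scale
  corpora (10⁴–10⁵ windows), not whole-proteome scans in one call.
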