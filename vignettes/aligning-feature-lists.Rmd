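---
title: "Aligning LC-MS feature lists with a learned pair classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning LC-MS feature lists with a learned pair classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The correspondence problem

An LC-MS run yields a *feature list*: MS1 precursor signals with m/z
(Th), retention time (RT, minutes), intensity and charge. Comparing
abundances across runs requires knowing which feature in run B is the
same analyte as a given feature in run A. RT drifts between runs — with
gradient ageing, temperature and column effects the drift can be
non-monotonic, which a single monotone warping function cannot repair.
`rtalign` instead combines a piecewise coarse correction with a learned
classifier that judges each candidate feature pair on its local context.

## The model

### Coarse alignment

Each run's RTs are scaled by `rt * target_rt_range / max(rt)` onto a
common range (default 80 min — the gradient length of the cohorts the
method was developed on). Scaling is anchored at zero rather than
min–max: gradients start near zero, so the simple ratio is the least
surprising linear map, and it preserves RT order exactly.

For shift estimation each run is first collapsed to its most intense
feature per m/z (rounded to `mz_round_decimals = 2`); this stabilizes
the pairing against noise features. The scaled axis is cut into
half-open pieces `[k, k+1)` of `piece_width = 1` min. Every feature of a
non-anchor run is paired with the anchor feature nearest in m/z within
`coarse_mass_tol = 0.01` Th (m/z-distance ties break by nearest scaled
RT; features without a partner are ignored), and each piece's mean shift
`anchor RT − sample RT` is *added* to all features of that piece — the
full list, not only the reduced one. The anchor run (by default the
first sample) is the fixed reference. Pieces without pairs apply no
correction; no smoothing is performed across pieces, because each
piece's estimate is already an average over many pairs and
interpolation would invent structure where there is no evidence.

A constant offset on the common axis is removed *exactly* by this
construction (every piece estimates the same mean), which the tests
assert to 1e-9 min. When runs are scaled by their own observed maxima, a
constant pre-scaling offset also changes the scale factor, so removal is
exact only up to a residual of order `c·w·T/M²` (about 0.003 min for a
0.5-min offset on an 80-min gradient) — negligible against the
classifier's tolerance but not against machine precision. This is why
the numerical-exactness check constructs its cohort on the common axis,
while the end-to-end check (full pipeline including per-run scaling)
asserts complete re-matching instead.

### m/z windows

Candidate pairs are only formed inside narrow m/z windows: the feature's
m/z is rounded to `bin_precision = 2` decimals (round half to even, R's
`round()`, for cross-platform determinism) and the window index is
`floor(key / bin_width)` with `bin_width = 0.03` Th. A small epsilon
(1e-7 window units) guards keys that sit one representation error below
an exact grid line. Two features closer than 0.03 Th can straddle a
window boundary and never be compared; an optional overlap mode (each
feature also joins the adjacent window) is available but off by default,
since the default semantics give each feature exactly one window. An
optional per-window intensity filter (highest-intensity feature per RT
window per sample) is likewise off by default.

### The 40-value pair encoding

Inside a window, the per-run lists are sorted by corrected RT, and each
candidate pair is encoded from the two features plus their two
RT-neighbors on each side (missing neighbors at list edges replicate the
terminal feature, keeping all entries on physical scales). Contexts are
paired positionally (i ↔ i, the target at position 3); the fixed 5 × 8
shape implies positional rather than all-to-all pairing. The layout is
Part 2 (differences, positions 1–10), Part 3 (their negations, 11–20),
Part 1 (first run's originals, 21–30), Part 4 (second run's originals,
31–40); within each part, context position *i* occupies slots
(2i−1, 2i) as (RT, m/z). The target pair's difference entries therefore
sit at flat positions 5/6 and 15/16 — the indexing used when reporting
feature importances. Differences are divided by (5 min, 0.03 Th) and
originals by (80 min, 1500 Th), putting all entries on comparable
scales; intensity is deliberately absent, as matching uses RT and m/z
only.

### The classifier

The pair classifier is a feed-forward network, 40 inputs → three hidden
layers → one sigmoid probability unit, with sigmoid activations
throughout, trained with binary cross-entropy and Adam
(betas 0.9/0.999, eps 1e-8), batch size 500, initial learning rate 1e-3
stepped down ×0.1 every 100 epochs, uniform fan-in initialization, and
per-epoch reshuffling. It is written in plain matrix algebra, so
training is bit-reproducible under a seed. The published configuration
of the method uses three 5000-unit layers and 400 epochs; the package
default is three 64-unit layers and 50 epochs, which preserves the
method's geometry (the encoding, loss, optimizer and schedule are
identical) at interactive cost — `net_config(hidden_sizes =
c(5000, 5000, 5000), epochs = 400)` restores the full scale. The output
head is a single sigmoid unit because the loss operates on
probabilities; the decision threshold (0.5) is configurable.

Training pairs come from a ground-truth correspondence: positives are
linked cross-run pairs, negatives are *unlinked* pairs within 0.03 Th —
the near-isobaric hard cases that make this problem difficult. Sampling
is without replacement under a seed and fails loudly (reporting the
available counts) when the requested counts exceed the eligible pools.

### Assembly and quality control

Candidate pairs are gated at |ΔRT| ≤ 5 min (the RT scale of the
difference normalization), scored, thresholded at 0.5, and accepted
greedily in descending score order under a one-to-one constraint (ties:
smaller |Δm/z|, then |ΔRT|, then ids — fully deterministic). Cohorts are
assembled as a star around the anchor: each run is aligned against the
anchor and groups join accepted pairs through their shared anchor
feature. The decoy FDR procedure selects, per m/z window, one non-anchor
run at random; its features form the target set, and a decoy copy
shifted by +`bin_width` in m/z (same RT and neighborhood geometry, one
window over — so none should align) is aligned identically. The estimate
is accepted decoys over accepted targets with a guarded denominator.

### Evaluation

Precision and recall are means over sample pairs of
|A_k ∩ G_k|/|A_k| and |A_k ∩ G_k|/|G_k|. A sample pair with an empty
aligned set contributes 0 to the precision mean — the ratio is undefined
there and 0 is the conservative choice; it is reported with a message.
For real data, ground truth comes from mapping identifications onto
features (±10 ppm, identification RT inside the feature's elution
bounds; features without bounds use a ±0.5-min window around the apex;
features hit by two sequences are excluded as ambiguous).

## The synthetic benchmark

The generator emulates what a feature extractor produces from a real
run: m/z uniform over 300–1500 Th with a tunable fraction (default 0.1)
re-seated within 0.02 Th of another feature to create near-isobaric
clusters; RT uniform over 80 min; intensities log10-uniform over
1e5–1e9; charges 2–6 (proteomic) or 1–6 (metabolomic). Shift benchmarks
add per-feature N(μ, σ²) RT noise over the grid μ ∈ {0, 5, 10} min,
σ ∈ {0, 0.1, 0.3, 0.5, 0.7, 1, 3, 5} min, with identity ground truth.
Shifted RTs are clipped at zero rather than wrapped (negative elution
times do not exist); with RT uniform on [0, 80], a few percent of
features clip at the largest σ values, which mildly compresses the noise
near the void volume.

Default training conditions, chosen once: a 10,000-feature base run
(2,000 features yield only a few hundred eligible ≤ 0.03 Th negatives —
too few for a 2,000 + 2,000 pair set), near-isobaric fraction 0.1, shift
N(0, 0.5 min) (the middle of the σ grid), 2,000 positive + 2,000
negative pairs, compact network, 50 epochs. Evaluation cohorts use
independently seeded 2,000-feature runs. On this benchmark the tests
assert ≥ 0.99 precision and recall at zero noise, exact re-matching
after a constant offset, monotone recall degradation with σ, and
μ-invariance of precision — and the same quantities are recomputed by
`scripts/acceptance.R` from any seed.

What the generator does *not* emulate: correlated (chromatography-
shaped) drift within a run, intensity-dependent m/z error, charge-state
satellite structure, isotope envelopes, or missing features between
runs. Passing these tests therefore demonstrates the method's geometry
and implementation, not its performance on any particular instrument's
data.

## Numerical and design choices

* RT is canonicalized to minutes everywhere; featureXML seconds are
  converted at read time. The generic CSV dialect assumes minutes, which
  the reader documentation states explicitly.
* Invalid rows (non-positive m/z, negative RT or intensity, bounds not
  bracketing the apex) are dropped with a logged count rather than
  failing: real extractor output contains sentinel rows.
* Shift sign: shift = anchor − sample, so addition moves a sample toward
  the anchor.
* Per-m/z reduction ties break by earliest RT, then feature id; greedy
  assembly ties by |Δm/z|, |ΔRT|, then ids. All orderings are total, so
  results are permutation-invariant in the input.
* Charge is carried through but never used as a matching criterion.
* The aligned CSV includes per-sample feature ids beyond m/z/RT/
  intensity so group membership survives a write/read round trip
  despite rounded output (4 decimals for m/z, 2 for RT).

## Known limitations

* The decoy construction (+one window in m/z) reproduces the RT
  geometry but not the excess of very-close-m/z negatives: on cohorts
  rich in near-isobaric clusters a *well-trained* classifier's rare
  false matches concentrate at tiny Δm/z, and the decoy estimate
  understates the truth (by roughly 3× in our measurements). In the
  regime the estimate is designed for — an imperfect classifier making
  ≥ 1 % errors — decoy and truth agree within a factor of two, which is
  what the tests assert. The transformation is isolated behind
  `estimate_fdr()` and straightforward to swap.
* With the compact default network, a fraction of a percent of
  near-isobaric features (clusters within ~0.01 Th *and* close RT) can
  be cross-assigned; the full-scale configuration sharpens this
  boundary at commensurate cost.
* Star assembly through the anchor never compares two non-anchor runs
  directly; features absent from the anchor cannot seed a group.
* The 1-epoch compact network is degenerate (its outputs sit below the
  0.5 threshold and it accepts nothing); the undertrained regime used to
  exercise the FDR estimate is 8 of 50 epochs, where the classifier
  accepts broadly and errs on 2–3 % of matches.
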