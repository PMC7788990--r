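---
title: "distval: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{distval: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distval)
```

## The evaluation problem

A distance predictor proposes, for every residue pair (i, j) of a
protein, either a binary contact confidence, a real-valued Cβ–Cβ
distance, or a probability distribution over distance bins (a
distogram). `distval` scores any of these against the native structure
and renders them for visual inspection. This vignette records the model
behind each number, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the decisions taken where more than one reasonable design existed.

## Data model and conventions

* **Indices** are 1-based everywhere a user sees them, and every stored
  pair satisfies i < j. Distance/contact matrices are symmetric in
  principle, so only the upper triangle is ever consulted — for metrics
  and visualization alike. A corrupted lower triangle cannot change any
  result (this is a tested invariant).
* **Representative atom**: Cβ, falling back to Cα for glycine or when
  Cβ is missing. Residues with neither atom are *invalid*: their pairs
  are excluded from every metric's denominator rather than imputed, and
  they reduce the effective length
  `L = min(sequence length, valid residues)` that top-L counts use.
* **Separation classes**: with s = |i − j|, local s < 6, short
  6 ≤ s < 12, medium 12 ≤ s < 24, long s ≥ 24. The long-range boundary
  is taken as s ≥ 24 (the inequality-chain convention); prose
  descriptions sometimes say "separated by at least 23 residues", which
  is the same set described by the gap j − i − 1.
* **Contact**: true representative-atom distance < 8 Å, the CASP
  convention, consistent with the classic RR upper bound of 8.
* **Standardization** (visual comparability): distances below 3.5 Å are
  ceiled to 3.5, distances above 20 Å are masked. The transform is
  idempotent; all heatmap values inhabit [3.5, 20].

## Input formats

* **Classic RR**: header keywords (`PFRMAT`, `TARGET`, `MODEL`,
  sequence lines, ...) then 5-column pair lines
  `i j lower upper probability`; column 5 is the ranking confidence.
* **RMODE 1**: declared by a `RMODE 1` header line; parsed as
  contact-style records using the third column as confidence, trailing
  per-bin columns ignored. The exact RMODE 1 grammar is only loosely
  standardized; this tolerant reading is a documented assumption.
* **RMODE 2**: the distogram variant over the ten standardized bins
  [0,4), [4,6), ..., [18,20), [20,∞) Å. Each pair line carries the two
  indices and ten probabilities.
* Duplicate pair lines: the **last occurrence wins** with a warning,
  tolerating concatenated submissions. Self-pairs are dropped; i > j is
  transposed. RR indices are taken as positional (1..L of the parsed
  chain); author renumbering in PDB files is not consulted.
* **Dense matrices**: the single-array `.npy` binary layout or a
  whitespace/CSV text matrix. If the two triangles disagree by more
  than 1e-3 Å the upper triangle is trusted; smaller discrepancies are
  averaged. Nonpositive or non-finite cells are masked.
* **Distogram bundles**: a `.tgz`/`.npz` archive containing an
  L×L×B `.npy` tensor. Explicit `edges` members win; otherwise B = 37 is
  read as the trRosetta layout (no-contact channel first, then 36
  half-Å bins spanning 2–20 Å, reordered here so bins ascend with the
  open no-contact bin last) and B = 10 as the CASP14 bins. Rows whose
  mass is in [0.5, 1.5] but not 1 are renormalized with a warning
  (float truncation); anything further off is rejected as corrupt.
* **Secondary structure** is accepted as a plain H/E/C string (DSSP
  letters are folded into the three classes); it is never computed
  internally.

## Distogram handling

Flattening uses the midpoint of the highest-probability bin. Ties break
toward the lower-distance bin (deterministic, and the short distance is
the structurally informative one). The open final bin maps to its lower
edge + 1 (21 Å for the CASP14 bins): any value beyond the 20 Å cap is
masked by standardization, so only "beyond cap" semantics matter.
Flattening discards multi-peak information by design; no property here
claims otherwise. Contact confidence is the total mass in bins lying
entirely below 8 Å; the bin set must place an edge at 8 (both supported
conventions do — there is deliberately no partial-bin interpolation).

## Metric definitions and parameters

| metric | pair set | notes |
|---|---|---|
| MAE, RMSE | unmasked in both maps, class ∈ {long} or {medium, long}, true ≤ 20 Å | the 20 Å filter applies to the *true* distance, fixing the reference set independently of the predictor |
| PCC | as MAE | undefined below 3 pairs or zero variance |
| Cβ-LDDT | true pairs with s ≥ {6, 12, 24}, true < R0 | R0 = 15 Å; tolerances {0.5, 1, 2, 4} Å; pair-averaged |
| precision top-L/5, top-L | predicted pairs in class, sorted by confidence | k = max(1, ⌊L/5⌋) or L |

LDDT details: the published metric is defined per-residue against a
reference set within an inclusion radius, averaged over four
tolerances. The source evaluations do not print their radius or
tolerance set, so the defaults of the metric's own publication are used
(R0 = 15 Å, tolerances 0.5/1/2/4 Å) in a symmetric, single-reference,
globally pair-averaged form — simpler than the per-residue average and
identical in the limit of uniform pair coverage. Reference pairs whose
prediction is masked count as not preserved (a predictor cannot gain by
omitting hard pairs).

Precision details: predictions are filtered to the requested classes,
sorted by descending confidence with lexicographic (i, j) tie-breaks
(platform determinism), pairs with no evaluable true distance are
skipped *without* consuming a top-k slot, and the top k are scored
against the 8 Å contact definition. Real-valued maps enter this ranking
by ascending distance; the stored confidence `(20 − clamp(d))/16.5` is
a monotone display transform only. An identity prediction reaches
precision 1.0 only when the class holds at least k true contacts — a
property of the metric, not a defect; the synthetic generator is
compact enough that n = 60 chains comfortably exceed k = L.

Metrics over empty pair sets are reported as `NA` (serialized as
`null`), never 0 — zero would fake a worst score. Every reported value
carries the pair count `n` it was computed over.

## Visualization

Heatmaps place the prediction in the upper triangle and the true map in
the lower (empty when absent); the diagonal shows helix/strand/coil
bands (red/green/white) when secondary structure is supplied, else a
red-through-green-to-blue residue gradient shared with the chord
diagrams' arcs. An optional 45° rotation makes the diagonal vertical
(the canvas becomes wider than tall). The error heatmap shows
|pred − true| on standardized maps. Three schemes: `gradient`,
`threshold` (three flat bands with discontinuities exactly at 8 and
12 Å) and perceptually `uniform`; exact colors are configuration, the
monotone value→bin mapping is the contract.

Chords: width decreases and transparency increases linearly with
standardized distance (`w = w_max(20 − d)/16.5`, so 3.5 Å gives the
maximum width and 20 Å width zero and is not drawn); for contacts width
and opacity are proportional to confidence. Each chord takes the arc
color of its lower-index residue, which makes interaction hubs pop out.
The display filter — distance pairs under 12 Å with s ≥ 6, contact top
2L — keeps diagrams readable and is configurable; linearity of the
width law and the exact filter constants are this package's choices
(the underlying direction "closer/more confident ⇒ wider, more opaque"
is the contract). True and predicted diagrams are drawn separately for
side-by-side reading.

## The synthetic world

The generator exists so every pipeline stage is testable offline; its
defaults are fixed, not tuned.

* `make_structure(n, seed)`: a self-avoiding random walk with 3.8 Å
  steps (Cα–Cα virtual bond length), 3.5 Å minimum clearance between
  non-consecutive residues, confined to a sphere of radius
  `max(6, 2.6·n^{1/3})` Å. The confinement models globular collapse:
  the radius constant is chosen once so chains are dense enough that
  every separation class contains sub-8 Å contacts and a 60-residue
  chain holds well over L long-range contacts (~130 in practice),
  matching compact single-domain proteins, while staying sparse enough
  for the rejection sampler to place residues reliably. Glycines (8%
  by default, a typical composition) are written CA-only so the
  Cβ-fallback path is exercised. All randomness flows from the single
  seed, and the caller's RNG state is untouched.
* `make_prediction(true, σ)`: zero-mean Gaussian noise on the upper
  triangle, mirrored, floored at 1 Å. Its MAE is the half-normal mean
  σ√(2/π), which the suite verifies across σ ∈ {0.5, 1, 2, 4} Å —
  the σ range spanning excellent to poor predictors.
* `make_distogram(true, edges, sharpness)`: per-pair Gaussian mass
  around the true distance, renormalized; `sharpness = 0.5` Å emulates
  a confident predictor and guarantees the argmax bin contains the
  true distance except exactly on a bin edge (measure zero for
  continuous coordinates), which bounds the flatten round-trip error
  by half the containing bin's width.

What the generator does **not** emulate: real secondary-structure
regularity (helices/sheets), heavy-tailed or distance-dependent error
profiles, systematic predictor bias, multi-peak distograms, missing
density beyond whole-residue invalidity, and real PDB messiness
(altlocs, insertion codes appear only in parser unit fixtures). A green
test therefore establishes the *bookkeeping* — pair sets, conventions,
formulas, rankings — not field performance of any predictor.

## Numerical choices and degenerate inputs

* Argmax and confidence ties break deterministically (lower bin;
  lexicographic (i, j)).
* Undefined metrics are `NA`, with `n = 0`.
* Structures need ≥ 2 valid residues; RMODE 2 rows must carry exactly
  ten probabilities in [0, 1]; probabilities outside [0, 1] and
  non-numeric pair fields are located errors, not warnings.
* Distance comparisons use the written precision of their formats:
  PDB round-trips are exact to 1e-3 Å (the `%8.3f` column), RR
  confidences to 1e-6.

## Known limitations

* No 3D model reconstruction or TM-score/GDT-TS "utility" scoring, no
  DSSP computation, no web/URL ingestion, no mmCIF, no CASP group-zip
  batch pages — all deliberately out of scope.
* The RMODE 1 column interpretation is an assumption (see above).
* The npy reader covers the single-array numeric layouts predictors
  emit (little/big-endian float/int, C or Fortran order), not pickled
  object arrays.
* Rendering is deliberately simple base-graphics output; publication
  figures may want finer typography than `render()` provides.
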