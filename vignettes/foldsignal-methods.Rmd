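---
title: "foldsignal: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldsignal: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldsignal)
```

## The problem

Multiple sequence alignments of orthologous proteins carry, position by
position, a record of what evolution required and what it tolerated at each
residue. foldsignal quantifies that record with three per-column scores and
asks how far they anticipate structural features of the protein: the
boundaries and bodies of secondary-structure elements, solvent burial and
crystallographic mobility, the residues involved in switching between the
two biologically relevant conformations of a protein (an active, often
ligand-bound, more closed state A and an inactive, more open state I), and
residue–residue contacts.

## The three column scores

For an alignment column (one residue position observed across all
orthologs):

* **VAR (variability)** — the number of distinct residue types whose
  relative frequency in the column is at least `min_freq` (default 0.01).
  It measures what the position *tolerates*. The definition is pluggable
  (`column_variability(fun = ...)`): variability conventions differ between
  alignment servers, and some produce sub-integer values, which is also why
  the box-filter bounds below are configuration rather than constants.
* **ENT (normalized Shannon entropy)** —
  `100 * (-sum(p * log(p))) / log(20)` over the residue-type frequencies
  `p`, clipped to `[0, 100]`. 0 means fully conserved, 100 means uniform
  over all 20 amino-acid types. The 0–100 scale is fixed by the canonical
  ENT filter band 50–60, which is meaningless on a `[0, 1]` scale.
* **KOL (Kolmogorov complexity score)** — the column's residue string is
  serialized as one byte per character (uppercase, gaps `-` kept verbatim,
  no separators, no trailing newline) and compressed with bzip2; the score
  is compressed size / raw size. True Kolmogorov complexity is
  uncomputable; a block-sorting compressor is the standard practical upper
  bound. The serialization and compression level (9, maximum — the level
  base R's `memCompress()` uses) are fixed so scores are bit-reproducible.

Gap handling differs deliberately between the scores: frequencies for VAR
and ENT exclude gaps and unknown residues (`X`) — they are statements about
amino-acid usage — while the KOL byte string keeps gaps, because the
compressor should see the column exactly as the alignment states it. Both
choices are overridable flags. An all-gap column is flagged `allgap` and
excluded from downstream filters rather than silently dropped, so position
indexing stays intact.

Because of bzip2 container overhead (header plus block checksums, roughly
45 bytes), the ratio exceeds 1 for short columns and no clipping is
applied. For the same reason the canonical KOL filter band 1.5–3.5 cannot
correspond to a plain compressed/raw ratio at large alignment depths; the
normalization behind that published band is not fully specified, so filter
bounds in this package are parameters with those defaults, not constants.

## Structure-derived tracks

* **HST encoding**: sheet S = 1, helix H = 2, 3₁₀ helix G = 3, turn T = 4,
  coil C = 5 (`hst_encode()`, with `dssp_to_hst()` mapping DSSP letters
  E→S, H/G/T→themselves, everything else→C). **HSTD** ("HST
  differentiated", `hst_differentiate()`) re-values the first and last
  residues of every maximal S run to 0 and of every maximal H run to 0.5.
  Low values mean strong conservation pressure in the complexity tracks, so
  these "antispikes" make SSE termini visually and numerically comparable
  with conservation dips. Only S and H runs are re-valued; the rule is not
  extended to G/T because terminus values are defined only for the two
  canonical SSE classes.
* **AREA** (`triangle_area_track()`): for each position i, the area of the
  triangle CA(i), CA(i+2), CG, where CG is the protein's centre of gravity
  — by default the unweighted CA centroid, the only well-defined choice on
  CA-only input (per-residue `weights` accept masses when available).
  Consecutive CA atoms sit at an essentially constant 3.81 Å, but the
  i→i+2 distance follows the backbone dihedrals, so the area is a scalar
  proxy for local secondary structure. The area is reported at position i,
  which displaces the track slightly rightward of residue-centred tracks;
  `pair_tracks(lag = )` compensates. One caution established while testing:
  the helix-versus-strand area ordering (helices smaller) holds when both
  elements sit at a comparable, nonzero distance from a *shared* CG, as in
  a real globule. An isolated idealized strand is a degenerate case — its
  own centroid lies in its zigzag plane next to the chain line, collapsing
  the triangles — so comparisons between toy traces must use a common CG.
* **Contact maps** (`contact_map_from_structure()`): CA–CA distance ≤ 8 Å
  (inclusive) with sequence separation j − i ≥ 1 by default. The published
  benchmark's confusion-count row sums equal L(L−1)/2 exactly, which fixes
  the default pair universe as *all* i < j pairs; the cutoff and atom set
  behind the original experimental maps are not stated, so both are
  parameters.
* **DISP** (`displacement_track()`): per-residue distance between cognate
  CA atoms of the A and I structures, after least-squares rigid-body
  superposition (Kabsch, via SVD with the reflection-excluding determinant
  correction) by default. Whether the original analysis superposed first is
  unstated; superposition is the defensible default since without it DISP
  mixes rigid placement with conformational change, and `superpose_first =
  FALSE` is available when two traces already share a frame.
* **OACC / BVLC** (`difference_track()`): elementwise `|A − I|` of paired
  accessibility or B-value tracks, `NA` where either side is missing.

## Contact prediction and evaluation

`passing_positions()` applies inclusive score bands ("between x and y" is
read inclusively, fixed and documented): the canonical VAR/ENT "1:2 box"
is VAR ∈ [0.5, 1.5] together with ENT ∈ [50, 60] (`combine = "all"`), the
KOL band is [1.5, 3.5]. `predict_contacts()` turns the passing set P into
the rank-1 map {(i, j) : i < j, both in P} — the filtered score plotted
against itself — with a `pair_score` hook for future correlated-mutation
style pair scoring. `confusion()` counts TP/FP/FN/TN over the full
L(L−1)/2 universe, optionally excluding every pair touching a masked
position: in the published benchmark the actual-positive counts (TP+FN)
differ slightly between the two methods on the same protein, implying some
undocumented masking of unscored positions, which the `mask` argument can
emulate without guessing the cause. `mcc()` implements

    MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))

with the four marginal sums formed in double precision before
multiplication — protein-sized universes overflow 32-bit intermediate
products — and the conventional value 0 when any marginal sum is zero.
The shipped benchmark table (`contact_benchmark()`) carries the printed
counts and coefficients for 20 chains × 2 methods; the package reproduces
every printed MCC from its counts to within 4-decimal rounding (maximum
deviation 5.0e-5, asserted in the test suite).

## Track correlation

`pair_tracks()` aligns two per-residue tracks by position with pairwise
deletion of missing values and an integer lag; `correlate_tracks()` returns
the Pearson product-moment coefficient (Spearman available as an option,
since the underlying relationships are not certainly linear), in
`mode = "absolute"` by default for benchmark-style tables: difference
tracks such as DISP can correlate with conservation in either sense, and
it is the tempo of variation along the chain, not its sign, that is
compared. Zero-variance tracks yield a flagged `NA`, rendered `.` in TSV
output.

## The synthetic world

The generators state a fixed world; their defaults were chosen once and are
not tuned to test outcomes.

* `synth_msa()` draws each column i.i.d. from `k` residue types chosen
  uniformly from the 20 (uniform within the set, or Dirichlet with
  concentration `alpha`), `k` from the per-position conservation profile,
  with independent gaps at `gap_rate`. It emulates the conserved-versus-
  variable column structure of real ortholog alignments; it has no
  phylogeny, no substitution-matrix structure and no alignment errors, so a
  green test establishes correct score arithmetic and ordering, not
  evolutionary realism. Alignment depths in the hundreds-to-thousands used
  in the tests match the ortholog counts (334–2851) of the original data
  set.
* `synth_helix_trace()` uses canonical helix geometry — 100° twist per
  residue, 1.52 Å rise, radius solved from the 3.81 Å consecutive-CA chord
  (≈ 2.2803 Å) — so tests can assert exact distances.
  `synth_extended_trace()` is a planar zigzag with consecutive CA–CA
  3.81 Å and i→i+2 = 6.5 Å (the extended-strand value).
* `synth_hinge_pair()` rotates the residues after a hinge by `angle_deg`
  about an axis through the hinge CA (default direction z, making the
  analytic chord displacement 2·r·sin(θ/2) exactly checkable, r the
  perpendicular distance from the axis), then adds isotropic Gaussian noise
  to both copies. It emulates a two-domain hinge switch between A and I
  states; real switches involve flexible hinge regions and side-chain
  repacking it does not model.
* `synth_correlated_tracks()` draws `y = ρx + sqrt(1 − ρ²)ε` with x, ε
  standard normal, for correlation-recovery checks at known ρ.

All generators take an explicit seed, restore the caller's RNG state, and
are bit-reproducible.

## Numerical choices

* ENT is computed with natural logarithms and normalized by `log(20)`;
  `0 log 0 = 0` by omitting zero frequencies; results clipped to [0, 100]
  against floating-point spill.
* MCC marginal sums are doubles before multiplication (see above);
  zero denominator → 0.
* Superposition uses SVD; ties/degenerate (collinear) inputs fall back to
  whatever rotation the SVD returns, which is still a least-squares
  optimum. Collinear triangle triples give area 0, not an error.
* Filter bounds are inclusive on both ends; boundary values pass.
* Indexing is 1-based in every interface and output; A/I residue
  correspondence is positional (the intended input pairs have identical
  sequences).
* Pipeline outputs contain no timestamps, so identical configuration and
  inputs give byte-identical files; the manifest records package version,
  parameters and input MD5 checksums.

## Limitations

* The package consumes alignments and secondary-structure strings; it does
  not build alignments, assign secondary structure from coordinates, or
  compute solvent accessibility.
* The exact VAR formula and KOL normalization behind the published filter
  bands are not reproducible from public information; the bands are
  defaults, not calibrated constants, and results with other alignment
  pipelines will need re-tuned bands.
* Contact prediction from a single passing set is rank-1: it cannot
  express pair-specific evidence. The `pair_score` hook exists for such
  extensions but none is implemented.
* No 3D reconstruction from contact maps, no domain/hinge decomposition,
  no multivariate partitioning of the score–structure relationships.
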