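---
title: "Methods: vocal sequence statistics and Area X cell classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal sequence statistics and Area X cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songkit)
```

This vignette is the package's account of its methods: the statistical
models, the parameters that matter, the design decisions taken where the
procedure was genuinely open, and what the synthetic-data tests do and do
not establish.

## Song representation and segmentation

The substrate of all sequence statistics is an annotation log: one row per
syllable rendition with a label, onset and offset in seconds, and optional
per-rendition acoustic features. `songkit` treats these annotations as
ground truth; it never touches audio.

All segmentation rules are phrased in terms of the silent gap
`next onset − current offset`, with thresholds in `segmentation_config()`:

| parameter | default | role |
|---|---|---|
| `min_syllable_gap` | 0.005 s | validation floor between adjacent syllables |
| `bout_gap` | 0.5 s | a gap at or above this starts a new song bout |
| `boundary_gap` | 0.1 s | a gap strictly above this is a song boundary (`/`) |
| `call_isolation_gap` | 0.1 s | isolation threshold for the call-removal rule |

Inequality conventions: bouts hold together while inter-motif intervals are
*under* 500 ms, so a gap `>= bout_gap` splits; boundaries and calls use
strict `>` ("over 100 ms"). Events closer than 5 ms trigger a warning, not a
merge — sub-threshold gaps indicate an annotation problem upstream, and
silently rewriting the data would mask it.

Two edge conventions are worth stating. The start and end of a recording
count as infinitely long silence for the call rule, so a lone event is
removed as a call. And bout segmentation is a pure partition: concatenating
bout label sequences reproduces the recording, so segmentation is
idempotent.

The operational definition of a bout here is a single silence threshold. A
fuller definition (introductory elements followed by motif renditions)
involves recognizing motifs; since motif structure is exactly what the
downstream statistics measure, using it for segmentation would be circular.

## Repetition counting and the d′ statistic

The per-bout repetition count of a vocal element is the total number of
consecutive renditions excluding the first of each run: a maximal run of
*k* occurrences contributes *k* − 1. Elements may span several tokens (a
repeated syllable pair); multi-token runs are tiled greedily left to right
without overlap, the unique tiling consistent with "consecutively
repeated". An element is worth tracking (`select_repeating_elements()`)
when it repeats at least twice in a single run on at least one occasion,
i.e. a run length of three or more — the stricter of the two possible
readings, chosen because stable song already contains occasional single
repeats and the statistic targets *uncharacteristic* repetition.

Changes between a day *i* and the baseline day *b* are scored with

$$ d'_i = \frac{\sqrt{2}\,(\bar n_i - \bar n_b)}{\sqrt{\sigma_i^2 + \sigma_b^2}} $$

Variances are day-level *sample* variances (n − 1): the bouts of a day are
a sample from that day's behavioral state. When both variances vanish the
statistic is 0 if the means agree and an error otherwise — an infinite
standardized change should fail loudly rather than silently propagate.
`d'` is antisymmetric and invariant under common shifts and positive
rescalings of both samples, and these invariances are property-tested.

The same formula on per-rendition pitch gives `pitch_shift_dprime()`, with
the conventional learning criterion |d′| > 0.75. Note the estimator's
standard error is roughly √(2/n); at n = 100 renditions per day a true
0.8-SD shift is flagged only ~2/3 of the time, so reliable detection needs
either a larger shift or more renditions (the test suite uses 1.2 SD).

Rendition-to-rendition variability is summarized as the coefficient of
variation, `100·sd/|mean|`, of pitch or Wiener entropy; stable adult song
sits near 1.5% pitch CV, the default scale of the song generator.

## Transition and difference matrices

Transition matrices are first-order tallies over token streams in which
`/` marks song boundaries: gaps over `boundary_gap` and recording edges.
Isolated calls are removed before tallying. Rows with at least one count
are normalized to probabilities (row sums within 1e−9 of 1); `/` has no
self-transition by construction.

Two choices deserve justification:

* **Pruning** (`prune_rare_states()`): syllables present in under 20% of
  bouts at *any* timepoint are omitted. The implementation deletes the
  pruned tokens from the stored sequences and re-tallies, rather than
  renormalizing the remaining row mass. Renormalization would silently
  redistribute the pruned probability; re-tallying answers a well-posed
  question (what follows what, ignoring rare syllables) and matches the
  display-filter purpose of the rule. The matrix object therefore carries
  its source sequences.
* **Difference orientation**: `difference_matrix()` defaults to
  baseline − comparison, so positive entries mark transitions that *lost*
  probability after a manipulation. The `flip` flag reverses the sign for
  the opposite plotting convention.

## Syntax classification

`classify_syntax_changes()` compares post-manipulation bouts to a baseline
motif template. Design of the classifier:

1. Repeat runs are collapsed to single tokens first, so repetition — scored
   by its own statistic — cannot masquerade as insertion.
2. Introductory elements are stripped; the remaining core is globally
   aligned to *m* concatenated template copies, with *m* chosen to minimize
   the alignment cost (ties to fewer motifs).
3. The cost model is unit mismatch/indel with matches free, and tied
   deletions placed leftmost. The alignment engine is verified against an
   exhaustive minimal-edit-distance recursion on short sequences.
4. Template-position bookkeeping classifies each edit: deletions are
   omissions, insertions of labels absent from the baseline repertoire are
   de novo additions, and adjacent label pairs unseen in baseline song are
   new transitions. Edits at the first or last motif position are recorded
   but excluded from the percentage of syntax-altered bouts, which counts
   interior changes only.
5. Percentages are computed over a seeded uniform subsample of 30 bouts per
   timepoint (all bouts, with a warning, when fewer are available).

The classifier's sensitivity and specificity are established on generated
song: programmed interior omissions and insertions are detected in over 90%
of affected bouts, and unmodified song yields exactly zero alterations,
omissions, and additions.

A human expert classifies syntax by eye; the cost model here is the
package's own operationalization and is deliberately minimal. Ambiguous
alignments (e.g. an omission adjacent to a novel insertion) resolve by the
leftmost-deletion rule, which is arbitrary but deterministic.

## The song generator

`song_model()` emulates annotated adult song: per bout, a run of
introductory notes followed by 2–3 motif renditions, with syllable
durations ~N(80 ms, 8 ms), within-bout gaps uniform on 20–80 ms (safely
under the 100 ms boundary), and inter-bout gaps on 0.7–1.5 s (safely over
the 500 ms bout threshold). Per-syllable pitch is Normal with CV 1.5%, the
variability scale of stable adult song.

Repetition is modeled as a *shifted geometric* law: the per-bout repeat
count of an eligible element is `base + Geom(p)`, drawn once per bout at
the element's template position. The pure geometric (`base = 0`, the
default) is the minimal memoryless repeat/advance model. The deterministic
floor `base` exists because a geometric's mean/SD ratio is bounded by 1,
which caps the achievable d′ between two geometric models at √2; observed
repetition effects around d′ ≈ 2 therefore cannot be expressed without it.
With the floor, moments stay closed-form (mean `base + (1−p)/p`, variance
`(1−p)/p²`), `expected_repetition_dprime()` is exact, and
`calibrate_repeat_effect()` can root-find a law hitting any non-negative
target d′ (smallest adequate `base`, then `p` by `uniroot`).

Effects (`song_effect()`) are step changes: a new repeat law for one
element, omission-probability increments, an insertion-rate increment
(novel labels are generated outside the baseline repertoire, so additions
are detectable by identity, mirroring how annotators label variant
syllables), and pitch shifts in SD units. Time courses are composed by the
caller; the generator does not model learning dynamics, social context, or
acoustics.

Parameter recovery closes the loop: at 30 bouts per day, the full chain
(generate → segment → count → d′) recovers injected analytic d′ targets of
0, 1 and 2 within ±0.3 averaged over 50 seeds, and the empirical transition
matrix of a known first-order chain converges within 0.05 (L∞) by ~3,000
transitions.

## The snRNA-seq chain

Quality control removes cells with more than 10,000 total UMIs (doublet
proxy) or more than 5% mitochondrial UMIs (degraded-nucleus proxy); both
comparisons are strict, retaining boundary cells, and "percent
mitochondrial" means percent of UMIs, not of detected genes. The filter is
idempotent and is tested against a brute-force predicate. Normalization is
`ln(1 + count/total × 10⁴)` — natural log, zeros preserved.

`cluster_cells()` chains the standard steps: variable-gene selection by
normalized-value variance (default 2,000 genes), optional per-gene linear
regression on cell covariates (UMI total, mito %) keeping residuals,
per-gene z-scaling clipped at ±10, truncated PCA (irlba), a shared
nearest-neighbor graph (scran, Jaccard weights, k = 20), and Louvain
community detection (igraph). Clusters are renumbered by decreasing size.
The PC count defaults to an automated elbow (largest distance to the chord
of the variance curve), overridable with `n_pcs`. All stochastic steps are
seeded; a fixed seed reproduces assignments exactly.

The Louvain `resolution` (default 0.8) sets granularity, and modularity
optimization will subdivide large homogeneous populations at fine
resolutions. This matters for interpretation: on the Area X preset the
default resolution resolves the receptor/FoxP2 substructure *within* each
MSN program into separate clusters — qualitatively the right behavior for
striatal tissue, where MSN subtypes are real — while recovery tests that
ask "were the k programmed populations found?" use a coarse resolution
(0.05), at which the pipeline recovers well-separated programs essentially
exactly (ARI ≈ 1). Composition and receptor statistics aggregate clusters
after typing and are insensitive to this choice.

Typing (`assign_cell_types()`) is rule-based on per-cluster marker
summaries: an MSN call requires *joint* expression of Gad2, Ppp1r1b and
FoxP1 (all three must be measured — the rule is dropped, not weakened, if a
marker is absent from the matrix); pallidal-like projection neurons by
Penk; interneuron, glutamatergic, and glial classes by their single
markers. The score threshold is 50% of cells expressing; clusters clearing
no rule are "unassigned". "Expressing" means a positive normalized value,
i.e. at least one UMI — the only unambiguous threshold; stricter cutoffs
are exposed via `min_value`.

Receptor classification is exclusive by construction — D1/5-only, D2-only,
both, or none, with a FoxP2 flag — so class percentages always sum to 100.
Pathway differential expression follows the conventional marker-test
recipe (expression-fraction ≥ 0.1 in a group, |log fold change| ≥ 0.25 as
difference of mean ln-normalized values, per-group subsampling to 200
cells, Wilcoxon rank-sum, Bonferroni over tested genes); p-values are
verified against an exact enumeration oracle on small tied-free samples.
Welch's unequal-variance t-test (`receptor_shift_test()`) compares receptor
expression between conditions within receptor-pattern groups.
`bootstrap_dendrogram()` clusters per-cluster mean profiles over the union
of each cluster's top-50 fold-change genes, with correlation distance and
average linkage; node support is the fraction of gene-resampling
replicates reproducing each clade, computed in-package and exportable as
Newick.

Cross-dataset anchor integration is intentionally not implemented:
comparisons between conditions operate on per-dataset normalized values.

## The expression simulator

`simulate_counts()` draws each cell from a program: a library size
(lognormal, median 6,500 UMIs, log-SD 0.15), a mitochondrial fraction
(Beta(2, 78), mean 2.5%), negative-binomial counts (dispersion 0.3, the
usual UMI regime) around the program's profile rescaled to the library,
a binomial mitochondrial share spread over 13 mito genes, and — for
MSN-like programs — a sampled receptor/FoxP2 status that *gates* the
receptor genes (a positive status guarantees ≥ 1 UMI, a negative one
exactly 0), making programmed co-occurrence exact rather than approximate.
Doublets sum two random singlets; with the default library law a doublet
exceeds the 10,000-UMI ceiling with probability ≈ 0.99 by construction,
which is what makes the QC doublet-sensitivity test meaningful rather than
circular.

`area_x_preset()` packages the census used throughout the recovery tests:
68% MSNs split evenly between a direct-like program (receptor classes
60/2/6/32) and an indirect-like program (12/24/30/34), averaging to the
36/13/18/33 split; 2.4% pallidal-like cells; interneurons, astrocytes and
oligodendrocytes for the remainder; 3% doublets. FoxP2 co-expression is
61% within D1/5-only cells and 21% within D2-only cells; the "both" and
"none" classes take 50% and 40%, plausible intermediates consistent with
FoxP2-rich and FoxP2-poor cluster structure but not pinned by any published
figure — conclusions should rest only on the 61/21 rates. Each program
carries a 15-gene signature block (mean 6 relative counts) over 470 filler
genes, strong enough that program separation, not marker leakage, drives
clustering.

At 10,000 cells the full chain recovers the programmed receptor-class
split within ±2 percentage points and FoxP2 co-expression within ±3, with
doublet-removal sensitivity above 0.9 — the end-to-end bar the test suite
and `scripts/acceptance.R` both enforce.

What the simulator does **not** emulate: gene–gene correlation beyond
program blocks, ambient RNA, batch effects, depth-dependent dropout
beyond the NB law, or continuous differentiation gradients. Passing
recovery tests therefore demonstrates the correctness of the statistical
chain, not robustness to every artifact of real tissue.

## Problem sizes and runtime

Defaults were chosen so the whole suite exercises realistic regimes while
staying light: repetition/d′ recovery uses 30 bouts per day across 50
seeds per effect size; chain-recovery uses ~3,000 transitions; the
expression recovery test uses the full 10,000-cell preset (about half a
minute including clustering); oracle-comparison property tests use 1,000
random cases each. `scripts/acceptance.R` reruns all of the above from a
single `--seed`.

## Known limitations

* Bout segmentation is silence-threshold-only (see above).
* The syntax classifier assumes a single baseline motif; birds with
  several representative motifs need per-motif calls.
* Repeat laws are (shifted) geometric; heavier-tailed repetition would
  need a different law, though the analytic d′ interface would carry over.
* `receptor_shift_test()` groups by expression pattern per dataset;
  if expression thresholds differ between conditions, group membership
  shifts with them.
* The marker rule set targets Area X; other tissues need their own
  `identity_rules()`-style table.
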