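---
title: "Methods: elliptic Fourier contour detection and per-cell fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elliptic Fourier contour detection and per-cell fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`efdcell` implements an auxiliary-detection workflow for fluorescence
micrographs of cell nuclei, aimed at flagging tumor-like cells by their
probe-channel brightness. The pipeline has three stages:

1. **Contour detection.** Cell boundaries are represented as elliptic
   Fourier descriptors (EFDs). A small convolutional network with a
   feature-pyramid backbone takes the nuclear (DAPI) channel and predicts,
   per pixel, (i) a center heatmap and (ii) the EFD coefficients of the
   cell centered there. Peaks of the heatmap become detections; the
   regressed coefficients decode into closed contours and pixel masks.
2. **Quantification.** The RGB probe channel is collapsed to a grayscale
   fluorescence-intensity image; each detected cell's mean intensity over
   its mask is computed and the cell is flagged *suspicious* iff the mean
   exceeds a threshold θ (default 10 native gray counts; a mean exactly at
   θ falls in the normal bin).
3. **Evaluation.** Detections are scored against instance masks with F1 at
   IoU thresholds T = (0.5, 0.6, 0.7, 0.8, 0.9), summarized as
   F1avg = (1/|T|) Σ F1_τ.

## Elliptic Fourier descriptors

A closed contour traversed at parameter *t* over cumulative arc length
(total perimeter *T*) is expanded as

x(t) = A0 + Σ_n [ a_n cos(2πnt/T) + b_n sin(2πnt/T) ],
y(t) = C0 + Σ_n [ c_n cos(2πnt/T) + d_n sin(2πnt/T) ],

the chain/arc-length ("Kuhl–Giardina") form, which is the canonical meaning
of "elliptic Fourier descriptor". The DC terms (A0, C0) are the
arc-length-weighted boundary centroid — the package's definition of a cell
center. Coefficients are computed in closed form from the polygon segments
and are stored **without** phase, rotation or scale normalization: labels
are traced deterministically (below), so the network learns consistently
phased coefficients; morphometric normalization is a non-goal.

Numerical facts the tests pin down, and their reasons:

* A circle of radius r encodes to first harmonic (r, 0, 0, r) to machine
  precision (constant traversal speed).
* An eccentric ellipse does **not** encode to its semi-axes: with axes
  (20, 8) the arc-length first harmonic is (17.80, 0, 0, 8.71), because
  the angle parametrization is not arc length. The semi-axes are recovered
  in the near-circular limit only. Tests verify coefficients against an
  independent dense numerical Fourier integration.
* Decode-then-re-encode reproduces the coefficients to 1e-6 only for
  constant-speed curves (circles). For a general shape the truncated
  Fourier curve has non-uniform speed, so re-encoding by arc length shifts
  coefficients at the ~1% level while the decoded geometry stays put
  (mask IoU ≥ 0.99). Tests assert exactly that, rather than an
  unattainable identity.
* Reversing traversal (start vertex fixed) maps t → T − t and therefore
  negates the sine columns b_n and d_n. Traced contours are always
  re-oriented to positive signed area first, making signs deterministic.

**Mask tracing.** Contours are traced along pixel *cracks* (the edges
between foreground and background pixels), giving vertices at half-integer
coordinates, starting at the top-left corner of the topmost-then-leftmost
pixel. Compared with tracing through boundary-pixel centers this removes a
half-pixel inward bias: Fourier smoothing then straddles the true edge
symmetrically, and the mask → contour → rasterized-mask roundtrip is exact
for rectangles and, in practice, for the generator's smooth cells (the
identity-pipeline test observes IoU = 1 at N = 20). Rasterization uses the
even-odd rule on pixel centers with boundary points counting as inside.

## Network and training targets

The backbone is a three-level encoder (strides 1, 2, 4; widths w, 2w, 4w;
default w = 12) with 1×1 lateral projections and nearest-neighbor top-down
merges — a miniature feature pyramid sized for CPU training. Two 1×1 heads
produce a 1-channel sigmoid heatmap and a (2 + 4N)-channel linear
regression map (sub-pixel center offset plus N harmonic quadruples,
default N = 6; the harmonic order is not prescribed by the source and is
config-exposed).

Supervision follows the anchor-free heatmap-plus-regression design:

* the center heatmap target carries one Gaussian bump per cell
  (σ = 0.1 × mean equivalent diameter, floored at 1 px) with value exactly
  1 at the rounded center pixel;
* regression targets live only at those center pixels (a `valid` mask
  marks them); offsets are stored raw, harmonic coefficients divided by a
  scale constant;
* losses: penalty-reduced focal loss (α = 2, β = 4) on the heatmap,
  normalized by the number of centers, plus smooth-L1 on the regression
  channels at valid pixels; total = heat + λ·reg. The heatmap
  head bias is initialized to −2.19 (sigmoid ≈ 0.1) so the sea of negative
  pixels does not dominate the first epochs.

**Scale constant.** `make_targets()` defaults to dividing harmonics by the
crop size (256). For desk-scale training the detector config overrides
this to 32 (about twice a nuclear diameter): at 256 the targets are
O(0.04) and their smooth-L1 gradients are too weak to learn against the
heatmap loss — training then converges to a near-constant regression
output. The constant travels inside targets and checkpoints, so decoding
always de-normalizes exactly.

**Label canonicalization.** Two choices proved decisive for learnability
and were adopted after the naive versions demonstrably failed (held-out
F1avg pinned at 0):

1. *Start phase.* Tracing labels from the topmost boundary pixel makes
   the Fourier phase jump when that pixel slides along a flat cell top, so
   the coefficient labels are a near-discontinuous function of shape.
   Training labels instead start the traversal at the boundary vertex
   nearest the +x ray from the cell centroid — smooth in shape for convex
   cells, still deterministic. (With this convention an axis-aligned
   ellipse labels as a1 ≈ rx, d1 ≈ ry, b1 ≈ c1 ≈ 0.)
2. *Flip rules.* A naive coordinate mirror of the coefficients leaves
   reversed orientation and a shifted phase; under random flip
   augmentation such labels average to zero and the regression collapses.
   The rules used restore the canonical parametrization: vertical flip
   maps (a, b, c, d) → (a, −b, −c, d) with Δy negated (exact up to the
   one-vertex jitter of the ray-start choice); horizontal flip
   additionally shifts phase by half a period, giving (a, −b, −c, d) for
   odd harmonics and (−a, b, c, −d) for even ones with Δx negated (exact
   up to the half-period approximation, ≲1 px). The tests verify both
   against re-tracing the flipped masks.

Training is plain Adam (β = 0.9/0.999) with L2 weight decay, random crops
and these canonical flips; the learning rate steps down 5× for the final
quarter of the epochs to settle the heads and reduce run-to-run variance.
The regression head, supervised at only a handful of pixels per crop,
sees noisy gradients and therefore uses a 10× learning-rate multiplier
and a near-zero weight initialization (He-scale initial outputs are O(1)
garbage against O(0.3) targets and destabilize early epochs
seed-dependently); the regression loss is averaged over cells (summed
over channels) and weighted by λ = 0.25 against the heatmap loss — the
balance at which both heads converge in the desk budget. One integer
seed drives weight init, sample order and augmentation; two same-seed
runs are bit-identical (single-threaded BLAS).
The published recipe (Adam, lr 1e-4, weight decay 1e-8, batch 256,
90 epochs, 256×256 crops) ships as `published_config()`; the shorthand
"10e-4"/"10e-8" in the source is read as 1e-4/1e-8. Desk defaults (tiny
network, batch 8, 20 epochs, 128×128) exist so the full loop trains on one
CPU in minutes; matching the published dataset-scale score is explicitly
out of scope.

**Decoding.** Detection peaks are 3×3 local maxima with score ≥ 0.3,
capped at the 300 highest scores (an untrained network's plateau heatmap
otherwise floods the decoder); each peak's regression vector becomes a
descriptor whose decoded, rasterized mask enters greedy IoU
non-maximum-suppression (threshold 0.5, higher score kept). Feeding
ground-truth targets through this decoder recovers every cell exactly —
the identity path that separates representation errors from learning
errors.

## Synthetic scenes

The generator states a world consistent with the published cell-level
observations: probe-channel mean fluorescence *near zero* for normal-like
cells and *above 40* for tumor-like cells, separated by the θ = 10
two-class rule. Defaults: normal mean 3 (sd 2), tumor mean 45 (sd 8)
counts; tumor fraction 0.5 (both populations well represented per image);
Poisson(20) cells on 256² px (Poisson(8) on 128² for training fixtures);
ellipse semi-axes 6–12 px, matching cultured-cell nuclei at roughly
0.5 µm/px; relative harmonic-2–4 irregularity 6%; pairwise mask IoU capped
at 0.05; DAPI foreground 180 ± 25 over background 12; Gaussian pixel noise
sd 4; intensities clipped to 8 bits. Shapes are sampled directly in EFD
space (rotated harmonic-1 ellipse plus small higher harmonics), so every
cell carries exact descriptor ground truth and parameter-recovery tests
have an exact reference.

What the generator does **not** emulate: optical PSF blur, photobleaching,
subnuclear texture (probe/DAPI colocalization is represented only as
spatial coincidence of the two channels), touching cell clusters beyond
the small overlap cap, and staining artifacts. A green test therefore
establishes correctness of the algorithms on well-separated, smooth,
two-population scenes — not clinical performance on pathology slides,
whose published score (F1avg 0.658 on an unreleased dataset) this package
does not attempt to reproduce.

## Numerical and design choices

* **Matching rule.** TP counting uses maximum bipartite matching (Kuhn's
  augmenting paths) on the τ-thresholded IoU graph — deterministic, never
  understates TP, and verified against exhaustive assignment enumeration
  for ≤ 6 cells.
* **Empty sets.** F1_τ = 1 when both prediction and truth are empty
  (vacuous agreement), 0 whenever TP = 0 otherwise; IoU of two empty
  masks is an error.
* **Dataset aggregation.** "Average F1avg" is macro (per-image scores
  averaged); micro pooling of TP/FP/FN is exposed as an option.
* **Grayscale conversion.** Default probe RGB → gray is the channel mean;
  "max" and Rec.601 "luma" are options. The probe fluorescence is
  red-dominant, so luma reads systematically low — documented, not
  default. Intensities stay in native counts because θ = 10 is an
  absolute rule.
* **Overlapping detections.** Pixels claimed by several cells are assigned
  to the higher-scoring cell for intensity averaging; a fully-claimed cell
  falls back to its own mask. Deterministic, and rare under NMS.
* **Tie-breaks.** Plateau heatmap maxima all qualify as peaks and are
  resolved by NMS; two cells rounding to the same center pixel keep the
  later label's regression target (counts then disagree by design and the
  warning surfaces in training data quality).
* **Degenerate inputs.** Constant images preprocess to all-zeros; empty
  masks yield empty targets (legal negative examples); a label split into
  several components keeps its largest piece with a warning; unplaceable
  synthetic cells are skipped with a warning.
* **Image formats.** The R imaging stack guaranteed in the runtime has no
  PNG/TIFF codecs, so images use binary netpbm: 8-bit PGM/PPM for
  channels, 16-bit big-endian PGM for instance masks (lossless to 65535
  labels). Configs are JSON.

## Known limitations

* The detector is sized for synthetic fixtures; no GPU path, no batch-norm
  or schedulers, and `published_config()` training at batch 256 on large
  pathology images is computationally out of reach here by design.
* EFD phase is tied to the deterministic tracing start; rotating an image
  changes coefficients (rotation-invariant descriptors are a non-goal).
* Regression supervision exists only at center pixels; accuracy at a
  peak found 1–2 px off the true center relies on the smoothness of the
  convolutional output.
* The crack-boundary tracer treats diagonal pinches as connected
  (left-turn preference); pathological checkerboard regions rasterize
  approximately, which smooth nuclei never exhibit.

## What the desk-scale training run establishes

The scaled-down acceptance training (64 synthetic 128×128 scenes, ~4–5 CPU
minutes) reaches a held-out F1avg around 0.6–0.75 with the default recipe:
every cell is found (the count is usually exact) and most masks match at
IoU 0.5–0.8, while the τ = 0.9 band stays low — boundary-pixel accuracy
beyond ~90% IoU is not attainable for a ~50k-parameter network and 2,500
optimizer steps. The criterion this run is held to (F1avg ≥ 0.5 and
strictly above the untrained network) tests that the whole
representation–training–decoding loop learns, not that it rivals the
GPU-scale result.

## Intensity semantics of the generator

The class intensity model is stated in *measured* units: the drawn
per-cell mean is the value the pipeline's grayscale conversion recovers
(the red channel is painted with 3m/1.1 so the channel-mean gray equals
the draw m, with 5% autofluorescence in green/blue). Normal-like draws
are truncated below the threshold-10 line — the reported distributions
show every normal cell below 10 — while tumor-like draws are left
untruncated (the reported tumor groups contain occasional sub-threshold
cells). On noiseless scenes the measured suspicious count therefore
equals the planted count exactly; with default noise the per-cell
classification accuracy stays above 99% because the two populations sit
4+ standard deviations from the threshold.
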