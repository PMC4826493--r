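---
title: "Automated PHH3/MART1 proliferation quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PHH3/MART1 proliferation quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The mitotic index of primary cutaneous melanoma — the number of dividing
tumor cells in the busiest square millimetre ("hot spot") of the lesion —
is a staging variable, and a notoriously laborious and subjective one to
read on H&E sections. Immunohistochemical dual staining helps: an
antibody against phosphohistone H3 (PHH3, a histone mark carried by cells
in late G2 and M phase) is visualised with DAB (brown), while MART1, a
cytoplasmic antigen of melanocytic cells, is visualised with alkaline-
phosphatase red, over a hematoxylin (blue) counterstain. A mitosis of a
*tumor* cell then reads as a brown nucleus wrapped in red cytoplasm,
distinguishable from a proliferating lymphocyte (brown nucleus, no red
surrounding).

`mitospot` implements a fully automated reading of such slides: pixel
classification by color deconvolution, cell-object detection with
post-processing gates, the MART1-verified tumor reference area,
circle-overlap heat-map hot-spot selection in a fixed 1-mm² square, and
MART1-adjusted proliferation indices. It also ships the method-comparison
statistics used to evaluate the automated reading against a manual one
(Bland–Altman limits of agreement, a 2×2 detection contingency table,
hot-spot overlap categories, and diagnostic performance), and — because
real stained cohorts cannot travel with a package — a synthetic slide
*phantom* generator with exhaustive ground truth against which every
stage is tested.

## Pixel model

A calibrated RGB image (µm-per-pixel known; origin top-left, x rightward,
y downward; pixel *(i, j)* covers the half-open square
*[(j−1)s, js) × [(i−1)s, is)*) is converted per channel to optical
density, OD = −log₁₀((I + ε)/255) with ε = 10⁻⁶, and projected onto a
3×3 stain basis of unit-norm OD vectors for hematoxylin, DAB and AP red
(the standard published stain vectors; the chromogens are named by the
protocol, their colorimetric values are not, so the basis is an explicit,
overridable constant). Solving the linear system per pixel gives three
stain densities, clipped at zero.

Pixels are then classified by a deterministic cascade:

1. **Background**: bright (mean RGB > 200) with all densities < 0.10 OD.
2. **PHH3 (brown)**: DAB density ≥ `t_brown` *and* more brown than blue
   (DAB > hematoxylin density — this operationalises the manual reading
   rule "nuclei more brown than blue" in a basis-independent way) *and*
   either a local standard-deviation filter response ≥ `t_sd` (contour
   enhancement) or mean intensity ≤ `t_dark`. The darkness rescue exists
   because densely stained metaphase plates are nearly uniform inside:
   they have low local variance but are very dark.
3. **MART1 (red)**: red density ≥ `t_red`.
4. **Hematoxylin (blue)**: blue density ≥ `t_blue`.
5. otherwise background.

The SD filter uses a (2r+1)² window (r = 2 px default) with symmetric
edge reflection and population variance. The commercial system the
protocol derives from never published its thresholds; all defaults here
(`t_brown` 0.35 OD, `t_red` 0.20, `t_blue` 0.20, `t_sd` 0.08 OD,
`t_dark` 120) were fixed once against the phantom generator and live in a
versioned YAML configuration whose hash is embedded in every output.

## Cell detection

The PHH3 pixel class is dilated by a disc of physical radius 2.5 µm and
connected components are labelled on the dilated mask, so that the two
chromatin masses of an anaphase or telophase figure fuse into one object;
all measurements (area, centroid, mean DAB OD) are taken on the original,
undilated pixels. Whether the original system measured before or after
dilation is unstated; measuring on original pixels keeps areas physical.

Each object carries four features and is kept (flagged, never silently
dropped) for audit:

* area in µm² — gate [8, 120] µm²;
* mean DAB OD — gate ≥ 0.5;
* MART1 surround fraction: the fraction of a 2-µm perinuclear ring
  (dilation of the object minus the object) classified MART1 — gate
  ≥ 0.3, the automated counterpart of "noticeable MART1 surrounding";
* irregularity, 1 − solidity (object area over the grid-filled convex
  hull of its pixels) — gate ≤ 0.6. The protocol does not say in which
  direction nuclear irregularity discriminates; the package rejects
  *high* irregularity, aimed at speckled pigment aggregates, while
  mitotic discs, bars and fused anaphase pairs (measured irregularity
  ≲ 0.45) pass.

The **MART1-verified tumor area** — the denominator of all adjusted
indices — is, inside the manual outline minus any exclusion polygons, the
union of MART1 pixels, hematoxylin-nucleus components whose own MART1
surround reaches 0.3 (PHH3-negative tumor nuclei reclassified into the
tumor area), and the pixels of accepted PHH3 cells, with holes up to
50 µm² filled.

## Hot-spot selection

A circle of radius 200 µm is conceptually centred on every accepted
positive cell; each point inside a circle accumulates 1. The resulting
integer surface (the object heat map) is evaluated on a 10-µm grid — a
deliberate economy: features of a 200-µm kernel cannot vary meaningfully
below that scale, and a per-pixel mode remains available for oracle
tests. The hot-spot centre is the eligible grid argmax; ties are resolved
by taking the largest 8-connected component of maximal grid points and
using its centroid, then scan order (y, then x) between equal components.
Multiple maxima are legitimate (the count in the square is what is
reported, and near-ties give nearly identical counts). The centre is
covered by an axis-aligned 1000 × 1000 µm square, half-open on the
right/bottom, and the count of positive centroids inside it is reported.

The 200-µm circle optimises circle overlap, not the square count, and the
two optima can disagree — the package therefore also provides a
`selector = "square"` oracle mode that exhaustively maximises the square
count itself on the grid (in that mode the centre is an argmax grid point
so the reported count equals the exhaustive maximum). With zero positive
cells there is no hot spot: the pipeline returns a distinguished
"no hot spot" outcome rather than a zero-filled one.

Manual and automated hot spots are compared by the absolute differences
of their square-centre coordinates in mm, combined with the maximum
(Chebyshev) rule, which reproduces the geometry in which two unit squares
overlap iff both coordinate distances are below 1.0 mm: perfect overlap
< 0.10, mayor overlap [0.10, 0.75), minor overlap [0.75, 1.0], none
> 1.0. The printed bands "0.10–0.74" and "0.75–1.0" leave (0.74, 0.75)
undefined; the half-open partition above is gap-free and preserves the
printed edges. At exactly 1.0 the closed squares share an edge (zero
area, non-empty intersection), which is still "minor".

## Indices

* global MART1-adjusted index = accepted cells / MART1-verified area
  (cells/mm²);
* hot-spot count = cells in the square;
* hot-spot MART1-adjusted index = cells in the square / (MART1-verified
  area ∩ square).

Division by a zero area is a tri-state, not a NaN: a value when the area
is positive, a flagged "undefined" when count and area are both zero, and
a hard inconsistency error when cells were detected on zero tumor area —
small lesions make a single miscounted cell swing the index, so silent
division is hazardous. Cut-off presets for dichotomising each index
route (e.g. hot-spot count 0 vs ≥ 1; adjusted hot-spot > 7.7 or > 14 per
mm²) ship as data in `index_cutoffs()`.

## Evaluation statistics

Bland–Altman agreement uses differences automated − manual, the sample
SD (n − 1), and limits d̄ ± 1.96 SD; outliers are excluded only when the
caller names case ids (no automatic rule). The detection table
cross-classifies cases by manual/automated {0, ≥ 1} counts with rounded
cell percentages. Diagnostic performance dichotomises at a cut-off
(test-positive ⇔ value ≥ cut-off) and reports sensitivity, specificity,
PPV and NPV with exact Clopper–Pearson 95 % intervals (the source
protocol does not name its CI method; exact intervals are reproducible
and conservative), and a rank-based ROC area (Mann–Whitney with midrank
ties). Wilcoxon, paired-t and Spearman statistics are deliberately left
to standard backends and are not part of the tested contract.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()` / `render_phantom()` produce a calibrated image and full
ground truth. Per-pixel stain amounts are composed shape by shape and
converted to RGB by the forward Beer–Lambert model
I = 255·10^(−Σ aₖ·vₖ) over the same stain basis, with additive Gaussian
8-bit noise — so color deconvolution is an approximate inverse by
construction, and the forward/inverse pair is itself a tested invariant.

The stated world, chosen once:

* the lesion polygon is filled with red cytoplasm (a confluent melanoma
  sheet), so the true MART1 tumor area equals the lesion rasterisation;
* PHH3-negative nuclei are blue ellipses (major axis 7–10 µm) that punch
  through the red (cytoplasmic antigen does not stain the nucleus), which
  forces the nucleus-reclassification path of the tumor area to do real
  work on every phantom;
* mitotic morphology follows phase: prophase ≈ disc (r 3.2–4 µm),
  metaphase ≈ 8 × 2.5 µm bar, anaphase/telophase = two blobs (r 2.5/2.2
  µm) separated by a configurable 4-µm chromatin gap;
* positives keep ≥ 30 µm spacing (mitoses are rare events; this also
  keeps *distinct* figures resolvable by the 2.5-µm fusion dilation,
  whose job is intra-figure chromatin), and a configurable fraction of
  them is planted as an isotropic Gaussian cluster — the known hot spot;
* confounders follow the classic failure modes of automated dual-stain
  reading: PHH3-positive lymphocytes in the peritumoral stroma (brown,
  no red surround), melanophage-like pigment aggregates (fused granule
  rings whose area exceeds the nucleus size gate, plus sub-minimum
  satellite granules), pale-MART1 patches (red too weak to classify, so
  positives inside them lose their surround and are missed), and
  over-dark MART1 patches. Dark patches are rendered at OD amount 1.6 —
  dark (intensity ≈ 55, well inside the classifier's darkness band) but
  *below 8-bit saturation*: a saturated patch destroys the OD information
  deconvolution needs, and no deconvolution-based classifier can be
  expected to read a numerically black pixel.

Not emulated: photorealistic texture, scanner noise spectra, JPEG
artifacts, stain variation between sections, nuclear chromatin texture,
touching-nuclei segmentation. A green test on phantoms therefore
establishes algorithmic correctness against the stated model of the
stains — not clinical performance on real slides, where staining
variability is the acknowledged open problem.

## Numerical choices and degenerate inputs

* Calibration default 0.46 µm/px (20X scan); most tests render at
  1–2 µm/px to stay within time budgets. At 2 µm/px the 2.5-µm fusion
  dilation degrades to a 1-px structuring element and 4-µm telophase gaps
  occasionally fail to fuse (the real-world split-figure failure mode);
  exact-count assertions therefore run at 1 µm/px.
* Rasterisation is by pixel-centre membership; polygon membership by the
  even-odd rule; areas in mm² are exact pixel counts × s²/10⁶.
* The heat map is integer; argmax ties are resolved as described above,
  deterministically.
* `sample_positions()` rejection-samples with bounded attempts and fails
  loudly when the requested density is infeasible.
* Determinism: a fixed spec + seed yields a bit-identical phantom; the
  generator saves and restores the caller's RNG state.

## Known limitations

* Stain vectors are fixed constants; no per-slide stain estimation or
  normalisation (explicitly out of scope — it is the open problem of the
  field).
* The detector does not segment touching PHH3-negative nuclei (only
  their area contribution matters) and does not classify mitotic phase.
* Survival modelling on the dichotomised indices is out of scope; the
  cut-off presets are shipped as data only.
* Whole-slide pyramidal formats are not decoded; input is a calibrated
  PNG (with a JSON sidecar) at analysis resolution.
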