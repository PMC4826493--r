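# mitospot

Fully automated quantification of tumor-cell proliferation in
PHH3/MART1 dual-stained histology, with automated hot-spot selection.

Melanoma staging uses the mitotic index: the number of dividing tumor
cells in the busiest 1-mm² of the lesion. On a dual stain, a mitosis of a
melanocytic cell reads as a DAB-brown nucleus (phosphohistone H3, a
late-G2/M histone mark) wrapped in AP-red cytoplasm (MART1, a
melanocyte-lineage antigen), over a blue hematoxylin counterstain — so
proliferating lymphocytes (brown, but without red surrounding) can be
told apart from tumor mitoses. `mitospot` is for image-analysis and
digital-pathology researchers who want that reading automated end to end
and *testable*: every stage is exercised against a synthetic slide
phantom with exhaustive ground truth.

## What it computes

Given a calibrated RGB slide image, a tumor outline and optional
exclusion polygons (epidermis/adnexa):

1. **Stain separation and classification.** Per-pixel optical density
   OD = −log₁₀((I+ε)/255) is projected onto a hematoxylin/DAB/AP-red
   basis; a rule cascade labels pixels background / PHH3 / MART1 /
   hematoxylin using density thresholds, an SD contour filter and an HSI
   darkness rescue.
2. **Cell detection.** PHH3 pixels are dilated by 2.5 µm so split
   anaphase/telophase chromatin fuses to one object; objects are gated by
   area ∈ [8, 120] µm², mean DAB OD ≥ 0.5, MART1 surround fraction of a
   2-µm perinuclear ring ≥ 0.3, and irregularity (1 − solidity) ≤ 0.6.
3. **Reference area.** The MART1-verified tumor area: MART1 pixels ∪
   reclassified PHH3-negative tumor nuclei ∪ accepted cells, holes
   filled.
4. **Hot spot.** An object heat map adds 1 inside a 200-µm circle around
   every positive cell; the eligible argmax (deterministic tie-break)
   becomes the centre of a fixed 1-mm² square.
5. **Indices.** Global MART1-adjusted index (cells/mm²), hot-spot count
   per square, and the MART1-adjusted hot-spot index
   count / (tumor area ∩ square).
6. **Evaluation statistics.** Bland–Altman limits of agreement
   (d̄ ± 1.96 SD), manual×automated {0, ≥1} detection tables, hot-spot
   overlap categories (Chebyshev distance of square centres: perfect
   < 0.10 mm, mayor [0.10, 0.75), minor [0.75, 1.0], none > 1.0), and
   diagnostic performance with Clopper–Pearson CIs and rank-based ROC
   area.

## Worked example

```r
library(mitospot)

spec <- phantom_spec(um_per_px = 2, seed = 7)   # 1.5 x 1.5 mm phantom
ph   <- render_phantom(spec)                    # image + ground truth
out  <- run_pipeline(ph$image, spec$lesion_polygon)
print(out$result)
#> <proliferation_result>
#>   global: 49 cells / 0.7224 mm^2 = 67.8 cells/mm^2
#>   hot spot: 47 cells / 0.6864 mm^2 = 68.5 cells/mm^2
print(out$hotspot)
#> <hot_spot> center (813.3, 712.2) um, peak intensity 26, 47 cells in square
```

The phantom planted 50 PHH3⁺/MART1⁺ cells (80 % of them as a Gaussian
cluster of SD 150 µm around (755, 747) µm) plus lymphocytes, pigment
aggregates and pale/over-dark MART1 patches. The pipeline recovered 49
of them over a detected MART1-verified area of 0.72 mm² (truth: 0.76 mm²
— pale patches are invisible to the classifier by design); the selected
hot-spot centre lies 58/35 µm from the planted cluster centre, a
*perfect* overlap by the distance bands:

```r
categorize_overlap(out$hotspot$center, spec$cluster_center)$category
#> [1] "PERFECT"
```

A command-line pipeline is included
(`inst/cli/mitospot simulate|run|evaluate ...`), writing the cell table
(CSV), heat map (PNG), hot spot and proliferation result (JSON, with the
configuration hash) beside a YAML copy of the resolved configuration.

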