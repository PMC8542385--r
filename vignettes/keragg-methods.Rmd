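---
title: "Methods: per-cell keratin aggregate quantification and screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell keratin aggregate quantification and screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keragg)
```

## The measurement

Keratinocytes carrying severe EBS mutations in keratin 14 show cytoplasmic
keratin aggregates: bright puncta of collapsed GFP-tagged keratin, much
brighter than the dim filament network that fills the rest of the cell.
The assay's readout is the fraction of cells carrying at least one such
aggregate. `keragg` computes it per field as

\[
\text{percent positive} = 100 \times
\frac{\#\{\text{aggregate-positive cell regions}\}}
     {\#\{\text{cell regions segmented}\}}
\]

where a *cell region* is one Voronoi region of the image tessellated from
the segmented nuclei, standing in for one cell. The pipeline
(`analyze_field()`) is a fixed composition:

1. **Blur rejection** (`qc_filter()`): the mean Sobel gradient magnitude
   of the GFP channel must reach a threshold. The mean (not sum) makes the
   metric independent of field size; it is invariant to intensity offsets
   and linear in contrast, so a per-setup calibration is a single number.
2. **Nuclei segmentation** (`segment_nuclei()`): Gaussian blur →
   threshold → binarize → fill holes → watershed of the Euclidean
   distance transform → minimum-area filter → consecutive relabelling.
3. **Tessellation** (`voronoi_regions()`): every pixel joins the nearest
   nucleus *component* (exact Euclidean distance to any component pixel,
   ties to the smaller label), so nucleus pixels stay with their own
   label and irregular nuclei are handled correctly, matching the
   binary-Voronoi semantics of interactive image-analysis tools.
4. **Exclusions** (`exclude_background_and_edge()`): regions touching the
   image border are dropped first (a cell cut by the frame cannot be
   scored); remaining regions whose GFP-foreground coverage is below
   `background_coverage_min` are dropped as background.
5. **Aggregate calling** (`enhance_puncta()`, `call_regions()`): a
   difference of Gaussians band-passes the GFP channel; within each
   analyzable region, response components above an intensity threshold
   with area inside an inclusive window count as puncta; one punctum makes
   the region positive.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `qc_threshold` | 0.04 | gradient units | sharp synthetic fields score ~0.14, defocus that destroys few-pixel puncta (σ ≥ 4 px) scores ≤ 0.02; the default sits in the gap |
| `nuclei_blur_sigma` | 1 | px | smooths noise before thresholding without merging adjacent nuclei |
| `watershed_tolerance` | 0.3 | distance units | minimum peak prominence in the distance transform; lower splits touching nuclei more aggressively |
| `min_nucleus_area` | 10 | px | discards debris and watershed slivers |
| `min_foreground` | 0.1 | intensity | floor for the Otsu threshold so an *empty* channel (noise only) segments nothing — Otsu always bisects a histogram, even of pure noise |
| `gfp_blur_sigma` | 2 | px | background-mask smoothing; must be coarse enough that the filament texture merges into one colony mode, else Otsu separates puncta from filaments instead of colony from background |
| `background_coverage_min` | 0.2 | fraction | a region is a cell only if a fifth of it is GFP-covered; the original procedure states the intent without a number |
| `dog_sigma_small`, `dog_sigma_large` | 1, 4 | px | band-pass matched to puncta of a few pixels radius |
| `intensity_mad_mult` | 4 | — | adaptive response threshold = 4 × MAD of the response *within analyzable regions*; measuring the MAD over the whole image would reflect empty-background camera noise and sit far below the filament texture |
| `punctum_area_min/max` | 4 / median nucleus area | px | inclusive window; the upper default rejects whole-cell brightness artifacts |
| screen `cutoff` | 0.25 | fraction | hit = reduction from DMSO baseline of at least 25%, boundary inclusive |
| `min_fragment_area` | 500 | px | published minimum fragment size, inclusive |

All are overridable through `segmentation_params()`,
`aggregate_params()`, `fragment_params()` and the YAML `run_config()`.

## What the synthetic generator emulates — and what it does not

`generate_reporter_field()` builds a subconfluent colony: nucleus centres
rejection-sampled in a disk with a minimum spacing, Gaussian nuclear
blobs, cell footprints as centre-Voronoi cells clipped to the cell
radius, a GFP channel of background plus *oriented* band-pass filament
texture inside the colony, bright circular puncta planted in a controlled
fraction of cells with a peripheral placement bias, and additive Gaussian
noise clipped to [0, 1]. Defaults (320×320 px, 80 cells, aggregate
fraction 0.75, peak 0.85 vs texture 0.15 vs background 0.04) encode the
untreated mutant regime in which 70–80% of cells carry aggregates that
are much brighter than the filament background. The texture is strongly
elongated (~10:1): filament bundles are locally one-dimensional, which is
exactly why a blob filter can separate them from compact puncta; an
isotropic texture of the same amplitude would be punctate itself and
misrepresent the biology.

The generator does **not** model optical point-spread functions, uneven
illumination, cell-shape irregularity, mitotic or apoptotic morphologies,
or intensity variation between cells. Passing tests therefore demonstrate
the *algorithmic* correctness and calibration-consistency of the
pipeline, not its performance on real micrographs; on real data the QC
threshold, blur scales and the intensity multiplier are the knobs to
recalibrate.

Fragment dishes plant irregular blobs grown pixel-by-pixel to *exactly*
the requested area, so the inclusive 500-px boundary can be probed
exactly. Viability fields place sparser nuclei (spacing 3.2 r + 2), as in
subconfluent LIVE/DEAD wells, with dead nuclei co-located in the Hoechst
and EthD-1 channels.

## Numerical choices

- Images are floating matrices in [0, 1], `[row, col]`, 0-based geometry
  only at the ground-truth level; bit depth exists only in I/O (16-bit
  TIFF out; 8/16-bit normalized on read).
- Gaussian blur and Sobel gradients are applied as dense separable
  operators with whole-sample *reflect* boundaries — exact, cached per
  image size, and free of the spurious border edges that zero padding
  would create.
- The tessellation uses an exact squared-Euclidean distance transform
  per nucleus component (Felzenszwalb–Huttenlocher lower envelope, in
  C++), pruned to provably sufficient windows by a global all-site
  transform: a component can only win a pixel whose global
  nearest-site distance reaches the component's bounding box. Distance
  ties go to the smaller label, deterministically.
- Connected components are 8-connected (4-connected available); the
  region-calling rule assigns a component straddling a boundary to the
  region holding its maximum-response pixel (first such pixel in
  column-major order on exact ties).
- `aggregate_fraction × n_cells` rounds half up and is recorded in the
  scene; degenerate inputs (blank channels, empty dishes, zero analyzable
  regions) return explicit empty results rather than errors, while
  impossible requests (undefined baseline, no segmented cells) raise
  errors naming the stage.

## Design choices where the procedure was open

The published description names operations but almost no numbers; the
open points were resolved as follows. The blur-rejection "edge filter" is
realized as the mean Sobel gradient with a single threshold. The
background criterion ("remove background portions") is formalized as
GFP-foreground coverage per region with an Otsu mask. The
intensity-and-size rule uses a MAD-adaptive intensity threshold so it
transfers across exposure scales, with the MAD measured inside analyzable
regions. The 25% hit cut-off is applied to well means (whether the
original screen applied it per replicate is not stated). Positive-control
wells are reported but never enter the baseline or hit set. Hit and
fragment boundaries are inclusive ("at least"). Edge exclusion precedes
background exclusion so the three region sets partition the labels.

## Problem sizes used in validation

The packaged tests and the acceptance script validate at desk scale,
chosen once: default fields of 80 cells at 320² px for recovery studies
(10 seeds × fractions 0, 0.2, 0.7), screen plates of 96 wells × 1 field
at 256² px with 90 cells per field (10 seeds), oracle-equivalence
fixtures at ≤ 64² px, and dishes of radius 100–160 px. At these sizes a
plate analyzes in ~25 s and a field in well under a second on one CPU.

## Known limitations

- Counting is per-region, not per-object-track: a cell whose nucleus
  fails segmentation silently joins a neighbouring region.
- The dead-nuclei count is independent of the total count (no
  colocalization matching), faithful to the original macro; gross channel
  misregistration therefore produces a flagged-inconsistent result rather
  than a corrected one.
- Dose–response analysis reports monotonicity and a rank-correlation
  trend only; potency (IC50) fitting is deliberately out of scope.
- The dish detector assumes the dish is the dominant bright region
  (≥ 25% of the frame); unusual framings should use `full_frame`.
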