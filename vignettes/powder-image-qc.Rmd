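---
title: "Fractal and texture signatures of powder aggregation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal and texture signatures of powder aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powdertex)
```

## The problem

A milled powder that leaves specification usually does so in one of two
recognizable spatial ways: a coarse fraction appears alongside the correct
fine fraction (a bimodal, right-shifted particle size distribution), and the
coarse material often arrives as aggregates that clump on a dispersed slide.
Volume-based PSD curves from laser diffraction flag the shift but cannot see
the arrangement. `powdertex` quantifies the arrangement directly from
transmitted-light micrographs of the dispersed powder, where particles are
dark objects on a bright field, using two complementary families of image
descriptors and a chemometric readout.

## Box-counting fractal dimension

For a binary foreground mask the package counts, at every dyadic box size
$r \in \{1, 2, 4, \dots, 2^K\}$, the number $n(r)$ of grid-aligned
$r \times r$ boxes containing at least one foreground pixel. The
Minkowski–Bouligand (box-counting) dimension is estimated as the magnitude
of the ordinary least-squares slope of $\log n(r)$ against $\log(1/r)$.
The per-scale *local* dimension is the negative discrete gradient
$-\Delta \log_2 n / \Delta \log_2 r$, central differences at interior
scales and one-sided at the two extremes; its mean and standard deviation
over scales summarize one mask.

Numerical conventions, all of which affect the counts and are therefore
fixed and documented:

* **Grid anchor and padding.** The counting grid is anchored at the
  top-left corner and the mask is padded with background to the next
  power-of-two square, so box sizes halve cleanly from the full canvas to
  one pixel. Counts are anchor-dependent in general; no anchor sweep is
  performed.
* **Binarization is strict.** Foreground is `intensity < T`. A pixel equal
  to the threshold is background. This makes masks nested in `T` (box
  counts are monotone in the threshold at every scale — a property the test
  suite asserts), and fixes an ambiguity that an inclusive comparison would
  resolve the other way; nothing downstream depends on the choice beyond
  a one-gray-level shift of the sweep.
* **Degenerate masks.** Scales with zero counts cannot enter a log
  regression. Because occupancy is hereditary across scales, a mask is
  either empty (all counts zero) or fully regular (all counts positive);
  empty masks are reported as dimension 0 with an explicit degeneracy flag
  rather than `NA`, so threshold sweeps stay rectangular.
* **Regression scales.** All valid dyadic scales enter the fit; no trimming
  of extreme scales is applied. Trimming is easy to emulate through the
  `scale_range` band (in pixels) accepted by the summary functions, which
  is also how the analysis restricts attention to a physical band such as
  1.7–217 µm.

The engine is verified against a brute-force tile scan on random masks
(exact integer equality), against the sandwich bound
$n(2r) \le n(r) \le 4\,n(2r)$, and against constructions with known
dimension: a full square (exactly 2 at every scale), a one-pixel line
(exactly 1), a Sierpinski triangle on a dyadic canvas (the bitwise-AND
construction makes the estimate exactly $\log 3/\log 2$), and a Sierpinski
carpet (canvas side $3^d$, so dyadic boxes do not align with the
construction and the estimate carries a small bias — about 0.012 below
$\log 8/\log 3$ at depth 5 — which is why the carpet tolerance is wider).

**Threshold sweep.** The per-image signature evaluates the mean local
dimension at thresholds 0 to 255 in steps of 5 (52 points). The sweep
endpoints and step are configurable; the default mirrors standard practice
for 8-bit micrographs and keeps the signature short enough for PCA with
small sample counts.

## Gray-level co-occurrence texture

The GLCM at offset $(\Delta row, \Delta col)$ counts ordered pixel pairs;
it is deliberately *asymmetric* (no transposed pairs are added) and
normalized by the realized in-bounds pair count $R$. Four directions are
evaluated at pixel distance $D$ (default 1): 0° $(0, D)$, 45° $(-D, D)$,
90° $(-D, 0)$ and 135° $(-D, -D)$ — the standard Haralick geometry. From
the normalized matrix the package computes ASM, CON, COR and ENT, plus the
directional mean µ.

Conventions:

* **Gray levels.** $N_g = 256$ by default (the full 8-bit range).
  Re-quantization to fewer levels is available but off by default; COR is
  invariant to the 0-based level indexing because it is a correlation.
* **Correlation degeneracy.** When either marginal standard deviation is
  zero (e.g. a constant image), COR is defined as 1. Marginal standard
  deviations are *population* (probability-weighted) moments, not
  sample-corrected — they are moments of a distribution, not of data.
* **Entropy.** Natural logarithm by default with $0 \log 0 := 0$; the base
  is configurable and recorded in batch configs, since published tables do
  not always state it.
* **Rounding.** Tables are exported with 3-decimal half-up rounding;
  internal values keep full precision. Half-up (not banker's) rounding is
  what reproduces conventional printed descriptor tables.

Aggregation is a fixed hierarchy of unweighted means: directions are
averaged within an image (µ), images within a sample, samples within a
condition. The order matters only through weighting when counts differ;
fixing it makes condition tables exactly the mean of their sample rows,
which the tests assert, and matches how reference per-sample tables
combine into condition tables (verified on the bundled reference table:
e.g. ASM µ 0.104 for one OOS sample; condition means 0.123/0.199/0.958
for ASM/CON/COR).

## Chemometrics

Curves are assembled into a samples × variables matrix, **autoscaled**
(per-variable mean 0 and *sample* (n−1) standard deviation 1 — the
convention of the major chemometrics toolboxes), and decomposed by SVD.
Zero-variance variables (e.g. the threshold-0 point of an FD sweep, which
is identically degenerate) carry no information on the autoscaled metric
and are dropped with a warning and a record. Equivalence with the
eigendecomposition of the correlation matrix is part of the test contract,
with the eigen route used only as the independent oracle.

Loading signs are made deterministic (largest-magnitude element of each
loading positive), since score-plot orientation is otherwise arbitrary; the
separation report then states explicitly which group sits on the positive
side of PC1 instead of assuming an orientation. Group dispersion on the
score plane is summarized by 95% confidence ellipses with the
$\chi^2_{2}$ radius, and group separation by per-component standardized
mean differences and the mean silhouette width on PC1 (exploratory
descriptors; no significance claims).

## The synthetic generator

The generator exists so that the full pipeline is testable without
proprietary micrographs. It emulates, qualitatively, the two batch classes:

* **IS-like:** diameters from a single lognormal (median 40 µm,
  `sdlog` 0.35 — a typical span for milled API powders), placed uniformly.
* **OOS-like:** a 0.6/0.4 mixture of the same fine mode with a coarse mode
  (median 120 µm, `sdlog` 0.25), placed by a Neyman–Scott parent–child
  process (Gaussian scatter, radius 200 µm) as the aggregation surrogate.

Rendering follows transmitted-light physics to first order: each particle
is a filled disk at its calibrated pixel radius (1.7 µm/px by default, the
rounded calibration of a 1× acquisition where 1 mm ≈ 575 px); where $k$
particles overlap, intensity is attenuated multiplicatively,
$I = bg \cdot (particle/bg)^k$, so aggregates develop the dark cores that
drive low-threshold fractal responses in real images. Defocus is a
Gaussian blur (sd 2 px) and sensor noise additive Gaussian (sd 2 gray
levels). The noise scale and the default particle count (60 per 512 px
image) were set on realism grounds: they keep areal coverage in the
10–30% range typical of a properly dispersed slide for both classes and
produce descriptor magnitudes of the same order as published
transmitted-light tables (entropies of a few nats rather than the ~7–8
nats a heavily noise-dominated render produces). With these defaults the
expected class contrasts emerge as orderings — OOS ensembles show higher
mean FD across the 20–170 threshold band, lower ASM, higher CON and ENT,
and complete PC1 separation of the FD-threshold curves — and the test
suite asserts exactly these orderings, never particular values.

What the generator does **not** emulate: irregular particle shapes (disks
only by default; laser diffraction makes the same sphere assumption),
uneven illumination, 3-D stacking geometry beyond the multiplicative
attenuation, agglomerate mechanics, and diffraction-limited optics.
Passing the ensemble tests therefore demonstrates that the *pipeline*
recovers planted class structure of the stated kind — not that any
particular real powder will separate, which depends on dispersion quality
and acquisition conditions.

## Problem sizes and determinism

The shipped tests run the engines against brute-force oracles on
50 random 64×64 masks and batches of random 16×16 images, fractal fixtures
up to side 512, and ensemble checks at the full default conditions
(3 samples × 2 images × 512×512 px per class); pipeline round-trips use
96 px canvases with a coarser 5 µm/px calibration so every default
diameter fits. All stochastic stages take explicit seeds: per-image seeds
are derived deterministically from the base seed, making ensembles and
batch CSVs reproducible bit for bit, which the suite also asserts.

## Known limitations

* Box counts are anchor- and padding-dependent, as in any fixed-grid
  box-counting implementation; comparisons are meaningful within a fixed
  geometry only.
* The carpet bias noted above applies generally to sets whose natural
  scale ratio is not 2: dyadic grids estimate their dimension with a small
  systematic offset.
* The asymmetric GLCM makes COR sensitive to direction reversal in
  principle; for natural micrographs the 0°/180° difference is negligible,
  and the four-direction mean further suppresses it.
* With very few samples (the realistic QC regime), PCA ellipses at 95%
  from 3 points are descriptive at best; the separation report's silhouette
  is the more robust summary.
* The generator's class contrast is a planted effect at documented
  parameters; it calibrates and tests the software, it does not validate
  the method on real powders.
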