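---
title: "Methods: correlating tissue morphology with MSI peptide signatures"
author: "msicor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating tissue morphology with MSI peptide signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msicor)
```

## The problem this package addresses

Label-free second-harmonic-generation (SHG) microscopy reveals the collagen
scaffold of a tissue section, H&E histology reveals its cellularity, and
MALDI mass spectrometry imaging (MSI) measures a full tryptic-peptide
spectrum at every raster position (here 50 µm, m/z 800–3200). `msicor`
implements an open, testable version of the correlative workflow that joins
these three views of the *same* section: morphology maps are computed,
thresholded into region classes, co-registered onto the MSI raster, and the
peptide content of the resulting region strata is compared by supervised
ROC analysis, PCA, and spatial segmentation. The motivating application is
colorectal cancer, where left-sided (LSCC) and right-sided (RSCC) tumours
are contrasted, but nothing in the code is specific to that design.

## Morphology maps

**Collagen coherence.** The SHG image is denoised by zeroing everything
below a global Otsu threshold (256-bin histogram; `otsu_foreground()`).
On the denoised image the structure tensor

$$J = G_{\sigma_w} \ast \left( \nabla I \, \nabla I^{\top} \right),
\qquad \nabla I \text{ at scale } \sigma_g,$$

is evaluated per pixel and the coherence is
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2) \in [0,1]$, the canonical
anisotropy measure of fibre-orientation analysis: 1 for perfectly aligned
structures, 0 for isotropic texture. Defaults are $\sigma_g = 2$ px and
$\sigma_w = 8$ px at an acquisition scale of about 0.38 µm/px; both are
exposed because they trade localisation against stability (the window scale
must be large enough to average several fibres, or even a disordered field
looks locally coherent). All convolutions use reflective padding. Where the
tensor trace falls below $\varepsilon = 10^{-3}\times$ the mean gradient
energy the coherence is defined as 0; this keeps flat interiors from
producing noise-driven anisotropy. Foreground pixels with coherence in
$[0, 0.5)$ are classified *chaotic* and $[0.5, 1]$ *organised*; the
boundary value 0.5 closes upward, so the two classes partition the
foreground exactly.

**Nuclei density.** Nuclei segmentation itself is external (a pre-trained
deep segmenter in the motivating study); `msicor` consumes its centroids
(CSV) or label image. Centroids are counted on half-open square tiles
(default 100 µm — coarse enough for stable counts, fine enough to map onto
the 50 µm MSI raster), optionally smoothed (Gaussian, σ = 1 tile), and
min–max normalised to [0, 1]. Values in $[0, 0.5)$ are *LND* (low nuclei
distribution), $[0.5, 1]$ *HND*, mirroring the coherence rule. A map in
which every tile holds the same count has no contrast to normalise; it is
set to 0.5 everywhere by convention so classification stays defined.

## Co-registration and region labels

All modalities live in physical micrometres. An affine transform (2×3
matrix; identity when modalities share a frame, as the phantom generator
guarantees) maps each source map into MSI coordinates. Finer-than-raster
maps are aggregated per 50 µm pixel footprint — continuous values by the
mean, class maps by majority vote with background excluded; coarser maps
are sampled at the pixel centre through the inverse transform. A
landmark-based least-squares helper (`fit_affine()`, ≥ 3 pairs) reports its
RMS residual rather than guessing alignment quality. Pathologist
annotations arrive as QuPath-dialect GeoJSON polygons; a pixel carries a
polygon's class iff its centre lies inside under the even-odd rule, with
edge points counting as inside and later features overriding earlier ones
(each override is logged). Percent areas are computed over non-background
pixels and always sum to 100.

## MSI processing

Spectra are TIC-normalised: every spectrum is scaled so its total ion count
equals the dataset mean over included pixels, which preserves relative
intensities and is idempotent. Zero-TIC pixels cannot be normalised; they
are flagged and excluded from all statistics rather than imputed. Peak
finding operates on the dataset mean spectrum (uniform grid, default
0.1 Da; per-pixel maximum per bin, averaged over pixels): the "medium"
noise-reduction mode applies a 3-bin running median, local maxima are
plateau-aware (a median-flattened peak top is one peak, centred), and a
maximum qualifies when it exceeds the spectrum's robust baseline (median)
by at least `snr_min` (default 3) times the robust noise
(1.4826 × MAD). A baseline-relative threshold was chosen because a purely
multiplicative SNR cut degenerates whenever truncated additive noise gives
the baseline a positive median — the threshold then falls below the
baseline and every smoothed wiggle qualifies. Each peak also has to be the
maximum of its own ± half-width window so flank wiggles of a larger peak
are not reported twice. Peaks receive ± 0.4 Da intervals, truncated at the
midpoint between neighbouring centres; membership is half-open so intervals
stay disjoint. The feature value of pixel *p* at peak *k* is the *maximum*
intensity inside interval *k* ("maximal interval" extraction), 0 when no
point falls inside. Deisotoping and baseline subtraction are deliberately
out of scope.

Both imzML 1.1 (continuous and processed binary mode) and a plain-text
fixture bundle are read and written; the imzML writer derives its UUID from
the content so identical datasets give byte-identical files and the writer
leaves the RNG state untouched.

## Discriminative statistics

For each peak and an ordered class pair (A, B), the ROC AUC with B positive
is estimated as $P(X_B > X_A) + \tfrac12 P(X_B = X_A)$ over all cross-class
pixel pairs — the normalised Mann–Whitney U statistic, computed from ranks.
The two-sided p-value uses the normal approximation with tie correction and
no continuity correction (the pixel counts are in the hundreds;
permutation p-values would change nothing material and are much slower).
A peak is a candidate marker iff AUC ≥ 0.6 or ≤ 0.4 *and* raw p < 0.01;
Benjamini–Hochberg q-values are reported alongside for information but do
not drive selection, matching the workflow this package reimplements.

PCA runs on the candidate features, column-mean-centred and unscaled by
default (TIC-normalised intensities share a scale; unit-variance scaling is
a flag). Signs follow a deterministic convention — the largest-magnitude
loading of each component is made positive — so repeated runs agree
exactly. Scores map back to the pixel grid as component intensity images.

Protein assignment matches detected peak centres against an LC-MS/MS
peptide table: a candidate must differ by strictly less than 0.15 Da
(evaluated with a 10⁻⁹ Da guard so a difference printed as exactly 0.15 is
rejected), the smallest mass difference wins, ties break toward the higher
identification score, and a protein is *identified* only when ≥ 2 distinct
peaks match ≥ 2 distinct peptide sequences of that protein — one ambiguous
peak can never identify a protein.

The percent areas of the morphology classes are compared across tumour
groups by a two-way fixed-effects ANOVA with interaction, using Type II
sums of squares so mildly unbalanced cohorts remain interpretable; on
balanced designs these coincide with the textbook sequential decomposition
(asserted to 10⁻⁹ in the tests).

## Spatial segmentation

`bisecting_kmeans()` implements divisive clustering: starting from one
cluster, the leaf with the largest within-cluster SSE is split by 2-means
(greedy k-means++ initialisation, 10 restarts, lowest-SSE split kept) until
K segments exist. K defaults to 5 — the segment count the motivating
figures display — and is a per-analysis choice; automatic model selection
is out of scope. The default metric row-standardises each pixel's feature
vector before Euclidean 2-means, making squared distance an affine function
of Pearson correlation, the common choice for MSI segmentation; plain
Euclidean is a flag, as is splitting the largest-cardinality leaf instead.
Pixels are processed in canonical raster order and all randomness flows
from one mandatory seed, so runs are reproducible and permuting the input
rows permutes the labels identically. Segment composition tables report,
per region class, the percentage of its pixels in each segment; rows sum
to 100.

## The phantom generator

Because the motivating study deposited no raw data, every stage is
validated against `phantom_spec()` phantoms: co-registered synthetic
modalities on one physical frame with known ground truth. The default
layout is a 2 × 2 mm tissue, 40 × 40 MSI pixels at 50 µm, crossing tumour
group (left/right half) with coherence class and density class (four
horizontal strips) so every comparison stratum is populated.

* **SHG**: line-segment fibres (default 8000/mm², 100 µm long) with
  orientations from a wrapped normal of dispersion κ per region — κ → 0
  gives an aligned, *organised* field; large κ a uniform, *chaotic* one.
  Fibres are splatted with bilinear weights so rasterisation staircase
  anisotropy does not leak into the coherence estimate, then lightly
  blurred over a weak-noise background.
* **Nuclei**: an inhomogeneous Poisson process, 3000/mm² in HND regions
  versus 300/mm² in LND (ratio 10, chosen so the min–max midpoint
  separates the classes cleanly at 100 µm tiles).
* **MSI**: 50 Gaussian peaks (σ = 0.2 Da) on an 800–1300 Da axis at
  0.1 Da — a compact slice of the acquisition range that keeps a full
  datacube around 60 MB; 10 planted peaks differ between the two classes
  of a chosen attribute by 1.5 within-class SD (alternating direction),
  on top of a log-normal per-pixel TIC factor (sdlog 0.2) and additive
  truncated-Gaussian baseline noise. Effect sizes are specified in units
  of within-class SD on TIC-normalised intensities so recovery tests are
  scale-free.
* **Peptides**: synthetic proteins with two peptides each within 0.05 Da
  of distinct planted peaks, plus decoys more than 0.2 Da from every peak;
  scores uniform in [20, 100].

Everything is a deterministic function of spec + seed (byte-identical
files on rerun), and the generators restore the caller's RNG state.
`default_phantom()` renders SHG at 2 µm/px so a full multimodal phantom
builds in seconds; SHG-only validation phantoms use about 1 µm/px on
300–800 µm fields, and the statistical validations use 400–1600 pixels and
10–50 replicate phantoms — sizes chosen so each property is measured with
comfortable margin at interactive runtimes. What the phantom deliberately
omits: isotope envelopes, matrix clusters, chemical-noise structure,
H&E colour synthesis, stain/section deformation between modalities
(co-registration is exercised through explicit affine transforms, not
recovered from image content). Passing tests therefore demonstrate the
*algorithms* are correct and calibrated, not that real-tissue nuisances
are handled.

## Numerical choices and edge cases

* Binning uses half-open intervals everywhere (tiles, peak intervals, MSI
  pixel footprints) with a 10⁻⁷-bin epsilon against floating-point jitter
  of grid-aligned coordinates.
* Majority votes break ties toward the lower class code; annotation
  overlaps resolve last-listed-wins, logged.
* Degenerate inputs fail loudly: constant images (no Otsu threshold),
  all-zero datacubes, empty peptide tables, empty design cells, K larger
  than the pixel count.
* A 2-means split of a leaf whose rows are all identical falls back to a
  deterministic positional split; this can only arise on duplicated
  spectra.
* The pipeline manifest stamps every output table with an FNV-1a hash of
  the analysis-relevant configuration (output paths excluded), so a table
  can always be traced to the exact parameter set that produced it.

## Known limitations

Registration is affine only; nonrigid tissue deformation between imaging
rounds must be handled upstream. The ROC p-value is asymptotic; for very
small strata (tens of pixels) an exact or permutation test would be
preferable. Peak detection parameters are surrogates for an unpublished
vendor pipeline and are therefore fully configurable rather than fixed.
The ANOVA treats percent areas as unbounded responses; with percentages
near 0 or 100 a transformed or beta model would be more faithful.
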