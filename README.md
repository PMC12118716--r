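# msicor

Correlative analysis of MALDI mass spectrometry imaging (MSI) with
label-free microscopy and histology.

Tumour tissue looks different in every modality: second-harmonic-generation
(SHG) microscopy shows how ordered the collagen scaffold is, H&E histology
shows where the cells are, and MALDI MSI records a tryptic-peptide mass
spectrum at every 50 µm raster position. `msicor` is for analysts who have
all three views of the same section and want to ask, reproducibly, *which
peptides distinguish which kinds of tissue region* — for example left-sided
versus right-sided colorectal carcinoma (LSCC / RSCC), cell-rich versus
cell-poor areas, or ordered versus disordered stroma.

## What it computes

* **Collagen coherence heatmaps** from SHG images: Otsu denoising, then the
  structure-tensor coherence (λ₁−λ₂)/(λ₁+λ₂) ∈ [0, 1]; regions are
  classified *chaotic* ([0, 0.5)) or *organised* ([0.5, 1]).
* **Nuclei-density heatmaps** from externally segmented nuclei centroids:
  counts per unit area, min–max normalised; *LND* / *HND* split at 0.5.
* **MSI processing**: imzML 1.1 and plain-text fixture I/O, TIC
  normalisation, dataset-wide peak detection on the mean spectrum, and
  "maximal interval" feature extraction (max intensity per ±0.4 Da peak
  interval per pixel).
* **Co-registration** of heatmaps, class maps and QuPath GeoJSON
  annotations onto the MSI pixel grid through explicit affine transforms.
* **Supervised ROC discrimination** per peak (Mann–Whitney AUC =
  P(X_B > X_A) + ½P(X_B = X_A)); candidate markers are peaks with
  AUC ≥ 0.6 or ≤ 0.4 and p < 0.01.
* **Protein assignment** by accurate mass: |Δm| < 0.15 Da (strict),
  smallest Δ then highest score, and ≥ 2 distinct peptides on ≥ 2 distinct
  peaks per identified protein.
* **PCA** on candidate features with deterministic sign convention, and
  **bisecting k-means** spatial segmentation (largest-SSE leaf, seeded
  k-means++ 2-means splits) with per-region segment composition.
* **Two-way ANOVA** (Type II) comparing percent areas across groups.
* A fully seeded **multimodal phantom generator** that renders all inputs
  on one physical frame with known ground truth, so the entire pipeline is
  testable without any external data.

## Worked example

Generate a phantom (2 × 2 mm tissue, 40 × 40 MSI pixels, 50 peaks of which
10 discriminate the two tumour groups at 1.5 SD) and run the full workflow:

```r
library(msicor)

spec <- default_phantom(seed = 42)
dir <- file.path(tempdir(), "phantom42")
write_phantom(spec, dir)      # shg.tif, nuclei.csv, msi/, regions.geojson,
                              # peptides.tsv, manifest.json (ground truth)

report <- run_pipeline(run_config(list(
  msi         = file.path(dir, "msi"),
  shg         = file.path(dir, "shg.tif"), um_per_px = 2,
  nuclei      = file.path(dir, "nuclei.csv"),
  annotations = file.path(dir, "regions.geojson"),
  peptides    = file.path(dir, "peptides.tsv"),
  seed        = 42)))
#> detected 50 peaks
#> ROC group: 10/50 candidate peaks
#> proteins: 5 identified of 5 matched accessions
#> PCA: first 3 components explain 62.73% of variance

head(subset(report$roc$group, selected,
            select = c(mz, auc, p_value, direction)), 5)
#>         mz       auc       p_value direction
#> 7   864.85 0.8684000 1.325734e-143   up_in_b
#> 19  985.45 0.1657453 1.433308e-118 down_in_b
#> 20  995.35 0.8537391 1.473301e-132   up_in_b
#> 26 1055.25 0.1252094 1.471347e-148 down_in_b
#> 27 1065.15 0.8561516 2.406569e-134   up_in_b

report$areas$coherence_class
#>       class n_pixels  percent
#> 1   chaotic      801 50.09381
#> 2 organised      798 49.90619

report$composition            # segment share per tumour group (%)
#>   class segment_1 segment_2 segment_3 segment_4 segment_5
#> 1  LSCC      40.5     5.875     27.00     6.125      20.5
#> 2  RSCC       0.0    47.125     0.25    52.625      0.0
```

Reading the output: all 10 planted markers are selected (AUC far from 0.5,
direction matching the planted sign; `up_in_b` means higher intensity in
RSCC), the chaotic/organised split recovers the phantom's 50/50 layout, the
five synthetic proteins — and no decoys — are identified from the peptide
table, and the proteomic segments separate the two groups almost
completely. `report$labels`, `report$pca` and `report$segmentation` hold
the per-pixel tables behind these summaries; with `out_dir` set, everything
is written as TSV stamped with the configuration hash.

A thin command-line wrapper over the same functions is installed at
`inst/cli/msic.R` (subcommands `phantom`, `coherence`, `density`, `peaks`,
`roc`, `segment`, `run`).

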