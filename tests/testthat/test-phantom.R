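one_region <- function(coh = "organised", den = "HND", ext = c(400, 400)) {
  data.frame(name = "r", x0 = 0, y0 = 0, x1 = ext[1], y1 = ext[2],
             group = "LSCC", coherence_class = coh, density_class = den)
}

test_that("aligned and isotropic fibre phantoms hit the coherence limits", {
  spec_a <- phantom_spec(extent_um = c(400, 400), image_um_per_px = 1,
                         regions = one_region("organised"),
                         kappa_organised = 0, 
                         seed = 5)
  cm_a <- coherence_map(make_shg(spec_a)$image, 2, 8)
  expect_gt(mean(cm_a$values[cm_a$foreground]), 0.9)

  spec_c <- phantom_spec(extent_um = c(400, 400), image_um_per_px = 1,
                         regions = one_region("chaotic"),
                         seed = 6)
  cm_c <- coherence_map(make_shg(spec_c)$image, 2, 8)
  expect_lt(mean(cm_c$values[cm_c$foreground]), 0.3)
})

test_that("two-region phantom classification matches ground truth", {
  regions <- data.frame(name = c("top", "bottom"),
                        x0 = 0, y0 = c(0, 400), x1 = 800, y1 = c(400, 800),
                        group = "LSCC",
                        coherence_class = c("organised", "chaotic"),
                        density_class = "HND")
  spec <- phantom_spec(extent_um = c(800, 800), image_um_per_px = 1,
                       regions = regions, seed = 9)
  shg <- make_shg(spec)
  rm <- classify_coherence(coherence_map(shg$image, 2, 8))
  fg <- rm$classes != 0L
  truth <- ifelse(row(rm$classes) <= 400, 2L, 1L)  # organised top
  expect_gt(mean(rm$classes[fg] == truth[fg]), 0.9)
})

test_that("nuclei phantom is Poisson-consistent and classes recover", {
  spec <- default_phantom(seed = 41)
  nuc <- make_nuclei(spec)$nuclei
  # expected count: sum of intensity x area over regions
  lam <- with(spec$regions,
              sum(ifelse(density_class == "HND", spec$nuclei_high_per_mm2,
                         spec$nuclei_low_per_mm2) *
                    (x1 - x0) * (y1 - y0) / 1e6))
  expect_lt(abs(nrow(nuc$centroids) - lam), 4 * sqrt(lam))

  # 10:1 intensity ratio: HND recovery of high-intensity tiles >= 80%
  rm <- classify_density(density_map(nuc, tile_um = spec$tile_um))
  tx <- (col(rm$classes) - 0.5) * spec$tile_um
  ty <- (row(rm$classes) - 0.5) * spec$tile_um
  rid <- msicor:::region_of(spec, tx, ty)
  truth_hnd <- spec$regions$density_class[rid] == "HND"
  expect_gte(mean(rm$classes[truth_hnd] == 2L), 0.8)
  expect_gte(mean(rm$classes[!truth_hnd] == 1L), 0.8)

  # points only appear where intensity is positive
  spec0 <- phantom_spec(extent_um = c(400, 400),
                        regions = one_region(den = "HND"),
                        nuclei_low_per_mm2 = 0, seed = 3)
  spec0$regions <- rbind(spec0$regions,
                         data.frame(name = "void", x0 = 0, y0 = 200,
                                    x1 = 400, y1 = 400, group = "LSCC",
                                    coherence_class = "chaotic",
                                    density_class = "LND"))
  spec0$regions$y1[1] <- 200
  nuc0 <- make_nuclei(spec0)$nuclei
  expect_true(all(nuc0$centroids$y_um < 200))
})

test_that("MSI phantom plants recoverable effects and honest nulls", {
  spec <- default_phantom(seed = 19, effect_sd = 2)
  msi <- make_msi(spec)
  ds <- tic_normalize(msi$dataset)
  fm <- build_feature_matrix(
    ds, peak_table(msi$manifest$center, msi$manifest$center - 0.4,
                   msi$manifest$center + 0.4))
  lab <- region_labels(ds, group = msi$truth$group)
  rocs <- roc_per_peak(fm, lab, "group", "LSCC", "RSCC")
  planted <- msi$manifest$planted
  # 2 SD effects give AUC far from 0.5 in the planted direction
  expect_true(all(abs(rocs$auc[planted] - 0.5) > 0.3))
  up <- msi$manifest$direction == 1
  expect_true(all(rocs$auc[planted & up] > 0.8))
  expect_true(all(rocs$auc[planted & !up] < 0.2))
  # non-planted peaks stay near 0.5 at n = 800 per class
  expect_true(all(abs(rocs$auc[!planted] - 0.5) < 0.1))
})

test_that("a noise-free single-region phantom gives identical spectra", {
  spec <- phantom_spec(extent_um = c(200, 200),
                       regions = one_region(ext = c(200, 200)),
                       noise_cv = 0, tic_sdlog = 0, additive_sd = 0,
                       n_peaks = 5L, n_planted = 0L, seed = 2)
  ds <- make_msi(spec)$dataset
  expect_equal(n_pixels(ds), 16)
  ref <- ds$intensity[1, ]
  for (i in 2:16) expect_equal(ds$intensity[i, ], ref)
})

test_that("peptide tables follow the matching geometry of the planted peaks", {
  spec <- default_phantom(seed = 27)
  msi <- make_msi(spec)
  pep <- make_peptide_table(spec, msi$manifest)
  syn <- pep[grepl("^SYN", pep$accession), ]
  dec <- pep[grepl("^DEC", pep$accession), ]
  expect_true(all(table(syn$accession) >= 2))
  for (mz in syn$mz)
    expect_lte(min(abs(mz - msi$manifest$center)), 0.05)
  for (mz in dec$mz)
    expect_gt(min(abs(mz - msi$manifest$center)), 0.15)
  expect_true(all(pep$score >= 20 & pep$score <= 100))

  # identification pipeline: synthetic proteins in, decoys out
  pk <- peak_table(msi$manifest$center, msi$manifest$center - 0.4,
                   msi$manifest$center + 0.4)
  res <- assign_proteins(pk, pep)
  idd <- res$proteins$accession[res$proteins$identified]
  expect_true(all(grepl("^SYN", idd)))
  expect_setequal(idd, unique(syn$accession))
})

test_that("phantom bundles are byte-identical for identical spec and seed", {
  spec <- phantom_spec(extent_um = c(400, 400), image_um_per_px = 2,
                       mass_range = c(800, 850), n_peaks = 5L,
                       n_planted = 2L, seed = 77)
  d1 <- file.path(withr::local_tempdir(), "p1")
  d2 <- file.path(withr::local_tempdir(), "p2")
  write_phantom(spec, d1, imzml = TRUE)
  write_phantom(spec, d2, imzml = TRUE)
  for (f in list.files(d1, recursive = TRUE)) {
    a <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(a, b)
  }
})

test_that("modalities share one frame: polygons agree with the pixel truth", {
  spec <- default_phantom(seed = 13)
  msi <- make_msi(spec)
  f <- file.path(withr::local_tempdir(), "regions.geojson")
  write_annotations(phantom_annotations(spec), f)
  grp <- import_annotations(f, msi$dataset, classes = c("LSCC", "RSCC"))
  m <- match(paste(msi$truth$ix, msi$truth$iy), paste(grp$ix, grp$iy))
  expect_true(all(grp$class[m] == msi$truth$group))
  tum <- import_annotations(f, msi$dataset, classes = "tumour")
  expect_true(all(tum$class == "tumour"))
})

test_that("phantom generators leave the caller's RNG state untouched", {
  set.seed(1); before <- .Random.seed
  invisible(make_msi(default_phantom(seed = 99,
                                     mass_range = c(800, 820),
                                     n_peaks = 3L, n_planted = 0L,
                                     extent_um = c(200, 200),
                                     regions = one_region(ext = c(200, 200)))))
  expect_identical(.Random.seed, before)
})
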