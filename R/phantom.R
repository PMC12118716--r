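# run expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a co-registered multimodal phantom
#'
#' Defines, on one shared physical frame, the regions and noise model from
#' which all synthetic modalities are rendered: SHG fibre images, nuclei
#' point patterns, MSI datacubes with planted region-specific peaks,
#' annotations and peptide tables. The default layout crosses tumour group
#' (left/right half: LSCC/RSCC) with coherence class and nuclei-density
#' class (four horizontal strips), giving a 2 x 2 x 2 design on a
#' 2 x 2 mm tissue, 40 x 40 MSI pixels at 50 um raster.
#'
#' @param extent_um Tissue extent (width, height) in micrometres.
#' @param msi_spacing_um MSI raster pitch (default 50).
#' @param image_um_per_px SHG pixel size (default 0.38, the acquisition
#'   scale; the bundled [default_phantom()] coarsens this for speed).
#' @param tile_um Nuclei-density tile (default 100).
#' @param regions Data frame: `name`, `x0`, `y0`, `x1`, `y1` (um),
#'   `group`, `coherence_class`, `density_class`. NULL = default layout.
#' @param mass_range,mz_grid_da m/z axis (default 800-1300 Da at 0.1 Da).
#' @param mz_sigma_da Gaussian peak width in Da (default 0.2).
#' @param n_peaks,n_planted Total and planted discriminative peak counts.
#' @param effect_sd Planted between-class effect size in units of
#'   within-class SD (default 1.5).
#' @param planted_attribute Which attribute the planted peaks discriminate:
#'   `"group"`, `"density_class"` or `"coherence_class"`.
#' @param noise_cv Within-class amplitude SD as fraction of base intensity.
#' @param tic_sdlog SD (log scale) of the per-pixel multiplicative TIC
#'   factor.
#' @param additive_sd Additive spectral noise SD.
#' @param nuclei_low_per_mm2,nuclei_high_per_mm2 Nuclei intensities of the
#'   LND / HND regions (default 300 / 3000: ratio 10).
#' @param fibres_per_mm2,fibre_length_um Fibre rendering density and length.
#' @param kappa_organised,kappa_chaotic Orientation dispersion (radians, SD
#'   of a wrapped normal) of organised / chaotic regions.
#' @param seed Integer seed; every generator is a deterministic function of
#'   spec + seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent_um = c(2000, 2000), msi_spacing_um = 50,
                         image_um_per_px = 0.38, tile_um = 100,
                         regions = NULL,
                         mass_range = c(800, 1300), mz_grid_da = 0.1,
                         mz_sigma_da = 0.2,
                         n_peaks = 50L, n_planted = 10L, effect_sd = 1.5,
                         planted_attribute = "group",
                         noise_cv = 0.3, tic_sdlog = 0.2, additive_sd = 1,
                         nuclei_low_per_mm2 = 300,
                         nuclei_high_per_mm2 = 3000,
                         fibres_per_mm2 = 8000, fibre_length_um = 100,
                         kappa_organised = 0.15, kappa_chaotic = 10,
                         seed = 1L) {
  stopifnot(msi_spacing_um > 0, image_um_per_px > 0, tile_um > 0,
            mz_grid_da > 0, mz_sigma_da > 0, n_planted <= n_peaks,
            is.finite(effect_sd),
            planted_attribute %in% c("group", "density_class",
                                     "coherence_class"))
  if (is.null(regions)) {
    w <- extent_um[1]; h <- extent_um[2]
    strip <- function(i) c((i - 1) * h / 4, i * h / 4)
    coh <- c("organised", "organised", "chaotic", "chaotic")
    den <- c("HND", "LND", "HND", "LND")
    rows <- list()
    for (g in 1:2) for (s in 1:4) {
      ys <- strip(s)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s_%s_%s", c("LSCC", "RSCC")[g], coh[s], den[s]),
        x0 = (g - 1) * w / 2, y0 = ys[1], x1 = g * w / 2, y1 = ys[2],
        group = c("LSCC", "RSCC")[g],
        coherence_class = coh[s], density_class = den[s])
    }
    regions <- do.call(rbind, rows)
  }
  stopifnot(all(regions$x1 <= extent_um[1] + 1e-9),
            all(regions$y1 <= extent_um[2] + 1e-9))
  structure(list(extent_um = extent_um, msi_spacing_um = msi_spacing_um,
                 image_um_per_px = image_um_per_px, tile_um = tile_um,
                 regions = regions, mass_range = mass_range,
                 mz_grid_da = mz_grid_da, mz_sigma_da = mz_sigma_da,
                 n_peaks = as.integer(n_peaks),
                 n_planted = as.integer(n_planted),
                 effect_sd = effect_sd, planted_attribute = planted_attribute,
                 noise_cv = noise_cv, tic_sdlog = tic_sdlog,
                 additive_sd = additive_sd,
                 nuclei_low_per_mm2 = nuclei_low_per_mm2,
                 nuclei_high_per_mm2 = nuclei_high_per_mm2,
                 fibres_per_mm2 = fibres_per_mm2,
                 fibre_length_um = fibre_length_um,
                 kappa_organised = kappa_organised,
                 kappa_chaotic = kappa_chaotic,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default multimodal phantom specification
#'
#' The standard test-scale phantom: 2 x 2 mm, 40 x 40 MSI pixels, 50 peaks
#' of which 10 discriminate the tumour groups at 1.5 SD, SHG rendered at
#' 2 um/px so a full multimodal phantom builds in seconds.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
default_phantom <- function(seed = 1L, ...) {
  args <- list(...)
  if (is.null(args$image_um_per_px)) args$image_um_per_px <- 2
  do.call(phantom_spec, c(args, list(seed = seed)))
}

# region id (row of spec$regions) for physical points; 0 when outside all
region_of <- function(spec, x, y) {
  id <- integer(length(x))
  for (r in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[r, ]
    inside <- x >= rg$x0 & x < rg$x1 & y >= rg$y0 & y < rg$y1
    id[inside] <- r
  }
  id
}

#' Render a synthetic SHG fibre image
#'
#' Line-segment fibres per region, orientations drawn from a wrapped normal
#' with the region's dispersion (kappa -> 0: aligned, hence organised;
#' large kappa: uniform orientations, hence chaotic), lightly blurred, on a
#' weak-noise background.
#'
#' @param spec A [phantom_spec()].
#' @return List: `image` (an [intensity_image()]), `truth` (the region
#'   table with intended coherence class).
#' @export
make_shg <- function(spec) with_seed(spec$seed + 101L, {
  px <- spec$image_um_per_px
  nx <- round(spec$extent_um[1] / px); ny <- round(spec$extent_um[2] / px)
  img <- matrix(0, ny, nx)
  for (r in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[r, ]
    area_mm2 <- (rg$x1 - rg$x0) * (rg$y1 - rg$y0) / 1e6
    nf <- max(1L, round(spec$fibres_per_mm2 * area_mm2))
    kappa <- if (rg$coherence_class == "organised") spec$kappa_organised
             else spec$kappa_chaotic
    theta0 <- stats::runif(1, 0, pi)
    cxs <- stats::runif(nf, rg$x0, rg$x1)
    cys <- stats::runif(nf, rg$y0, rg$y1)
    thetas <- (theta0 + stats::rnorm(nf, 0, kappa)) %% pi
    half <- spec$fibre_length_um / 2
    steps <- seq(-half, half, by = px / 4)
    # sample points along every fibre, splat with bilinear weights so the
    # rendered lines are free of rasterisation staircase anisotropy
    xs <- (sweep(outer(steps, cos(thetas)), 2, cxs, "+")) / px
    ys <- (sweep(outer(steps, sin(thetas)), 2, cys, "+")) / px
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    for (dd in 0:3) {
      ddx <- dd %% 2L; ddy <- dd %/% 2L
      w <- abs(1 - ddx - fx) * abs(1 - ddy - fy)
      cc <- as.vector(x0) + ddx + 1L
      rr <- as.vector(y0) + ddy + 1L
      ok <- cc >= 1 & cc <= nx & rr >= 1 & rr <= ny
      idx <- rr[ok] + (cc[ok] - 1L) * ny
      acc <- rowsum(as.vector(w)[ok], idx)
      ii <- as.integer(rownames(acc))
      img[ii] <- img[ii] + acc[, 1]
    }
  }
  img <- gauss_smooth(img, 1)
  img <- img / max(img) * 200
  img <- img + abs(stats::rnorm(length(img), 0, 0.5))
  list(image = intensity_image(matrix(img, ny, nx), px),
       truth = spec$regions[, c("name", "coherence_class")])
})

#' Simulate a nuclei point pattern
#'
#' Inhomogeneous Poisson process with region-wise intensity set by the
#' region's density class. Ground-truth class per region is its intensity
#' relative to the phantom's min-max midpoint.
#'
#' @param spec A [phantom_spec()].
#' @return List: `nuclei` (a [nuclei_set()]), `truth` (region table with
#'   intended density class).
#' @export
make_nuclei <- function(spec) with_seed(spec$seed + 202L, {
  xs <- numeric(0); ys <- numeric(0)
  for (r in seq_len(nrow(spec$regions))) {
    rg <- spec$regions[r, ]
    lambda <- if (rg$density_class == "HND") spec$nuclei_high_per_mm2
              else spec$nuclei_low_per_mm2
    area_mm2 <- (rg$x1 - rg$x0) * (rg$y1 - rg$y0) / 1e6
    n <- stats::rpois(1, lambda * area_mm2)
    if (n > 0) {
      xs <- c(xs, stats::runif(n, rg$x0, rg$x1))
      ys <- c(ys, stats::runif(n, rg$y0, rg$y1))
    }
  }
  if (!length(xs)) stop("phantom produced no nuclei; raise the intensities")
  list(nuclei = nuclei_set(data.frame(x_um = xs, y_um = ys),
                           extent_um = spec$extent_um),
       truth = spec$regions[, c("name", "density_class")])
})

# per-pixel attribute tables for the MSI grid of a spec
phantom_msi_truth <- function(spec) {
  nxy <- floor(spec$extent_um / spec$msi_spacing_um)
  coords <- expand.grid(ix = 0:(nxy[1] - 1L), iy = 0:(nxy[2] - 1L))
  cx <- (coords$ix + 0.5) * spec$msi_spacing_um
  cy <- (coords$iy + 0.5) * spec$msi_spacing_um
  rid <- region_of(spec, cx, cy)
  keep <- rid > 0
  data.frame(ix = coords$ix[keep], iy = coords$iy[keep],
             group = spec$regions$group[rid[keep]],
             coherence_class = spec$regions$coherence_class[rid[keep]],
             density_class = spec$regions$density_class[rid[keep]])
}

#' Simulate an MSI datacube with planted discriminative peaks
#'
#' Continuous-mode datacube on the phantom's m/z grid: Gaussian peaks at
#' seeded centres whose per-pixel amplitudes depend on the pixel's region
#' attributes. `n_planted` peaks differ between the two classes of
#' `planted_attribute` by `effect_sd` within-class standard deviations
#' (alternating direction); a per-pixel log-normal TIC factor and additive
#' baseline noise are applied on top. The manifest records which peaks are
#' planted and their direction.
#'
#' @param spec A [phantom_spec()].
#' @return List: `dataset` (an [msi_dataset()]), `manifest` (per-peak
#'   table), `truth` (per-pixel attribute table).
#' @export
make_msi <- function(spec) with_seed(spec$seed + 303L, {
  truth <- phantom_msi_truth(spec)
  np <- nrow(truth)
  margin <- 5
  centers <- seq(spec$mass_range[1] + margin, spec$mass_range[2] - margin,
                 length.out = spec$n_peaks)
  centers <- sort(centers + stats::runif(spec$n_peaks, -0.5, 0.5))
  base <- stats::rlnorm(spec$n_peaks, log(100), 0.4)
  planted <- rep(FALSE, spec$n_peaks)
  planted[sample.int(spec$n_peaks, spec$n_planted)] <- TRUE
  direction <- integer(spec$n_peaks)
  direction[planted] <- rep_len(c(1L, -1L), spec$n_planted)
  attr_vals <- truth[[spec$planted_attribute]]
  classes <- sort(unique(attr_vals))
  # single-class phantoms have nothing to contrast; effects vanish
  is_b <- if (length(classes) < 2) rep(FALSE, np) else attr_vals == classes[2]
  sigma <- spec$noise_cv * base
  amp <- matrix(stats::rnorm(np * spec$n_peaks), np, spec$n_peaks)
  amp <- sweep(amp, 2, sigma, "*")
  amp <- sweep(amp, 2, base, "+")
  shift <- outer(is_b, direction * spec$effect_sd * sigma)
  amp <- pmax(amp + shift, 0)
  mz <- seq(spec$mass_range[1], spec$mass_range[2], by = spec$mz_grid_da)
  prof <- matrix(0, spec$n_peaks, length(mz))
  for (k in seq_len(spec$n_peaks)) {
    cols <- which(abs(mz - centers[k]) < 4 * spec$mz_sigma_da)
    prof[k, cols] <- exp(-(mz[cols] - centers[k])^2 /
                           (2 * spec$mz_sigma_da^2))
  }
  intensity <- amp %*% prof
  ticfac <- stats::rlnorm(np, 0, spec$tic_sdlog)
  intensity <- intensity * ticfac
  intensity <- pmax(intensity +
                      stats::rnorm(length(intensity), 0, spec$additive_sd), 0)
  ds <- msi_dataset(truth[, c("ix", "iy")], spec$msi_spacing_um, mz,
                    intensity,
                    metadata = list(mode = "continuous phantom",
                                    mass_range = spec$mass_range))
  manifest <- data.frame(peak = seq_len(spec$n_peaks), center = centers,
                         base = base, planted = planted,
                         attribute = spec$planted_attribute,
                         direction = direction,
                         effect_sd = ifelse(planted, spec$effect_sd, 0))
  list(dataset = ds, manifest = manifest, truth = truth)
})

random_peptide_seq <- function(n_res) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_res,
               replace = TRUE), collapse = "")
}

#' Simulate an LC-MS/MS peptide identification table
#'
#' For a set of synthetic proteins, two or more peptides each with
#' theoretical m/z within 0.05 Da of planted peak centres (so the
#' mass-matching rules can identify them downstream), plus decoy peptides
#' more than 0.15 Da away from every peak.
#'
#' @param spec A [phantom_spec()].
#' @param manifest Peak manifest from [make_msi()] (regenerated when NULL).
#' @param n_decoys Number of decoy peptides (default 10).
#' @return Data frame of peptide records (see [read_peptide_table()]).
#' @export
make_peptide_table <- function(spec, manifest = NULL, n_decoys = 10L) {
  if (is.null(manifest)) manifest <- make_msi(spec)$manifest
  with_seed(spec$seed + 404L, {
    planted <- manifest$center[manifest$planted]
    if (length(planted) < 2) planted <- manifest$center[1:2]
    n_prot <- length(planted) %/% 2L
    rows <- list()
    for (p in seq_len(n_prot)) {
      acc <- sprintf("SYN%03d", p)
      for (j in 1:2) {
        ctr <- planted[2 * (p - 1) + j]
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = random_peptide_seq(sample(8:15, 1)),
          mz = ctr + stats::runif(1, -0.05, 0.05),
          accession = acc,
          protein_name = sprintf("Synthetic protein %d", p),
          score = stats::runif(1, 20, 100))
      }
    }
    for (d in seq_len(n_decoys)) {
      repeat {
        mzd <- stats::runif(1, spec$mass_range[1], spec$mass_range[2])
        if (min(abs(mzd - manifest$center)) > 0.2) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = random_peptide_seq(sample(8:15, 1)),
        mz = mzd, accession = sprintf("DEC%03d", d),
        protein_name = sprintf("Decoy protein %d", d),
        score = stats::runif(1, 20, 100))
    }
    do.call(rbind, rows)
  })
}

#' Region and tumour annotation polygons of a phantom
#'
#' Rectangular polygons for each tumour group plus a whole-tissue `tumour`
#' annotation, in the shared physical frame (identity transform to MSI).
#'
#' @param spec A [phantom_spec()].
#' @return Feature list suitable for [write_annotations()].
#' @export
phantom_annotations <- function(spec) {
  rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  feats <- list()
  for (g in unique(spec$regions$group)) {
    rg <- spec$regions[spec$regions$group == g, ]
    feats[[length(feats) + 1L]] <- list(
      name = g, polygon = rect(min(rg$x0), min(rg$y0), max(rg$x1),
                               max(rg$y1)))
  }
  feats[[length(feats) + 1L]] <- list(
    name = "tumour", polygon = rect(0, 0, spec$extent_um[1],
                                    spec$extent_um[2]))
  feats
}

#' Write a complete phantom fixture bundle
#'
#' Renders every modality of `spec` into `dir`: `shg.tif`, `nuclei.csv`,
#' `msi/` (fixture bundle; optionally also `msi.imzML` + `.ibd`),
#' `regions.geojson`, `peptides.tsv` and `manifest.json` (ground truth).
#' Fully seeded: identical spec + seed gives byte-identical files.
#'
#' @param spec A [phantom_spec()].
#' @param dir Output directory (created).
#' @param imzml Also write imzML (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(spec, dir, imzml = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shg <- make_shg(spec)
  tiff::writeTIFF(shg$image$values / max(shg$image$values),
                  file.path(dir, "shg.tif"), bits.per.sample = 16)
  nuc <- make_nuclei(spec)
  utils::write.csv(nuc$nuclei$centroids, file.path(dir, "nuclei.csv"),
                   row.names = FALSE)
  msi <- make_msi(spec)
  write_msi(msi$dataset, file.path(dir, "msi"), format = "fixture")
  if (imzml) write_msi(msi$dataset, file.path(dir, "msi.imzML"),
                       format = "imzml")
  write_annotations(phantom_annotations(spec),
                    file.path(dir, "regions.geojson"))
  write_peptide_table(make_peptide_table(spec, msi$manifest),
                      file.path(dir, "peptides.tsv"))
  jsonlite::write_json(
    list(spec = spec[setdiff(names(spec), "regions")],
         regions = spec$regions, peaks = msi$manifest,
         pixel_truth = msi$truth),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
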