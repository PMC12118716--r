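#' Construct a single mass spectrum
#'
#' A spectrum is a pair of parallel vectors: strictly increasing m/z values
#' (Da) and non-negative intensities.
#'
#' @param mz Numeric vector of m/z values in Da, strictly increasing.
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @return An object of class `msi_spectrum` (a list with `mz`, `intensity`).
#' @export
mass_spectrum <- function(mz, intensity) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) && any(diff(mz) <= 0))
    stop("mz values must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  structure(list(mz = mz, intensity = intensity), class = "msi_spectrum")
}

#' Construct an MSI dataset
#'
#' An MSI dataset is a raster of mass spectra: integer grid coordinates with
#' a physical raster pitch (`spacing_um`), one spectrum per pixel. Two
#' storage layouts are supported: *continuous* (a shared m/z axis and a
#' pixels-by-bins intensity matrix) and *processed* (per-pixel m/z vectors).
#'
#' @param coords Data frame with integer columns `ix`, `iy`; rows unique.
#' @param spacing_um Raster pitch in micrometres (> 0).
#' @param mz Shared numeric m/z axis (continuous layout) or a list with one
#'   m/z vector per pixel (processed layout).
#' @param intensity Matrix `nrow(coords)` x `length(mz)` (continuous) or a
#'   list of per-pixel intensity vectors (processed).
#' @param origin_um Physical coordinate of the centre of pixel (0, 0),
#'   length-2 numeric (default `c(0, 0)`).
#' @param metadata Free-form named list (instrument mode, mass range, ...).
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, spacing_um, mz, intensity,
                        origin_um = c(0, 0), metadata = list()) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("ix", "iy") %in% names(coords)))
  coords$ix <- as.integer(coords$ix); coords$iy <- as.integer(coords$iy)
  if (anyDuplicated(coords[c("ix", "iy")]))
    stop("pixel coordinates must be unique")
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("spacing_um must be a positive scalar")
  continuous <- !is.list(mz)
  np <- nrow(coords)
  if (continuous) {
    mz <- as.numeric(mz)
    if (any(diff(mz) <= 0)) stop("mz axis must be strictly increasing")
    intensity <- as.matrix(intensity)
    if (nrow(intensity) != np || ncol(intensity) != length(mz))
      stop("intensity matrix must be n_pixels x n_mz")
    if (any(intensity < 0)) stop("intensities must be non-negative")
  } else {
    if (length(mz) != np || length(intensity) != np)
      stop("processed layout needs one mz and intensity vector per pixel")
    for (i in seq_len(np)) {
      if (length(mz[[i]]) != length(intensity[[i]]))
        stop(sprintf("pixel %d: mz and intensity lengths differ", i))
      if (length(mz[[i]]) > 1 && any(diff(mz[[i]]) <= 0))
        stop(sprintf("pixel %d: mz not strictly increasing", i))
      if (any(intensity[[i]] < 0))
        stop(sprintf("pixel %d: negative intensity", i))
    }
  }
  structure(list(
    coords = coords, spacing_um = spacing_um,
    origin_um = as.numeric(origin_um),
    mz = mz, intensity = intensity,
    continuous = continuous, metadata = metadata,
    tic_normalized = FALSE, tic_zero = rep(FALSE, np)
  ), class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset: %d pixels, %s layout, %.0f um raster\n",
              nrow(x$coords), if (x$continuous) "continuous" else "processed",
              x$spacing_um))
  rng <- mz_range(x)
  cat(sprintf("  m/z %.2f-%.2f; TIC-normalized: %s\n", rng[1], rng[2],
              x$tic_normalized))
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param ds An `msi_dataset`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(ds) nrow(ds$coords)

#' @keywords internal
#' @noRd
mz_range <- function(ds) {
  if (ds$continuous) range(ds$mz) else range(unlist(lapply(ds$mz, range)))
}

#' Extract one pixel's spectrum
#' @param ds An `msi_dataset`.
#' @param i Pixel row index into `ds$coords`.
#' @return An `msi_spectrum`.
#' @export
get_spectrum <- function(ds, i) {
  if (ds$continuous) mass_spectrum(ds$mz, ds$intensity[i, ])
  else mass_spectrum(ds$mz[[i]], ds$intensity[[i]])
}

#' Per-pixel total ion counts
#' @param ds An `msi_dataset`.
#' @return Numeric vector of TICs, one per pixel.
#' @export
tic <- function(ds) {
  if (ds$continuous) rowSums(ds$intensity)
  else vapply(ds$intensity, sum, numeric(1))
}

#' TIC normalisation
#'
#' Scales every spectrum so its total ion count equals the dataset mean TIC
#' of included pixels. Pixels with TIC = 0 cannot be normalised; they are
#' flagged in `tic_zero` and excluded from downstream statistics. Relative
#' intensities within a spectrum are unchanged, and the operation is
#' idempotent.
#'
#' @param ds An `msi_dataset`.
#' @return The dataset with scaled intensities, `tic_normalized = TRUE` and
#'   `tic_zero` flags set.
#' @export
tic_normalize <- function(ds) {
  tics <- tic(ds)
  zero <- tics <= 0
  if (all(zero)) stop("all pixels have zero TIC; nothing to normalise")
  target <- mean(tics[!zero])
  scale <- ifelse(zero, 1, target / tics)
  if (ds$continuous) {
    ds$intensity <- ds$intensity * scale
  } else {
    ds$intensity <- Map(function(v, s) v * s, ds$intensity, scale)
  }
  ds$tic_zero <- zero
  ds$tic_normalized <- TRUE
  ds
}

#' Dataset mean spectrum on a common m/z grid
#'
#' Bins every pixel's spectrum onto a uniform grid (`grid_da` bin width
#' spanning the dataset mass range), taking the per-pixel *maximum* within
#' each bin (0 where a pixel has no data point in the bin), then averages
#' across pixels. Pixels flagged `tic_zero` are excluded.
#'
#' @param ds An `msi_dataset` (non-empty).
#' @param grid_da Bin width in Da (default 0.1).
#' @return An `msi_spectrum` at bin centres, with attribute `grid_da`.
#' @export
mean_spectrum <- function(ds, grid_da = 0.1) {
  if (grid_da <= 0) stop("grid_da must be positive")
  if (n_pixels(ds) == 0) stop("empty dataset")
  keep <- which(!ds$tic_zero)
  if (!length(keep)) stop("all pixels excluded (zero TIC)")
  rng <- mz_range(ds)
  lo <- floor(rng[1] / grid_da) * grid_da
  nbin <- floor((rng[2] - lo) / grid_da) + 1L
  centers <- lo + (seq_len(nbin) - 0.5) * grid_da
  acc <- numeric(nbin)
  if (ds$continuous) {
    bin <- pmin(pmax(floor((ds$mz - lo) / grid_da + 1e-7) + 1L, 1L), nbin)
    sub <- ds$intensity[keep, , drop = FALSE]
    # per-pixel max within each bin, then mean over pixels
    if (!anyDuplicated(bin)) {
      acc[bin] <- colMeans(sub)
    } else {
      for (b in unique(bin)) {
        cols <- which(bin == b)
        mx <- sub[, cols[1]]
        for (cc in cols[-1]) mx <- pmax(mx, sub[, cc])
        acc[b] <- mean(mx)
      }
    }
  } else {
    for (i in keep) {
      bin <- pmin(pmax(floor((ds$mz[[i]] - lo) / grid_da + 1e-7) + 1L, 1L), nbin)
      mx <- numeric(nbin)
      ok <- ds$intensity[[i]] > mx[bin]
      while (any(ok)) {  # resolve duplicates-in-bin by repeated max update
        mx[bin[ok]] <- pmax(mx[bin[ok]], ds$intensity[[i]][ok])
        ok <- ds$intensity[[i]] > mx[bin]
      }
      acc <- acc + mx
    }
    acc <- acc / length(keep)
  }
  s <- mass_spectrum(centers, acc)
  attr(s, "grid_da") <- grid_da
  s
}

#' Construct a peak table
#'
#' @param center Numeric m/z centres, strictly increasing.
#' @param lo,hi Interval bounds; membership is half-open, `lo <= mz < hi`,
#'   which keeps truncated neighbouring intervals disjoint.
#' @param provenance Named list of detection parameters.
#' @return A data frame of class `peak_table` with columns `peak_id`,
#'   `center`, `lo`, `hi`.
#' @export
peak_table <- function(center, lo, hi, provenance = list()) {
  stopifnot(length(center) == length(lo), length(lo) == length(hi))
  if (length(center) > 1 && any(diff(center) <= 0))
    stop("peak centers must be strictly increasing")
  if (any(lo > center) || any(hi < center)) stop("interval must contain center")
  if (length(center) > 1 && any(hi[-length(hi)] > lo[-1] + 1e-12))
    stop("peak intervals must be pairwise disjoint")
  structure(
    data.frame(peak_id = seq_along(center), center = center, lo = lo, hi = hi),
    class = c("peak_table", "data.frame"), provenance = provenance)
}

#' Peak detection on the dataset mean spectrum
#'
#' Local maxima of the mean spectrum exceeding the robust baseline (its
#' median) by at least `snr_min` times a robust noise level (1.4826 x
#' median absolute deviation of the mean spectrum, i.e. `stats::mad`)
#' become peaks. Each peak gets a +/- `half_width_da`
#' interval; overlapping intervals are truncated at the midpoint between
#' adjacent centres. `noise_mode = "medium"` applies a 3-bin running median
#' before maxima detection; `"none"` detects on the raw mean spectrum.
#'
#' @param mean_spec Mean spectrum on a uniform grid (see [mean_spectrum()]).
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param half_width_da Interval half-width in Da (default 0.4).
#' @param noise_mode `"medium"` (default) or `"none"`.
#' @return A [peak_table()].
#' @export
detect_peaks <- function(mean_spec, snr_min = 3, half_width_da = 0.4,
                         noise_mode = c("medium", "none")) {
  noise_mode <- match.arg(noise_mode)
  y <- mean_spec$intensity
  if (!length(y)) stop("empty spectrum")
  if (noise_mode == "medium" && length(y) >= 3)
    y <- as.numeric(stats::runmed(y, 3, endrule = "median"))
  noise <- stats::mad(y)
  # threshold is relative to the robust baseline: a purely multiplicative
  # snr * noise cut degenerates when detector offset / truncated noise give
  # the baseline a positive median
  thr <- stats::median(y) + snr_min * noise
  n <- length(y)
  if (n < 3) return(peak_table(numeric(0), numeric(0), numeric(0)))
  # plateau-aware local maxima: a maximal run of equal values is one peak
  # (centred) when it exceeds both flanking runs; median filtering flattens
  # peak tops, so a strict three-point test would miss real peaks
  r <- rle(y)
  nr <- length(r$values)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  idx <- integer(0)
  if (nr >= 3) {
    j <- 2:(nr - 1)
    is_max <- r$values[j] > r$values[j - 1] & r$values[j] > r$values[j + 1]
    idx <- ((run_start[j] + run_end[j]) %/% 2L)[is_max]
  }
  idx <- idx[y[idx] >= thr & y[idx] > 0]
  # a peak must also be the maximum of its own +/- half_width window, so
  # noise wiggles on the flank of a larger peak are not reported twice
  if (length(idx)) {
    grid <- if (length(mean_spec$mz) > 1) mean_spec$mz[2] - mean_spec$mz[1]
            else half_width_da
    hw_bins <- max(1L, round(half_width_da / grid))
    keep <- vapply(idx, function(i) {
      win <- max(1L, i - hw_bins):min(n, i + hw_bins)
      y[i] >= max(y[win])
    }, logical(1))
    idx <- idx[keep]
  }
  centers <- mean_spec$mz[idx]
  lo <- centers - half_width_da
  hi <- centers + half_width_da
  if (length(centers) > 1) {
    mid <- (centers[-length(centers)] + centers[-1]) / 2
    hi[-length(hi)] <- pmin(hi[-length(hi)], mid)
    lo[-1] <- pmax(lo[-1], mid)
  }
  peak_table(centers, lo, hi,
             provenance = list(snr_min = snr_min,
                               half_width_da = half_width_da,
                               noise_mode = noise_mode, noise = noise,
                               grid_da = attr(mean_spec, "grid_da")))
}

#' Build the pixels-by-peaks feature matrix
#'
#' "Maximal interval" feature extraction: entry (p, k) is the maximum
#' intensity of pixel p's spectrum within peak interval k (half-open
#' `[lo, hi)`), or 0 when no data point falls inside. Pixels flagged
#' `tic_zero` are dropped from the matrix.
#'
#' @param ds A TIC-normalised `msi_dataset`.
#' @param peaks A [peak_table()] (non-empty).
#' @return An object of class `feature_matrix`: list with `values` (matrix),
#'   `pixel_index` (coords data frame), `peaks`, `normalized`.
#' @export
build_feature_matrix <- function(ds, peaks) {
  if (!inherits(peaks, "peak_table") || nrow(peaks) == 0)
    stop("empty peak table")
  keep <- which(!ds$tic_zero)
  np <- length(keep); nk <- nrow(peaks)
  values <- matrix(0, np, nk)
  if (ds$continuous) {
    sub <- ds$intensity[keep, , drop = FALSE]
    for (k in seq_len(nk)) {
      cols <- which(ds$mz >= peaks$lo[k] & ds$mz < peaks$hi[k])
      if (!length(cols)) next
      mx <- sub[, cols[1]]
      for (cc in cols[-1]) mx <- pmax(mx, sub[, cc])
      values[, k] <- mx
    }
  } else {
    for (j in seq_along(keep)) {
      i <- keep[j]
      mzv <- ds$mz[[i]]; iv <- ds$intensity[[i]]
      for (k in seq_len(nk)) {
        inside <- mzv >= peaks$lo[k] & mzv < peaks$hi[k]
        if (any(inside)) values[j, k] <- max(iv[inside])
      }
    }
  }
  colnames(values) <- sprintf("mz_%.4f", peaks$center)
  structure(list(values = values,
                 pixel_index = ds$coords[keep, , drop = FALSE],
                 peaks = peaks, normalized = ds$tic_normalized),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d pixels x %d peaks (normalized: %s)\n",
              nrow(x$values), ncol(x$values), x$normalized))
  invisible(x)
}
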