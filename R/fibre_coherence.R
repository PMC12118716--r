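#' Construct an intensity image
#'
#' A 2-D non-negative scalar field with a physical pixel size. Matrices are
#' stored row = y (down), column = x.
#'
#' @param values Numeric matrix of finite, non-negative intensities.
#' @param um_per_px Physical pixel size in micrometres (> 0).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(values, um_per_px) {
  values <- as.matrix(values)
  if (!is.numeric(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be positive")
  if (any(!is.finite(values))) stop("image values must be finite")
  if (any(values < 0)) stop("image values must be non-negative")
  structure(list(values = values, um_per_px = um_per_px),
            class = "intensity_image")
}

#' Read a grayscale TIFF as an intensity image
#' @param path TIFF file (8/16-bit grayscale or float).
#' @param um_per_px Physical pixel size in micrometres.
#' @return An [intensity_image()].
#' @export
read_intensity_image <- function(path, um_per_px) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  intensity_image(m, um_per_px)
}

#' Global Otsu foreground mask
#'
#' Threshold maximising between-class variance on a 256-bin histogram of
#' the intensity range; the mask keeps pixels strictly above the threshold.
#'
#' @param img An [intensity_image()] with at least two distinct values.
#' @return Logical matrix (TRUE = foreground), with the threshold (on the
#'   original intensity scale) in attribute `threshold`.
#' @export
otsu_foreground <- function(img) {
  v <- img$values
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate histogram: constant image")
  scaled <- (v - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  thr <- rng[1] + thr01 * (rng[2] - rng[1])
  mask <- v > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Structure-tensor coherence map
#'
#' Computes the local fibre-orientation coherence of an SHG image. The image
#' is first denoised by zeroing sub-Otsu background, then the structure
#' tensor J = G_sigma_w * (grad I grad I^T) is formed with
#' Gaussian-derivative gradients at scale `sigma_g` and window smoothing at
#' scale `sigma_w` (reflective boundaries throughout). Coherence is
#' (lambda1 - lambda2) / (lambda1 + lambda2) of J, in [0, 1]: 1 for
#' perfectly aligned structures, 0 for isotropic texture. Pixels whose
#' tensor trace falls below epsilon = 1e-3 x mean gradient energy (flat
#' regions) get coherence 0.
#'
#' @param img An [intensity_image()].
#' @param sigma_g Gradient (derivative) scale in pixels (default 2).
#' @param sigma_w Tensor-averaging window scale in pixels (default 8);
#'   must satisfy `sigma_w >= sigma_g`.
#' @param foreground Optional logical mask; computed by [otsu_foreground()]
#'   when missing.
#' @return An object of class `coherence_map`: list with `values` (matrix in
#'   `[0, 1]`, 0 outside foreground), `foreground`, `um_per_px`, `params`.
#' @export
coherence_map <- function(img, sigma_g = 2, sigma_w = 8, foreground = NULL) {
  if (sigma_g <= 0 || sigma_w <= 0) stop("scales must be positive")
  if (sigma_w < sigma_g) stop("sigma_w must be >= sigma_g")
  if (is.null(foreground)) foreground <- otsu_foreground(img)
  v <- img$values
  v[!foreground] <- 0
  g <- gaussian_kernel_1d(sigma_g)
  d <- gaussian_kernel_1d(sigma_g, order = 1L)
  gx <- conv_sep(v, d, g)   # derivative along x (columns)
  gy <- conv_sep(v, g, d)   # derivative along y (rows)
  w <- gaussian_kernel_1d(sigma_w)
  jxx <- conv_sep(gx * gx, w, w)
  jyy <- conv_sep(gy * gy, w, w)
  jxy <- conv_sep(gx * gy, w, w)
  tr <- jxx + jyy
  disc <- sqrt(pmax((jxx - jyy)^2 + 4 * jxy^2, 0))
  eps <- 1e-3 * mean(tr)
  coh <- matrix(0, nrow(v), ncol(v))
  ok <- tr > eps
  coh[ok] <- disc[ok] / tr[ok]
  coh <- pmin(pmax(coh, 0), 1)
  coh[!foreground] <- 0
  structure(list(values = coh, foreground = foreground,
                 um_per_px = img$um_per_px,
                 params = list(sigma_g = sigma_g, sigma_w = sigma_w)),
            class = "coherence_map")
}

#' Construct a categorical region map
#' @param classes Integer matrix of level codes (0-based into `levels`).
#' @param levels Character vector of class names; code 0 = `levels[1]`.
#' @param um_per_px Pixel size in micrometres.
#' @return An object of class `region_map`.
#' @export
region_map <- function(classes, levels, um_per_px) {
  stopifnot(all(classes %in% (seq_along(levels) - 1L)))
  structure(list(classes = classes, levels = levels, um_per_px = um_per_px),
            class = "region_map")
}

#' Classify coherence into chaotic / organised regions
#'
#' Foreground pixels with coherence in `[0, 0.5)` are chaotic and `[0.5, 1]`
#' organised (the boundary value 0.5 closes upward into "organised");
#' non-foreground pixels are background.
#'
#' @param cm A [coherence_map()].
#' @return A [region_map()] with levels `background`, `chaotic`, `organised`.
#' @export
classify_coherence <- function(cm) {
  cls <- matrix(0L, nrow(cm$values), ncol(cm$values))
  cls[cm$foreground & cm$values < 0.5] <- 1L
  cls[cm$foreground & cm$values >= 0.5] <- 2L
  region_map(cls, c("background", "chaotic", "organised"), cm$um_per_px)
}

#' Percent area per class of a region map
#'
#' Percentages over non-background pixels; they sum to 100.
#'
#' @param rm A [region_map()].
#' @return Named numeric vector (one entry per non-background level).
#' @export
region_map_percent <- function(rm) {
  fg <- rm$classes != 0L
  if (!any(fg)) stop("no non-background pixels to evaluate")
  lv <- rm$levels[-1]
  counts <- vapply(seq_along(lv),
                   function(k) sum(rm$classes == k), numeric(1))
  stats::setNames(100 * counts / sum(counts), lv)
}

#' Write a heatmap as 32-bit float TIFF with a JSON parameter sidecar
#' @param map A [coherence_map()] or [density_map()].
#' @param path Output TIFF path; `<path>.json` gets the parameters.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, path) {
  tiff::writeTIFF(pmin(pmax(map$values, 0), 1), path, bits.per.sample = 32)
  side <- map[setdiff(names(map), c("values", "foreground", "raw_counts"))]
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
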