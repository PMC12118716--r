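#' Construct a nuclei centroid set
#'
#' Nuclei centroids in physical coordinates (micrometres), with the extent
#' of the source H&E image. Segmentation itself is external; this package
#' consumes its exported centroids (or a label image, see
#' [nuclei_from_labels()]).
#'
#' @param centroids Data frame with numeric columns `x_um`, `y_um`.
#' @param extent_um Length-2 numeric, width and height of the source image
#'   in micrometres; defaults to the centroid bounding box.
#' @return An object of class `nuclei_set`.
#' @export
nuclei_set <- function(centroids, extent_um = NULL) {
  centroids <- as.data.frame(centroids)
  stopifnot(all(c("x_um", "y_um") %in% names(centroids)))
  if (any(!is.finite(centroids$x_um)) || any(!is.finite(centroids$y_um)))
    stop("centroid coordinates must be finite")
  if (is.null(extent_um))
    extent_um <- c(max(centroids$x_um, 0), max(centroids$y_um, 0))
  if (nrow(centroids) &&
      (any(centroids$x_um < 0) || any(centroids$y_um < 0) ||
       any(centroids$x_um > extent_um[1]) || any(centroids$y_um > extent_um[2])))
    stop("centroids must lie within the source extent")
  structure(list(centroids = centroids, extent_um = as.numeric(extent_um)),
            class = "nuclei_set")
}

#' Read nuclei centroids from CSV
#' @param path CSV file with header `x_um,y_um`.
#' @param extent_um Optional source extent (see [nuclei_set()]).
#' @return A [nuclei_set()].
#' @export
read_nuclei_csv <- function(path, extent_um = NULL) {
  nuclei_set(utils::read.csv(path), extent_um)
}

#' Reduce a label image to nuclei centroids
#'
#' Each positive integer label becomes one centroid (centre of mass of its
#' pixels, pixel-centre convention).
#'
#' @param labels Integer matrix (row = y, col = x); 0 = background.
#' @param um_per_px Physical pixel size in micrometres.
#' @return A [nuclei_set()].
#' @export
nuclei_from_labels <- function(labels, um_per_px) {
  idx <- which(labels > 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("label image contains no nuclei")
  lab <- labels[labels > 0]
  x <- tapply((idx[, "col"] - 0.5) * um_per_px, lab, mean)
  y <- tapply((idx[, "row"] - 0.5) * um_per_px, lab, mean)
  nuclei_set(data.frame(x_um = as.numeric(x), y_um = as.numeric(y)),
             extent_um = c(ncol(labels), nrow(labels)) * um_per_px)
}

#' Nuclei-per-unit-area density heatmap
#'
#' Counts centroids per half-open tile `[x, x + tile) x [y, y + tile)` on a
#' regular grid covering the source extent, optionally smooths the count
#' field (Gaussian, sigma = 1 tile), then min-max normalises to `[0, 1]`
#' (1 = densest tile). When every tile holds the same count the normalised
#' map is set to 0.5 everywhere so downstream classification stays defined.
#'
#' @param nuclei A non-empty [nuclei_set()].
#' @param tile_um Analysis window size in micrometres (default 100).
#' @param smooth Logical; smooth raw counts before normalisation
#'   (default FALSE).
#' @return An object of class `density_map`: list with `values` (matrix in
#'   `[0, 1]`), `raw_counts`, `tile_um`.
#' @export
density_map <- function(nuclei, tile_um = 100, smooth = FALSE) {
  if (tile_um <= 0) stop("tile_um must be positive")
  pts <- nuclei$centroids
  if (!nrow(pts)) stop("empty nuclei set")
  nx <- max(1L, ceiling(nuclei$extent_um[1] / tile_um))
  ny <- max(1L, ceiling(nuclei$extent_um[2] / tile_um))
  tx <- pmin(pmax(floor(pts$x_um / tile_um), 0), nx - 1L)
  ty <- pmin(pmax(floor(pts$y_um / tile_um), 0), ny - 1L)
  counts <- matrix(0, ny, nx)
  tab <- table(factor(ty * nx + tx, levels = 0:(nx * ny - 1L)))
  counts[] <- matrix(as.numeric(tab), ny, nx, byrow = TRUE)
  field <- counts
  if (smooth && min(dim(field)) > 3) field <- gauss_smooth(field, 1)
  rng <- range(field)
  values <- if (rng[1] == rng[2]) matrix(0.5, ny, nx)
            else (field - rng[1]) / (rng[2] - rng[1])
  structure(list(values = values, raw_counts = counts, tile_um = tile_um,
                 um_per_px = tile_um),
            class = "density_map")
}

#' Classify nuclei density into LND / HND regions
#'
#' Tiles with normalised density in `[0, 0.5)` are low nuclei distribution
#' (LND) and `[0.5, 1]` high (HND); 0.5 closes upward into HND, mirroring
#' the coherence rule.
#'
#' @param dm A [density_map()].
#' @return A [region_map()] with levels `background`, `LND`, `HND` (no tile
#'   is background; the level exists so density maps compose with the other
#'   region maps).
#' @export
classify_density <- function(dm) {
  cls <- matrix(1L, nrow(dm$values), ncol(dm$values))
  cls[dm$values >= 0.5] <- 2L
  region_map(cls, c("background", "LND", "HND"), dm$tile_um)
}
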