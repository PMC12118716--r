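#' Affine transform between modality frames
#'
#' A 2x3 matrix `[A | b]` mapping modality coordinates (micrometres) to MSI
#' physical coordinates: `x' = A x + b`.
#'
#' @param m Numeric 2x3 matrix with invertible linear part.
#' @return An object of class `affine2d`.
#' @export
affine_transform <- function(m) {
  m <- matrix(as.numeric(m), 2, 3)
  if (abs(det(m[, 1:2])) < 1e-12) stop("affine transform is not invertible")
  structure(m, class = "affine2d")
}

#' Identity affine transform
#' @return An `affine2d` that leaves coordinates unchanged.
#' @export
affine_identity <- function() affine_transform(cbind(diag(2), c(0, 0)))

#' Apply an affine transform to points
#' @param transform An [affine_transform()].
#' @param pts Two-column matrix (x, y) in micrometres.
#' @return Transformed two-column matrix.
#' @export
apply_affine <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  t(transform[, 1:2] %*% t(pts) + transform[, 3])
}

#' Least-squares affine from landmark pairs
#'
#' @param src,dst Two-column matrices of corresponding points (>= 3 pairs,
#'   not collinear).
#' @return An [affine_transform()]; attribute `rms_residual_um` reports the
#'   root-mean-square landmark residual.
#' @export
fit_affine <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  if (nrow(src) < 3 || nrow(src) != nrow(dst))
    stop("need >= 3 corresponding landmark pairs")
  X <- cbind(src, 1)
  beta <- tryCatch(qr.solve(X, dst),
                   error = function(e) stop("landmarks are degenerate"))
  tr <- affine_transform(rbind(c(beta[1, 1], beta[2, 1], beta[3, 1]),
                               c(beta[1, 2], beta[2, 2], beta[3, 2])))
  res <- apply_affine(tr, src) - dst
  attr(tr, "rms_residual_um") <- sqrt(mean(rowSums(res^2)))
  tr
}

# Physical centres of the source map's pixels/tiles (map frame, um).
map_pixel_centers <- function(map) {
  v <- if (inherits(map, "region_map")) map$classes else map$values
  step <- map$um_per_px
  xs <- (seq_len(ncol(v)) - 0.5) * step
  ys <- (seq_len(nrow(v)) - 0.5) * step
  list(x = xs, y = ys)
}

#' Resample a heatmap or class map onto the MSI pixel grid
#'
#' Every source map pixel centre is mapped through `transform` into the MSI
#' physical frame and assigned to the (half-open) 50-um MSI pixel footprint
#' it lands in. Continuous maps are aggregated per MSI pixel by the mean,
#' class maps by majority vote with background excluded (ties break toward
#' the lower class code; an all-background footprint stays background).
#' MSI pixels receiving no source pixel are background / NA.
#'
#' @param map A [coherence_map()], [density_map()] or [region_map()].
#' @param ds The target [msi_dataset()].
#' @param transform An [affine_transform()] from map to MSI coordinates
#'   (default identity: shared frame).
#' @param rule `"auto"` (mean for continuous, majority for class maps),
#'   `"mean"` or `"majority"`.
#' @return Data frame aligned to `ds$coords`: columns `ix`, `iy` and either
#'   `value` (numeric, NA where empty) or `class` (character, `"background"`
#'   where empty).
#' @export
resample_to_msi <- function(map, ds, transform = affine_identity(),
                            rule = c("auto", "mean", "majority")) {
  rule <- match.arg(rule)
  is_class <- inherits(map, "region_map")
  if (rule == "auto") rule <- if (is_class) "majority" else "mean"
  src <- if (is_class) map$classes else map$values
  ctr <- map_pixel_centers(map)
  pts <- cbind(rep(ctr$x, each = nrow(src)), rep(ctr$y, times = ncol(src)))
  val <- as.vector(src)
  if (!is_class && !is.null(map$foreground)) {
    keep <- as.vector(map$foreground)
    pts <- pts[keep, , drop = FALSE]; val <- val[keep]
  }
  phys <- apply_affine(transform, pts)
  jx <- floor((phys[, 1] - ds$origin_um[1]) / ds$spacing_um)
  jy <- floor((phys[, 2] - ds$origin_um[2]) / ds$spacing_um)
  key <- paste(jx, jy)
  pixkey <- paste(ds$coords$ix, ds$coords$iy)
  out <- ds$coords
  # reverse lookup for MSI pixels receiving no source sample (source map
  # coarser than the MSI raster): sample the map cell containing the pixel
  # centre pulled back through the inverse transform
  lookup_center <- function(miss) {
    pc <- cbind(ds$origin_um[1] + (ds$coords$ix[miss] + 0.5) * ds$spacing_um,
                ds$origin_um[2] + (ds$coords$iy[miss] + 0.5) * ds$spacing_um)
    back <- t(solve(transform[, 1:2]) %*% (t(pc) - transform[, 3]))
    cc <- floor(back[, 1] / map$um_per_px) + 1L
    rr <- floor(back[, 2] / map$um_per_px) + 1L
    ok <- cc >= 1 & cc <= ncol(src) & rr >= 1 & rr <= nrow(src)
    v <- rep(NA_real_, length(miss))
    v[ok] <- src[cbind(rr[ok], cc[ok])]
    if (!is_class && !is.null(map$foreground))
      v[ok][!map$foreground[cbind(rr[ok], cc[ok])]] <- NA_real_
    v
  }
  if (rule == "mean") {
    agg <- tapply(val, key, mean)
    out$value <- as.numeric(agg[pixkey])
    miss <- which(is.na(out$value))
    if (length(miss)) out$value[miss] <- lookup_center(miss)
  } else {
    if (is_class) { drop0 <- val != 0L; key <- key[drop0]; val <- val[drop0] }
    cls <- integer(nrow(out))
    tab <- tapply(val, key, function(v) {
      tt <- table(v)
      as.integer(names(tt)[which.max(tt)])  # which.max: first = lowest code
    })
    hit <- match(pixkey, names(tab))
    cls[!is.na(hit)] <- as.integer(tab[hit[!is.na(hit)]])
    miss <- which(is.na(hit))
    if (length(miss)) {
      v <- lookup_center(miss)
      cls[miss[!is.na(v)]] <- as.integer(v[!is.na(v)])
    }
    lv <- if (is_class) map$levels else
      stop("majority rule requires a region_map")
    out$class <- lv[cls + 1L]
  }
  out
}

#' Import QuPath-style GeoJSON annotations onto the MSI grid
#'
#' Reads a GeoJSON FeatureCollection whose polygon coordinates are in MSI
#' physical micrometres (or supplies `transform`). An MSI pixel gets a
#' polygon's class iff the pixel centre lies inside the polygon under the
#' even-odd rule; points exactly on an edge count as inside. When polygons
#' overlap, the last-listed feature wins (a message reports each overwrite).
#'
#' @param path GeoJSON file. Class names are read from
#'   `properties.classification.name` (QuPath dialect) with fallback to
#'   `properties.name`.
#' @param ds The target [msi_dataset()].
#' @param transform Optional [affine_transform()] applied to polygon
#'   coordinates.
#' @param classes Optional character vector: only import these classes.
#' @return Data frame aligned to `ds$coords`: `ix`, `iy`, `class` (`"none"`
#'   where unlabelled).
#' @export
import_annotations <- function(path, ds, transform = affine_identity(),
                               classes = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  cx <- ds$origin_um[1] + (ds$coords$ix + 0.5) * ds$spacing_um
  cy <- ds$origin_um[2] + (ds$coords$iy + 0.5) * ds$spacing_um
  lab <- rep("none", nrow(ds$coords))
  for (f in feats) {
    cls <- f$properties$classification$name %||% f$properties$name %||% "none"
    if (!is.null(classes) && !(cls %in% classes)) next
    geom <- f$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) next
    fid <- f$id %||% cls
    inside <- rep(FALSE, length(cx))
    for (ring in geom$coordinates) {
      poly <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
      poly <- apply_affine(transform, poly)
      if (polygon_self_intersects(poly))
        stop("invalid (self-intersecting) polygon in feature '", fid, "'")
      inside <- xor(inside, point_in_polygon(cx, cy, poly))
    }
    overwritten <- inside & lab != "none"
    if (any(overwritten))
      message(sum(overwritten), " pixel(s) relabelled by overlapping feature '",
              fid, "' (last-listed wins)")
    lab[inside] <- cls
  }
  data.frame(ix = ds$coords$ix, iy = ds$coords$iy, class = lab)
}

#' Write polygon annotations as QuPath-dialect GeoJSON
#' @param features List of `list(name =, polygon = )` where `polygon` is a
#'   two-column matrix of vertices in micrometres.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path) {
  fl <- lapply(seq_along(features), function(i) {
    f <- features[[i]]
    ring <- lapply(seq_len(nrow(f$polygon)),
                   function(r) as.numeric(f$polygon[r, ]))
    ring[[length(ring) + 1L]] <- ring[[1L]]
    list(type = "Feature", id = paste0("feat-", i),
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(objectType = "annotation",
                           classification = list(name = f$name)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fl), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble per-MSI-pixel region labels
#'
#' One row per MSI pixel; attribute columns are independent categorical
#' labellings (`group`, `coherence_class`, `density_class`, `annotation`,
#' or any others supplied).
#'
#' @param ds An [msi_dataset()].
#' @param ... Named character vectors (length = pixels) or data frames with
#'   `ix`, `iy`, `class` as returned by [resample_to_msi()] /
#'   [import_annotations()].
#' @return Data frame of class `region_labels`.
#' @export
region_labels <- function(ds, ...) {
  out <- ds$coords
  attrs <- list(...)
  pixkey <- paste(out$ix, out$iy)
  for (nm in names(attrs)) {
    a <- attrs[[nm]]
    if (is.data.frame(a)) {
      m <- match(pixkey, paste(a$ix, a$iy))
      out[[nm]] <- a$class[m]
    } else {
      stopifnot(length(a) == nrow(out))
      out[[nm]] <- as.character(a)
    }
  }
  class(out) <- c("region_labels", "data.frame")
  out
}

#' Percent area occupied by each class of an attribute
#'
#' Percentages are over evaluated pixels: non-background (and non-`"none"`)
#' pixels of `attribute`, optionally restricted by other attributes (e.g.
#' within the tumour annotation). The returned percentages sum to 100.
#'
#' @param labels A [region_labels()] data frame.
#' @param attribute Column to tabulate.
#' @param within Optional named character vector of filters, e.g.
#'   `c(annotation = "tumour")`.
#' @return Data frame `class`, `n_pixels`, `percent`.
#' @export
percent_area <- function(labels, attribute, within = NULL) {
  if (!attribute %in% names(labels))
    stop("unknown attribute: ", attribute)
  keep <- rep(TRUE, nrow(labels))
  for (nm in names(within)) keep <- keep & labels[[nm]] == within[[nm]]
  v <- labels[[attribute]][keep]
  v <- v[!is.na(v) & !(v %in% c("background", "none"))]
  if (!length(v)) stop("zero evaluated pixels for attribute ", attribute)
  tt <- table(v)
  data.frame(class = names(tt), n_pixels = as.integer(tt),
             percent = 100 * as.numeric(tt) / sum(tt), row.names = NULL)
}

#' Export region labels as TSV
#' @param labels A [region_labels()] data frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_region_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
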