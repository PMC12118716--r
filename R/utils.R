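# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
gaussian_kernel_1d <- function(sigma, order = 0L) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  # first derivative of the Gaussian; normalised so the response to a
  # unit-slope ramp is 1 (sum(-x * k) == 1)
  k <- -x / sigma^2 * g
  k / sum(-x * k)
}

# Reflective padding (mirror without repeating the border sample is not
# required here; simple mirror-with-edge suffices for smoothing scales).
#' @keywords internal
#' @noRd
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r < nr, r < nc)
  ri <- c(rev(seq_len(r)), seq_len(nr), nr - seq_len(r) + 1L)
  ci <- c(rev(seq_len(r)), seq_len(nc), nc - seq_len(r) + 1L)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with reflective boundary handling. kx filters along
# rows (x = columns), ky along columns (y = rows). Kernels must be odd-length.
#' @keywords internal
#' @noRd
conv_sep <- function(m, kx, ky) {
  r <- max((length(kx) - 1L) %/% 2L, (length(ky) - 1L) %/% 2L)
  p <- pad_reflect(m, r)
  # filter2 correlates; our kernels are either symmetric or antisymmetric,
  # so build the full 2-D kernel and let EBImage's FFT path do the work.
  k2 <- outer(rev(ky), rev(kx))
  f <- EBImage::filter2(p, k2, boundary = "circular")
  f[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

#' @keywords internal
#' @noRd
gauss_smooth <- function(m, sigma) {
  g <- gaussian_kernel_1d(sigma)
  conv_sep(m, g, g)
}

# Even-odd point-in-polygon; points on an edge count as inside.
# poly: matrix with columns x, y (ring need not be closed).
#' @keywords internal
#' @noRd
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ]))) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  stopifnot(n >= 3L)
  x <- poly[, 1]; y <- poly[, 2]
  xj <- c(x[-1], x[1]); yj <- c(y[-1], y[1])
  inside <- logical(length(px))
  onedge <- logical(length(px))
  for (e in seq_len(n)) {
    x1 <- x[e]; y1 <- y[e]; x2 <- xj[e]; y2 <- yj[e]
    # boundary test: collinear and within bounding box of the edge
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    on <- abs(cross) <= 1e-9 * (abs(x2 - x1) + abs(y2 - y1) + 1) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    onedge <- onedge | on
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
  }
  inside | onedge
}

# Segment self-intersection check for polygon validation (O(n^2); rings in
# annotation files are small).
#' @keywords internal
#' @noRd
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ]))) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 4L) return(FALSE)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  inter <- function(a, b) {
    d1 <- a[2, ] - a[1, ]; d2 <- b[2, ] - b[1, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    t <- ((b[1, 1] - a[1, 1]) * d2[2] - (b[1, 2] - a[1, 2]) * d2[1]) / den
    u <- ((b[1, 1] - a[1, 1]) * d1[2] - (b[1, 2] - a[1, 2]) * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && u > 1e-9 && u < 1 - 1e-9
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the closure
      if (inter(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# output tables with a config checksum; not cryptographic.
#' @keywords internal
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261  # kept as double; split into 16-bit halves for bit ops
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 65536; hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), b)
    h <- hi * 65536 + lo
    # (h * prime) mod 2^32 without exceeding double precision
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
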