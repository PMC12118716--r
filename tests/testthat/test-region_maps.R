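msi_grid <- function(nx, ny, spacing = 50) {
  coords <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  msi_dataset(coords, spacing, c(1000, 1001),
              matrix(1, nrow(coords), 2))
}

test_that("resampling a constant map gives a constant value for any transform", {
  ds <- msi_grid(4, 4)
  cm <- structure(list(values = matrix(0.7, 100, 100), foreground = NULL,
                       um_per_px = 2, params = list()),
                  class = "coherence_map")
  out <- resample_to_msi(cm, ds)
  expect_true(all(out$value == 0.7))
  # non-trivial invertible transform (rotation + shift); the constant pulls
  # through wherever defined
  tr <- affine_transform(rbind(c(cos(0.3), -sin(0.3), 10),
                               c(sin(0.3), cos(0.3), -5)))
  out2 <- resample_to_msi(cm, ds, transform = tr)
  expect_true(all(out2$value[!is.na(out2$value)] == 0.7))
})

test_that("majority vote follows the extra pixel and excludes background", {
  ds <- msi_grid(1, 1, spacing = 50)
  # 5x5 source map at 10 um: 12 chaotic, 13 organised
  cls <- matrix(1L, 5, 5)
  cls[1:13] <- 2L
  rm <- region_map(cls, c("background", "chaotic", "organised"), 10)
  out <- resample_to_msi(rm, ds)
  expect_equal(out$class, "organised")
  # tipping one pixel back flips the majority
  rm$classes[13] <- 1L
  expect_equal(resample_to_msi(rm, ds)$class, "chaotic")
  # background pixels do not vote
  rm2 <- region_map(matrix(c(rep(0L, 24), 1L), 5, 5),
                    c("background", "chaotic", "organised"), 10)
  expect_equal(resample_to_msi(rm2, ds)$class, "chaotic")
})

test_that("mean pooling equals brute-force footprint averaging", {
  set.seed(12)
  ds <- msi_grid(3, 2)
  v <- matrix(runif(75 * 50), 50, 75)  # 2 um/px -> 150 x 100 um... scaled
  cm <- structure(list(values = v, foreground = NULL, um_per_px = 2,
                       params = list()), class = "coherence_map")
  out <- resample_to_msi(cm, ds)
  for (i in seq_len(nrow(out))) {
    x0 <- out$ix[i] * 50; y0 <- out$iy[i] * 50
    cc <- which((seq_len(75) - 0.5) * 2 >= x0 & (seq_len(75) - 0.5) * 2 < x0 + 50)
    rr <- which((seq_len(50) - 0.5) * 2 >= y0 & (seq_len(50) - 0.5) * 2 < y0 + 50)
    expect_equal(out$value[i], mean(v[rr, cc]))
  }
})

test_that("coarser maps are sampled at the pixel centre", {
  ds <- msi_grid(4, 4, spacing = 50)   # 200 x 200 um
  dm <- structure(list(values = matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2),
                       raw_counts = matrix(1, 2, 2), tile_um = 100,
                       um_per_px = 100), class = "density_map")
  out <- resample_to_msi(dm, ds)
  expect_false(any(is.na(out$value)))
  # pixel (0,0) centre (25,25) lies in tile [0,100)^2 -> 0.1
  expect_equal(out$value[out$ix == 0 & out$iy == 0], 0.1)
  expect_equal(out$value[out$ix == 3 & out$iy == 0], 0.4)
  expect_equal(out$value[out$ix == 0 & out$iy == 3], 0.9)
})

test_that("GeoJSON annotations label pixels by the centre-in-polygon rule", {
  ds <- msi_grid(4, 4)
  d <- withr::local_tempdir()
  f <- file.path(d, "ann.geojson")
  # square covering centres of pixels (1,1),(2,1),(1,2),(2,2)
  sq <- cbind(c(60, 160, 160, 60), c(60, 60, 160, 160))
  write_annotations(list(list(name = "tumour", polygon = sq)), f)
  out <- import_annotations(f, ds)
  hit <- out[out$class == "tumour", ]
  expect_equal(nrow(hit), 4)
  expect_setequal(paste(hit$ix, hit$iy),
                  c("1 1", "2 1", "1 2", "2 2"))

  # empty feature list labels nothing
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       file.path(d, "empty.geojson"), auto_unbox = TRUE)
  expect_true(all(import_annotations(file.path(d, "empty.geojson"),
                                     ds)$class == "none"))

  # pixel centre exactly on an edge counts as inside
  edge <- cbind(c(75, 200, 200, 75), c(0, 0, 200, 200))
  write_annotations(list(list(name = "t", polygon = edge)),
                    file.path(d, "edge.geojson"))
  oute <- import_annotations(file.path(d, "edge.geojson"), ds)
  expect_true(all(oute$class[oute$ix == 1] == "t"))

  # vertex order does not matter
  write_annotations(list(list(name = "tumour", polygon = sq[4:1, ])),
                    file.path(d, "rev.geojson"))
  expect_equal(import_annotations(file.path(d, "rev.geojson"), ds)$class,
               out$class)

  # self-intersecting bow-tie polygon is rejected by feature id
  bow <- cbind(c(0, 100, 0, 100), c(0, 100, 100, 0))
  write_annotations(list(list(name = "bad", polygon = bow)),
                    file.path(d, "bow.geojson"))
  expect_error(import_annotations(file.path(d, "bow.geojson"), ds),
               "self-intersecting.*feat-1")

  # overlapping polygons: last-listed wins, with a message
  sq2 <- cbind(c(60, 110, 110, 60), c(60, 60, 110, 110))
  write_annotations(list(list(name = "A", polygon = sq),
                         list(name = "B", polygon = sq2)),
                    file.path(d, "ovl.geojson"))
  expect_message(outo <- import_annotations(file.path(d, "ovl.geojson"), ds),
                 "last-listed wins")
  expect_equal(outo$class[outo$ix == 1 & outo$iy == 1], "B")
  expect_equal(outo$class[outo$ix == 2 & outo$iy == 2], "A")
})

test_that("percent areas count classes over evaluated pixels and sum to 100", {
  ds <- msi_grid(10, 10)
  coh <- c(rep("chaotic", 30), rep("organised", 70))
  ann <- c(rep("tumour", 50), rep("none", 50))
  labels <- region_labels(ds, coherence_class = coh, annotation = ann)
  pa <- percent_area(labels, "coherence_class")
  expect_equal(pa$percent[pa$class == "chaotic"], 30)
  expect_equal(pa$percent[pa$class == "organised"], 70)
  expect_equal(sum(pa$percent), 100)

  pat <- percent_area(labels, "coherence_class",
                      within = c(annotation = "tumour"))
  expect_equal(pat$percent[pat$class == "chaotic"], 60)
  expect_equal(sum(pat$percent), 100)

  # brute-force counting oracle on random labels
  set.seed(2)
  lab2 <- region_labels(ds, cls = sample(c("a", "b", "c", "background"),
                                         100, replace = TRUE))
  pa2 <- percent_area(lab2, "cls")
  ev <- lab2$cls[lab2$cls != "background"]
  for (k in pa2$class)
    expect_equal(pa2$percent[pa2$class == k], 100 * sum(ev == k) / length(ev))
  expect_equal(sum(pa2$percent), 100, tolerance = 1e-9)

  expect_error(percent_area(labels, "nope"), "unknown attribute")
})

test_that("landmark affine fit recovers a known transform", {
  tr_true <- affine_transform(rbind(c(0.98, -0.05, 120),
                                    c(0.04, 1.02, -40)))
  set.seed(6)
  src <- cbind(runif(6, 0, 2000), runif(6, 0, 2000))
  dst <- apply_affine(tr_true, src)
  fit <- fit_affine(src, dst)
  expect_lt(max(abs(unclass(fit) - unclass(tr_true))), 1e-9)
  expect_lt(attr(fit, "rms_residual_um"), 1e-9)
  expect_error(fit_affine(src[1:2, ], dst[1:2, ]), ">= 3")
  expect_error(affine_transform(rbind(c(1, 0, 0), c(2, 0, 0))),
               "invertible")
})
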