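# Small in-code fixtures shared across test files.

# continuous-mode dataset on a given axis from a pixels x bins matrix
make_cont_ds <- function(intensity, mz = NULL, spacing = 50) {
  np <- nrow(intensity)
  if (is.null(mz)) mz <- seq(800, by = 0.1, length.out = ncol(intensity))
  msi_dataset(data.frame(ix = seq_len(np) - 1L, iy = 0L),
              spacing, mz, intensity)
}

# processed-mode dataset from a list of (mz, intensity) pairs
make_proc_ds <- function(spectra, spacing = 50) {
  np <- length(spectra)
  msi_dataset(data.frame(ix = seq_len(np) - 1L, iy = 0L), spacing,
              lapply(spectra, `[[`, "mz"),
              lapply(spectra, `[[`, "intensity"))
}

# brute-force all-pairs AUC: P(Xb > Xa) + 0.5 P(Xb == Xa)
brute_auc <- function(xa, xb) {
  s <- 0
  for (b in xb) for (a in xa) s <- s + (b > a) + 0.5 * (b == a)
  s / (length(xa) * length(xb))
}

# tiny feature-matrix object without going through peak detection
make_fm <- function(values, peaks_mz = NULL) {
  np <- nrow(values)
  if (is.null(peaks_mz)) peaks_mz <- seq(1000, by = 10,
                                         length.out = ncol(values))
  structure(list(
    values = values,
    pixel_index = data.frame(ix = seq_len(np) - 1L, iy = 0L),
    peaks = peak_table(peaks_mz, peaks_mz - 0.4, peaks_mz + 0.4),
    normalized = TRUE), class = "feature_matrix")
}

labels_for_fm <- function(fm, ...) {
  df <- fm$pixel_index
  args <- list(...)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  class(df) <- c("region_labels", "data.frame")
  df
}
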