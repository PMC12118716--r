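# within-cluster sum of squares about the centroid
cluster_sse <- function(X) {
  if (nrow(X) <= 1) return(0)
  ctr <- colMeans(X)
  sum(sweep(X, 2, ctr)^2)
}

# greedy k-means++ initialisation: the second centre is chosen among a few
# distance-weighted candidates as the one minimising the resulting SSE.
kmeanspp_centers <- function(X, k = 2L, n_candidates = 3L) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(X, 1, function(r)
      min(colSums((t(centers) - r)^2)))
    if (sum(d2) <= 0) {
      cand <- sample.int(n, 1L)
      centers <- rbind(centers, X[cand, , drop = FALSE])
      next
    }
    cand <- sample.int(n, min(n_candidates, n), prob = d2 / sum(d2),
                       replace = TRUE)
    best <- cand[1]; best_sse <- Inf
    for (ci in unique(cand)) {
      trial <- rbind(centers, X[ci, , drop = FALSE])
      assign_d2 <- apply(X, 1, function(r)
        min(colSums((t(trial) - r)^2)))
      if (sum(assign_d2) < best_sse) { best_sse <- sum(assign_d2); best <- ci }
    }
    centers <- rbind(centers, X[best, , drop = FALSE])
  }
  centers
}

# best-of-n-restarts 2-means split; returns integer vector of 1/2
best_split <- function(X, restarts = 10L) {
  distinct <- nrow(unique(X))
  if (distinct < 2) {  # degenerate: identical rows, split by position
    half <- rep(1L, nrow(X)); half[seq_len(nrow(X) %/% 2)] <- 2L
    return(half)
  }
  best <- NULL; best_sse <- Inf
  for (r in seq_len(restarts)) {
    init <- kmeanspp_centers(X, 2L)
    km <- suppressWarnings(
      stats::kmeans(X, centers = init, algorithm = "Lloyd", iter.max = 100))
    if (km$tot.withinss < best_sse) {
      best_sse <- km$tot.withinss; best <- km$cluster
    }
  }
  best
}

#' Bisecting k-means segmentation of MSI pixels
#'
#' Divisive clustering of the candidate-feature matrix: start from a single
#' cluster of all pixels and repeat K - 1 times: take the leaf with the
#' largest within-cluster sum of squares (SSE) and split it by 2-means
#' (greedy k-means++ initialisation, `restarts` restarts, lowest-SSE split
#' kept). The run is fully deterministic given `seed`; pixels are processed
#' in canonical raster order, so permuting the input rows permutes the
#' labels identically. The `"correlation"` metric row-standardises each
#' pixel's feature vector (zero mean, unit SD) before Euclidean 2-means,
#' which makes squared distance an affine function of Pearson correlation.
#'
#' @param fm A [build_feature_matrix()] result, usually restricted to
#'   selected peaks via `selected`.
#' @param K Number of segments (`1 <= K <=` pixels).
#' @param seed Integer RNG seed (mandatory: initialisation is stochastic).
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param selected Optional logical/integer peak subset.
#' @param split_rule `"largest_sse"` (default) or `"largest_size"`.
#' @param restarts 2-means restarts per split (default 10).
#' @return Object of class `segmentation_result`: `labels` (segment id
#'   1..K per matrix row), `pixel_index`, `K`, `seed`, `metric`,
#'   `split_tree` (one row per bisection: parent, new segment id, SSE
#'   before/after), `total_sse_path`.
#' @export
bisecting_kmeans <- function(fm, K = 5L, seed, metric = c("correlation",
                                                          "euclidean"),
                             selected = NULL, split_rule = c("largest_sse",
                                                             "largest_size"),
                             restarts = 10L) {
  metric <- match.arg(metric); split_rule <- match.arg(split_rule)
  if (missing(seed)) stop("seed is mandatory")
  sel <- if (is.null(selected)) seq_len(ncol(fm$values))
         else if (is.logical(selected)) which(selected) else as.integer(selected)
  X <- fm$values[, sel, drop = FALSE]
  if (!ncol(X)) stop("empty feature set")
  n <- nrow(X)
  if (K < 1 || K > n) stop("K must be between 1 and the number of pixels")
  if (metric == "correlation") {
    mu <- rowMeans(X); s <- apply(X, 1, stats::sd)
    s[s == 0] <- 1
    X <- (X - mu) / s
  }
  ord <- order(fm$pixel_index$iy, fm$pixel_index$ix)
  Xo <- X[ord, , drop = FALSE]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  members <- list(seq_len(n))          # per segment: row indices into Xo
  sse <- cluster_sse(Xo)
  tree <- NULL
  total_path <- sum(sse)
  while (length(members) < K) {
    score <- if (split_rule == "largest_sse") sse
             else vapply(members, length, numeric(1))
    splittable <- vapply(members, length, integer(1)) >= 2L
    if (!any(splittable)) stop("no splittable segment left before reaching K")
    score[!splittable] <- -Inf
    pid <- which.max(score)
    rows <- members[[pid]]
    part <- best_split(Xo[rows, , drop = FALSE], restarts)
    # the child containing the parent's first (canonical) pixel keeps its id
    keep_side <- part[1]
    child_keep <- rows[part == keep_side]
    child_new <- rows[part != keep_side]
    new_id <- length(members) + 1L
    sse_before <- sse[pid]
    members[[pid]] <- child_keep
    members[[new_id]] <- child_new
    sse[pid] <- cluster_sse(Xo[child_keep, , drop = FALSE])
    sse[new_id] <- cluster_sse(Xo[child_new, , drop = FALSE])
    tree <- rbind(tree, data.frame(
      step = new_id - 1L, parent = pid, new_segment = new_id,
      n_parent = length(rows), sse_before = sse_before,
      sse_after = sse[pid] + sse[new_id]))
    total_path <- c(total_path, sum(sse))
  }
  lab_o <- integer(n)
  for (k in seq_along(members)) lab_o[members[[k]]] <- k
  labels <- integer(n)
  labels[ord] <- lab_o
  structure(list(labels = labels, pixel_index = fm$pixel_index, K = K,
                 seed = seed, metric = metric,
                 split_tree = tree, total_sse_path = total_path),
            class = "segmentation_result")
}

#' Segment composition per region class
#'
#' For each class of a region attribute, the percentage of its pixels that
#' falls in each segment. Every row sums to 100. Classes with zero pixels
#' are omitted with a warning.
#'
#' @param seg A [bisecting_kmeans()] result.
#' @param labels A [region_labels()] data frame on the same pixel set.
#' @param attribute Label column to stratify by.
#' @return Data frame: `class`, one `segment_<k>` column per segment,
#'   rows summing to 100.
#' @export
segment_composition <- function(seg, labels, attribute) {
  m <- match(paste(seg$pixel_index$ix, seg$pixel_index$iy),
             paste(labels$ix, labels$iy))
  lab <- labels[[attribute]][m]
  classes <- setdiff(unique(lab[!is.na(lab)]), c("background", "none"))
  rows <- list()
  for (cl in sort(classes)) {
    idx <- which(lab == cl)
    if (!length(idx)) { warning("class '", cl, "' has zero pixels; omitted")
                        next }
    tab <- tabulate(seg$labels[idx], nbins = seg$K)
    rows[[cl]] <- c(100 * tab / length(idx))
  }
  if (!length(rows)) stop("no class with pixels to tabulate")
  out <- data.frame(class = names(rows),
                    do.call(rbind, rows), row.names = NULL)
  names(out)[-1] <- sprintf("segment_%d", seq_len(seg$K))
  out
}

#' Export a segmentation as TSV (+ JSON split tree)
#' @param seg A [bisecting_kmeans()] result.
#' @param path Output TSV (`ix`, `iy`, `segment`); `<path>.tree.json` gets
#'   the split tree.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(
    data.frame(ix = seg$pixel_index$ix, iy = seg$pixel_index$iy,
               segment = seg$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(K = seg$K, seed = seg$seed, metric = seg$metric,
         splits = seg$split_tree, total_sse_path = seg$total_sse_path),
    paste0(path, ".tree.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
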