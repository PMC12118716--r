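#' Per-peak ROC discrimination between two pixel classes
#'
#' For every peak, the ROC area under the curve with `class_b` as the
#' positive class: AUC = P(X_b > X_a) + 0.5 P(X_b = X_a) over all
#' cross-class pixel pairs, the normalised Mann-Whitney U statistic. AUC
#' close to 1 means higher intensity in `class_b`, close to 0 higher in
#' `class_a`, 0.5 non-discriminative. The two-sided p-value comes from the
#' normal approximation to the rank-sum test with tie correction (no
#' continuity correction). Benjamini-Hochberg q-values are reported for
#' information; selection uses the raw p (see [select_candidates()]).
#'
#' @param fm A [build_feature_matrix()] result.
#' @param labels A [region_labels()] data frame covering the matrix pixels.
#' @param attribute Label column holding the two classes.
#' @param class_a,class_b Class names; each needs >= 2 pixels.
#' @return Data frame of class `roc_results`: `peak_id`, `mz`, `auc`,
#'   `p_value`, `q_value`, `n_a`, `n_b`, `direction`, `selected` (NA until
#'   [select_candidates()]).
#' @export
roc_per_peak <- function(fm, labels, attribute, class_a, class_b) {
  m <- match(paste(fm$pixel_index$ix, fm$pixel_index$iy),
             paste(labels$ix, labels$iy))
  lab <- labels[[attribute]][m]
  ia <- which(!is.na(lab) & lab == class_a)
  ib <- which(!is.na(lab) & lab == class_b)
  n_a <- length(ia); n_b <- length(ib)
  if (n_a < 2 || n_b < 2)
    stop(sprintf("both classes need >= 2 pixels (got %d '%s', %d '%s')",
                 n_a, class_a, n_b, class_b))
  x <- fm$values[c(ia, ib), , drop = FALSE]
  grp_b <- c(rep(FALSE, n_a), rep(TRUE, n_b))
  N <- n_a + n_b
  res <- apply(x, 2, function(v) {
    r <- rank(v)
    u_b <- sum(r[grp_b]) - n_b * (n_b + 1) / 2
    auc <- u_b / (n_a * n_b)
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    s2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    p <- if (s2 <= 0) 1 else 2 * stats::pnorm(-abs(u_b - n_a * n_b / 2) / sqrt(s2))
    c(auc = auc, p = min(p, 1))
  })
  out <- data.frame(
    peak_id = fm$peaks$peak_id, mz = fm$peaks$center,
    auc = res["auc", ], p_value = res["p", ],
    q_value = stats::p.adjust(res["p", ], method = "BH"),
    n_a = n_a, n_b = n_b,
    direction = ifelse(res["auc", ] >= 0.5, "up_in_b", "down_in_b"),
    selected = NA, row.names = NULL)
  class(out) <- c("roc_results", "data.frame")
  attr(out, "classes") <- c(a = class_a, b = class_b)
  out
}

#' Select candidate marker peaks from ROC results
#'
#' A peak is a candidate marker iff its AUC is at or beyond either threshold
#' (`auc >= auc_hi` or `auc <= auc_lo`) and its raw rank-test p-value is
#' below `p_max`. Defaults: AUC >= 0.6 or <= 0.4, p < 0.01.
#'
#' @param rocs A [roc_per_peak()] result.
#' @param auc_hi,auc_lo AUC thresholds in `[0, 1]`, `auc_lo < auc_hi`.
#' @param p_max Raw p-value cut (default 0.01).
#' @return `rocs` with the `selected` column filled.
#' @export
select_candidates <- function(rocs, auc_hi = 0.6, auc_lo = 0.4, p_max = 0.01) {
  if (auc_lo >= auc_hi || auc_hi > 1 || auc_lo < 0)
    stop("need 0 <= auc_lo < auc_hi <= 1")
  rocs$selected <- (rocs$auc >= auc_hi | rocs$auc <= auc_lo) &
    rocs$p_value < p_max
  rocs
}

#' Read / write a peptide identification table
#'
#' TSV with columns `sequence`, `mz`, `accession`, `protein_name`, `score`
#' (the LC-MS/MS identification confidence, -10lgP).
#'
#' @param path TSV file.
#' @return Data frame of peptide records.
#' @export
read_peptide_table <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence", "mz", "accession", "protein_name", "score")
  if (!all(need %in% names(pt)))
    stop("peptide table lacks columns: ",
         paste(setdiff(need, names(pt)), collapse = ", "))
  if (any(pt$mz <= 0) || any(pt$score < 0))
    stop("peptide table has non-positive mz or negative score")
  pt
}

#' @rdname read_peptide_table
#' @param peptides Data frame of peptide records.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign peptides and proteins to MSI peaks by accurate mass
#'
#' A peptide is a candidate for a peak when |peak centre - theoretical m/z|
#' is strictly below `tol_da`. Per peak, the candidate with the smallest
#' mass difference is kept; ties break toward the highest identification
#' score. A protein counts as *identified* only when at least two distinct
#' peaks are assigned to at least two distinct peptide sequences of that
#' protein, so a single ambiguous peak can never identify a protein. Input
#' order does not matter (records are sorted internally).
#'
#' @param peaks A [peak_table()].
#' @param peptides Peptide records (see [read_peptide_table()]).
#' @param tol_da Mass tolerance in Da, strict upper bound (default 0.15).
#' @return List with `assignments` (one row per matched peak) and `proteins`
#'   (per-accession summary with the `identified` flag).
#' @export
assign_proteins <- function(peaks, peptides, tol_da = 0.15) {
  if (tol_da <= 0) stop("tol_da must be positive")
  if (is.null(peptides) || nrow(peptides) == 0) stop("empty peptide table")
  peptides <- peptides[order(peptides$accession, peptides$sequence,
                             peptides$mz), , drop = FALSE]
  rows <- lapply(seq_len(nrow(peaks)), function(k) {
    delta <- abs(peaks$center[k] - peptides$mz)
    # strict upper bound, robust to floating-point representation of the
    # boundary (a difference printed as exactly tol_da is rejected)
    cand <- which(delta < tol_da - 1e-9)
    if (!length(cand)) return(NULL)
    best <- cand[order(delta[cand], -peptides$score[cand])][1]
    data.frame(peak_id = peaks$peak_id[k], peak_mz = peaks$center[k],
               sequence = peptides$sequence[best],
               mz_theoretical = peptides$mz[best],
               delta_da = delta[best],
               accession = peptides$accession[best],
               protein_name = peptides$protein_name[best],
               score = peptides$score[best])
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- data.frame(peak_id = integer(0), peak_mz = numeric(0),
                              sequence = character(0),
                              mz_theoretical = numeric(0),
                              delta_da = numeric(0), accession = character(0),
                              protein_name = character(0), score = numeric(0))
  prot <- if (nrow(assignments)) {
    sp <- split(assignments, assignments$accession)
    do.call(rbind, lapply(sp, function(d) data.frame(
      accession = d$accession[1], protein_name = d$protein_name[1],
      n_peaks = length(unique(d$peak_id)),
      n_peptides = length(unique(d$sequence)),
      identified = length(unique(d$peak_id)) >= 2 &&
        length(unique(d$sequence)) >= 2)))
  } else {
    data.frame(accession = character(0), protein_name = character(0),
               n_peaks = integer(0), n_peptides = integer(0),
               identified = logical(0))
  }
  rownames(prot) <- NULL
  list(assignments = assignments, proteins = prot[order(prot$accession), ,
                                                  drop = FALSE])
}

#' PCA on candidate marker features
#'
#' Column-mean-centred principal component analysis of the feature matrix
#' restricted to selected peaks (unit-variance scaling off by default,
#' matching TIC-normalised unscaled features). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is made positive.
#'
#' @param fm A [build_feature_matrix()] result.
#' @param selected Logical/integer vector of peaks to use (e.g. the
#'   `selected` column of [select_candidates()]); default all peaks.
#' @param scale Logical, unit-variance scaling (default FALSE).
#' @return Object of class `pca_result`: `loadings` (peaks x components),
#'   `scores` (pixels x components), `explained_variance_ratio`,
#'   `pixel_index`, `peak_ids`.
#' @export
pca_on_candidates <- function(fm, selected = NULL, scale = FALSE) {
  sel <- if (is.null(selected)) seq_len(ncol(fm$values))
         else if (is.logical(selected)) which(selected) else as.integer(selected)
  X <- fm$values[, sel, drop = FALSE]
  if (ncol(X) < 2) stop("need >= 2 selected peaks for PCA")
  if (nrow(X) < 3) stop("need >= 3 pixels for PCA")
  if (all(apply(X, 2, stats::sd) == 0)) stop("rank-0 feature matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = pc$x,
                 explained_variance_ratio = evr,
                 pixel_index = fm$pixel_index,
                 peak_ids = fm$peaks$peak_id[sel]),
            class = "pca_result")
}

#' Map a principal-component score back onto the pixel grid
#' @param pca A [pca_on_candidates()] result.
#' @param component Component number (default 1).
#' @return Data frame `ix`, `iy`, `value`.
#' @export
pc_score_image <- function(pca, component = 1) {
  data.frame(ix = pca$pixel_index$ix, iy = pca$pixel_index$iy,
             value = pca$scores[, component])
}

#' Two-way ANOVA on percent areas
#'
#' Standard two-way fixed-effects ANOVA with interaction comparing a
#' per-sample percentage (e.g. area occupied by a morphology class) across
#' two crossed factors, typically tumour group and region class. Type II
#' sums of squares are used so mildly unbalanced designs remain
#' interpretable; on balanced data these equal the textbook sequential SS.
#'
#' @param table Data frame with the response and both factor columns; every
#'   factor-level cell needs >= 2 samples.
#' @param response Response column name (default `"percent"`).
#' @param factors Length-2 character vector of factor column names
#'   (default `c("group", "class")`).
#' @return Data frame `term`, `sum_sq`, `df`, `statistic` (F), `p_value`
#'   (terms: both factors, interaction, residuals).
#' @export
compare_area_groups <- function(table, response = "percent",
                                factors = c("group", "class")) {
  stopifnot(length(factors) == 2,
            all(c(response, factors) %in% names(table)))
  f1 <- factor(table[[factors[1]]]); f2 <- factor(table[[factors[2]]])
  cells <- table(f1, f2)
  if (any(cells < 2))
    stop("every design cell needs >= 2 samples (empty or singleton cell)")
  d <- data.frame(y = table[[response]], f1 = f1, f2 = f2)
  fit <- stats::lm(y ~ f1 * f2, data = d)
  a <- car::Anova(fit, type = 2)
  terms_map <- c("f1" = factors[1], "f2" = factors[2],
                 "f1:f2" = paste(factors, collapse = ":"),
                 "Residuals" = "residuals")
  data.frame(term = unname(terms_map[rownames(a)]),
             sum_sq = a[["Sum Sq"]], df = a[["Df"]],
             statistic = a[["F value"]], p_value = a[["Pr(>F)"]],
             row.names = NULL)
}

#' Write ROC results as TSV
#' @param rocs A `roc_results` data frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_roc_results <- function(rocs, path) {
  utils::write.table(rocs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
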