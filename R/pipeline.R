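#' Build and validate a pipeline run configuration
#'
#' Merges user settings over the documented defaults and validates ranges.
#' Every constant of the analysis is a named default here: the 0.5 class
#' cut is built into the classifiers, AUC thresholds 0.6 / 0.4, p < 0.01,
#' mass tolerance 0.15 Da, raster 50 um.
#'
#' @param config Named list or path to a YAML file. Recognised input keys:
#'   `shg` (TIFF path) + `um_per_px`, `nuclei` (centroid CSV), `msi`
#'   (fixture dir or .imzML), `annotations` (GeoJSON with group polygons
#'   and optionally a tumour class), `peptides` (TSV), `area_table`
#'   (multi-sample TSV `sample`, `group`, `class`, `percent` for the
#'   two-way ANOVA), `out_dir`. Parameter keys: `sigma_g`, `sigma_w`,
#'   `tile_um`, `grid_da`, `snr`, `half_width`, `noise_mode`, `auc_hi`,
#'   `auc_lo`, `p_max`, `tol_da`, `K`, `metric`, `seed` (mandatory),
#'   `groups` (two class names, default LSCC/RSCC), `transform`
#'   (2x3 matrix rows, map -> MSI um).
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(sigma_g = 2, sigma_w = 8, tile_um = 100, grid_da = 0.1,
                   snr = 3, half_width = 0.4, noise_mode = "medium",
                   auc_hi = 0.6, auc_lo = 0.4, p_max = 0.01, tol_da = 0.15,
                   K = 5L, metric = "correlation",
                   groups = c("LSCC", "RSCC"), smooth_density = FALSE,
                   annotation_class = "tumour", um_per_px = 0.38)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config error: seed is mandatory")
  if (!(cfg$auc_hi > 0.5 && cfg$auc_hi > cfg$auc_lo && cfg$auc_lo < 0.5 &&
        cfg$auc_hi <= 1 && cfg$auc_lo >= 0))
    stop("config error: need auc_lo < 0.5 < auc_hi (got ",
         cfg$auc_lo, ", ", cfg$auc_hi, ")")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("config error: p_max in (0, 1]")
  if (cfg$tol_da <= 0) stop("config error: tol_da must be positive")
  if (cfg$K < 1) stop("config error: K >= 1")
  if (cfg$sigma_w < cfg$sigma_g) stop("config error: sigma_w >= sigma_g")
  cfg$transform <- if (is.null(cfg$transform)) affine_identity()
                   else affine_transform(do.call(rbind, cfg$transform))
  class(cfg) <- c("run_config", "list")
  cfg
}

pipeline_stage <- function(name, input, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed on input '", input, "': ",
         conditionMessage(e), call. = FALSE))
}

# derived attribute: cls within a filter class of another attribute
restrict_attribute <- function(labels, attribute, filter_attr, filter_class) {
  out <- labels[[attribute]]
  out[is.na(labels[[filter_attr]]) |
        labels[[filter_attr]] != filter_class] <- NA
  out
}

#' Run the full correlative workflow
#'
#' Executes coherence mapping, nuclei density mapping, co-registration onto
#' the MSI raster, TIC normalisation and peak detection, the supervised ROC
#' comparisons (group vs group over the annotated tumour; HND vs LND;
#' chaotic vs organised; group contrasts within the HND, chaotic and
#' organised strata), candidate selection, protein assignment, PCA and
#' bisecting k-means segmentation with per-group segment composition, and
#' (when a multi-sample area table is supplied) the two-way ANOVA on
#' percent areas. When `out_dir` is set, result tables (TSV, stamped with
#' the config hash), the parameter manifest (JSON) and a structured log are
#' written there.
#'
#' @param config A [run_config()] (or list/YAML path accepted by it).
#' @return A report list; see details in the package vignette.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  # the hash covers analysis-relevant settings; pure output locations do
  # not change results and are excluded
  hashed <- cfg[setdiff(sort(names(cfg)), "out_dir")]
  cfg_json <- jsonlite::toJSON(hashed, auto_unbox = TRUE, force = TRUE)
  cfg_hash <- fnv1a_hash(as.character(cfg_json))
  log <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log <<- c(log, line)
    message(line)
  }

  note("config hash ", cfg_hash)
  ds <- pipeline_stage("read_msi", cfg$msi, read_msi(cfg$msi))
  ds <- pipeline_stage("tic_normalize", cfg$msi, tic_normalize(ds))
  note("MSI: ", n_pixels(ds), " pixels, ", sum(ds$tic_zero),
       " zero-TIC excluded")
  ms <- pipeline_stage("mean_spectrum", cfg$msi,
                       mean_spectrum(ds, grid_da = cfg$grid_da))
  peaks <- pipeline_stage("detect_peaks", cfg$msi,
                          detect_peaks(ms, snr_min = cfg$snr,
                                       half_width_da = cfg$half_width,
                                       noise_mode = cfg$noise_mode))
  note("detected ", nrow(peaks), " peaks")
  fm <- pipeline_stage("build_feature_matrix", cfg$msi,
                       build_feature_matrix(ds, peaks))

  cm <- rmc <- NULL
  if (!is.null(cfg$shg)) {
    img <- pipeline_stage("read_shg", cfg$shg,
                          read_intensity_image(cfg$shg, cfg$um_per_px))
    cm <- pipeline_stage("coherence_map", cfg$shg,
                         coherence_map(img, cfg$sigma_g, cfg$sigma_w))
    rmc <- classify_coherence(cm)
    note("coherence map: ", sum(cm$foreground), " foreground px")
  }
  dmap <- rmd <- NULL
  if (!is.null(cfg$nuclei)) {
    nuc <- pipeline_stage("read_nuclei", cfg$nuclei,
                          read_nuclei_csv(cfg$nuclei))
    dmap <- pipeline_stage("density_map", cfg$nuclei,
                           density_map(nuc, tile_um = cfg$tile_um,
                                       smooth = cfg$smooth_density))
    rmd <- classify_density(dmap)
    note("density map: ", nrow(nuc$centroids), " nuclei")
  }

  lab_args <- list(ds)
  if (!is.null(rmc))
    lab_args$coherence_class <- pipeline_stage(
      "resample_coherence", cfg$shg,
      resample_to_msi(rmc, ds, cfg$transform))
  if (!is.null(rmd))
    lab_args$density_class <- pipeline_stage(
      "resample_density", cfg$nuclei, resample_to_msi(rmd, ds, cfg$transform))
  if (!is.null(cfg$annotations)) {
    lab_args$group <- pipeline_stage(
      "import_groups", cfg$annotations,
      import_annotations(cfg$annotations, ds, classes = cfg$groups))
    lab_args$annotation <- pipeline_stage(
      "import_annotations", cfg$annotations,
      import_annotations(cfg$annotations, ds,
                         classes = cfg$annotation_class))
  }
  labels <- do.call(region_labels, lab_args)

  areas <- list()
  for (attrib in intersect(c("coherence_class", "density_class"),
                           names(labels)))
    areas[[attrib]] <- percent_area(labels, attrib)
  if (all(c("group", "coherence_class") %in% names(labels)))
    for (g in cfg$groups)
      areas[[paste0("coherence_class|", g)]] <-
        percent_area(labels, "coherence_class", within = c(group = g))
  if (all(c("group", "density_class") %in% names(labels)))
    for (g in cfg$groups)
      areas[[paste0("density_class|", g)]] <-
        percent_area(labels, "density_class", within = c(group = g))

  comparisons <- list()
  if ("group" %in% names(labels))
    comparisons$group <- list(attribute = "group", a = cfg$groups[1],
                              b = cfg$groups[2])
  if ("density_class" %in% names(labels))
    comparisons$density <- list(attribute = "density_class",
                                a = "LND", b = "HND")
  if ("coherence_class" %in% names(labels))
    comparisons$coherence <- list(attribute = "coherence_class",
                                  a = "chaotic", b = "organised")
  strata <- list(c("density_class", "HND"), c("coherence_class", "chaotic"),
                 c("coherence_class", "organised"))
  if ("group" %in% names(labels)) for (st in strata) {
    if (!st[1] %in% names(labels)) next
    nm <- paste0("group_within_", st[2])
    labels[[nm]] <- restrict_attribute(labels, "group", st[1], st[2])
    comparisons[[nm]] <- list(attribute = nm, a = cfg$groups[1],
                              b = cfg$groups[2])
  }

  rocs <- list()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    rocs[[nm]] <- pipeline_stage(
      paste0("roc_", nm), cmp$attribute,
      select_candidates(
        roc_per_peak(fm, labels, cmp$attribute, cmp$a, cmp$b),
        auc_hi = cfg$auc_hi, auc_lo = cfg$auc_lo, p_max = cfg$p_max))
    note("ROC ", nm, ": ", sum(rocs[[nm]]$selected), "/", nrow(peaks),
         " candidate peaks")
  }

  proteins <- NULL
  if (!is.null(cfg$peptides)) {
    pep <- pipeline_stage("read_peptides", cfg$peptides,
                          read_peptide_table(cfg$peptides))
    proteins <- pipeline_stage("assign_proteins", cfg$peptides,
                               assign_proteins(peaks, pep,
                                               tol_da = cfg$tol_da))
    note("proteins: ", sum(proteins$proteins$identified), " identified of ",
         nrow(proteins$proteins), " matched accessions")
  }

  primary <- if (!is.null(rocs$group)) rocs$group else rocs[[1]]
  sel <- primary$selected
  if (sum(sel) < 2) {
    note("fewer than 2 candidate peaks; PCA/segmentation fall back to all peaks")
    sel <- rep(TRUE, nrow(peaks))
  }
  pca <- pipeline_stage("pca", "candidate features",
                        pca_on_candidates(fm, selected = sel))
  note(sprintf("PCA: first 3 components explain %.2f%% of variance",
               100 * sum(pca$explained_variance_ratio[1:min(3,
                 length(pca$explained_variance_ratio))])))
  seg <- pipeline_stage("segmentation", "candidate features",
                        bisecting_kmeans(fm, K = cfg$K, seed = cfg$seed,
                                         metric = cfg$metric,
                                         selected = sel))
  composition <- NULL
  if ("group" %in% names(labels))
    composition <- pipeline_stage("segment_composition", "group",
                                  segment_composition(seg, labels, "group"))

  anova_tbl <- NULL
  if (!is.null(cfg$area_table)) {
    at <- utils::read.delim(cfg$area_table)
    anova_tbl <- pipeline_stage("two_way_anova", cfg$area_table,
                                compare_area_groups(at))
    note("two-way ANOVA on ", cfg$area_table)
  }

  report <- list(config = cfg, config_hash = cfg_hash, peaks = peaks,
                 feature_matrix = fm, labels = labels, areas = areas,
                 roc = rocs, proteins = proteins, pca = pca,
                 segmentation = seg, composition = composition,
                 anova = anova_tbl, coherence_map = cm, density_map = dmap,
                 log = log)
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_stamped_tsv <- function(df, path, hash) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a pipeline report bundle to disk
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- report$config_hash
  write_stamped_tsv(as.data.frame(report$peaks),
                    file.path(out_dir, "peaks.tsv"), h)
  write_stamped_tsv(report$labels, file.path(out_dir, "region_labels.tsv"), h)
  for (nm in names(report$roc))
    write_stamped_tsv(report$roc[[nm]],
                      file.path(out_dir, paste0("roc_", nm, ".tsv")), h)
  for (nm in names(report$areas))
    write_stamped_tsv(report$areas[[nm]],
                      file.path(out_dir,
                                paste0("area_", gsub("[^A-Za-z0-9]", "_", nm),
                                       ".tsv")), h)
  if (!is.null(report$proteins)) {
    write_stamped_tsv(report$proteins$assignments,
                      file.path(out_dir, "peak_assignments.tsv"), h)
    write_stamped_tsv(report$proteins$proteins,
                      file.path(out_dir, "proteins.tsv"), h)
  }
  write_stamped_tsv(
    data.frame(component = seq_along(report$pca$explained_variance_ratio),
               explained_variance_ratio =
                 report$pca$explained_variance_ratio),
    file.path(out_dir, "pca_variance.tsv"), h)
  write_segmentation(report$segmentation, file.path(out_dir, "segments.tsv"))
  if (!is.null(report$composition))
    write_stamped_tsv(report$composition,
                      file.path(out_dir, "segment_composition.tsv"), h)
  if (!is.null(report$anova))
    write_stamped_tsv(report$anova, file.path(out_dir, "anova.tsv"), h)
  cfg <- report$config
  cfg$transform <- unclass(cfg$transform)
  jsonlite::write_json(list(config_hash = h, config = cfg,
                            package_version =
                              as.character(utils::packageVersion("msicor"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
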