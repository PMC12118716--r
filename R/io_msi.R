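#' Read an MSI datacube
#'
#' Supports two dialects: the package's plain-text fixture bundle (a
#' directory with `meta.json`, `coords.csv` and either `mz.csv` +
#' `intensity.csv` for a shared axis or `spectra.csv` in long form) and
#' imzML 1.1 (continuous and processed binary mode, `.imzML` + `.ibd`).
#'
#' @param path Path to a fixture directory or an `.imzML` file.
#' @param format `"auto"` (default, by extension), `"fixture"` or `"imzml"`.
#' @return An [msi_dataset()].
#' @export
read_msi <- function(path, format = c("auto", "fixture", "imzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml"
              else "fixture"
  }
  if (format == "fixture") read_msi_fixture(path) else read_imzml(path)
}

#' Write an MSI datacube
#'
#' @param ds An [msi_dataset()].
#' @param path Output directory (fixture) or `.imzML` file path (the `.ibd`
#'   is written next to it).
#' @param format `"fixture"` (default) or `"imzml"`.
#' @return `path`, invisibly.
#' @export
write_msi <- function(ds, path, format = c("fixture", "imzml")) {
  format <- match.arg(format)
  if (format == "fixture") write_msi_fixture(ds, path)
  else write_imzml(ds, path)
  invisible(path)
}

num_fmt <- function(x) sprintf("%.17g", x)

write_msi_fixture <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(layout = if (ds$continuous) "continuous" else "processed",
               spacing_um = ds$spacing_um, origin_um = ds$origin_um,
               metadata = ds$metadata)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(ds$coords, file.path(path, "coords.csv"),
                   row.names = FALSE)
  if (ds$continuous) {
    writeLines(num_fmt(ds$mz), file.path(path, "mz.csv"))
    conn <- file(file.path(path, "intensity.csv"), "w")
    on.exit(close(conn))
    for (i in seq_len(nrow(ds$intensity)))
      writeLines(paste(num_fmt(ds$intensity[i, ]), collapse = ","), conn)
  } else {
    conn <- file(file.path(path, "spectra.csv"), "w")
    on.exit(close(conn))
    writeLines("pixel,mz,intensity", conn)
    for (i in seq_along(ds$mz)) {
      if (!length(ds$mz[[i]])) next
      writeLines(paste(i, num_fmt(ds$mz[[i]]), num_fmt(ds$intensity[[i]]),
                       sep = ","), conn)
    }
  }
  path
}

read_msi_fixture <- function(path) {
  metaf <- file.path(path, "meta.json")
  if (!file.exists(metaf))
    stop("not a fixture bundle: missing ", metaf)
  meta <- jsonlite::read_json(metaf, simplifyVector = TRUE)
  if (is.null(meta$spacing_um))
    stop("fixture meta.json lacks required field 'spacing_um'")
  coords <- utils::read.csv(file.path(path, "coords.csv"))
  if (identical(meta$layout, "continuous")) {
    mz <- as.numeric(readLines(file.path(path, "mz.csv")))
    lines <- readLines(file.path(path, "intensity.csv"))
    if (length(lines) != nrow(coords))
      stop("intensity.csv rows inconsistent with coords.csv")
    intensity <- do.call(rbind, lapply(strsplit(lines, ","), as.numeric))
    msi_dataset(coords, meta$spacing_um, mz, intensity,
                origin_um = meta$origin_um %||% c(0, 0),
                metadata = as.list(meta$metadata))
  } else {
    long <- utils::read.csv(file.path(path, "spectra.csv"))
    np <- nrow(coords)
    mz <- vector("list", np); intensity <- vector("list", np)
    sp <- split(long, factor(long$pixel, levels = seq_len(np)))
    for (i in seq_len(np)) {
      mz[[i]] <- sp[[i]]$mz
      intensity[[i]] <- sp[[i]]$intensity
    }
    msi_dataset(coords, meta$spacing_um, mz, intensity,
                origin_um = meta$origin_um %||% c(0, 0),
                metadata = as.list(meta$metadata))
  }
}

# ---- imzML 1.1 ------------------------------------------------------------

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED  <- "IMS:1000031"
IMS_PIXEL_X    <- "IMS:1000046"
IMS_POS_X      <- "IMS:1000050"
IMS_POS_Y      <- "IMS:1000051"
IMS_OFFSET     <- "IMS:1000102"
IMS_LENGTH     <- "IMS:1000103"
IMS_ENCLEN     <- "IMS:1000104"
MS_MZ_ARRAY    <- "MS:1000514"
MS_INT_ARRAY   <- "MS:1000515"

write_imzml <- function(ds, path) {
  stopifnot(grepl("\\.imzml$", path, ignore.case = TRUE))
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  # deterministic UUID (content-derived) so identical datasets give
  # byte-identical files and the writer leaves the RNG state untouched
  h <- paste0(fnv1a_hash(paste(n_pixels(ds), ds$spacing_um)),
              fnv1a_hash(paste(range(ds$coords$ix), range(ds$coords$iy),
                               collapse = "-")),
              fnv1a_hash(paste(format(mz_range(ds)), collapse = "-")),
              fnv1a_hash("msicor-ibd"))
  uuid <- as.raw(strtoi(substring(h, seq(1, 31, 2), seq(2, 32, 2)), 16L))
  con <- file(ibd_path, "wb"); on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  np <- n_pixels(ds)
  specs <- vector("list", np)
  mz_off <- NULL; mz_len <- NULL
  for (i in seq_len(np)) {
    if (ds$continuous) {
      if (is.null(mz_off)) {
        mz_off <- offset; mz_len <- length(ds$mz)
        writeBin(as.numeric(ds$mz), con, size = 8, endian = "little")
        offset <- offset + 8 * mz_len
      }
      this_mz <- c(mz_off, mz_len)
      ivec <- as.numeric(ds$intensity[i, ])
    } else {
      writeBin(as.numeric(ds$mz[[i]]), con, size = 8, endian = "little")
      this_mz <- c(offset, length(ds$mz[[i]]))
      offset <- offset + 8 * length(ds$mz[[i]])
      ivec <- as.numeric(ds$intensity[[i]])
    }
    writeBin(ivec, con, size = 8, endian = "little")
    specs[[i]] <- list(mz_off = this_mz[1], mz_len = this_mz[2],
                       i_off = offset, i_len = length(ivec))
    offset <- offset + 8 * length(ivec)
  }
  mode_acc <- if (ds$continuous) IMS_CONTINUOUS else IMS_PROCESSED
  mode_name <- if (ds$continuous) "continuous" else "processed"
  bda <- function(ref, off, len) paste0(
    '<binaryDataArray encodedLength="', 8 * len, '">',
    '<referenceableParamGroupRef ref="', ref, '"/>',
    '<cvParam cvRef="IMS" accession="', IMS_OFFSET, '" name="external offset" value="', off, '"/>',
    '<cvParam cvRef="IMS" accession="', IMS_LENGTH, '" name="external array length" value="', len, '"/>',
    '<cvParam cvRef="IMS" accession="', IMS_ENCLEN, '" name="external encoded length" value="', 8 * len, '"/>',
    '<binary/></binaryDataArray>')
  spec_xml <- vapply(seq_len(np), function(i) {
    s <- specs[[i]]
    paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i, '" defaultArrayLength="0">',
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="', IMS_POS_X, '" name="position x" value="', ds$coords$ix[i] + 1L, '"/>',
      '<cvParam cvRef="IMS" accession="', IMS_POS_Y, '" name="position y" value="', ds$coords$iy[i] + 1L, '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      bda("mzArray", s$mz_off, s$mz_len),
      bda("intensityArray", s$i_off, s$i_len),
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="', mode_acc, '" name="', mode_name, '"/>',
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="', MS_MZ_ARRAY, '" name="m/z array"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="', MS_INT_ARRAY, '" name="intensity array"/>',
    '</referenceableParamGroup></referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="', IMS_PIXEL_X, '" name="pixel size (x)" value="',
    num_fmt(ds$spacing_um), '"/>',
    '</scanSettings></scanSettingsList>\n',
    '<run id="run1"><spectrumList count="', np, '">\n',
    paste(spec_xml, collapse = "\n"),
    '\n</spectrumList></run></mzML>\n')
  writeLines(xml, path)
  path
}

read_imzml <- function(path) {
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd companion for ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  cv_value <- function(node, accession) {
    n <- xml2::xml_find_first(
      node, sprintf(".//cvParam[@accession='%s']", accession))
    if (inherits(n, "xml_missing")) NA_character_
    else xml2::xml_attr(n, "value")
  }
  mode_cont <- !inherits(xml2::xml_find_first(
    doc, sprintf("//cvParam[@accession='%s']", IMS_CONTINUOUS)), "xml_missing")
  px <- xml2::xml_find_first(
    doc, sprintf("//cvParam[@accession='%s']", IMS_PIXEL_X))
  if (inherits(px, "xml_missing"))
    stop("imzML lacks required pixel size metadata (", IMS_PIXEL_X,
         ", 'pixel size (x)')")
  spacing_um <- as.numeric(xml2::xml_attr(px, "value"))
  specs <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(specs)) stop("imzML contains no spectra")
  ibd <- file(ibd_path, "rb"); on.exit(close(ibd), add = TRUE)
  read_arr <- function(off, len) {
    seek(ibd, where = off, origin = "start")
    readBin(ibd, "double", n = len, size = 8, endian = "little")
  }
  np <- length(specs)
  ix <- integer(np); iy <- integer(np)
  mzl <- vector("list", np); il <- vector("list", np)
  for (i in seq_len(np)) {
    sp <- specs[[i]]
    ix[i] <- as.integer(cv_value(sp, IMS_POS_X)) - 1L
    iy[i] <- as.integer(cv_value(sp, IMS_POS_Y)) - 1L
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    got_mz <- FALSE; got_i <- FALSE
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, ".//referenceableParamGroupRef"), "ref")
      is_mz <- identical(ref, "mzArray") ||
        !inherits(xml2::xml_find_first(
          arr, sprintf(".//cvParam[@accession='%s']", MS_MZ_ARRAY)),
          "xml_missing")
      off <- as.numeric(cv_value(arr, IMS_OFFSET))
      len <- as.integer(cv_value(arr, IMS_LENGTH))
      if (is.na(off) || is.na(len))
        stop("binaryDataArray without external offset/length in spectrum ", i)
      if (is_mz) { mzl[[i]] <- read_arr(off, len); got_mz <- TRUE }
      else { il[[i]] <- read_arr(off, len); got_i <- TRUE }
    }
    if (!got_mz || !got_i)
      stop("spectrum ", i, " lacks an m/z or intensity array")
    if (length(mzl[[i]]) != length(il[[i]]))
      stop("spectrum ", i, ": m/z and intensity array lengths differ")
  }
  coords <- data.frame(ix = ix, iy = iy)
  if (mode_cont) {
    msi_dataset(coords, spacing_um, mzl[[1]], do.call(rbind, il))
  } else {
    msi_dataset(coords, spacing_um, mzl, il)
  }
}
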