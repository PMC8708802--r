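#' MSI dataset container
#'
#' A mass spectrometry imaging dataset: a rectangular pixel grid of
#' centroided peak lists plus acquisition metadata. Pixels are 0-based,
#' row-major, x the fastest axis. Kept deliberately tabular: `peaks` is one
#' long tibble so the whole dplyr grammar applies directly.
#'
#' @param peaks Tibble with columns `x`, `y` (integer pixel coordinates),
#'   `mz`, `intensity`.
#' @param coords Tibble of all scanned pixels (`x`, `y`) — includes pixels
#'   whose spectrum is empty. Defaults to the pixels present in `peaks`.
#' @param polarity One of `"negative"`, `"positive"`, `"adducted_positive"`.
#' @param mz_window Numeric length-2 acquisition window (Da).
#' @param pixel_pitch Raster step size in micrometres.
#' @return An `msi_dataset` object.
#' @export
msi_dataset <- function(peaks, coords = NULL,
                        polarity = c("negative", "positive", "adducted_positive"),
                        mz_window = c(150, 1800), pixel_pitch = 150) {
  polarity <- match.arg(polarity)
  peaks <- as_tibble(peaks)
  stopifnot(all(c("x", "y", "mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) && any(peaks$intensity < 0)) abort("negative intensities")
  if (nrow(peaks) &&
      (any(peaks$mz < mz_window[1] - 1e-9) || any(peaks$mz > mz_window[2] + 1e-9))) {
    abort("peak m/z outside the declared mz_window")
  }
  if (is.null(coords)) coords <- dplyr::distinct(peaks[, c("x", "y")])
  coords <- dplyr::arrange(as_tibble(coords), .data$y, .data$x)
  structure(list(peaks = peaks, coords = coords, polarity = polarity,
                 mz_window = as.numeric(mz_window),
                 pixel_pitch = as.numeric(pixel_pitch)),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %s mode, %d pixels, %d peaks, m/z %g-%g, pitch %g um\n",
              x$polarity, nrow(x$coords), nrow(x$peaks),
              x$mz_window[1], x$mz_window[2], x$pixel_pitch))
  invisible(x)
}

format_uuid <- function(bytes) {
  stopifnot(length(bytes) == 16)
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0F), 0x40) # version 4
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3F), 0x80) # RFC 4122 variant
  hx <- sprintf("%02x", bytes)
  paste0(paste0(hx[1:4], collapse = ""), "-", paste0(hx[5:6], collapse = ""),
         "-", paste0(hx[7:8], collapse = ""), "-", paste0(hx[9:10], collapse = ""),
         "-", paste0(hx[11:16], collapse = ""))
}

#' Write an MSI dataset to imzML
#'
#' Writes processed-mode imzML 1.1: an XML index file plus the companion
#' binary `.ibd` holding per-spectrum m/z and intensity arrays as 64-bit
#' floats (so the round trip is lossless at full double precision). The ibd
#' UUID is drawn from R's random number generator, which makes seeded runs
#' byte-identical.
#'
#' @param dataset An `msi_dataset`.
#' @param path Output path ending in `.imzML`; the `.ibd` is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "msi_dataset"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uuid_bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
  uuid <- format_uuid(uuid_bytes)

  px <- dataset$coords
  key <- paste(dataset$peaks$x, dataset$peaks$y)
  spectra <- split(dataset$peaks[, c("mz", "intensity")],
                   factor(key, levels = paste(px$x, px$y)))

  con <- file(ibd_path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(uuid_bytes), con)
  offset <- 16
  n <- length(spectra)
  mz_off <- int_off <- lens <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    sp <- sp[order(sp$mz), , drop = FALSE]
    lens[i] <- nrow(sp)
    mz_off[i] <- offset
    writeBin(as.numeric(sp$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * lens[i]
    int_off[i] <- offset
    writeBin(as.numeric(sp$intensity), con, size = 8, endian = "little")
    offset <- offset + 8 * lens[i]
  }

  pol_cv <- if (dataset$polarity == "negative") {
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  }
  spec_xml <- vapply(seq_len(n), function(i) {
    paste0(
      '<spectrum index="', i - 1L, '" id="spectrum=', i, '" defaultArrayLength="', lens[i], '">',
      pol_cv,
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="', px$x[i] + 1L, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="', px$y[i] + 1L, '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', lens[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * lens[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', sprintf("%.0f", mz_off[i]), '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', lens[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * lens[i], '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', sprintf("%.0f", int_off[i]), '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{', uuid, '}"/>',
    '<userParam name="msipair:polarity" value="', dataset$polarity, '"/>',
    '<userParam name="msipair:mz_window_low" value="', sprintf("%.6f", dataset$mz_window[1]), '"/>',
    '<userParam name="msipair:mz_window_high" value="', sprintf("%.6f", dataset$mz_window[2]), '"/>',
    '<userParam name="msipair:pixel_pitch_um" value="', sprintf("%.6f", dataset$pixel_pitch), '"/>',
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', max(px$x) + 1L, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', max(px$y) + 1L, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="',
    sprintf("%.0f", dataset$pixel_pitch), '"/>',
    '</scanSettings></scanSettingsList>\n',
    '<softwareList count="1"><software id="msipair" version="0.1.0"/></softwareList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1" softwareRef="msipair">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">\n<spectrumList count="', n, '" defaultDataProcessingRef="dp1">\n',
    paste0(spec_xml, collapse = "\n"),
    '\n</spectrumList>\n</run>\n</mzML>\n')
  writeLines(xml, path, sep = "", useBytes = TRUE)
  invisible(path)
}

cv_value <- function(node, accession) {
  v <- xml2::xml_attr(
    xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", accession)),
    "value")
  v
}

#' Read an imzML dataset
#'
#' Reads processed- or continuous-mode imzML 1.1 with its companion `.ibd`.
#' Both 64-bit and 32-bit float arrays are understood; coordinates are
#' converted to the package's 0-based convention. Missing coordinates inside
#' the scanned bounding box are filled in as empty pixels with a warning.
#'
#' @param path Path to the `.imzML` file.
#' @param polarity,mz_window,pixel_pitch Overrides for metadata missing from
#'   the file; files written by [write_imzml()] round-trip these
#'   automatically.
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path, polarity = NULL, mz_window = NULL,
                       pixel_pitch = NULL) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(path)) abort(paste0("no such imzML file: ", path))
  if (!file.exists(ibd_path)) abort(paste0("missing companion ibd file: ", ibd_path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_first(doc, ".//fileDescription/fileContent")
  uparam <- function(name) {
    xml2::xml_attr(xml2::xml_find_first(
      fc, sprintf(".//userParam[@name='msipair:%s']", name)), "value")
  }
  if (is.null(polarity)) {
    polarity <- uparam("polarity")
    if (is.na(polarity)) polarity <- "positive"
  }
  if (is.null(mz_window)) {
    lo <- suppressWarnings(as.numeric(uparam("mz_window_low")))
    hi <- suppressWarnings(as.numeric(uparam("mz_window_high")))
    mz_window <- if (is.na(lo) || is.na(hi)) NULL else c(lo, hi)
  }
  if (is.null(pixel_pitch)) {
    pixel_pitch <- suppressWarnings(as.numeric(uparam("pixel_pitch_um")))
    if (is.na(pixel_pitch)) pixel_pitch <- 150
  }

  # data type per referenceable param group
  groups <- xml2::xml_find_all(doc, ".//referenceableParamGroup")
  sizes <- setNames(rep(8, length(groups)), xml2::xml_attr(groups, "id"))
  for (g in groups) {
    id <- xml2::xml_attr(g, "id")
    if (!is.na(xml2::xml_attr(
      xml2::xml_find_first(g, ".//cvParam[@accession='MS:1000521']"), "name"))) {
      sizes[id] <- 4
    }
  }

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  con <- file(ibd_path, open = "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(arr) {
    ref <- xml2::xml_attr(
      xml2::xml_find_first(arr, ".//referenceableParamGroupRef"), "ref")
    size <- if (!is.na(ref) && ref %in% names(sizes)) sizes[[ref]] else 8
    len <- as.numeric(cv_value(arr, "IMS:1000103"))
    off <- as.numeric(cv_value(arr, "IMS:1000102"))
    is_mz <- !is.na(ref) && grepl("mz", ref, ignore.case = TRUE)
    if (is.na(is_mz) || is.na(ref)) {
      is_mz <- !is.na(xml2::xml_attr(
        xml2::xml_find_first(arr, ".//cvParam[@accession='MS:1000514']"), "name"))
    }
    if (is.na(len) || len == 0) return(list(values = numeric(0), is_mz = is_mz))
    seek(con, where = off, origin = "start")
    list(values = readBin(con, "double", n = len, size = size, endian = "little"),
         is_mz = is_mz)
  }
  rows <- vector("list", length(spectra))
  coords <- matrix(NA_integer_, nrow = length(spectra), ncol = 2)
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    x <- as.integer(cv_value(sp, "IMS:1000050")) - 1L
    y <- as.integer(cv_value(sp, "IMS:1000051")) - 1L
    coords[i, ] <- c(x, y)
    arrs <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mzv <- intv <- numeric(0)
    for (arr in arrs) {
      a <- read_array(arr)
      if (a$is_mz) mzv <- a$values else intv <- a$values
    }
    if (length(mzv)) {
      rows[[i]] <- tibble(x = x, y = y, mz = mzv, intensity = intv)
    }
  }
  peaks <- dplyr::bind_rows(rows)
  coord_tb <- tibble(x = coords[, 1], y = coords[, 2])
  full <- tidyr::expand_grid(y = min(coord_tb$y):max(coord_tb$y),
                             x = min(coord_tb$x):max(coord_tb$x))[, c("x", "y")]
  missing <- dplyr::anti_join(full, coord_tb, by = c("x", "y"))
  if (nrow(missing) > 0 && nrow(missing) < nrow(full) / 2) {
    warn(sprintf("%d coordinate gap(s) inside the scanned grid filled as empty pixels",
                 nrow(missing)))
    coord_tb <- dplyr::bind_rows(coord_tb, missing)
  }
  if (is.null(mz_window)) {
    mz_window <- if (nrow(peaks)) range(peaks$mz) else c(0, Inf)
  }
  msi_dataset(peaks, coords = coord_tb, polarity = polarity,
              mz_window = mz_window, pixel_pitch = pixel_pitch)
}

#' Read a single spectrum from an mzML file
#'
#' Thin wrapper over mzR for pulling MS/MS spectra acquired as standalone
#' mzML files into the `mz`/`abundance` tibble shape used by
#' [match_msms()] and [spectral_accuracy()].
#'
#' @param path Path to an mzML file.
#' @param scan Scan number (default 1).
#' @return A tibble with `mz` and `abundance`.
#' @export
read_mzml_spectrum <- function(path, scan = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    abort("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  pk <- mzR::peaks(handle, scan)
  tibble(mz = pk[, 1], abundance = pk[, 2])
}
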