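#' Construct a mass spectrum object
#'
#' A `seldi_spectrum` holds one SELDI-TOF mass spectrum: a strictly
#' increasing m/z axis (Da, singly charged assumed) with one nonnegative
#' intensity per point, plus the sample metadata the pipeline needs
#' (sample id, nodal-status label, protein-chip id for reproducibility
#' grouping).
#'
#' @param mz Numeric vector of mass-to-charge values in Da, strictly
#'   increasing.
#' @param intensity Numeric vector of intensities, same length as `mz`,
#'   finite.
#' @param sample_id Character scalar identifying the sample.
#' @param label One of `"node_positive"`, `"node_negative"`,
#'   `"unlabelled"`.
#' @param chip_id Character scalar naming the protein-chip array the
#'   spectrum was acquired on (used for intra- vs inter-assay QC).
#' @param meta Optional named list of extra metadata (e.g. TIC scale
#'   factors recorded by [normalize_tic()]).
#' @return An object of class `seldi_spectrum`.
#' @export
seldi_spectrum <- function(mz, intensity, sample_id = "sample",
                           label = "unlabelled", chip_id = "chip01",
                           meta = list()) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length")
  if (length(mz) && any(diff(mz) <= 0))
    stop("mz must be strictly increasing")
  if (length(intensity) && !all(is.finite(intensity)))
    stop("intensities must be finite")
  label <- match.arg(label, c("node_positive", "node_negative", "unlabelled"))
  structure(
    list(sample_id = as.character(sample_id), mz = mz, intensity = intensity,
         label = label, chip_id = as.character(chip_id), meta = meta),
    class = "seldi_spectrum")
}

#' @export
print.seldi_spectrum <- function(x, ...) {
  cat(sprintf("<seldi_spectrum> %s [%s, %s]: %d points, m/z %.1f-%.1f\n",
              x$sample_id, x$label, x$chip_id, length(x$mz),
              if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' Construct a cohort of spectra
#'
#' @param spectra List of [seldi_spectrum()] objects with unique sample
#'   ids.
#' @param role One of `"training"`, `"test"`, `"qc_replicates"`.
#' @return An object of class `seldi_cohort`.
#' @export
seldi_cohort <- function(spectra, role = c("training", "test", "qc_replicates")) {
  role <- match.arg(role)
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(spectra = spectra, role = role), class = "seldi_cohort")
}

#' @export
print.seldi_cohort <- function(x, ...) {
  labs <- vapply(x$spectra, function(s) s$label, character(1))
  cat(sprintf("<seldi_cohort> role=%s, n=%d (%d node_positive, %d node_negative)\n",
              x$role, length(x$spectra), sum(labs == "node_positive"),
              sum(labs == "node_negative")))
  invisible(x)
}

#' @export
length.seldi_cohort <- function(x) length(x$spectra)

cohort_labels <- function(cohort) {
  vapply(cohort$spectra, function(s) s$label, character(1))
}

#' Read a single spectrum from disk
#'
#' Native format is a two-column delimited text file (header
#' `mz,intensity`); both comma- and tab-delimited files are accepted.
#' Minimal read-only mzML support (uncompressed or zlib 32/64-bit float
#' binary arrays, single-spectrum runs) is provided for
#' interoperability.
#'
#' @param path Path to the spectrum file.
#' @param format `"csv"` or `"mzml"`; `"auto"` guesses from the file
#'   extension.
#' @param sample_id,label,chip_id Metadata, typically supplied by the
#'   cohort manifest.
#' @return A [seldi_spectrum()]. Rows are sorted by ascending m/z.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "mzml"),
                          sample_id = NULL, label = "unlabelled",
                          chip_id = "chip01") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "csv"
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "mzml") {
    arr <- read_mzml_arrays(path)
    ord <- order(arr$mz)
    return(seldi_spectrum(arr$mz[ord], arr$intensity[ord], sample_id = sample_id,
                          label = label, chip_id = chip_id))
  }
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = "auto", data.table = FALSE),
    error = function(e) stop("malformed spectrum file ", path, ": ",
                             conditionMessage(e)))
  if (ncol(dt) < 2L)
    stop("spectrum file ", path, " must have two columns (mz, intensity)")
  mz <- suppressWarnings(as.numeric(dt[[1]]))
  it <- suppressWarnings(as.numeric(dt[[2]]))
  bad <- which(!is.finite(mz) | !is.finite(it))
  if (length(bad))
    stop("malformed row ", bad[1] + 1L, " in ", path,
         " (non-numeric mz or intensity)")
  ord <- order(mz)
  mz <- mz[ord]; it <- it[ord]
  if (anyDuplicated(mz))
    stop("duplicate m/z value ", mz[which(duplicated(mz))[1]], " in ", path)
  seldi_spectrum(mz, it, sample_id = sample_id, label = label, chip_id = chip_id)
}

#' Write a spectrum as comma-delimited text
#'
#' @param s A [seldi_spectrum()].
#' @param path Output path; always comma-delimited with header
#'   `mz,intensity`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "seldi_spectrum"))
  data.table::fwrite(data.table::data.table(mz = s$mz, intensity = s$intensity),
                     path)
  invisible(path)
}

# Minimal mzML binary-array reader (read-only; enough for plain
# single-run files with uncompressed or zlib-compressed little-endian
# 32/64-bit float arrays).
read_mzml_arrays <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrumList/spectrum")
  if (inherits(spec, "xml_missing"))
    stop("no <spectrum> element found in mzML file ", path)
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  out <- list()
  for (a in arrays) {
    acc <- xml2::xml_attr(xml2::xml_find_all(a, ".//cvParam"), "accession")
    kind <- if ("MS:1000514" %in% acc) "mz"
            else if ("MS:1000515" %in% acc) "intensity" else next
    size <- if ("MS:1000521" %in% acc) 4L else 8L
    raw <- jsonlite::base64_dec(xml2::xml_text(xml2::xml_find_first(a, ".//binary")))
    if ("MS:1000574" %in% acc)  # zlib
      raw <- memDecompress(raw, type = "gzip")
    out[[kind]] <- readBin(raw, what = "double", n = length(raw) %/% size,
                           size = size, endian = "little")
  }
  if (is.null(out$mz) || is.null(out$intensity))
    stop("mzML file ", path, " lacks m/z or intensity binary arrays")
  if (length(out$mz) != length(out$intensity))
    stop("mzML arrays of unequal length in ", path)
  out
}

#' Read a cohort manifest and its spectra
#'
#' The manifest is a delimited file with header
#' `sample_id,label,chip_id,path`; `path` is resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest file path.
#' @param read_spectra If `FALSE`, only validate the manifest and return
#'   its table (skeleton); spectra files must still exist.
#' @param role Cohort role, see [seldi_cohort()].
#' @return A [seldi_cohort()] (or the manifest `data.frame` when
#'   `read_spectra = FALSE`).
#' @export
read_manifest <- function(path, read_spectra = TRUE,
                          role = c("training", "test", "qc_replicates")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- data.table::fread(path, header = TRUE, sep = "auto", data.table = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "label", "chip_id", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(man$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(man$sample_id[duplicated(man$sample_id)]), collapse = ", "))
  ok <- man$label %in% c("node_positive", "node_negative", "unlabelled")
  if (!all(ok))
    stop("unknown label '", man$label[!ok][1], "' in manifest (allowed: ",
         "node_positive, node_negative, unlabelled)")
  files <- file.path(dirname(path), man$path)
  missing <- !file.exists(files)
  if (any(missing))
    stop("spectrum file referenced by manifest does not exist: ",
         files[missing][1])
  if (!read_spectra) return(man)
  spectra <- lapply(seq_len(nrow(man)), function(i)
    read_spectrum(files[i], sample_id = man$sample_id[i],
                  label = man$label[i], chip_id = man$chip_id[i]))
  seldi_cohort(spectra, role = role)
}

#' Write a cohort to disk (spectra plus manifest)
#'
#' @param cohort A [seldi_cohort()].
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name within `dir`.
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest = "manifest.csv") {
  stopifnot(inherits(cohort, "seldi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$spectra, function(s) {
    fn <- paste0(s$sample_id, ".csv")
    write_spectrum(s, file.path(dir, fn))
    data.frame(sample_id = s$sample_id, label = s$label,
               chip_id = s$chip_id, path = fn, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mpath <- file.path(dir, manifest)
  data.table::fwrite(man, mpath)
  invisible(mpath)
}
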