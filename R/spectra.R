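#' Construct a spectrum object
#'
#' A spectrum is one strain-replicate's (m/z, intensity) profile. Peaks are
#' stored sorted by ascending m/z; intensities must be finite and
#' non-negative.
#'
#' @param mz Numeric vector of m/z values (Th).
#' @param intensity Numeric vector of intensities, same length as `mz`.
#' @param spectrum_id Character scalar identifying the spectrum.
#' @param gene_id Gene knocked out in this strain, or `"UNKNOWN"`.
#' @param replicate Replicate index (1-based).
#' @return An object of class `mass_spectrum`: a tibble with columns `mz` and
#'   `intensity` and attributes `spectrum_id`, `gene_id`, `replicate`.
#' @export
mass_spectrum <- function(mz, intensity, spectrum_id = "spectrum",
                          gene_id = "UNKNOWN", replicate = 1L) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("`mz` and `intensity` must have equal length", call. = FALSE)
  }
  if (length(mz) == 0L) stop("empty spectrum", call. = FALSE)
  if (anyNA(mz) || anyNA(intensity) || any(!is.finite(intensity))) {
    stop("non-finite m/z or intensity values", call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative intensities", call. = FALSE)
  if (is.unsorted(mz, strictly = FALSE)) {
    warning("m/z values out of order; sorting ascending", call. = FALSE)
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
  }
  out <- tibble::tibble(mz = mz, intensity = intensity)
  attr(out, "spectrum_id") <- as.character(spectrum_id)
  attr(out, "gene_id") <- as.character(gene_id)
  attr(out, "replicate") <- as.integer(replicate)
  class(out) <- c("mass_spectrum", class(out))
  out
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mass_spectrum> %s (gene %s, replicate %d): %d peaks, m/z %.1f-%.1f\n",
    attr(x, "spectrum_id"), attr(x, "gene_id"), attr(x, "replicate"),
    nrow(x), min(x$mz), max(x$mz)
  ))
  invisible(x)
}

#' Read one spectrum from disk
#'
#' Supports two-column TSV peak lists (m/z, intensity; `#` comment lines) and
#' mzML (first scan of the file, via the mzR library).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"mzml"`; the default guesses from the file
#'   extension.
#' @param spectrum_id Identifier to attach; defaults to the file name without
#'   extension.
#' @inheritParams mass_spectrum
#' @return A [mass_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "mzml"),
                          spectrum_id = NULL, gene_id = "UNKNOWN",
                          replicate = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  }
  if (is.null(spectrum_id)) {
    spectrum_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "tsv") {
    tab <- tryCatch(
      utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                        colClasses = "numeric", col.names = c("mz", "intensity")),
      error = function(e) {
        stop("unparseable TSV peak list '", path, "': ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (nrow(tab) == 0L) stop("empty spectrum in ", path, call. = FALSE)
    mass_spectrum(tab$mz, tab$intensity, spectrum_id, gene_id, replicate)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("mzML input requires the mzR package", call. = FALSE)
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    if (nrow(mzR::header(handle)) < 1L) stop("no scans in ", path, call. = FALSE)
    pk <- mzR::peaks(handle, 1L)
    if (nrow(pk) == 0L) stop("empty spectrum in ", path, call. = FALSE)
    mass_spectrum(pk[, 1], pk[, 2], spectrum_id, gene_id, replicate)
  }
}

#' Write one spectrum to disk
#'
#' TSV output is a two-column (m/z, intensity) peak list with a `#` header
#' line; mzML output is a single-scan file written via mzR. Both round-trip
#' through [read_spectrum()].
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @param format `"tsv"` or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("tsv", "mzml")) {
  format <- match.arg(format)
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spectrum_id=%s gene_id=%s replicate=%d",
                       attr(spectrum, "spectrum_id"),
                       attr(spectrum, "gene_id"),
                       attr(spectrum, "replicate")), con)
    utils::write.table(as.data.frame(spectrum)[, c("mz", "intensity")], con,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("mzML output requires the mzR package", call. = FALSE)
    }
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
      peaksCount = nrow(spectrum), totIonCurrent = sum(spectrum$intensity),
      retentionTime = 0, basePeakMZ = spectrum$mz[which.max(spectrum$intensity)],
      basePeakIntensity = max(spectrum$intensity), collisionEnergy = 0,
      ionisationEnergy = 0, lowMZ = min(spectrum$mz), highMZ = max(spectrum$mz),
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
      centroided = TRUE, ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
      scanWindowUpperLimit = NA_real_
    )
    mzR::writeMSData(list(cbind(spectrum$mz, spectrum$intensity)), path,
                     header = hdr, outformat = "mzml")
  }
  invisible(path)
}
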