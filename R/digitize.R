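#' Digitization settings
#'
#' A spectrum is binarized by cutting the mass window into equal-width
#' intervals and setting a bit to 1 when the maximum standard score of the
#' peaks in that interval reaches `z_threshold`. Defaults give the canonical
#' 1,700-bit fingerprint: window m/z 3,000-20,000, 10 m/z bins, threshold 52.
#'
#' The standard score can be computed against two references. `"noise_floor"`
#' (the default) standardizes against the mean and standard deviation of the
#' low-intensity samples (those at or below the `noise_quantile` (default 0.5) intensity
#' quantile), i.e. the spectrum's own noise baseline; this behaves like the
#' classic all-sample z-score on dense profile spectra, where baseline samples
#' dominate, but remains meaningful on sparse centroided peak lists, where an
#' all-sample z-score is capped at sqrt(n - 1) and could never reach 52.
#' `"global"` uses all intensity samples (see [standard_scores()]).
#'
#' @param window_low,window_high Mass window bounds in Th.
#' @param bin_width Interval width in Th; `(window_high - window_low)` must be
#'   divisible by it.
#' @param z_threshold Standard-score cutoff for calling a bit 1.
#' @param score_reference `"noise_floor"` or `"global"`.
#' @param noise_quantile Intensity quantile bounding the noise-floor reference
#'   sample.
#' @return A `digitization_config` list.
#' @export
digitization_config <- function(window_low = 3000, window_high = 20000,
                                bin_width = 10, z_threshold = 52,
                                score_reference = c("noise_floor", "global"),
                                noise_quantile = 0.5) {
  score_reference <- match.arg(score_reference)
  stopifnot(window_high > window_low, bin_width > 0, z_threshold > 0,
            noise_quantile > 0, noise_quantile <= 1)
  n_bins <- (window_high - window_low) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("(window_high - window_low) must be divisible by bin_width",
         call. = FALSE)
  }
  structure(
    list(window_low = window_low, window_high = window_high,
         bin_width = bin_width, z_threshold = z_threshold,
         score_reference = score_reference, noise_quantile = noise_quantile,
         n_bins = as.integer(round(n_bins))),
    class = "digitization_config"
  )
}

#' Number of fingerprint bins implied by a digitization config
#' @param cfg A [digitization_config()].
#' @return Integer bin count; 1,700 under defaults.
#' @export
n_bins <- function(cfg = digitization_config()) cfg$n_bins

#' Standard scores of peak intensities
#'
#' Computes `(intensity - mean) / sd` for every intensity sample of a
#' spectrum. With `reference = "global"` mean and sd are taken over all
#' samples (population sd, denominator n). With `reference = "noise_floor"`
#' they are taken over the samples at or below the `noise_quantile` (default 0.5) intensity
#' quantile, so that tall peaks are scored in units of baseline noise.
#'
#' @param spectrum A [mass_spectrum()] or numeric vector of intensities.
#' @param reference Scoring population; see [digitization_config()].
#' @param noise_quantile Quantile bounding the noise-floor sample.
#' @return Numeric vector of scores, one per intensity sample.
#' @export
standard_scores <- function(spectrum, reference = c("global", "noise_floor"),
                            noise_quantile = 0.5) {
  reference <- match.arg(reference)
  intensity <- if (inherits(spectrum, "mass_spectrum")) spectrum$intensity
               else as.numeric(spectrum)
  n <- length(intensity)
  if (n == 0L) return(numeric(0))
  ref <- if (reference == "global") {
    intensity
  } else {
    flo <- intensity[intensity <= stats::quantile(intensity, noise_quantile)]
    if (length(flo) < 2L) intensity else flo
  }
  mu <- mean(ref)
  sigma <- sqrt(mean((ref - mu)^2)) # population sd
  if (sigma == 0) {
    warning("zero intensity spread; all standard scores set to 0",
            call. = FALSE)
    return(rep(0, n))
  }
  (intensity - mu) / sigma
}

#' Digitize one spectrum into a binary fingerprint vector
#'
#' Bin `i` (0-based) covers the half-open interval
#' `[window_low + i * bin_width, window_low + (i + 1) * bin_width)`. Bit `i`
#' is 1 iff the maximum standard score among the peaks falling in bin `i` is
#' at least `z_threshold`. Peaks outside the window are ignored; empty bins
#' are 0.
#'
#' @param spectrum A [mass_spectrum()].
#' @param cfg A [digitization_config()].
#' @return Integer 0/1 vector of length `n_bins(cfg)` with names
#'   `bin_0000`...; attribute `spectrum_id` carries the identifier.
#' @export
digitize <- function(spectrum, cfg = digitization_config()) {
  stopifnot(inherits(spectrum, "mass_spectrum"),
            inherits(cfg, "digitization_config"))
  z <- standard_scores(spectrum, reference = cfg$score_reference,
                       noise_quantile = cfg$noise_quantile)
  keep <- spectrum$mz >= cfg$window_low & spectrum$mz < cfg$window_high
  idx <- floor((spectrum$mz[keep] - cfg$window_low) / cfg$bin_width)
  bits <- integer(cfg$n_bins)
  hit <- idx[z[keep] >= cfg$z_threshold]
  bits[unique(hit) + 1L] <- 1L
  names(bits) <- sprintf("bin_%04d", seq_len(cfg$n_bins) - 1L)
  attr(bits, "spectrum_id") <- attr(spectrum, "spectrum_id")
  bits
}

#' Bundle binary fingerprints with their strain table
#'
#' A `fingerprint_set` couples a 0/1 matrix (rows = spectra, columns =
#' fingerprint bins) with a strain table (`spectrum_id`, `gene_id`,
#' `replicate`). It is the universal feature object consumed by every model
#' in the package.
#'
#' @param bits Integer 0/1 matrix, rows named by spectrum id.
#' @param meta Tibble with columns `spectrum_id`, `gene_id`, `replicate`, in
#'   row order matching `bits`.
#' @param cfg The [digitization_config()] used (stored for provenance).
#' @return A `fingerprint_set`.
#' @export
fingerprint_set <- function(bits, meta, cfg = digitization_config()) {
  bits <- as.matrix(bits)
  storage.mode(bits) <- "integer"
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("spectrum_id", "gene_id", "replicate") %in% names(meta)),
            nrow(bits) == nrow(meta))
  if (anyDuplicated(meta$spectrum_id)) {
    stop("duplicate spectrum_ids: ",
         paste(unique(meta$spectrum_id[duplicated(meta$spectrum_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0/1", call. = FALSE)
  rownames(bits) <- meta$spectrum_id
  if (is.null(colnames(bits))) {
    colnames(bits) <- sprintf("bin_%04d", seq_len(ncol(bits)) - 1L)
  }
  structure(list(bits = bits, meta = meta, config = cfg),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_set> %d spectra x %d bins; %d genes; %d bits on (%.2f%%)\n",
    nrow(x$bits), ncol(x$bits), length(unique(x$meta$gene_id)),
    sum(x$bits), 100 * mean(x$bits)
  ))
  invisible(x)
}

#' @export
dim.fingerprint_set <- function(x) dim(x$bits)

#' @method as_tibble fingerprint_set
#' @export
as_tibble.fingerprint_set <- function(x, ...) {
  dplyr::bind_cols(x$meta, tibble::as_tibble(x$bits))
}

#' Coerce a wide fingerprint table back to a fingerprint_set
#'
#' Inverse of `as_tibble()` on a `fingerprint_set`: expects the strain-table
#' columns followed by `bin_*` columns.
#'
#' @param df Data frame with `spectrum_id`, `gene_id`, `replicate` and
#'   `bin_*` columns.
#' @param cfg Digitization config to attach.
#' @return A [fingerprint_set()].
#' @export
as_fingerprint_set <- function(df, cfg = digitization_config()) {
  if (inherits(df, "fingerprint_set")) return(df)
  df <- tibble::as_tibble(df)
  bin_cols <- grep("^bin_", names(df), value = TRUE)
  if (length(bin_cols) == 0L) stop("no bin_* columns found", call. = FALSE)
  fingerprint_set(as.matrix(df[bin_cols]),
                  df[c("spectrum_id", "gene_id", "replicate")], cfg)
}

#' Digitize a list of spectra into a fingerprint set
#'
#' @param spectra List of [mass_spectrum()] objects.
#' @param cfg A [digitization_config()].
#' @param min_on_bins Per-spectrum QC floor: spectra with fewer super-threshold
#'   bins are flagged (`qc_pass = FALSE` in the strain table) but kept.
#' @return A [fingerprint_set()] whose strain table carries `qc_pass`.
#' @export
digitize_library <- function(spectra, cfg = digitization_config(),
                             min_on_bins = 1L) {
  stopifnot(length(spectra) > 0L)
  bits <- matrix(0L, nrow = length(spectra), ncol = cfg$n_bins,
                 dimnames = list(NULL, sprintf("bin_%04d",
                                               seq_len(cfg$n_bins) - 1L)))
  meta <- tibble::tibble(
    spectrum_id = vapply(spectra, attr, "", "spectrum_id"),
    gene_id = vapply(spectra, attr, "", "gene_id"),
    replicate = vapply(spectra, function(s) as.integer(attr(s, "replicate")),
                       1L)
  )
  for (i in seq_along(spectra)) bits[i, ] <- digitize(spectra[[i]], cfg)
  meta$qc_pass <- rowSums(bits) >= min_on_bins
  fingerprint_set(bits, meta, cfg)
}

#' Group fingerprint vectors by gene, preserving replicates
#'
#' Vectors are never averaged or merged: grouping is lossless, so downstream
#' duplicate-consistency rules can test each replicate individually.
#'
#' @param fp A [fingerprint_set()].
#' @param strain_table Optional tibble (`spectrum_id`, `gene_id`, `replicate`)
#'   overriding the set's own strain table. Every `spectrum_id` in `fp` must
#'   appear in it.
#' @return Named list (one element per gene) of row-index vectors into
#'   `fp$bits`, ordered by replicate.
#' @export
collapse_replicates <- function(fp, strain_table = NULL) {
  stopifnot(inherits(fp, "fingerprint_set"))
  tab <- if (is.null(strain_table)) fp$meta else tibble::as_tibble(strain_table)
  orphans <- setdiff(fp$meta$spectrum_id, tab$spectrum_id)
  if (length(orphans) > 0L) {
    stop("spectrum_ids missing from strain table: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  tab <- tab[match(fp$meta$spectrum_id, tab$spectrum_id), ]
  idx <- seq_len(nrow(fp$bits))
  split(idx[order(tab$replicate)],
        factor(tab$gene_id[order(tab$replicate)],
               levels = unique(tab$gene_id)))[unique(tab$gene_id)]
}

#' Write a fingerprint set as TSV
#'
#' Two bit-exact, round-trippable dialects: `"wide"` (strain-table columns
#' then `bin_0000..`) and `"bits"` (compact: `spectrum_id`, `gene_id`,
#' `replicate`, then the fingerprint as a 0/1 character string).
#'
#' @param fp A [fingerprint_set()].
#' @param path Output path.
#' @param dialect `"wide"` or `"bits"`.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path, dialect = c("wide", "bits")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(fp, "fingerprint_set"))
  if (dialect == "wide") {
    readr::write_tsv(as_tibble.fingerprint_set(fp), path)
  } else {
    readr::write_tsv(tibble::tibble(
      spectrum_id = fp$meta$spectrum_id,
      gene_id = fp$meta$gene_id,
      replicate = fp$meta$replicate,
      bits = apply(fp$bits, 1L, paste0, collapse = "")
    ), path)
  }
  invisible(path)
}

#' Read a fingerprint TSV written by [write_fingerprints()]
#'
#' @param path Input path.
#' @param cfg Digitization config to attach.
#' @return A [fingerprint_set()].
#' @export
read_fingerprints <- function(path, cfg = digitization_config()) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("bits" %in% names(df) && is.character(df$bits)) {
    bits <- do.call(rbind, lapply(strsplit(df$bits, ""), as.integer))
    fingerprint_set(bits, df[c("spectrum_id", "gene_id", "replicate")], cfg)
  } else {
    as_fingerprint_set(df, cfg)
  }
}
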