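#' Read a wide spectral table
#'
#' Reads a wavelength-by-sample matrix: first column is the wavelength in
#' nm (conventionally headed `wavelength_nm`), every further column one
#' sample, with the header row carrying sample ids. The delimiter is
#' auto-detected between comma and tab; the decimal mark is `.`.
#'
#' @param path Path to a CSV or TSV file.
#' @param kind Spectrum kind passed through to [spectrum()].
#' @param meta Optional named list of per-sample metadata lists, keyed by
#'   sample id (as produced by [read_sample_metadata()]); matching entries
#'   are attached to each spectrum's `meta`.
#' @return A named list of [spectrum] objects, one per sample column.
#' @seealso [write_spectral_table()]
#' @export
read_spectral_table <- function(path, kind = "absorbance", meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (ncol(raw) < 2L) stop("spectral table needs a wavelength column and at least one sample")
  num <- as.data.frame(lapply(raw, function(col) suppressWarnings(as.numeric(col))))
  bad <- which(is.na(as.matrix(num)) , arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1, 1], colnames(raw)[bad[1, 2]]))
  }
  wl <- num[[1]]
  if (any(diff(wl) <= 0))
    stop("wavelength column is not strictly increasing (duplicate or unsorted values)")
  ids <- colnames(raw)[-1]
  out <- lapply(seq_along(ids), function(i) {
    m <- list(sample_id = ids[i])
    if (!is.null(meta) && ids[i] %in% names(meta))
      m <- utils::modifyList(m, as.list(meta[[ids[i]]]))
    spectrum(wl, num[[i + 1L]], kind = kind, meta = m)
  })
  names(out) <- ids
  out
}

#' Write spectra as a wide spectral table
#'
#' Inverse of [read_spectral_table()]: all spectra must share one
#' wavelength grid (resampled if not); writes one wavelength column plus
#' one column per spectrum.
#'
#' @param spectra List of [spectrum] objects (names become sample ids).
#' @param path Output path.
#' @param sep Field delimiter, `","` or `"\t"`.
#' @param digits Significant digits written. Default 12, enough for a
#'   round trip below 1e-9 AU.
#' @return `path`, invisibly.
#' @export
write_spectral_table <- function(spectra, path, sep = ",", digits = 12) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  spectra <- resample_to_common_grid(spectra)
  ids <- names(spectra)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(seq_along(spectra), function(i) {
      id <- spectra[[i]]$meta$sample_id
      if (is.null(id)) paste0("s", i) else as.character(id)
    }, character(1))
  tab <- data.frame(wavelength_nm = spectra[[1]]$wavelength,
                    check.names = FALSE)
  for (i in seq_along(spectra)) tab[[ids[i]]] <- spectra[[i]]$value
  fmt <- as.data.frame(lapply(tab, function(x) formatC(x, digits = digits,
                                                       format = "g")),
                       check.names = FALSE)
  utils::write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JSON metadata sidecar
#'
#' Per-sample metadata for a spectral table:
#' `{"sample_id": {"conc_uM": ..., "pH": ..., "temp_C": ..., "time_s": ...}}`.
#'
#' @param path Path to a JSON file.
#' @return Named list of metadata lists.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Resample spectra onto a common wavelength grid
#'
#' Linear interpolation of every spectrum onto the wavelengths of the
#' first spectrum restricted to the range covered by all spectra.
#' Extrapolation is never performed; disjoint ranges are an error.
#' Idempotent when the grids already agree.
#'
#' @param spectra List of [spectrum] objects with overlapping ranges.
#' @return List of [spectrum] objects sharing one grid.
#' @export
resample_to_common_grid <- function(spectra) {
  if (is_spectrum(spectra)) return(list(spectra))
  stopifnot(length(spectra) >= 1L)
  lo <- max(vapply(spectra, function(s) min(s$wavelength), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$wavelength), numeric(1)))
  if (lo >= hi) stop("spectra have disjoint wavelength ranges")
  grid <- spectra[[1]]$wavelength
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) stop("common wavelength range contains fewer than 2 grid points")
  lapply(spectra, function(s) {
    v <- if (length(s$wavelength) == length(grid) &&
             all(s$wavelength == grid)) s$value
         else stats::approx(s$wavelength, s$value, xout = grid,
                            method = "linear", rule = 1)$y
    spectrum(grid, v, kind = s$kind, meta = s$meta)
  })
}
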