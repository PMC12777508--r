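#' Read a centroided peak list
#'
#' CSV files need columns `mz,intensity`. Files ending in `.mzML` are read
#' through Bioconductor mzR (centroided spectra; all scans are summed)
#' when that package is installed.
#'
#' @param path File path.
#' @return A peak-list tibble (see [as_peak_list()]).
#' @export
read_peak_list <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      abort("reading mzML requires the mzR package")
    }
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- do.call(rbind, mzR::peaks(h))
    return(as_peak_list(tibble::tibble(mz = pk[, 1], intensity = pk[, 2])))
  }
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df))) {
    abort(sprintf("%s: expected columns 'mz' and 'intensity', found: %s",
                  path, paste(names(df), collapse = ", ")))
  }
  as_peak_list(df)
}

#' Write a peak list as CSV
#'
#' @param peaks Peak-list data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.csv(as_peak_list(peaks)[, c("mz", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a CAD energy-series manifest
#'
#' The manifest is a CSV with columns `voltage` and `file`; file paths are
#' resolved relative to the manifest's directory.
#'
#' @param manifest Path to the manifest CSV.
#' @param precursor Precursor description (list with at least `n`).
#' @return An [energy_series()].
#' @export
read_energy_series <- function(manifest, precursor) {
  df <- utils::read.csv(manifest)
  if (!all(c("voltage", "file") %in% names(df))) {
    abort("manifest needs columns 'voltage' and 'file'")
  }
  df <- df[order(df$voltage), ]
  paths <- file.path(dirname(manifest), df$file)
  energy_series(df$voltage, lapply(paths, read_peak_list), precursor)
}

#' Read a UV melting trace
#'
#' CSV with columns `temperature`, `absorbance` and optionally
#' `wavelength`, `direction`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_melting_curve <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!all(c("temperature", "absorbance") %in% names(df))) {
    abort(sprintf("%s: expected columns 'temperature' and 'absorbance'", path))
  }
  df
}

#' Write a fragment table as CSV
#'
#' @param fragments Output of [enumerate_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.csv(fragments, path, row.names = FALSE)
  invisible(path)
}

#' Write a breakdown curve as CSV (wide, one column per species)
#'
#' @param curve A `breakdown_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breakdown_table <- function(curve, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(curve), names_from = "species",
                             values_from = "pct")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
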