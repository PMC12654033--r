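#' Sample metadata for a reflectance spectrum
#'
#' Lightweight record describing the sample a spectrum was acquired from.
#' `concentration` requires `conc_units` ("ng/mL" or "U/mL" in practice, but any
#' unit string is accepted). Clinical stage labels, when given, must come from
#' the standard vocabulary `IA, IIA, IIB, IIIA, IIIB, IIIC, IV`; anything else
#' is rejected rather than coerced.
#'
#' @param sample_id character scalar identifying the sample (may be `NA`).
#' @param biomarker character label, e.g. `"HER-II"` or `"CA15-3"` (may be `NA`).
#' @param concentration nonnegative number, or `NA` if unknown.
#' @param conc_units unit string; required when `concentration` is given.
#' @param stage optional clinical stage label (see Details), or `NA`.
#' @return An object of class `sample_meta` (named list).
#' @export
sample_meta <- function(sample_id = NA_character_, biomarker = NA_character_,
                        concentration = NA_real_, conc_units = NA_character_,
                        stage = NA_character_) {
  concentration <- as.numeric(concentration)
  if (!is.na(concentration)) {
    if (concentration < 0) stop("concentration must be nonnegative")
    if (is.na(conc_units) || !nzchar(conc_units))
      stop("conc_units is required when concentration is given")
  }
  if (!is.na(stage) && !stage %in% stage_levels())
    stop("unknown stage label '", stage, "'; expected one of: ",
         paste(stage_levels(), collapse = ", "))
  structure(list(sample_id = as.character(sample_id),
                 biomarker = as.character(biomarker),
                 concentration = concentration,
                 conc_units = as.character(conc_units),
                 stage = as.character(stage)),
            class = "sample_meta")
}

#' Recognized clinical stage labels
#' @return Character vector of accepted stage labels.
#' @export
stage_levels <- function() c("IA", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV")

#' Construct a reflectance spectrum
#'
#' A spectrum is a strictly increasing wavenumber grid (cm^-1) paired with
#' reflectance intensities (arbitrary units) and sample metadata. Inputs given
#' in descending order are sorted; duplicated wavenumbers are an error (they
#' usually indicate concatenated export files).
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1 (length >= 8).
#' @param intensities numeric vector of reflectance values, same length.
#' @param meta a [sample_meta()] record.
#' @return An object of class `spectrum` with fields `wavenumbers`,
#'   `intensities`, `meta`.
#' @examples
#' s <- spectrum(seq(4000, 4027, by = 3), rep(1, 10))
#' @export
spectrum <- function(wavenumbers, intensities, meta = sample_meta()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have the same length")
  if (length(wavenumbers) < 8)
    stop("a spectrum needs at least 8 points, got ", length(wavenumbers))
  if (!all(is.finite(wavenumbers)) || !all(is.finite(intensities)))
    stop("all wavenumbers and intensities must be finite")
  o <- order(wavenumbers)
  wavenumbers <- wavenumbers[o]
  intensities <- intensities[o]
  if (any(diff(wavenumbers) == 0))
    stop("duplicate wavenumbers found (is the file a concatenation of scans?)")
  if (!inherits(meta, "sample_meta")) stop("meta must be a sample_meta object")
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.1f-%.1f cm^-1", length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.na(x$meta$sample_id)) cat(sprintf(", sample %s", x$meta$sample_id))
  if (!is.na(x$meta$concentration))
    cat(sprintf(", %g %s", x$meta$concentration, x$meta$conc_units))
  cat("\n")
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$wavenumbers)

#' Collection of spectra on a common wavenumber grid
#'
#' Rows keep their insertion order; every row's intensity vector has the same
#' length as the grid. Metadata is stored as one data frame row per spectrum.
#'
#' @param grid strictly increasing wavenumber vector.
#' @param intensities numeric matrix, one row per spectrum, `length(grid)` columns.
#' @param meta data frame with columns `sample_id`, `biomarker`,
#'   `concentration`, `conc_units`, `stage` (one row per spectrum).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(grid, intensities, meta) {
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (ncol(intensities) != length(grid))
    stop("each row must have as many intensities as grid points")
  if (nrow(meta) != nrow(intensities))
    stop("meta must have one row per spectrum")
  rownames(intensities) <- NULL
  structure(list(grid = grid, intensities = intensities,
                 meta = as.data.frame(meta)),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d points, %.1f-%.1f cm^-1\n",
              nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

meta_as_row <- function(m) {
  data.frame(sample_id = m$sample_id, biomarker = m$biomarker,
             concentration = m$concentration, conc_units = m$conc_units,
             stage = m$stage, stringsAsFactors = FALSE)
}

row_as_meta <- function(df, i) {
  sample_meta(sample_id = df$sample_id[i], biomarker = df$biomarker[i],
              concentration = df$concentration[i],
              conc_units = df$conc_units[i], stage = df$stage[i])
}

#' Extract one row of a spectrum set as a spectrum
#' @param set a [spectrum_set()].
#' @param i row index.
#' @return A [spectrum()].
#' @export
set_spectrum <- function(set, i) {
  spectrum(set$grid, set$intensities[i, ], row_as_meta(set$meta, i))
}

# -- delimited-text I/O -------------------------------------------------------

split_fields <- function(line, delim) {
  if (identical(delim, "whitespace")) {
    strsplit(trimws(line), "[ \t]+")[[1]]
  } else {
    trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  }
}

parse_dialect <- function(lines, delim) {
  rows <- lapply(lines, split_fields, delim = delim)
  widths <- lengths(rows)
  if (any(widths < 2)) return(NULL)     # wrong delimiter
  first_num <- suppressWarnings(as.numeric(rows[[1]][1:2]))
  start <- if (any(is.na(first_num))) 2L else 1L   # header auto-detection
  if (length(rows) < start) return(NULL)
  wn <- numeric(0); iy <- numeric(0)
  for (k in seq(start, length(rows))) {
    v <- suppressWarnings(as.numeric(rows[[k]][1:2]))
    if (any(is.na(v)))
      stop("parse error on line ", k, ": non-numeric data row")
    wn <- c(wn, v[1]); iy <- c(iy, v[2])
  }
  list(wavenumbers = wn, intensities = iy)
}

#' Read a spectrum from two-column delimited text
#'
#' The file must have at least two numeric columns (wavenumber cm^-1,
#' intensity); a single non-numeric header line is detected and skipped. Unless
#' `delim` is given, the delimiter is auto-detected among comma, tab, semicolon
#' and whitespace — the first dialect that parses every row wins. Rows may be
#' in any order; the result is sorted by ascending wavenumber.
#'
#' @param path file path.
#' @param delim optional explicit delimiter (`","`, `"\t"`, `";"` or
#'   `"whitespace"`).
#' @param meta optional [sample_meta()] to attach.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path, delim = NULL, meta = sample_meta()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  dialects <- if (is.null(delim)) c(",", "\t", ";", "whitespace") else delim
  parsed <- NULL; last_err <- NULL
  for (d in dialects) {
    parsed <- tryCatch(parse_dialect(lines, d),
                       error = function(e) { last_err <<- e; NULL })
    if (!is.null(parsed)) break
  }
  if (is.null(parsed)) {
    if (!is.null(last_err)) stop(conditionMessage(last_err), " in ", path)
    stop("could not parse ", path, " with any known delimiter")
  }
  spectrum(parsed$wavenumbers, parsed$intensities, meta)
}

#' Write a spectrum as two-column delimited text
#'
#' Writes a header line (`wavenumber,intensity`) followed by one row per grid
#' point at full double precision (round-trips through [read_spectrum()] to
#' better than 1e-9 relative). `digits` optionally limits the significant
#' digits of the formatted values.
#'
#' @param s a [spectrum()].
#' @param path output file path.
#' @param delim field delimiter (default comma).
#' @param digits optional number of significant digits (default: full
#'   precision).
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(s, path, delim = ",", digits = NULL) {
  stopifnot(inherits(s, "spectrum"))
  fmt <- function(x) {
    if (is.null(digits)) sprintf("%.17g", x) else sprintf("%.*g", digits, x)
  }
  lines <- c(paste("wavenumber", "intensity", sep = delim),
             paste(fmt(s$wavenumbers), fmt(s$intensities), sep = delim))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Resample a spectrum onto a new wavenumber grid
#'
#' Linear interpolation; the target grid must lie within the source range (no
#' extrapolation is performed). Metadata is preserved.
#'
#' @param s a [spectrum()].
#' @param grid strictly increasing target wavenumbers.
#' @return A [spectrum()] on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("target grid must be strictly increasing")
  if (min(grid) < min(s$wavenumbers) || max(grid) > max(s$wavenumbers))
    stop("target grid extends beyond the source range; no extrapolation")
  y <- stats::approx(s$wavenumbers, s$intensities, xout = grid)$y
  spectrum(grid, y, s$meta)
}

#' Assemble spectra into a set on a common grid
#'
#' If all spectra already share one grid it is kept unchanged. Otherwise the
#' common grid spans the intersection of all wavenumber ranges (max of minima
#' to min of maxima) with spacing `step`, and every spectrum is linearly
#' resampled onto it. The output grid does not depend on the order of the
#' input spectra.
#'
#' @param spectra list of [spectrum()] objects (at least one).
#' @param grid optional explicit common grid.
#' @param step grid spacing in cm^-1 used when `grid` is absent (default 3).
#' @return A [spectrum_set()].
#' @export
assemble_set <- function(spectra, grid = NULL, step = 3) {
  if (!length(spectra)) stop("need at least one spectrum")
  lapply(spectra, function(s) stopifnot(inherits(s, "spectrum")))
  if (is.null(grid)) {
    grids <- lapply(spectra, `[[`, "wavenumbers")
    if (all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1)))) {
      grid <- grids[[1]]
    } else {
      lo <- max(vapply(grids, min, numeric(1)))
      hi <- min(vapply(grids, max, numeric(1)))
      if (lo >= hi) stop("spectra have no common wavenumber range")
      grid <- seq(lo, hi, by = step)
    }
  }
  rows <- lapply(spectra, resample_to_grid, grid = grid)
  X <- do.call(rbind, lapply(rows, `[[`, "intensities"))
  meta <- do.call(rbind, lapply(rows, function(s) meta_as_row(s$meta)))
  spectrum_set(grid, X, meta)
}

#' Default working wavenumber grid
#'
#' 4000-7000 cm^-1 at 3 cm^-1 spacing, covering the near-infrared
#' overtone/combination region used for reflectance quantification.
#'
#' @param lo,hi grid limits in cm^-1.
#' @param step spacing in cm^-1.
#' @return Numeric wavenumber vector.
#' @export
default_grid <- function(lo = 4000, hi = 7000, step = 3) seq(lo, hi, by = step)

#' Convert wavelength (nm) to wavenumber (cm^-1)
#'
#' Spectrometer exports on a wavelength axis can be converted with
#' `1e7 / nm`; note the resulting axis must be re-sorted ascending (handled by
#' [spectrum()]).
#'
#' @param nm wavelength in nanometres.
#' @return Wavenumber in cm^-1.
#' @export
wavelength_to_wavenumber <- function(nm) 1e7 / nm

#' Read a sample metadata table
#'
#' CSV keyed by `sample_id` with columns `sample_id`, `biomarker`,
#' `concentration`, `conc_units`, `stage` (missing columns are filled with
#' `NA`).
#'
#' @param path CSV file path.
#' @return Data frame with the five metadata columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  for (col in c("biomarker", "conc_units", "stage"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  if (!"concentration" %in% names(df)) df$concentration <- NA_real_
  df$sample_id <- as.character(df$sample_id)
  df$concentration <- as.numeric(df$concentration)
  df[c("sample_id", "biomarker", "concentration", "conc_units", "stage")]
}
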