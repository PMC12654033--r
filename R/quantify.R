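#' Detect prominent peaks in a spectrum
#'
#' Finds local extrema in the requested direction and keeps those whose
#' prominence is at least `min_prominence` times the signal range. Prominence
#' follows the standard contour-line definition: the height of a peak above
#' the higher of the two key saddles found by walking left and right until a
#' higher point (or the signal edge) is reached. `direction = "down"` detects
#' dips by negating the signal, so down-peaks on `y` coincide exactly with
#' up-peaks on `-y`.
#'
#' @param s a [spectrum()] (typically baseline-corrected).
#' @param min_prominence required prominence as a fraction of the signal
#'   range, in (0, 1).
#' @param direction `"up"` for maxima, `"down"` for minima.
#' @return Data frame with columns `position` (cm^-1), `intensity` (signal
#'   value at the extremum), `prominence`, `width` (cm^-1 at half prominence),
#'   sorted by position. May have zero rows.
#' @export
detect_peaks <- function(s, min_prominence = 0.05,
                         direction = c("down", "up")) {
  stopifnot(inherits(s, "spectrum"))
  direction <- match.arg(direction)
  if (min_prominence <= 0 || min_prominence >= 1)
    stop("min_prominence must be in (0, 1)")
  y <- if (direction == "down") -s$intensities else s$intensities
  x <- s$wavenumbers
  n <- length(y)
  rng <- diff(range(y))
  empty <- data.frame(position = numeric(0), intensity = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  if (rng == 0) return(empty)
  # local maxima: strictly above the previous point, at least as high as the
  # next (flat-top plateaus report their left edge)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(empty)
  prom <- vapply(idx, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence * rng
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty)
  width <- vapply(seq_along(idx), function(k)
    peak_width(x, y, idx[k], prom[k]), numeric(1))
  out <- data.frame(position = x[idx], intensity = s$intensities[idx],
                    prominence = prom, width = width)
  out[order(out$position), , drop = FALSE]
}

# contour-line prominence of the local maximum at index i
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i
  while (j > 1 && y[j - 1] <= y[i]) { j <- j - 1; left_min <- min(left_min, y[j]) }
  left_base <- if (j > 1) left_min else min(y[1:i])
  right_min <- y[i]; j <- i
  while (j < n && y[j + 1] <= y[i]) { j <- j + 1; right_min <- min(right_min, y[j]) }
  right_base <- if (j < n) right_min else min(y[i:n])
  y[i] - max(left_base, right_base)
}

# width (in x units) where the signal crosses half prominence below the peak
peak_width <- function(x, y, i, prom) {
  h <- y[i] - prom / 2
  n <- length(y)
  cross <- function(j0, j1) {
    # linear interpolation of the crossing between samples j0 (above h) and j1
    if (y[j0] == y[j1]) return(x[j1])
    x[j0] + (x[j1] - x[j0]) * (y[j0] - h) / (y[j0] - y[j1])
  }
  j <- i
  while (j > 1 && y[j] > h) j <- j - 1
  xl <- if (y[j] > h) x[1] else cross(j + 1, j)
  j <- i
  while (j < n && y[j] > h) j <- j + 1
  xr <- if (y[j] > h) x[n] else cross(j - 1, j)
  xr - xl
}

#' Consensus peaks across a set of spectra
#'
#' Detects peaks in every spectrum, pools them, and histograms their
#' positions into bins of `bin_width`. Each spectrum contributes at most once
#' per bin, so counts never exceed the number of spectra; high counts mark
#' bands observed consistently across the set.
#'
#' @param set a [spectrum_set()] with at least 2 rows.
#' @param bin_width histogram bin width in cm^-1.
#' @param min_prominence,direction passed to [detect_peaks()].
#' @return Data frame with `bin_center` and `count`, one row per non-empty
#'   bin.
#' @export
peak_consensus <- function(set, bin_width = 20, min_prominence = 0.05,
                           direction = c("down", "up")) {
  stopifnot(inherits(set, "spectrum_set"))
  direction <- match.arg(direction)
  if (nrow(set$intensities) < 2) stop("need at least 2 spectra")
  breaks <- seq(min(set$grid) - bin_width / 2,
                max(set$grid) + bin_width, by = bin_width)
  counts <- integer(length(breaks) - 1)
  for (i in seq_len(nrow(set$intensities))) {
    pk <- detect_peaks(set_spectrum(set, i), min_prominence, direction)
    if (!nrow(pk)) next
    bins <- unique(findInterval(pk$position, breaks))
    counts[bins] <- counts[bins] + 1L
  }
  keep <- counts > 0
  data.frame(bin_center = (breaks[-length(breaks)] + bin_width / 2)[keep],
             count = counts[keep])
}

#' Find wavenumber regions where peaks from all lists overlap
#'
#' Given one peak list per spectrum, returns the maximal wavenumber clusters
#' that contain at least one peak from every list with pairwise spread at most
#' `tol`, widened by `tol / 2` on each side. Used to locate the candidate
#' regions where reference and enhanced spectra share (slightly shifted)
#' bands.
#'
#' @param peaksets list of numeric vectors of peak positions (or data frames
#'   with a `position` column), at least 2.
#' @param tol maximum pairwise spread in cm^-1.
#' @return Data frame with columns `lo` and `hi`; zero rows when no overlap
#'   exists (e.g. an empty list).
#' @export
find_overlap_regions <- function(peaksets, tol = 50) {
  if (length(peaksets) < 2) stop("need at least 2 peak lists")
  pos_list <- lapply(peaksets, function(p)
    if (is.data.frame(p)) p$position else as.numeric(p))
  empty <- data.frame(lo = numeric(0), hi = numeric(0))
  if (any(!lengths(pos_list))) return(empty)
  pos <- unlist(pos_list)
  src <- rep(seq_along(pos_list), lengths(pos_list))
  o <- order(pos); pos <- pos[o]; src <- src[o]
  m <- length(pos_list)
  ivl <- NULL
  j <- 1
  for (i in seq_along(pos)) {
    if (j < i) j <- i
    while (j < length(pos) && pos[j + 1] - pos[i] <= tol) j <- j + 1
    if (length(unique(src[i:j])) == m)
      ivl <- rbind(ivl, c(pos[i], pos[j]))
  }
  if (is.null(ivl)) return(empty)
  # merge overlapping/touching intervals
  merged <- ivl[1, , drop = FALSE]
  if (nrow(ivl) > 1) for (k in 2:nrow(ivl)) {
    last <- nrow(merged)
    if (ivl[k, 1] <= merged[last, 2]) {
      merged[last, 2] <- max(merged[last, 2], ivl[k, 2])
    } else merged <- rbind(merged, ivl[k, ])
  }
  data.frame(lo = merged[, 1] - tol / 2, hi = merged[, 2] + tol / 2)
}

#' Quantification feature intensity within a spectral window
#'
#' Reads the signal value used for calibration from window `c(lo, hi)`.
#' `mode = "window_peak"` returns the intensity of the most prominent
#' in-window peak (falling back to the in-window extremum when no peak passes
#' the prominence threshold) — robust to small band shifts between samples.
#' `mode = "fixed_wavenumber"` reads the intensity at the grid point nearest
#' the window centre, reproducing the less reliable single-wavenumber
#' strategy.
#'
#' @param s a [spectrum()].
#' @param window numeric `c(lo, hi)` in cm^-1; must overlap the grid.
#' @param mode `"window_peak"` or `"fixed_wavenumber"`.
#' @param direction peak direction, `"down"` or `"up"`.
#' @param min_prominence prominence threshold for the in-window peak search.
#' @param peaks optional precomputed [detect_peaks()] result for `s` (an
#'   optimization used by the window search).
#' @return A single intensity value.
#' @export
feature_intensity <- function(s, window, mode = c("window_peak",
                                                  "fixed_wavenumber"),
                              direction = c("down", "up"),
                              min_prominence = 0.05, peaks = NULL) {
  stopifnot(inherits(s, "spectrum"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) stop("window must satisfy lo < hi")
  x <- s$wavenumbers
  if (hi < min(x) || lo > max(x)) stop("window lies outside the grid")
  if (mode == "fixed_wavenumber") {
    i <- which.min(abs(x - (lo + hi) / 2))
    return(s$intensities[i])
  }
  if (is.null(peaks)) peaks <- detect_peaks(s, min_prominence, direction)
  inw <- peaks[peaks$position >= lo & peaks$position <= hi, , drop = FALSE]
  if (nrow(inw)) return(inw$intensity[which.max(inw$prominence)])
  sel <- x >= lo & x <= hi
  ys <- s$intensities[sel]
  if (direction == "down") min(ys) else max(ys)
}

#' Fit a linear calibration model
#'
#' Ordinary least squares of feature intensity on concentration,
#' `intensity = slope * conc + intercept`. Replicates sharing a concentration
#' are averaged before fitting by default. At least 3 distinct concentrations
#' are required. The model records its window, R-squared, sample size and the
#' fitted points; concentration predictions outside `valid_range` are flagged
#' by [predict_concentration()].
#'
#' @param conc numeric concentrations.
#' @param intensity numeric feature intensities (same length).
#' @param window the spectral window `c(lo, hi)` the features were read from.
#' @param conc_units unit string (e.g. `"ng/mL"`).
#' @param average_replicates average replicate intensities at equal
#'   concentrations before fitting (default `TRUE`); `FALSE` pools them.
#' @param valid_range concentration range with validated performance,
#'   default `c(10, 100)`.
#' @return An object of class `calibration_model`.
#' @export
fit_calibration <- function(conc, intensity, window = c(NA_real_, NA_real_),
                            conc_units = "ng/mL", average_replicates = TRUE,
                            valid_range = c(10, 100)) {
  conc <- as.numeric(conc); intensity <- as.numeric(intensity)
  if (length(conc) != length(intensity))
    stop("conc and intensity must have the same length")
  if (average_replicates && anyDuplicated(conc)) {
    intensity <- as.numeric(tapply(intensity, conc, mean))
    conc <- sort(unique(conc))
  }
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct concentrations, got ",
         length(unique(conc)))
  fit <- stats::lm(intensity ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  structure(list(window = as.numeric(window),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = 1 - ss_res / ss_tot,
                 n = length(conc),
                 conc_units = conc_units,
                 valid_range = as.numeric(valid_range),
                 points = data.frame(conc = conc, intensity = intensity)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> window %.0f-%.0f cm^-1: I = %.4g * c %+.4g, R2 = %.3f (n = %d, %s)\n",
    x$window[1], x$window[2], x$slope, x$intercept, x$r2, x$n, x$conc_units))
  invisible(x)
}

#' Exhaustive calibration-window search
#'
#' Scans every window of width `width_min` to `width_max` (cm^-1, default
#' 20-370) on a `step`-spaced lattice of start positions, reads the
#' quantification feature from each calibration spectrum, fits a straight line
#' of intensity on concentration, and scores the window by the R-squared of
#' that fit. By default only windows with a negative (inverse) slope compete,
#' matching the expectation that reflectance decreases with concentration;
#' ties are broken by smaller width, then lower start wavenumber.
#'
#' @param set a [spectrum_set()] whose metadata carries concentrations (>= 3
#'   distinct values).
#' @param width_min,width_max window width limits in cm^-1.
#' @param step lattice spacing for window starts and widths, cm^-1.
#' @param mode,direction,min_prominence feature extraction options, see
#'   [feature_intensity()].
#' @param require_negative_slope only windows with slope < 0 are eligible
#'   (default `TRUE`).
#' @details In `window_peak` mode a window is only eligible to win when every
#'   calibration spectrum has a detected peak inside it: the regression is
#'   meant to run on actual peak intensities, and windows that merely clip a
#'   band flank (reading the window-edge extremum through the fallback) would
#'   otherwise tie with the true band window — at zero noise a fixed off-peak
#'   point is exactly linear in concentration, so every such window scores a
#'   perfect R-squared. All windows still appear in the candidate table with
#'   their fallback-based fits and their peak support. Windows whose feature
#'   varies by less than 1e-6 of the overall signal range across the series
#'   are treated as unresponsive and never eligible: on noise-free data the
#'   far tail of a Gaussian band makes every feature *exactly* linear in
#'   concentration at the 1e-8 level, which would otherwise score a perfect
#'   R-squared for windows with no real response.
#' @param normalize min/max-normalize each spectrum before feature extraction.
#' @param average_replicates,conc_units,valid_range passed to
#'   [fit_calibration()].
#' @return List of class `window_search` with `best` (a
#'   [fit_calibration()] model) and `candidates` (data frame of every window
#'   evaluated: `lo`, `hi`, `width`, `slope`, `intercept`, `r2`, `eligible`).
#' @export
search_optimal_window <- function(set, width_min = 20, width_max = 370,
                                  step = 10,
                                  mode = c("window_peak", "fixed_wavenumber"),
                                  direction = c("down", "up"),
                                  min_prominence = 0.05,
                                  require_negative_slope = TRUE,
                                  normalize = FALSE,
                                  average_replicates = TRUE,
                                  conc_units = NULL, valid_range = c(10, 100)) {
  stopifnot(inherits(set, "spectrum_set"))
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  conc <- set$meta$concentration
  if (any(is.na(conc))) stop("every spectrum needs a concentration")
  if (length(unique(conc)) < 3)
    stop("need calibration spectra at >= 3 distinct concentrations")
  if (is.null(conc_units)) {
    u <- unique(stats::na.omit(set$meta$conc_units))
    conc_units <- if (length(u) == 1) u else "ng/mL"
  }
  spectra <- lapply(seq_len(nrow(set$intensities)), set_spectrum, set = set)
  if (normalize) spectra <- lapply(spectra, normalize_minmax)
  peaks <- lapply(spectra, detect_peaks, min_prominence = min_prominence,
                  direction = direction)
  gmin <- min(set$grid); gmax <- max(set$grid)
  starts <- seq(gmin, gmax - width_min, by = step)
  widths_all <- seq(width_min, width_max, by = step)
  avg <- average_replicates && anyDuplicated(conc) > 0
  conc_use <- if (avg) sort(unique(conc)) else conc
  cc <- conc_use - mean(conc_use)
  sxx <- sum(cc^2)
  rows <- vector("list", length(starts))
  grid <- set$grid
  ints <- lapply(spectra, `[[`, "intensities")
  for (si in seq_along(starts)) {
    lo <- starts[si]
    widths <- widths_all[lo + widths_all <= gmax]
    if (!length(widths)) next
    feat <- vapply(widths, function(w) {
      hi <- lo + w
      i1 <- findInterval(lo, grid, left.open = TRUE) + 1L
      i2 <- findInterval(hi, grid)
      vapply(seq_along(spectra), function(k) {
        if (mode == "fixed_wavenumber")
          return(ints[[k]][which.min(abs(grid - (lo + hi) / 2))])
        pk <- peaks[[k]]
        inw <- which(pk$position >= lo & pk$position <= hi)
        if (length(inw))
          return(pk$intensity[inw[which.max(pk$prominence[inw])]])
        ys <- ints[[k]][i1:i2]
        if (direction == "down") min(ys) else max(ys)
      }, numeric(1))
    }, numeric(length(spectra)))
    feat <- matrix(feat, nrow = length(spectra))
    # fraction of spectra with a detected in-window peak
    peak_frac <- vapply(widths, function(w) {
      mean(vapply(peaks, function(pk)
        any(pk$position >= lo & pk$position <= lo + w), logical(1)))
    }, numeric(1))
    # average replicates at equal concentrations, then closed-form OLS per column
    if (avg) feat <- rowsum(feat, group = conc) / as.vector(table(conc))
    fm <- colMeans(feat)
    fc <- sweep(feat, 2, fm)
    sxy <- as.vector(crossprod(cc, fc))
    slope <- sxy / sxx
    syy <- colSums(fc^2)
    r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 0)
    frange <- apply(feat, 2, function(v) diff(range(v)))
    rows[[si]] <- data.frame(lo = lo, hi = lo + widths, width = widths,
                             slope = slope,
                             intercept = fm - slope * mean(conc_use), r2 = r2,
                             peak_support = peak_frac,
                             feature_range = frange)
  }
  cand <- do.call(rbind, rows)
  signal_range <- diff(range(set$intensities))
  cand$eligible <- cand$feature_range > 1e-6 * signal_range
  if (require_negative_slope) cand$eligible <- cand$eligible & cand$slope < 0
  if (mode == "window_peak")
    cand$eligible <- cand$eligible & cand$peak_support == 1
  ord <- order(-cand$r2, cand$width, cand$lo)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  el <- which(cand$eligible)
  if (!length(el)) {
    b <- cand[1, ]
    stop(sprintf(
      "no window satisfies the slope constraint; best unconstrained: %.0f-%.0f cm^-1 (slope %.4g, R2 %.3f)",
      b$lo, b$hi, b$slope, b$r2))
  }
  b <- cand[el[1], ]
  win <- c(b$lo, b$hi)
  feat_best <- vapply(seq_along(spectra), function(k)
    feature_intensity(spectra[[k]], win, mode, direction, min_prominence,
                      peaks = peaks[[k]]), numeric(1))
  best <- fit_calibration(conc, feat_best, window = win,
                          conc_units = conc_units,
                          average_replicates = average_replicates,
                          valid_range = valid_range)
  structure(list(best = best, candidates = cand,
                 mode = mode, direction = direction, normalize = normalize),
            class = "window_search")
}

#' @export
print.window_search <- function(x, ...) {
  cat(sprintf("<window_search> %d windows evaluated\n", nrow(x$candidates)))
  print(x$best)
  invisible(x)
}

#' Predict a concentration from a calibration model
#'
#' Classical inverse prediction: reads the feature intensity from the model's
#' window and inverts the fitted line, `c = (I - intercept) / slope`. Negative
#' estimates are clamped to 0; estimates outside the model's `valid_range` are
#' flagged `"out_of_range"`.
#'
#' @param s a preprocessed [spectrum()].
#' @param model a [fit_calibration()] model with nonzero slope.
#' @param mode,direction,min_prominence see [feature_intensity()].
#' @return List with `concentration` and `flag` (`"in_range"` or
#'   `"out_of_range"`).
#' @export
predict_concentration <- function(s, model,
                                  mode = c("window_peak", "fixed_wavenumber"),
                                  direction = c("down", "up"),
                                  min_prominence = 0.05) {
  stopifnot(inherits(model, "calibration_model"))
  if (model$slope == 0) stop("calibration slope is zero; cannot invert")
  i <- feature_intensity(s, model$window, mode, direction, min_prominence)
  conc <- (i - model$intercept) / model$slope
  flag <- if (conc >= model$valid_range[1] && conc <= model$valid_range[2])
    "in_range" else "out_of_range"
  if (conc < 0) { conc <- 0; flag <- "out_of_range" }
  list(concentration = conc, flag = flag)
}

#' Plasmonic enhancement factor
#'
#' The signal amplification of the enhanced substrate relative to the
#' unenhanced reference, corrected for the probe concentrations:
#' \deqn{EF = \frac{I_{SE}}{I_{ref}} \times \frac{C_{ref}}{C_{SE}}}
#' With the enhanced substrate probed at a 10^4-fold lower dye concentration,
#' equal intensities already imply a 10^4 enhancement.
#'
#' @param i_ftir reference substrate intensity (> 0).
#' @param i_seftir enhanced substrate intensity (> 0).
#' @param c_ftir reference probe concentration, molar (> 0).
#' @param c_seftir enhanced probe concentration, molar (> 0).
#' @param region optional wavenumber window `c(lo, hi)` the intensities were
#'   read from.
#' @return An object of class `ef_record` with the inputs and `ef`.
#' @examples
#' enhancement_factor(0.72, 1.35, 1e-2, 1e-6)$ef  # 18750
#' @export
enhancement_factor <- function(i_ftir, i_seftir, c_ftir, c_seftir,
                               region = c(NA_real_, NA_real_)) {
  vals <- c(i_ftir = i_ftir, i_seftir = i_seftir, c_ftir = c_ftir,
            c_seftir = c_seftir)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all intensities and concentrations must be positive")
  structure(list(region = as.numeric(region), i_ftir = i_ftir,
                 i_seftir = i_seftir, c_ftir = c_ftir, c_seftir = c_seftir,
                 ef = (i_seftir / i_ftir) * (c_ftir / c_seftir)),
            class = "ef_record")
}

#' @export
print.ef_record <- function(x, ...) {
  cat(sprintf("<ef_record> EF = %.4g (I ratio %.3f, C ratio %.3g)\n",
              x$ef, x$i_seftir / x$i_ftir, x$c_ftir / x$c_seftir))
  invisible(x)
}

#' Truncate to a number of significant figures
#'
#' Like [signif()] but rounding toward zero, the convention used when
#' enhancement factors are reported as e.g. `0.187e5` for a computed
#' `1.875e4`.
#'
#' @param x numeric.
#' @param digits significant figures to keep.
#' @return `x` truncated to `digits` significant figures.
#' @export
signif_trunc <- function(x, digits) {
  s <- sign(x); x <- abs(x)
  out <- ifelse(x == 0, 0, {
    e <- floor(log10(x)) - digits + 1
    trunc(x / 10^e) * 10^e
  })
  s * out
}

#' Serialize a calibration model to JSON text
#'
#' Stores the window, line coefficients, R-squared, sample size, units, valid
#' range, fitted points, and an optional pipeline configuration hash so
#' predictions are reproducible.
#'
#' @param model a [fit_calibration()] model.
#' @param path output file.
#' @param config_hash optional hash string of the preprocessing configuration
#'   (see [config_hash()]).
#' @return Invisibly, `path`.
#' @export
write_calibration <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- unclass(model)
  obj$config_hash <- config_hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path JSON file path.
#' @return A `calibration_model`; any stored `config_hash` is kept as an
#'   attribute-free list field.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- structure(list(window = as.numeric(obj$window), slope = obj$slope,
                      intercept = obj$intercept, r2 = obj$r2, n = obj$n,
                      conc_units = obj$conc_units,
                      valid_range = as.numeric(obj$valid_range),
                      points = as.data.frame(obj$points)),
                 class = "calibration_model")
  m$config_hash <- obj$config_hash
  m
}

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; used to tie stored calibration
#' models to the preprocessing they were built with.
#'
#' @param x any JSON-serializable object (e.g. a [preprocess_config()]).
#' @return Hex digest string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(x), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
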