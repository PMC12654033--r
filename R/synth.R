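#' Gaussian absorption band
#'
#' One term of the band-superposition forward model: a Gaussian dip of width
#' `sigma` centred at `center`, whose depth is `base_depth +
#' depth_per_conc * concentration`. Bands with `depth_per_conc = 0` are
#' concentration-independent distractors; responsive bands model the linear
#' decrease of reflectance with analyte concentration.
#'
#' @param center band centre in cm^-1.
#' @param sigma Gaussian width in cm^-1 (> 0); 30 cm^-1 is typical of broad
#'   near-infrared overtone envelopes.
#' @param base_depth concentration-independent depth (>= 0), intensity units.
#' @param depth_per_conc depth added per concentration unit (>= 0).
#' @return An object of class `synth_band`.
#' @export
band <- function(center, sigma = 30, base_depth = 0.05, depth_per_conc = 0) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (base_depth < 0) stop("base_depth must be >= 0")
  if (depth_per_conc < 0) stop("depth_per_conc must be >= 0")
  structure(list(center = center, sigma = sigma, base_depth = base_depth,
                 depth_per_conc = depth_per_conc),
            class = "synth_band")
}

#' Simulator configuration
#'
#' Defines the forward model for synthetic reflectance spectra:
#' `R(v) = baseline(v) - sum_j depth_j(c) * exp(-(v - center_j)^2 / (2 sigma_j^2)) + noise`.
#' The baseline is the quadratic
#' `b0 + b1 * x + b2 * x^2` in the scaled coordinate
#' `x = (v - mid) / half_range`, kept strictly positive over the grid; noise
#' is additive iid Gaussian with standard deviation `noise_sd`.
#'
#' @param grid wavenumber vector (default [default_grid()], 4000-7000 cm^-1
#'   at 3 cm^-1).
#' @param bands list of [band()] objects.
#' @param baseline_coeffs numeric `c(intercept, slope, curvature)` of the
#'   scaled-coordinate polynomial baseline.
#' @param noise_sd additive Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @param biomarker,conc_units default metadata attached to generated
#'   spectra.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid = default_grid(),
                         bands = her2_profile(),
                         baseline_coeffs = c(1.2, 0.1, 0.05),
                         noise_sd = 0.01, seed = 1,
                         biomarker = NA_character_, conc_units = "ng/mL") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lapply(bands, function(b) stopifnot(inherits(b, "synth_band")))
  cfg <- structure(list(grid = as.numeric(grid), bands = bands,
                        baseline_coeffs = as.numeric(baseline_coeffs),
                        noise_sd = noise_sd, seed = as.integer(seed),
                        biomarker = biomarker, conc_units = conc_units),
                   class = "synth_config")
  if (any(synth_baseline(cfg) <= 0))
    stop("baseline must be strictly positive over the grid")
  cfg
}

synth_baseline <- function(cfg) {
  v <- cfg$grid
  x <- (v - mean(range(v))) / (diff(range(v)) / 2)
  b <- cfg$baseline_coeffs
  b[1] + b[2] * x + b[3] * x^2
}

# noise-free reflectance at concentration c
synth_clean <- function(cfg, concentration) {
  r <- synth_baseline(cfg)
  for (b in cfg$bands) {
    depth <- b$base_depth + b$depth_per_conc * concentration
    r <- r - depth * exp(-(cfg$grid - b$center)^2 / (2 * b$sigma^2))
  }
  r
}

#' Default band profiles
#'
#' Two near-infrared band sets emulating the reflectance signatures of a
#' receptor-protein biomarker (`her2_profile`, responsive band at 6750 cm^-1,
#' inside the 6700-6800 cm^-1 quantification window) and a mucin glycoprotein
#' biomarker (`ca153_profile`, responsive band at 6530 cm^-1, inside
#' 6480-6580 cm^-1). Distractor band centres follow typical overtone /
#' combination assignments (CH/OH/NH bands between 4100 and 6600 cm^-1);
#' widths and depths are free parameters of the simulator.
#'
#' @param depth_per_conc depth gained per concentration unit by the
#'   responsive band.
#' @return List of [band()] objects.
#' @export
her2_profile <- function(depth_per_conc = 0.003) {
  list(band(4145, 40, 0.12), band(4606, 35, 0.06), band(5102, 30, 0.05),
       band(5300, 30, 0.07), band(5835, 30, 0.05), band(6108, 30, 0.04),
       band(6568, 30, 0.05),
       # the quantification band dominates its spectral neighbourhood over the
       # whole validated 10-100 range (depth 0.08 at the low end)
       band(6750, 30, 0.05, depth_per_conc))
}

#' @rdname her2_profile
#' @export
ca153_profile <- function(depth_per_conc = 0.003) {
  list(band(4195, 40, 0.14), band(5015, 35, 0.07), band(5200, 30, 0.06),
       band(5600, 30, 0.04), band(6300, 30, 0.05), band(6650, 30, 0.04),
       band(6530, 30, 0.05, depth_per_conc))
}

#' Simulate one reflectance spectrum
#'
#' Evaluates the band-superposition forward model at `concentration` and adds
#' seeded Gaussian noise. The same `(cfg, concentration, seed)` always yields
#' the same spectrum (the call sets the session RNG seed).
#'
#' @param cfg a [synth_config()].
#' @param concentration analyte concentration (>= 0).
#' @param meta optional [sample_meta()]; by default one is built from the
#'   config's biomarker/units and the true concentration.
#' @param seed RNG seed for the noise draw (default `cfg$seed`).
#' @return A [spectrum()] whose metadata carries the true concentration.
#' @export
simulate_spectrum <- function(cfg, concentration, meta = NULL,
                              seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  if (concentration < 0) stop("concentration must be >= 0")
  r <- synth_clean(cfg, concentration)
  if (any(r <= 0))
    stop("configured bands drive reflectance nonpositive at c = ",
         concentration)
  if (cfg$noise_sd > 0) {
    set.seed(seed)
    r <- r + stats::rnorm(length(r), 0, cfg$noise_sd)
  }
  if (is.null(meta))
    meta <- sample_meta(sample_id = paste0("sim_c", concentration, "_s", seed),
                        biomarker = cfg$biomarker,
                        concentration = concentration,
                        conc_units = cfg$conc_units)
  spectrum(cfg$grid, r, meta)
}

#' Simulate a calibration series
#'
#' Generates `replicates` spectra at each concentration (default 10-100 in
#' steps of 10, three replicates — the standard calibration design for this
#' assay), each replicate with its own noise draw derived from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @param concentrations numeric vector (>= 3 values).
#' @param replicates replicates per concentration.
#' @return A [spectrum_set()]; the true concentration of every row is in the
#'   metadata.
#' @export
simulate_calibration_series <- function(cfg,
                                        concentrations = seq(10, 100, by = 10),
                                        replicates = 3) {
  stopifnot(inherits(cfg, "synth_config"))
  if (length(concentrations) < 3) stop("need at least 3 concentrations")
  spectra <- list()
  k <- 0
  for (conc in concentrations) for (rep_i in seq_len(replicates)) {
    k <- k + 1
    meta <- sample_meta(sample_id = sprintf("cal_c%g_r%d", conc, rep_i),
                        biomarker = cfg$biomarker, concentration = conc,
                        conc_units = cfg$conc_units)
    spectra[[k]] <- simulate_spectrum(cfg, conc, meta = meta,
                                      seed = cfg$seed + k)
  }
  assemble_set(spectra, grid = cfg$grid)
}

#' Simulate a labeled two-class set
#'
#' Draws `n_per_class` spectra from each of two configurations (classes "A"
#' and "B") at a common concentration and returns them as a
#' [labeled_matrix()] for the classification harness. Identical
#' configurations produce classes that differ only in noise; a warning is
#' emitted because such classes are indistinguishable by construction.
#'
#' @param cfg_a,cfg_b [synth_config()] objects sharing a grid.
#' @param n_per_class spectra per class (>= 4).
#' @param concentration concentration at which spectra are drawn.
#' @return A [labeled_matrix()] with `y` in `c("A", "B")`.
#' @export
simulate_two_class_set <- function(cfg_a, cfg_b, n_per_class = 10,
                                   concentration = 50) {
  stopifnot(inherits(cfg_a, "synth_config"), inherits(cfg_b, "synth_config"))
  if (!isTRUE(all.equal(cfg_a$grid, cfg_b$grid)))
    stop("the two configurations must share a grid")
  if (n_per_class < 4) stop("need n_per_class >= 4")
  same <- isTRUE(all.equal(lapply(cfg_a$bands, unclass),
                           lapply(cfg_b$bands, unclass)))
  if (same)
    warning("identical band lists: classes are indistinguishable by construction")
  rows <- list(); y <- character(0)
  k <- 0
  for (cls in c("A", "B")) {
    cfg <- if (cls == "A") cfg_a else cfg_b
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      s <- simulate_spectrum(cfg, concentration, seed = cfg_a$seed + k)
      rows[[k]] <- s$intensities
      y <- c(y, cls)
    }
  }
  labeled_matrix(do.call(rbind, rows), cfg_a$grid, y)
}

#' Simulate a drifting scan series
#'
#' Repeated acquisitions of the same sample with cumulative baseline drift
#' (`drift_per_scan` added to the baseline intercept at each scan) and fresh
#' noise per scan — a simple stand-in for instrument batch effects.
#'
#' @param cfg a [synth_config()].
#' @param n_scans number of scans (>= 1).
#' @param drift_per_scan intercept increment per scan.
#' @param concentration analyte concentration held constant over scans.
#' @return A [spectrum_set()] with one row per scan, in acquisition order.
#' @export
simulate_scan_series <- function(cfg, n_scans, drift_per_scan = 0,
                                 concentration = 50) {
  stopifnot(inherits(cfg, "synth_config"))
  if (n_scans < 1) stop("n_scans must be >= 1")
  spectra <- lapply(seq_len(n_scans), function(i) {
    cfg_i <- cfg
    cfg_i$baseline_coeffs[1] <- cfg$baseline_coeffs[1] +
      drift_per_scan * (i - 1)
    meta <- sample_meta(sample_id = sprintf("scan_%03d", i),
                        biomarker = cfg$biomarker,
                        concentration = concentration,
                        conc_units = cfg$conc_units)
    simulate_spectrum(cfg_i, concentration, meta = meta, seed = cfg$seed + i)
  })
  assemble_set(spectra, grid = cfg$grid)
}
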