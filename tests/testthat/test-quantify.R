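make_set <- function(grid, rows, conc = NULL, units = "ng/mL", ids = NULL) {
  n <- nrow(rows)
  meta <- data.frame(
    sample_id = if (is.null(ids)) paste0("s", seq_len(n)) else ids,
    biomarker = NA_character_,
    concentration = if (is.null(conc)) NA_real_ else conc,
    conc_units = if (is.null(conc)) NA_character_ else units,
    stage = NA_character_)
  spectrum_set(grid, rows, meta)
}

test_that("detect_peaks finds dips, mirrors directions, and matches brute force", {
  g <- tiny_grid(301)
  s <- line_dips_spectrum(g, centers = 6750, depths = 0.3)
  pk <- detect_peaks(s, 0.1, "down")
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$position - 6750), diff(g)[1] + 1e-9)

  flat <- spectrum(g, rep(1, length(g)))
  expect_equal(nrow(detect_peaks(flat, 0.1, "down")), 0)

  # three dips with graded prominences; threshold keeps exactly two
  s3 <- line_dips_spectrum(tiny_grid(601), intercept = 1, slope = 0,
                           centers = c(4700, 5500, 6300),
                           depths = c(0.5, 0.2, 0.05))
  pk3 <- detect_peaks(s3, min_prominence = 0.15, direction = "down")
  expect_equal(nrow(pk3), 2)
  expect_equal(pk3$position, c(4700, 5500), tolerance = 1)

  # brute-force prominence oracle on rough random signals
  set.seed(21)
  for (rep in 1:10) {
    y <- cumsum(rnorm(80))
    s_r <- spectrum(seq(4000, by = 5, length.out = 80), y)
    pk_up <- detect_peaks(s_r, 0.05, "up")
    oracle <- bf_prominences(y)
    oracle <- oracle[oracle$prominence >= 0.05 * diff(range(y)), ]
    expect_equal(pk_up$position, s_r$wavenumbers[oracle$index])
    expect_equal(pk_up$prominence, oracle$prominence, tolerance = 1e-12)
    # down-peaks of y are exactly up-peaks of -y
    pk_down <- detect_peaks(spectrum(s_r$wavenumbers, -y), 0.05, "down")
    expect_equal(pk_down$position, pk_up$position)
    expect_equal(pk_down$prominence, pk_up$prominence)
  }
})

test_that("peak_consensus counts each spectrum at most once per bin", {
  g <- tiny_grid(601)
  set.seed(3)
  n_spec <- 8
  rows <- t(replicate(n_spec, {
    s <- line_dips_spectrum(g, centers = c(6750 + rnorm(1, 0, 3),
                                           runif(1, 4300, 6300)),
                            depths = c(0.4, 0.3), noise_sd = 0.002)
    s$intensities
  }))
  set <- make_set(g, rows)
  cons <- peak_consensus(set, bin_width = 30, min_prominence = 0.1,
                         direction = "down")
  expect_true(all(cons$count <= n_spec))
  # the planted common band is the modal bin with full support
  top <- cons[which.max(cons$count), ]
  expect_equal(top$count, n_spec)
  expect_lt(abs(top$bin_center - 6750), 30)
})

test_that("find_overlap_regions matches the exhaustive combination oracle", {
  # single tight cluster
  r <- find_overlap_regions(list(5300, 5305, 5298), tol = 20)
  expect_equal(nrow(r), 1)
  expect_true(r$lo <= 5300 & 5300 <= r$hi)

  # an empty list kills all overlap
  expect_equal(nrow(find_overlap_regions(list(c(5300, 6000), numeric(0)),
                                         tol = 20)), 0)

  set.seed(77)
  for (rep in 1:25) {
    m <- sample(2:4, 1)
    pos_list <- lapply(seq_len(m), function(i)
      sort(runif(sample(1:6, 1), 4000, 7000)))
    tol <- runif(1, 10, 200)
    got <- find_overlap_regions(pos_list, tol)
    want <- bf_overlap(pos_list, tol)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$lo, want$lo, tolerance = 1e-9)
      expect_equal(got$hi, want$hi, tolerance = 1e-9)
    }
  }
})

test_that("feature_intensity reads the trough in-window and the fixed point off-peak", {
  g <- tiny_grid(601)   # 5 cm^-1 step: band centres fall on grid points
  dip_center <- 6750
  s <- line_dips_spectrum(g, intercept = 1, slope = 0,
                          centers = dip_center, depths = 0.3)
  v_peak <- feature_intensity(s, c(6700, 6800), "window_peak", "down")
  expect_equal(v_peak, min(s$intensities), tolerance = 1e-12)
  v_fixed <- feature_intensity(s, c(6700, 6800), "fixed_wavenumber")
  expect_equal(v_fixed, v_peak, tolerance = 1e-6)  # window centred on the dip

  # dip shifted off the fixed point: fixed mode reads the band shape 10 cm^-1
  # off-centre, window mode still reads the trough
  s_shift <- line_dips_spectrum(g, intercept = 1, slope = 0,
                                centers = 6760, depths = 0.3)
  v_fixed2 <- feature_intensity(s_shift, c(6700, 6800), "fixed_wavenumber")
  v_peak2 <- feature_intensity(s_shift, c(6700, 6800), "window_peak", "down")
  expect_equal(v_peak2, 1 - 0.3, tolerance = 1e-3)
  expect_equal(v_fixed2 - v_peak2, 0.3 - 0.3 * exp(-10^2 / (2 * 30^2)),
               tolerance = 1e-3)

  expect_error(feature_intensity(s, c(8000, 8100), "window_peak"), "outside")
})

test_that("fit_calibration recovers exact lines and matches closed-form OLS", {
  conc <- seq(10, 100, by = 10)
  exact <- 1.0 - 0.005 * conc
  m <- fit_calibration(conc, exact, conc_units = "ng/mL")
  expect_equal(m$slope, -0.005)
  expect_equal(m$intercept, 1.0)
  expect_equal(m$r2, 1)

  expect_error(fit_calibration(c(10, 10, 20, 20), c(1, 1, 2, 2)),
               "3 distinct")

  # replicate averaging happens before fitting
  m2 <- fit_calibration(c(10, 10, 20, 30), c(1, 3, 5, 7))
  expect_equal(m2$n, 3)
  expect_equal(m2$points$intensity[1], 2)

  # noisy line: slope within 3 closed-form standard errors of the truth
  set.seed(8)
  slope_true <- -0.004
  y <- 1 + slope_true * conc + rnorm(10, 0, 0.01)
  m3 <- fit_calibration(conc, y)
  resid <- y - (m3$intercept + m3$slope * conc)
  se <- sqrt(sum(resid^2) / 8 / sum((conc - mean(conc))^2))
  expect_lt(abs(m3$slope - slope_true), 3 * se)
})

test_that("window search recovers a planted responsive band", {
  scfg <- synth_config(grid = default_grid(step = 5), noise_sd = 0,
                       bands = list(band(4800, 30, 0.2), band(5600, 30, 0.15),
                                    band(6300, 35, 0.02, 0.003)))
  set <- simulate_calibration_series(scfg, seq(10, 100, by = 15),
                                     replicates = 1)
  for (step in c(5, 10, 20)) {
    res <- search_optimal_window(set, step = step)
    expect_true(res$best$window[1] <= 6300 && 6300 <= res$best$window[2])
  }
  res <- search_optimal_window(set, step = 10)
  expect_gte(res$best$r2, 0.99)
  expect_lt(res$best$slope, 0)
  # candidate table is exhaustive and the winner maximizes eligible R2
  el <- res$candidates[res$candidates$eligible, ]
  expect_equal(res$best$r2, max(el$r2), tolerance = 1e-9)

  # R2 scale invariance: scaling all spectra leaves the best score unchanged
  set_scaled <- spectrum_set(set$grid, set$intensities * 3.5, set$meta)
  res_s <- search_optimal_window(set_scaled, step = 20)
  res_u <- search_optimal_window(set, step = 20)
  expect_equal(res_s$best$r2, res_u$best$r2, tolerance = 1e-9)
  expect_equal(res_s$best$window, res_u$best$window)

  # all bands unresponsive + inverse-slope requirement -> informative error
  scfg0 <- synth_config(grid = default_grid(step = 10), noise_sd = 0,
                        bands = list(band(5000, 30, 0.2), band(6000, 30, 0.1)))
  set0 <- simulate_calibration_series(scfg0, c(10, 50, 100), replicates = 1)
  expect_error(search_optimal_window(set0, step = 50), "no window")
})

test_that("candidate-table fits agree with per-window feature_intensity + fit_calibration", {
  scfg <- synth_config(grid = default_grid(step = 10), noise_sd = 0.01,
                       seed = 5)
  set <- simulate_calibration_series(scfg, c(10, 30, 50, 70, 100),
                                     replicates = 1)
  res <- search_optimal_window(set, step = 50)
  set.seed(6)
  for (row in sample(nrow(res$candidates), 8)) {
    cand <- res$candidates[row, ]
    feats <- vapply(seq_len(nrow(set$intensities)), function(i)
      feature_intensity(set_spectrum(set, i), c(cand$lo, cand$hi),
                        "window_peak", "down"), numeric(1))
    m <- fit_calibration(set$meta$concentration, feats,
                         window = c(cand$lo, cand$hi))
    expect_equal(cand$slope, m$slope, tolerance = 1e-9)
    expect_equal(cand$r2, m$r2, tolerance = 1e-9)
  }
})

test_that("predict_concentration inverts the line and applies the range rule", {
  model <- fit_calibration(seq(10, 100, 10), 1 - 0.005 * seq(10, 100, 10),
                           window = c(6700, 6800))
  g <- tiny_grid(601)   # 6750 lies on this grid
  mk <- function(level) spectrum(g, rep(level, length(g)) -
                                   0.001 * exp(-(g - 6750)^2 / 200))
  # intensity exactly at the model value for c = 50
  s50 <- mk(1 - 0.005 * 50 + 0.001)
  p <- predict_concentration(s50, model)
  expect_equal(p$concentration, 50, tolerance = 1e-6)
  expect_equal(p$flag, "in_range")

  s120 <- mk(1 - 0.005 * 120 + 0.001)
  p2 <- predict_concentration(s120, model)
  expect_equal(p2$concentration, 120, tolerance = 1e-6)
  expect_equal(p2$flag, "out_of_range")

  # implied negative concentration clamps to zero
  s_neg <- mk(1.2)
  p3 <- predict_concentration(s_neg, model)
  expect_equal(p3$concentration, 0)
  expect_equal(p3$flag, "out_of_range")

  zero <- model; zero$slope <- 0
  expect_error(predict_concentration(s50, zero), "zero")
})

test_that("enhancement factor follows the intensity-ratio formula and scaling laws", {
  expect_equal(enhancement_factor(0.72, 1.35, 1e-2, 1e-6)$ef, 1.875e4)
  expect_equal(enhancement_factor(1.76, 1.22, 1e-2, 1e-6)$ef, 0.693182e4,
               tolerance = 1e-5)
  expect_equal(enhancement_factor(1, 1, 5, 5)$ef, 1)
  expect_error(enhancement_factor(-1, 1, 1, 1), "positive")

  # homogeneity: intensity scaling cancels; reference-concentration scaling
  # multiplies
  base <- enhancement_factor(0.8, 1.6, 1e-2, 1e-6)$ef
  expect_equal(enhancement_factor(0.8 * 7, 1.6 * 7, 1e-2, 1e-6)$ef, base)
  expect_equal(enhancement_factor(0.8, 1.6, 3e-2, 1e-6)$ef, 3 * base)
})

test_that("significant-figure truncation rounds toward zero", {
  expect_equal(signif_trunc(18750, 2), 18000)
  expect_equal(signif_trunc(18750, 3), 18700)
  expect_equal(signif_trunc(-0.06931, 2), -0.069)
  expect_equal(signif_trunc(0, 3), 0)
})

test_that("calibration models survive a JSON round trip with a config hash", {
  d <- withr::local_tempdir()
  m <- fit_calibration(seq(10, 100, 10),
                       1 - 0.004 * seq(10, 100, 10) + rnorm(10, 0, 1e-4),
                       window = c(6480, 6580), conc_units = "U/mL")
  f <- file.path(d, "model.json")
  h <- config_hash(preprocess_config())
  write_calibration(m, f, config_hash = h)
  m2 <- read_calibration(f)
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$r2, m$r2)
  expect_equal(m2$window, m$window)
  expect_equal(m2$config_hash, h)
  expect_equal(m2$points$conc, m$points$conc)
})
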