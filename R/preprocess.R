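#' Preprocessing configuration
#'
#' Parameters of the smoothing and baseline-correction stage. Defaults are
#' chosen to behave well on ~1000-point grids over 4000-7000 cm^-1:
#' a 3rd-order Butterworth low-pass at 0.1 of Nyquist, and an IASLS baseline
#' with smoothness weight `lam = 1e7`, first-derivative weight `lam1 = 10`,
#' asymmetry `p = 0.01`. The first-derivative term is kept small because it
#' pulls the baseline into steep band flanks: large values (1e3 and up on a
#' ~1000-point grid) visibly eat into band depth and would bias
#' quantification. `peak_direction = "down"` treats absorption features
#' as dips below the baseline (reflectance decreases at absorbing
#' wavenumbers); `"up"` supports increasing-response signals.
#'
#' @param filter_order Butterworth filter order (small positive integer).
#' @param cutoff_frac low-pass cutoff as a fraction of Nyquist, in (0, 1).
#' @param lam baseline curvature penalty weight, > 0.
#' @param lam1 first-derivative residual penalty weight, >= 0.
#' @param p asymmetry weight in (0, 1); small values hug the baseline side.
#' @param max_iter maximum IASLS iterations.
#' @param tol convergence tolerance on the relative change of the weight
#'   vector.
#' @param peak_direction `"down"` (default) or `"up"`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 3, cutoff_frac = 0.1,
                              lam = 1e7, lam1 = 10, p = 0.01,
                              max_iter = 50, tol = 1e-3,
                              peak_direction = c("down", "up")) {
  peak_direction <- match.arg(peak_direction)
  # tolerate YAML scalars arriving as strings (e.g. "1e6")
  filter_order <- as.numeric(filter_order)
  cutoff_frac <- as.numeric(cutoff_frac)
  lam <- as.numeric(lam); lam1 <- as.numeric(lam1); p <- as.numeric(p)
  max_iter <- as.numeric(max_iter); tol <- as.numeric(tol)
  if (filter_order < 1 || filter_order != round(filter_order))
    stop("filter_order must be a positive integer")
  if (cutoff_frac <= 0 || cutoff_frac >= 1)
    stop("cutoff_frac must be in (0, 1)")
  if (lam <= 0) stop("lam must be > 0")
  if (lam1 < 0) stop("lam1 must be >= 0")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be positive")
  if (tol <= 0) stop("tol must be positive")
  structure(list(filter_order = filter_order, cutoff_frac = cutoff_frac,
                 lam = lam, lam1 = lam1, p = p, max_iter = max_iter,
                 tol = tol, peak_direction = peak_direction),
            class = "preprocess_config")
}

# Steady-state initial conditions for an IIR filter (direct form II
# transposed), so a constant input produces a constant output from sample one.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  # companion matrix of a, transposed
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Direct form II transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2)
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase low-pass smoothing
#'
#' Applies a Butterworth low-pass filter forward and then backward so the net
#' phase is zero: smooth features keep their positions and a constant signal
#' passes through unchanged (unit DC gain). Edge transients are suppressed by
#' odd-reflection padding of length three times the filter length, together
#' with steady-state initial filter conditions.
#'
#' @param s a [spectrum()].
#' @param order Butterworth order (default 3).
#' @param cutoff_frac cutoff as a fraction of Nyquist, in (0, 1).
#' @return The smoothed [spectrum()] on the same grid.
#' @export
smooth_zero_phase <- function(s, order = 3, cutoff_frac = 0.1) {
  stopifnot(inherits(s, "spectrum"))
  if (cutoff_frac <= 0 || cutoff_frac >= 1)
    stop("cutoff_frac must be in (0, 1)")
  bf <- signal::butter(order, cutoff_frac, type = "low")
  b <- bf$b; a <- bf$a
  nfilt <- max(length(a), length(b))
  pad <- 3 * nfilt
  y <- s$intensities
  n <- length(y)
  if (n <= pad)
    stop("spectrum too short for zero-phase padding (need > ", pad, " points)")
  # odd reflection about the end points
  front <- 2 * y[1] - y[(pad + 1):2]
  back <- 2 * y[n] - y[(n - 1):(n - pad)]
  ext <- c(front, y, back)
  zi <- filter_zi(b, a)
  fwd <- iir_filter(b, a, ext, zi * ext[1])
  rev_in <- rev(fwd)
  bwd <- iir_filter(b, a, rev_in, zi * rev_in[1])
  out <- rev(bwd)[(pad + 1):(pad + n)]
  spectrum(s$wavenumbers, out, s$meta)
}

# squared magnitude response of the forward-backward filter at normalized
# frequency f (fraction of Nyquist); used as an independent check in tests
filtfilt_gain <- function(b, a, f) {
  w <- pi * f
  z <- exp(-1i * w)
  H <- sapply(z, function(zz) {
    sum(b * zz^(seq_along(b) - 1)) / sum(a * zz^(seq_along(a) - 1))
  })
  Mod(H)^2
}

sparse_diff <- function(n, d) {
  D <- Matrix::bandSparse(n - 1, n, k = 0:1,
                          diagonals = list(rep(-1, n - 1), rep(1, n - 1)))
  if (d == 1) return(D)
  D2 <- Matrix::bandSparse(n - 2, n - 1, k = 0:1,
                           diagonals = list(rep(-1, n - 2), rep(1, n - 2)))
  D2 %*% D
}

#' Improved asymmetric least squares (IASLS) baseline estimation
#'
#' Estimates a smooth baseline `z` under the Whittaker penalty by iterating
#' the linear system
#' \deqn{(W + \lambda D_2^T D_2 + \lambda_1 D_1^T D_1)\, z =
#'       (W + \lambda_1 D_1^T D_1)\, y}
#' where \eqn{D_1, D_2} are first/second difference operators and
#' \eqn{W = \mathrm{diag}(w_i)} with \eqn{w_i = p} on the peak side of the
#' current baseline and \eqn{1 - p} elsewhere. The weights are initialized by
#' an ordinary asymmetric least squares pass, and the iteration stops when the
#' relative change of the weight vector drops below `tol` or `max_iter` is
#' reached. With `peak_direction = "down"` the signal is negated before the
#' asymmetric weighting so absorption dips end up below the baseline.
#'
#' Straight lines lie in the null space of both difference penalties, so a
#' band-free linear signal is reproduced exactly; as `lam` grows the baseline
#' tends to the asymmetric-weighted least squares straight line.
#'
#' @param s a [spectrum()].
#' @param cfg a [preprocess_config()].
#' @return An object of class `baseline_result`: list with `baseline`,
#'   `corrected` (= original - baseline), `n_iter`, `converged`.
#' @export
baseline_iasls <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectrum"), inherits(cfg, "preprocess_config"))
  y0 <- s$intensities
  flip <- cfg$peak_direction == "down"
  y <- if (flip) -y0 else y0
  n <- length(y)
  D1 <- sparse_diff(n, 1)
  D2 <- sparse_diff(n, 2)
  P2 <- cfg$lam * Matrix::crossprod(D2)
  P1 <- cfg$lam1 * Matrix::crossprod(D1)
  P1y <- as.vector(P1 %*% y)
  # plain AsLS warm start for the weights
  w <- rep(1, n)
  for (i in 1:10) {
    z <- as.vector(Matrix::solve(Matrix::Diagonal(x = w) + P2, w * y))
    wn <- ifelse(y > z, cfg$p, 1 - cfg$p)
    if (identical(wn, w)) break
    w <- wn
  }
  n_iter <- 0L; converged <- FALSE
  z <- y
  for (i in seq_len(cfg$max_iter)) {
    n_iter <- i
    A <- Matrix::Diagonal(x = w) + P2 + P1
    z <- tryCatch(as.vector(Matrix::solve(A, w * y + P1y)),
                  error = function(e)
                    stop("IASLS linear system could not be solved ",
                         "(degenerate grid?): ", conditionMessage(e)))
    wn <- ifelse(y > z, cfg$p, 1 - cfg$p)
    rel <- sqrt(sum((wn - w)^2)) / sqrt(sum(w^2))
    w <- wn
    if (rel < cfg$tol) { converged <- TRUE; break }
  }
  baseline <- if (flip) -z else z
  structure(list(baseline = baseline, corrected = y0 - baseline,
                 n_iter = n_iter, converged = converged),
            class = "baseline_result")
}

#' Smooth and baseline-correct a spectrum
#'
#' The composed preprocessing stage: zero-phase smoothing first, then IASLS
#' baseline subtraction. Metadata is preserved. The output intensities are the
#' baseline-corrected residual signal (absorption dips are negative when
#' `peak_direction = "down"`).
#'
#' @param s a [spectrum()].
#' @param cfg a [preprocess_config()].
#' @return The corrected [spectrum()].
#' @export
correct_spectrum <- function(s, cfg = preprocess_config()) {
  sm <- smooth_zero_phase(s, cfg$filter_order, cfg$cutoff_frac)
  bl <- baseline_iasls(sm, cfg)
  spectrum(s$wavenumbers, bl$corrected, s$meta)
}

#' Min/max normalization
#'
#' Maps intensities affinely onto \[0, 1\]: the minimum to 0 and the maximum
#' to 1. Invariant under any affine transform of the input; idempotent.
#'
#' @param s a [spectrum()].
#' @return The normalized [spectrum()].
#' @export
normalize_minmax <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  rng <- range(s$intensities)
  if (diff(rng) == 0) stop("cannot min/max normalize a constant spectrum")
  spectrum(s$wavenumbers, (s$intensities - rng[1]) / diff(rng), s$meta)
}

#' Z-score each row of a spectrum set
#'
#' Each row is centred to mean 0 and scaled to standard deviation 1 using the
#' population convention (divisor `n`). A constant row cannot be scaled; it is
#' set to all zeros with a warning.
#'
#' @param set a [spectrum_set()].
#' @return A [spectrum_set()] with z-scored rows.
#' @export
zscore_rows <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- set$intensities
  n <- ncol(X)
  mu <- rowMeans(X)
  sd_pop <- sqrt(rowMeans((X - mu)^2))
  Z <- (X - mu) / sd_pop
  if (any(sd_pop == 0)) {
    warning("constant row(s) set to zero: ",
            paste(which(sd_pop == 0), collapse = ", "))
    Z[sd_pop == 0, ] <- 0
  }
  spectrum_set(set$grid, Z, set$meta)
}
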