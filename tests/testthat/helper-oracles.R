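# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# O(n^2) time-domain cross-correlation of two mean-centred signals,
# normalized by the product of centred norms; lags -(n-1)..(n-1).
bf_xcorr <- function(a, b) {
  a0 <- a - mean(a); b0 <- b - mean(b)
  n <- length(a0)
  lags <- -(n - 1):(n - 1)
  amp <- vapply(lags, function(k) {
    t_idx <- seq_len(n)
    keep <- t_idx + k >= 1 & t_idx + k <= n
    sum(a0[t_idx[keep] + k] * b0[t_idx[keep]])
  }, numeric(1))
  amp / (sqrt(sum(a0^2)) * sqrt(sum(b0^2)))
}

# exhaustive contour-line prominence of every interior local maximum of y
bf_prominences <- function(y) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  prom <- vapply(idx, function(i) {
    higher_left <- which(y[1:(i - 1)] > y[i])
    lo_l <- if (length(higher_left)) min(y[(max(higher_left) + 1):i])
            else min(y[1:i])
    higher_right <- which(y[(i + 1):n] > y[i]) + i
    lo_r <- if (length(higher_right)) min(y[i:(min(higher_right) - 1)])
            else min(y[i:n])
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

# exhaustive overlap-region search: enumerate one peak per list, keep
# combinations with max-min <= tol, merge the resulting intervals, widen by
# tol/2
bf_overlap <- function(pos_list, tol) {
  if (any(!lengths(pos_list))) return(data.frame(lo = numeric(0), hi = numeric(0)))
  combos <- expand.grid(pos_list)
  span_ok <- apply(combos, 1, function(v) max(v) - min(v) <= tol)
  if (!any(span_ok)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  ivl <- t(apply(combos[span_ok, , drop = FALSE], 1, range))
  ivl <- ivl[order(ivl[, 1]), , drop = FALSE]
  merged <- ivl[1, , drop = FALSE]
  if (nrow(ivl) > 1) for (k in 2:nrow(ivl)) {
    last <- nrow(merged)
    if (ivl[k, 1] <= merged[last, 2])
      merged[last, 2] <- max(merged[last, 2], ivl[k, 2])
    else merged <- rbind(merged, ivl[k, ])
  }
  data.frame(lo = merged[, 1] - tol / 2, hi = merged[, 2] + tol / 2)
}

# squared filtfilt magnitude response from the filter polynomials (direct
# evaluation on the unit circle, independent of the time-domain code)
bf_filtfilt_gain <- function(order, cutoff_frac, f) {
  bf <- signal::butter(order, cutoff_frac, type = "low")
  z <- exp(-1i * pi * f)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}

# short test grid and a quick line + dips spectrum builder
tiny_grid <- function(n = 301, lo = 4000, hi = 7000) seq(lo, hi, length.out = n)

line_dips_spectrum <- function(grid, intercept = 1, slope = 5e-5,
                               centers = numeric(0), depths = numeric(0),
                               sigmas = 30, noise_sd = 0) {
  y <- intercept + slope * (grid - min(grid))
  sigmas <- rep_len(sigmas, length(centers))
  for (k in seq_along(centers))
    y <- y - depths[k] * exp(-(grid - centers[k])^2 / (2 * sigmas[k]^2))
  if (noise_sd > 0) y <- y + rnorm(length(grid), 0, noise_sd)
  spectrum(grid, y)
}
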