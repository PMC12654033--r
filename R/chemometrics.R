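#' Labeled intensity matrix
#'
#' Container pairing an `n_samples x n_features` intensity matrix with its
#' wavenumber axis and one label per row (biomarker type, stage, or sample
#' id).
#'
#' @param X numeric matrix, samples in rows.
#' @param feature_axis wavenumber vector, one value per column.
#' @param y label vector, one value per row.
#' @return An object of class `labeled_matrix`.
#' @export
labeled_matrix <- function(X, feature_axis, y) {
  X <- as.matrix(X)
  if (length(feature_axis) != ncol(X))
    stop("feature_axis length must equal the number of columns")
  if (length(y) != nrow(X))
    stop("y must have one label per row")
  structure(list(X = X, feature_axis = as.numeric(feature_axis), y = y),
            class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("<labeled_matrix> %d samples x %d features, %d label level(s)\n",
              nrow(x$X), ncol(x$X), length(unique(x$y))))
  invisible(x)
}

#' Normalized cross-correlation of two spectra via the FFT
#'
#' Both signals are mean-centred, cross-correlated in the frequency domain
#' (zero-padded to at least `2n - 1`), and normalized by the product of the
#' centred Euclidean norms, so the amplitude at lag 0 equals the Pearson
#' correlation of the two signals and all amplitudes lie in \[-1, 1\].
#' Amplitude at lag `k` corresponds to `sum(a[t + k] * b[t])` over the valid
#' overlap, lags running from `-(n-1)` to `n-1` grid steps.
#'
#' @param a,b [spectrum()] objects on identical grids.
#' @param pair_label optional label for the pair (e.g. `"10:20"`).
#' @return List of class `cross_correlogram` with `lags`, `amplitudes`,
#'   `lag0`, `pair_label`.
#' @export
cross_correlate <- function(a, b, pair_label = NA_character_) {
  stopifnot(inherits(a, "spectrum"), inherits(b, "spectrum"))
  if (!isTRUE(all.equal(a$wavenumbers, b$wavenumbers)))
    stop("spectra must share an identical wavenumber grid")
  a0 <- a$intensities - mean(a$intensities)
  b0 <- b$intensities - mean(b$intensities)
  na <- sqrt(sum(a0^2)); nb <- sqrt(sum(b0^2))
  if (na == 0 || nb == 0) stop("zero-variance signal; correlation undefined")
  n <- length(a0)
  nfft <- 2^ceiling(log2(2 * n - 1))
  A <- stats::fft(c(a0, rep(0, nfft - n)))
  B <- stats::fft(c(b0, rep(0, nfft - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / nfft
  # cc[1 + k] = sum_t a0[t + k] b0[t] for k >= 0; negative lags wrap around
  r <- c(cc[(nfft - n + 2):nfft], cc[1:n])
  amp <- r / (na * nb)
  lags <- -(n - 1):(n - 1)
  structure(list(lags = lags, amplitudes = amp, lag0 = amp[lags == 0],
                 pair_label = pair_label),
            class = "cross_correlogram")
}

#' @export
print.cross_correlogram <- function(x, ...) {
  cat(sprintf("<cross_correlogram> %s lag0 = %.3f (%d lags)\n",
              if (is.na(x$pair_label)) "" else paste0(x$pair_label, ":"),
              x$lag0, length(x$lags)))
  invisible(x)
}

#' Pairwise lag-0 cross-correlation table for a spectrum set
#'
#' Computes [cross_correlate()] lag-0 amplitudes for either consecutive
#' concentration pairs (rows sorted by ascending concentration, labels like
#' `"10:20"`) or all pairs, expressed as percentages.
#'
#' @param set a [spectrum_set()] with at least 2 rows.
#' @param pairing `"adjacent_concentrations"` or `"all_pairs"`.
#' @return Data frame with `pair_label` and `lag0_pct`.
#' @export
pairwise_fcc <- function(set, pairing = c("adjacent_concentrations",
                                          "all_pairs")) {
  stopifnot(inherits(set, "spectrum_set"))
  pairing <- match.arg(pairing)
  n <- nrow(set$intensities)
  if (n < 2) stop("need at least 2 spectra")
  lab <- function(i) {
    ci <- set$meta$concentration[i]
    if (!is.na(ci)) format(ci) else as.character(set$meta$sample_id[i])
  }
  if (pairing == "adjacent_concentrations") {
    conc <- set$meta$concentration
    if (any(is.na(conc)))
      stop("adjacent_concentrations pairing requires concentrations in the metadata")
    o <- order(conc)
    pairs <- cbind(o[-length(o)], o[-1])
  } else {
    pairs <- t(utils::combn(n, 2))
  }
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    cc <- cross_correlate(set_spectrum(set, i), set_spectrum(set, j),
                          pair_label = paste(lab(i), lab(j), sep = ":"))
    data.frame(pair_label = cc$pair_label, lag0_pct = 100 * cc$lag0)
  })
  do.call(rbind, out)
}

encode_response <- function(y) {
  if (is.numeric(y)) return(matrix(y, ncol = 1))
  f <- factor(y)
  if (nlevels(f) < 2) stop("response has fewer than 2 levels")
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL
  Y
}

#' PLS latent-variable extraction (NIPALS)
#'
#' Extracts `k` partial least squares components maximizing covariance
#' between the centred feature matrix and the (indicator-encoded) response,
#' using the standard iterative NIPALS algorithm with deflation after each
#' component. Score columns are mutually orthogonal; the first weight vector
#' is the dominant left singular vector of `t(X) %*% Y`.
#'
#' @param m a [labeled_matrix()]; categorical labels are one-hot encoded.
#' @param k number of components, at most `min(n_samples - 1, n_features)`.
#' @param tol,max_iter inner NIPALS iteration controls.
#' @return List of class `pls_model` with `scores` (n x k), `loadings`
#'   (p x k), `weights`, `y_loadings`, `rotation` (so new scores are
#'   `(X - x_mean) %*% rotation`), `x_mean`, `y_mean`.
#' @export
fit_pls_scores <- function(m, k, tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(m, "labeled_matrix"))
  X <- m$X
  n <- nrow(X); p <- ncol(X)
  if (k > min(n - 1, p))
    stop("k must be <= min(n_samples - 1, n_features) = ", min(n - 1, p))
  Y <- encode_response(m$y)
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xc <- sweep(X, 2, x_mean)
  Yc <- sweep(Y, 2, y_mean)
  W <- matrix(0, p, k); P <- matrix(0, p, k)
  Tm <- matrix(0, n, k); Q <- matrix(0, ncol(Y), k)
  for (comp in seq_len(k)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    w <- rep(0, p)
    for (it in seq_len(max_iter)) {
      w_new <- as.vector(crossprod(Xc, u))
      nw <- sqrt(sum(w_new^2))
      if (nw == 0) stop("degenerate component ", comp, ": zero weight vector")
      w_new <- w_new / nw
      t_vec <- as.vector(Xc %*% w_new)
      q <- as.vector(crossprod(Yc, t_vec)) / sum(t_vec^2)
      u_new <- as.vector(Yc %*% q) / sum(q^2)
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new; u <- u_new
      if (delta < tol) break
    }
    t_vec <- as.vector(Xc %*% w)
    q <- as.vector(crossprod(Yc, t_vec)) / sum(t_vec^2)
    p_vec <- as.vector(crossprod(Xc, t_vec)) / sum(t_vec^2)
    Xc <- Xc - tcrossprod(t_vec, p_vec)
    Yc <- Yc - tcrossprod(t_vec, q)
    W[, comp] <- w; P[, comp] <- p_vec; Tm[, comp] <- t_vec; Q[, comp] <- q
  }
  rotation <- W %*% solve(crossprod(P, W))
  structure(list(scores = Tm, loadings = P, weights = W, y_loadings = Q,
                 rotation = rotation, x_mean = x_mean, y_mean = y_mean),
            class = "pls_model")
}

#' Scores of new observations under a fitted PLS model
#' @param object a `pls_model` from [fit_pls_scores()].
#' @param newdata numeric matrix with the same feature columns.
#' @param ... unused.
#' @return Score matrix (rows x components).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata), 2, object$x_mean) %*% object$rotation
}

# Ridge-stabilized linear discriminant analysis on (low-dimensional) scores.
# Pooled within-class covariance; when it is not positive definite a ridge of
# eps * trace/dim is added to the diagonal.
lda_fit <- function(scores, y, ridge_eps = 1e-6) {
  y <- factor(y)
  scores <- as.matrix(scores)
  d <- ncol(scores)
  means <- do.call(rbind, lapply(levels(y), function(l)
    colMeans(scores[y == l, , drop = FALSE])))
  n <- nrow(scores); g <- nlevels(y)
  Sw <- matrix(0, d, d)
  for (l in levels(y)) {
    xs <- scores[y == l, , drop = FALSE]
    xs <- sweep(xs, 2, colMeans(xs))
    Sw <- Sw + crossprod(xs)
  }
  Sw <- Sw / max(n - g, 1)
  ridged <- FALSE
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch)) {
    Sw <- Sw + diag(ridge_eps * max(sum(diag(Sw)), .Machine$double.eps) / d,
                    d)
    ridged <- TRUE
    ch <- chol(Sw)
  }
  Sinv <- chol2inv(ch)
  priors <- as.vector(table(y)) / n
  list(levels = levels(y), means = means, Sinv = Sinv,
       log_priors = log(priors), ridged = ridged)
}

lda_predict <- function(fit, scores) {
  scores <- as.matrix(scores)
  disc <- vapply(seq_along(fit$levels), function(c_) {
    mu <- fit$means[c_, ]
    as.vector(scores %*% (fit$Sinv %*% mu)) -
      0.5 * sum(mu * (fit$Sinv %*% mu)) + fit$log_priors[c_]
  }, numeric(nrow(scores)))
  disc <- matrix(disc, nrow = nrow(scores))
  fit$levels[max.col(disc, ties.method = "first")]
}

# stratified fold assignment: per class, shuffle members and deal folds
# round-robin (uses the current RNG stream)
stratified_folds <- function(y, n_splits) {
  y <- factor(y)
  fold <- integer(length(y))
  for (l in levels(y)) {
    idx <- which(y == l)
    if (length(idx) < n_splits)
      stop("class '", l, "' has fewer members (", length(idx),
           ") than n_splits = ", n_splits)
    fold[sample(idx)] <- rep_len(seq_len(n_splits), length(idx))
  }
  fold
}

#' PLS-LDA classification under repeated stratified cross-validation
#'
#' For each component count `k` in `1..k_max`, runs repeated stratified
#' k-fold cross-validation: folds are re-randomized on every repeat from the
#' seeded RNG, stratification preserves class proportions per fold, and within
#' each fold the PLS projection is fitted on the training rows only, train and
#' test rows are projected, and an LDA classifier (pooled within-class
#' covariance, ridge-stabilized when singular) is fitted on the training
#' scores and evaluated on the test rows. Defaults mirror the
#' type-discrimination preset (`n_splits = 4`, `n_repeats = 100`, seed 1); a
#' staging-style analysis uses `n_splits = 2`.
#'
#' Calling this function sets the session RNG seed (reproducibility contract:
#' with the same seed, fold assignments are identical across runs).
#'
#' @param m a [labeled_matrix()] with a categorical `y`; every class needs at
#'   least `n_splits` members.
#' @param k_max largest number of PLS components to evaluate.
#' @param n_splits folds per repeat.
#' @param n_repeats number of repeats.
#' @param seed RNG seed.
#' @return List of class `cv_report`: `per_k` (data frame `k`,
#'   `mean_accuracy`, `sd_accuracy`, `max_accuracy`), `best_k`,
#'   `best_accuracy` (max mean accuracy), `cv_params`, and `folds` (list of
#'   per-repeat fold assignments).
#' @export
pls_lda_cv <- function(m, k_max = 3, n_splits = 4, n_repeats = 100,
                       seed = 1) {
  stopifnot(inherits(m, "labeled_matrix"))
  y <- factor(m$y)
  set.seed(seed)
  folds <- lapply(seq_len(n_repeats), function(r) stratified_folds(y, n_splits))
  acc <- matrix(NA_real_, nrow = n_splits * n_repeats, ncol = k_max)
  for (k in seq_len(k_max)) {
    row <- 0
    for (r in seq_len(n_repeats)) {
      fold <- folds[[r]]
      for (f in seq_len(n_splits)) {
        row <- row + 1
        tr <- fold != f; te <- !tr
        mt <- labeled_matrix(m$X[tr, , drop = FALSE],
                             m$feature_axis, as.character(y[tr]))
        pls <- fit_pls_scores(mt, k)
        lda <- lda_fit(pls$scores, y[tr])
        pred <- lda_predict(lda, predict(pls, m$X[te, , drop = FALSE]))
        acc[row, k] <- mean(pred == as.character(y[te]))
      }
    }
  }
  per_k <- data.frame(k = seq_len(k_max),
                      mean_accuracy = colMeans(acc),
                      sd_accuracy = apply(acc, 2, stats::sd),
                      max_accuracy = apply(acc, 2, max))
  best_k <- which.max(per_k$mean_accuracy)
  structure(list(per_k = per_k, best_k = best_k,
                 best_accuracy = per_k$mean_accuracy[best_k],
                 cv_params = list(n_splits = n_splits, n_repeats = n_repeats,
                                  seed = seed),
                 folds = folds),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> best mean accuracy %.3f at k = %d (%d-fold x %d repeats, seed %d)\n",
    x$best_accuracy, x$best_k, x$cv_params$n_splits, x$cv_params$n_repeats,
    x$cv_params$seed))
  print(x$per_k, row.names = FALSE)
  invisible(x)
}

#' Principal component scores of a labeled matrix
#'
#' Column-centred singular value decomposition (no scaling). Scores are
#' translation-invariant: adding a constant spectrum to every row changes
#' nothing.
#'
#' @param m a [labeled_matrix()].
#' @param n_pc number of components to return (at most the matrix rank).
#' @return List with `scores` (n x n_pc), `explained` (variance fractions,
#'   sum <= 1), and `labels` (= `m$y`).
#' @export
pca_scores <- function(m, n_pc = 2) {
  stopifnot(inherits(m, "labeled_matrix"))
  if (nrow(m$X) < 2) stop("need at least 2 samples")
  pr <- stats::prcomp(m$X, center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-10)
  if (n_pc > rank) stop("n_pc = ", n_pc, " exceeds the matrix rank ", rank)
  var_frac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_pc), drop = FALSE],
       explained = var_frac[seq_len(n_pc)], labels = m$y)
}

#' Z-scored heatmap matrix of a spectrum set
#'
#' Each scan (row) is z-score normalized via [zscore_rows()]; the result is a
#' [labeled_matrix()] with the wavenumber grid as feature axis and sample ids
#' as labels, ready for CSV export or rendering with an image/heatmap layer.
#'
#' @param set a [spectrum_set()].
#' @return A [labeled_matrix()].
#' @export
heatmap_matrix <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  z <- zscore_rows(set)
  labeled_matrix(z$intensities, z$grid, as.character(z$meta$sample_id))
}
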