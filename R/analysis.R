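# Population-coding analyses: cross-validated PCA eigenspectra and power-law
# fits, PLS-reduced discriminability d' with noise-covariance geometry,
# subsampling-robust branching-ratio estimation, Fano factors, rate
# distributions.

#' Cross-validated PCA eigenspectrum
#'
#' Given two repeats `X1`, `X2` (stimuli x neurons) of the same stimulus
#' ensemble, computes the eigenvectors `V` of the covariance of `X1` (via
#' SVD) and the cross-validated eigenvalues
#' `lambda_j = sum_i X1t[i, j] * X2t[i, j] / (S - 1)` of the projections
#' `Xkt = Xk V`. Only stimulus-locked variance survives the cross-repeat
#' product, so `lambda` estimates the signal variance along each component;
#' with `X2 = X1` it equals the ordinary PCA variance spectrum.
#'
#' @param X1,X2 Response matrices, stimuli x neurons (trial-averaged halves).
#' @param center Center both repeats by the column means of `X1`.
#'   Default TRUE.
#' @return Numeric vector of cross-validated eigenvalues, component order.
#' @export
cvpca <- function(X1, X2, center = TRUE) {
  if (!all(dim(X1) == dim(X2))) stop("repeats must have identical shape")
  S <- nrow(X1)
  if (center) {
    mu <- colMeans(X1)
    X1 <- sweep(X1, 2, mu); X2 <- sweep(X2, 2, mu)
  }
  V <- svd(X1)$v
  colSums((X1 %*% V) * (X2 %*% V)) / (S - 1)
}

#' Cross-validated eigenspectrum from repeated trials
#'
#' Splits the trials of each stimulus into two halves at random, averages
#' within each half, applies [cvpca()], and averages the spectrum over
#' `n_splits` random splits.
#'
#' @param responses Array stimuli x neurons x trials (trials >= 2).
#' @param n_splits Number of random half-splits. Default 10.
#' @param seed Integer seed.
#' @return Averaged cross-validated eigenvalue spectrum.
#' @export
cvpca_repeats <- function(responses, n_splits = 10, seed = 1) {
  stopifnot(length(dim(responses)) == 3, dim(responses)[3] >= 2)
  set.seed(seed)
  R <- dim(responses)[3]
  acc <- NULL
  for (k in seq_len(n_splits)) {
    idx <- sample.int(R, R %/% 2)
    X1 <- apply(responses[, , idx, drop = FALSE], c(1, 2), mean)
    X2 <- apply(responses[, , -idx, drop = FALSE], c(1, 2), mean)
    lam <- cvpca(X1, X2)
    acc <- if (is.null(acc)) lam else acc + lam
  }
  acc / n_splits
}

#' Power-law fit of an eigenspectrum
#'
#' Fits `f(n) = c * n^-alpha` by ordinary least squares in log10-log10 space
#' over every window `[n_min, n_max]` from the supplied grids and returns the
#' fit maximizing R^2. A fit is `flagged` when no window reaches
#' `R^2 > 0.99`.
#'
#' @param spectrum Positive eigenvalue vector (component order).
#' @param nmin_grid Candidate lower bounds. Default `1:20` (clipped).
#' @param nmax_grid Candidate upper bounds. Default `301 .. length` when the
#'   spectrum is long enough, otherwise an adapted upper range.
#' @param r2_threshold Acceptance threshold on R^2. Default 0.99.
#' @return List of class `power_law_fit`: `alpha`, `n_min`, `n_max`, `r2`,
#'   `flagged`.
#' @export
fit_power_law <- function(spectrum, nmin_grid = NULL, nmax_grid = NULL,
                          r2_threshold = 0.99) {
  L <- length(spectrum)
  if (is.null(nmin_grid)) nmin_grid <- seq_len(min(20L, max(1L, L %/% 4)))
  if (is.null(nmax_grid)) {
    nmax_grid <- if (L > 320) 301:L else max(nmin_grid[1] + 3, L %/% 2):L
  }
  keep <- spectrum > 0
  x <- log10(seq_len(L)); y <- log10(pmax(spectrum, .Machine$double.xmin))
  # prefix sums for O(1) OLS over any index window
  cx <- cumsum(x * keep); cy <- cumsum(y * keep)
  cxx <- cumsum(x^2 * keep); cyy <- cumsum(y^2 * keep)
  cxy <- cumsum(x * y * keep); cn <- cumsum(as.numeric(keep))
  best <- list(r2 = -Inf)
  for (n0 in nmin_grid) {
    lo <- if (n0 > 1) c(cx[n0 - 1], cy[n0 - 1], cxx[n0 - 1], cyy[n0 - 1],
                        cxy[n0 - 1], cn[n0 - 1]) else rep(0, 6)
    nm <- nmax_grid[nmax_grid > n0 + 1]
    if (length(nm) == 0) next
    m <- cn[nm] - lo[6]
    sx <- cx[nm] - lo[1]; sy <- cy[nm] - lo[2]
    sxx <- cxx[nm] - lo[3]; syy <- cyy[nm] - lo[4]; sxy <- cxy[nm] - lo[5]
    vx <- sxx - sx^2 / m; vy <- syy - sy^2 / m; vxy <- sxy - sx * sy / m
    ok <- m >= 3 & vx > 0 & vy > 0
    r2 <- ifelse(ok, vxy^2 / (vx * vy), -Inf)
    j <- which.max(r2)
    if (length(j) && r2[j] > best$r2) {
      best <- list(alpha = -vxy[j] / vx[j], n_min = n0, n_max = nm[j],
                   r2 = r2[j])
    }
  }
  if (!is.finite(best$r2)) stop("spectrum too short for the requested grids")
  best$flagged <- best$r2 <= r2_threshold
  structure(best, class = "power_law_fit")
}

#' Partial least squares dimensionality reduction
#'
#' Projects trial responses onto the top label-covariant dimensions
#' (PLS regression of the responses on the two-class label), retaining
#' `n_components` dimensions (default 5). Used before d' estimation when
#' trials are scarce relative to neurons.
#'
#' @param X Trials x neurons matrix of spike counts (e.g. 200-ms bins).
#' @param labels Two-class label per trial.
#' @param n_components Dimensions to retain. Default 5.
#' @return List: `scores` (trials x n_components), `loadings`
#'   (neurons x n_components), `labels`.
#' @export
pls_reduce <- function(X, labels, n_components = 5) {
  stopifnot(nrow(X) == length(labels))
  if (nrow(X) <= n_components) stop("fewer trials than components")
  y <- as.numeric(as.factor(labels)) - 1
  if (length(unique(y)) != 2) stop("labels must have exactly two classes")
  fit <- mixOmics::pls(X, y, ncomp = n_components, scale = FALSE)
  list(scores = unname(as.matrix(fit$variates$X)),
       loadings = unname(as.matrix(fit$loadings$X)),
       labels = labels)
}

#' Discriminability index d' between two response ensembles
#'
#' `(d')^2 = dmu' Sigma^-1 dmu` with `dmu = mean(A) - mean(B)` and
#' `Sigma = (Sigma_A + Sigma_B) / 2` the trial-to-trial (noise) covariance
#' averaged over conditions (1/(N-1) estimator). Also returns the
#' eigendecomposition of `Sigma`, the optimal discrimination axis
#' `w_opt = Sigma^-1 dmu`, the signal-to-noise decomposition
#' `(d')^2 = sum_beta |dmu . e_beta|^2 / lambda_beta`, and optionally the
#' trial-shuffled variant (responses of each neuron independently permuted
#' across trials within class, which destroys noise correlations).
#'
#' @param A,B Trials x dimensions response matrices (>= 2 trials each).
#' @param shuffle Also compute the shuffled (d')^2. Default FALSE.
#' @param seed Seed for the shuffling permutations.
#' @return List of class `dprime_result`: `dprime2`, `dmu`, `Sigma`, `w_opt`,
#'   `evalues`, `evectors`, `projections` (|dmu . e_beta| in descending
#'   eigenvalue order), `snr_terms`, and `dprime2_shuffled` if requested.
#' @export
dprime <- function(A, B, shuffle = FALSE, seed = 1) {
  stopifnot(nrow(A) >= 2, nrow(B) >= 2, ncol(A) == ncol(B))
  dmu <- colMeans(A) - colMeans(B)
  Sigma <- (stats::cov(A) + stats::cov(B)) / 2
  eg <- eigen(Sigma, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!all(pos)) warning("singular noise covariance; using pseudo-inverse")
  inv_vals <- ifelse(pos, 1 / eg$values, 0)
  w_opt <- eg$vectors %*% (inv_vals * crossprod(eg$vectors, dmu))
  proj <- abs(as.numeric(crossprod(eg$vectors, dmu)))
  snr <- ifelse(pos, proj^2 * inv_vals, 0)
  out <- list(dprime2 = sum(dmu * w_opt), dmu = dmu, Sigma = Sigma,
              w_opt = as.numeric(w_opt), evalues = eg$values,
              evectors = eg$vectors, projections = proj, snr_terms = snr)
  if (shuffle) {
    set.seed(seed)
    shuf <- function(M) apply(M, 2, function(col) col[sample.int(length(col))])
    sh <- dprime(shuf(A), shuf(B))
    out$dprime2_shuffled <- sh$dprime2
  }
  structure(out, class = "dprime_result")
}

#' Signal projections onto the noise eigenvectors
#'
#' Profile of `|dmu . e_beta|` against the noise-eigenvector rank `beta`
#' (descending eigenvalue order). Signal nearly orthogonal to the dominant
#' noise dimensions yields a profile that is small at low `beta`.
#'
#' @param dp A [dprime()] result.
#' @param normalize Divide by `|dmu|`. Default TRUE.
#' @return data.frame: `beta`, `evalue`, `projection`, `snr`.
#' @export
noise_signal_geometry <- function(dp, normalize = TRUE) {
  stopifnot(inherits(dp, "dprime_result"))
  p <- dp$projections
  if (normalize) p <- p / sqrt(sum(dp$dmu^2))
  data.frame(beta = seq_along(p), evalue = dp$evalues, projection = p,
             snr = dp$snr_terms)
}

#' Branching-ratio estimate from (subsampled) population counts
#'
#' For each lag `k = 1..k_max`, computes the linear-regression slope `m_k` of
#' `a[t+k]` on `a[t]`, then fits `m_k = b * m^k` by nonlinear least squares
#' (initialized from the log-linear slope). Under stationary subsampling the
#' multiplicative bias `b` absorbs the subsampling distortion, so `m` is
#' recovered where the naive lag-1 slope is biased low. `m < 1` indicates a
#' subcritical regime, `m = 1` critical, `m > 1` supercritical.
#'
#' @param a Integer/numeric vector of population counts per 1-ms bin.
#' @param k_max Maximal lag. Default 40.
#' @return List of class `branching_fit`: `m`, `b`, `m_k`, `k_max`,
#'   `failed` (TRUE when most slopes are non-positive).
#' @export
branching_ratio <- function(a, k_max = 40) {
  stopifnot(length(a) > k_max + 1)
  T <- length(a)
  m_k <- vapply(seq_len(k_max), function(k) {
    x <- a[seq_len(T - k)]; y <- a[(k + 1):T]
    stats::cov(x, y) / stats::var(x)
  }, numeric(1))
  failed <- mean(m_k > 0) < 0.5
  k <- seq_len(k_max)
  pos <- m_k > 0
  init <- stats::coef(stats::lm(log(m_k[pos]) ~ k[pos]))
  start <- list(b = exp(unname(init[1])), m = exp(unname(init[2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(m_k ~ b * m^k, start = start,
                      lower = c(b = 1e-8, m = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    m <- unname(cf["m"]); b <- unname(cf["b"])
  } else {
    m <- start$m; b <- start$b
  }
  structure(list(m = m, b = b, m_k = m_k, k_max = k_max, failed = failed),
            class = "branching_fit")
}

#' Naive lag-1 branching estimate (for bias comparison)
#' @param a Count series.
#' @return The lag-1 regression slope.
#' @export
branching_ratio_naive <- function(a) {
  T <- length(a)
  stats::cov(a[-T], a[-1]) / stats::var(a[-T])
}

#' Fano factor of windowed spike counts
#'
#' Spike counts in non-overlapping windows (default 10 ms), variance/mean
#' across repeated trials of identical input, averaged over windows and then
#' over neurons with nonzero mean count.
#'
#' @param rasters Array neurons x time x trials (>= 2 trials), or list of
#'   neuron x time matrices.
#' @param window Window length in ms. Default 10.
#' @return List: `fano` (grand average), `per_neuron` (vector, NA where the
#'   neuron never fires).
#' @export
fano_factor <- function(rasters, window = 10) {
  if (is.list(rasters)) {
    rasters <- array(unlist(rasters),
                     c(nrow(rasters[[1]]), ncol(rasters[[1]]), length(rasters)))
  }
  stopifnot(length(dim(rasters)) == 3, dim(rasters)[3] >= 2)
  n <- dim(rasters)[1]; T <- dim(rasters)[2]; R <- dim(rasters)[3]
  nw <- T %/% window
  stopifnot(nw >= 1)
  # counts: neurons x windows x trials
  counts <- array(0, c(n, nw, R))
  for (w in seq_len(nw)) {
    cols <- ((w - 1) * window + 1):(w * window)
    counts[, w, ] <- apply(rasters[, cols, , drop = FALSE], c(1, 3), sum)
  }
  mu <- apply(counts, c(1, 2), mean)
  va <- apply(counts, c(1, 2), stats::var)
  ff <- ifelse(mu > 0, va / mu, NA)
  per_neuron <- rowMeans(ff, na.rm = TRUE)
  per_neuron[!is.finite(per_neuron)] <- NA
  list(fano = mean(per_neuron, na.rm = TRUE), per_neuron = per_neuron)
}

#' Per-neuron firing rates and a log-binned histogram
#'
#' @param raster Binary matrix neurons x time (1-ms bins).
#' @param duration_ms Recording length; default `ncol(raster)`.
#' @param n_bins Histogram bins (log-spaced over the positive rates).
#' @return List: `rates_hz` per neuron, `histogram` (data.frame mid, count).
#' @export
rate_distribution <- function(raster, duration_ms = ncol(raster),
                              n_bins = 20) {
  rates <- rowSums(raster) / duration_ms * 1000
  pos <- rates[rates > 0]
  hist_df <- if (length(pos) >= 2 && min(pos) < max(pos)) {
    br <- exp(seq(log(min(pos)), log(max(pos)), length.out = n_bins + 1))
    h <- graphics::hist(pos, breaks = br, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  } else {
    data.frame(mid = numeric(0), count = integer(0))
  }
  list(rates_hz = rates, histogram = hist_df)
}

#' Global linear readout baseline
#'
#' Least-squares linear readout (`Y = W Z + B`) from the response-window
#' spike counts of *all* neurons, fitted by ridge-regularized regression on
#' the class indicator matrix: the upper-bound readout convention against
#' which the biologically constrained pool readout is compared.
#'
#' @param counts Trials x neurons matrix of response-window counts.
#' @param labels Class label per trial.
#' @param lambda Ridge penalty. Default 1e-3.
#' @return List with `predict(counts)` function and training `accuracy`.
#' @export
global_linear_readout <- function(counts, labels, lambda = 1e-3) {
  y <- as.factor(labels)
  Y <- stats::model.matrix(~ y - 1)
  X <- cbind(1, counts)
  XtX <- crossprod(X) + lambda * diag(ncol(X))
  W <- solve(XtX, crossprod(X, Y))
  pred_fun <- function(newc) {
    scores <- cbind(1, newc) %*% W
    levels(y)[max.col(scores)]
  }
  list(predict = pred_fun,
       accuracy = mean(pred_fun(counts) == as.character(y)))
}

#' Build response matrices for eigenspectrum analysis from simulations
#'
#' Presents each image of an ensemble twice (independent noise draws),
#' sums spikes over a 500-ms window starting at stimulus onset, and returns
#' the two stimuli x neurons repeats.
#'
#' @param network A `glif_network`.
#' @param ensemble Image array from [make_image_ensemble()].
#' @param bank An [lgn_filter_bank()].
#' @param noise A [noise_model()].
#' @param onset_ms Stimulus onset (ms). Default 50.
#' @param window_ms Count window (ms). Default 500.
#' @param seed Integer seed.
#' @return List `X1`, `X2` (stimuli x neurons spike counts).
#' @export
response_matrices <- function(network, ensemble, bank, noise = noise_model(),
                              onset_ms = 50, window_ms = 500, seed = 1) {
  S <- dim(ensemble)[3]
  n <- nrow(network$neurons)
  T <- onset_ms + window_ms
  X1 <- matrix(0, S, n); X2 <- matrix(0, S, n)
  for (s in seq_len(S)) {
    frames <- matrix(0, dim(ensemble)[1] * dim(ensemble)[2], T)
    frames[, (onset_ms + 1):T] <- as.vector(scale_image(ensemble[, , s]))
    stim <- visual_stimulus(frames, H = dim(ensemble)[1], W = dim(ensemble)[2])
    cur <- stimulus_currents(network, stim, bank)
    for (rep in 1:2) {
      sim <- simulate_network(network, cur, noise, T = T,
                              seed = seed + 2L * s + rep)
      cnt <- rowSums(sim$spikes[, (onset_ms + 1):T, drop = FALSE])
      if (rep == 1) X1[s, ] <- cnt else X2[s, ] <- cnt
    }
  }
  list(X1 = X1, X2 = X2)
}
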