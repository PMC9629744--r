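# Synthetic fixtures: every input the simulations and analyses assume,
# generated from (parameters, seed) so that no external data are needed.

#' Heavy-tailed noise-current distribution
#'
#' Returns a sampler for a zero-centered, symmetric, heavy-tailed current
#' distribution (pA): a Student-t with `df` degrees of freedom, truncated at
#' `+/- trunc` scale units and multiplied by `scale`. This is a synthetic
#' stand-in for an empirical noise-amplitude distribution decoded from awake
#' V1 recordings; its excess kurtosis is positive for `df <= 10`.
#'
#' @param scale Multiplicative scale (pA per unit draw). The default (50)
#'   makes the standard q = s = 2 noise amplitudes produce millivolt-scale
#'   membrane jitter in the GLIF_3 networks of this package.
#' @param df Degrees of freedom (> 2 so the variance exists). Default 3.
#' @param trunc Truncation bound in unit-scale draws. Default 50.
#' @return A function `f(n)` returning `n` i.i.d. draws (numeric, pA), with
#'   attributes `scale`, `df`, `trunc`.
#' @export
make_noise_distribution <- function(scale = 50, df = 3, trunc = 50) {
  stopifnot(df > 2, scale >= 0, trunc > 0)
  f <- function(n) {
    x <- stats::rt(n, df = df)
    # redraw the rare tail excursions beyond the truncation bound
    bad <- which(abs(x) > trunc)
    while (length(bad) > 0) {
      x[bad] <- stats::rt(length(bad), df = df)
      bad <- bad[abs(x[bad]) > trunc]
    }
    scale * x
  }
  attr(f, "scale") <- scale
  attr(f, "df") <- df
  attr(f, "trunc") <- trunc
  class(f) <- c("noise_distribution", class(f))
  f
}

#' Ensemble of 1/f-filtered texture images
#'
#' Generates `n_images` grayscale textures of `size x size` pixels whose radial
#' amplitude spectrum falls off as `1/f^spectrum_slope` (slope 0 gives white
#' noise). Values are normalized to \[0, 255\]. With `d` set, the ensemble is
#' rank-limited: all images lie in a `d`-dimensional pixel subspace, which is
#' the construction used to probe how eigenspectrum decay depends on the
#' dimensionality of the stimulus ensemble.
#'
#' @param n_images Number of images (>= 2).
#' @param size Image side length in pixels.
#' @param spectrum_slope Exponent of the radial amplitude falloff. Default 1.
#' @param d Optional subspace dimensionality limit.
#' @param seed Integer seed; the ensemble is reproducible from it.
#' @return Array `size x size x n_images`, values in \[0, 255\].
#' @export
make_image_ensemble <- function(n_images, size = 32, spectrum_slope = 1,
                                d = NULL, seed = 1) {
  stopifnot(n_images >= 2, size >= 4)
  set.seed(seed)
  fx <- stats::fft  # alias
  # radial frequency grid (cycles per image)
  f1 <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1)) / size
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- ifelse(fr == 0, 0, fr^(-spectrum_slope))
  imgs <- array(0, c(size, size, n_images))
  for (i in seq_len(n_images)) {
    white <- matrix(stats::rnorm(size * size), size)
    spec <- fx(white) * amp
    im <- Re(fx(spec, inverse = TRUE)) / (size * size)
    imgs[, , i] <- im
  }
  if (!is.null(d)) {
    stopifnot(d >= 1, d <= n_images)
    # project the stack onto its top-d principal pixel directions
    m <- matrix(imgs, nrow = size * size, ncol = n_images)
    sv <- svd(m, nu = d, nv = d)
    m <- sv$u %*% (diag(sv$d[seq_len(d)], d) %*% t(sv$v))
    imgs <- array(m, c(size, size, n_images))
  }
  lo <- min(imgs); hi <- max(imgs)
  imgs <- (imgs - lo) / (hi - lo) * 255
  imgs
}

#' Response-matrix pair with a planted power-law signal spectrum
#'
#' Constructs two repeats `X1`, `X2` (stimuli x neurons) sharing a signal whose
#' stimulus covariance has eigenvalues exactly `n^-alpha` for the first `rank`
#' components, plus independent Gaussian repeat noise. With `noise_level = 0`
#' the cross-validated spectrum of the pair equals the planted spectrum, which
#' makes the pair an end-to-end oracle for eigenspectrum estimation.
#'
#' @param S Number of stimuli. @param N Number of neurons.
#' @param alpha Planted power-law exponent.
#' @param noise_level SD of the additive repeat noise.
#' @param rank Number of planted components (default `min(S, N) - 1`).
#' @param seed Integer seed.
#' @return List with matrices `X1`, `X2` (S x N) and the planted `spectrum`.
#' @export
make_planted_spectrum_responses <- function(S, N, alpha = 1, noise_level = 0,
                                            rank = NULL, seed = 1) {
  if (is.null(rank)) rank <- min(S, N) - 1L
  stopifnot(S > rank, N >= rank, rank >= 1)
  set.seed(seed)
  lam <- seq_len(rank)^(-alpha)
  # stimulus scores: mean-zero orthonormal columns scaled so that the sample
  # covariance (1/(S-1), centered) of the signal is exactly Q diag(lam) Q'
  Z <- matrix(stats::rnorm(S * rank), S)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- qr.Q(qr(Z)) * sqrt(S - 1)
  Q <- qr.Q(qr(matrix(stats::rnorm(N * rank), N)))
  signal <- Z %*% (diag(sqrt(lam), rank) %*% t(Q))
  X1 <- signal + noise_level * matrix(stats::rnorm(S * N), S)
  X2 <- signal + noise_level * matrix(stats::rnorm(S * N), S)
  list(X1 = X1, X2 = X2, spectrum = lam)
}

#' Driven branching process with binomial subsampling
#'
#' Simulates `A[t+1] ~ Poisson(m * A[t] + h)` for `T` steps and an observed
#' subsample `a[t] ~ Binomial(A[t], subsample_prob)`. The pair is the standard
#' ground-truth fixture for branching-ratio estimation: the full series has
#' conditional mean `m * A[t] + h`, the subsample biases naive lag-1 slope
#' estimates but not the multi-lag exponential fit.
#'
#' @param m Branching parameter (>= 0).
#' @param h Mean external drive per step (>= 0).
#' @param T Number of time steps.
#' @param subsample_prob Probability that an event is observed. Default 1.
#' @param A0 Initial count (default `max(1, round(h / max(1 - m, 0.01)))`).
#' @param cap Guard cap on counts for explosive settings. Default 1e7.
#' @param seed Integer seed.
#' @return List with integer vectors `A` (full) and `a` (subsampled), length T.
#' @export
make_branching_process <- function(m, h, T, subsample_prob = 1,
                                   A0 = NULL, cap = 1e7, seed = 1) {
  stopifnot(m >= 0, h >= 0, T >= 2, subsample_prob >= 0, subsample_prob <= 1)
  set.seed(seed)
  if (is.null(A0)) A0 <- max(1, round(h / max(1 - m, 0.01)))
  A <- integer(T)
  A[1] <- as.integer(min(A0, cap))
  for (t in seq_len(T - 1)) {
    A[t + 1] <- as.integer(min(stats::rpois(1, m * A[t] + h), cap))
  }
  a <- stats::rbinom(T, A, subsample_prob)
  list(A = A, a = a)
}

# ---- glyph ensemble -------------------------------------------------------

# stroke templates on a [0,1]^2 canvas, one per class (10 digit-like glyphs);
# each row of a template is a segment (x0, y0, x1, y1)
.glyph_templates <- function() {
  seg <- function(...) matrix(c(...), ncol = 4, byrow = TRUE)
  list(
    seg(.3,.2,.7,.2, .7,.2,.7,.8, .7,.8,.3,.8, .3,.8,.3,.2),              # 0 box
    seg(.5,.2,.5,.8, .5,.8,.35,.65),                                      # 1
    seg(.3,.7,.7,.7, .7,.7,.7,.5, .7,.5,.3,.3, .3,.3,.3,.2, .3,.2,.7,.2), # 2
    seg(.3,.8,.7,.8, .7,.8,.5,.5, .5,.5,.7,.3, .7,.3,.3,.2),              # 3
    seg(.65,.2,.65,.8, .65,.8,.3,.4, .3,.4,.75,.4),                       # 4
    seg(.7,.8,.3,.8, .3,.8,.3,.55, .3,.55,.7,.55, .7,.55,.7,.2, .7,.2,.3,.2), # 5
    seg(.65,.8,.35,.5, .35,.5,.35,.25, .35,.25,.65,.25, .65,.25,.65,.45,
        .65,.45,.35,.45),                                                 # 6
    seg(.3,.8,.7,.8, .7,.8,.45,.2),                                       # 7
    seg(.4,.5,.6,.5, .6,.5,.65,.7, .65,.7,.35,.7, .35,.7,.4,.5,
        .4,.5,.3,.3, .3,.3,.7,.3, .7,.3,.6,.5),                           # 8
    seg(.65,.55,.35,.55, .35,.55,.35,.75, .35,.75,.65,.75, .65,.75,.65,.3,
        .65,.3,.4,.2)                                                     # 9
  )
}

# rasterize line segments with a Gaussian pen onto a size x size grid
.render_strokes <- function(segs, size, stroke_sd) {
  gx <- (seq_len(size) - 0.5) / size
  img <- matrix(0, size, size)
  for (k in seq_len(nrow(segs))) {
    p0 <- segs[k, 1:2]; p1 <- segs[k, 3:4]
    len <- sqrt(sum((p1 - p0)^2))
    npts <- max(2L, ceiling(len * size * 2))
    tt <- seq(0, 1, length.out = npts)
    xs <- p0[1] + tt * (p1[1] - p0[1])
    ys <- p0[2] + tt * (p1[2] - p0[2])
    for (i in seq_len(npts)) {
      dx2 <- (gx - xs[i])^2
      dy2 <- (gx - ys[i])^2
      img <- pmax(img, exp(-outer(dy2, dx2, "+") / (2 * stroke_sd^2)))
    }
  }
  img
}

#' Procedural 10-class glyph ensemble
#'
#' Renders stroke-based glyphs for 10 classes (digit-like shapes) with
#' per-sample jitter, rotation and scale variation: a synthetic substitute for
#' a handwritten-digit dataset in the 10-way image classification task.
#'
#' @param n_per_class Samples per class.
#' @param size Image side length in pixels. Default 32.
#' @param jitter SD of center jitter in canvas units. Default 0.04.
#' @param rot_sd SD of rotation (radians). Default 0.15.
#' @param scale_sd SD of log scale. Default 0.08.
#' @param seed Integer seed.
#' @return List: `images` (size x size x (10*n_per_class), values in
#'   \[0, 255\]) and `labels` (integer 0..9 per image).
#' @export
make_glyph_ensemble <- function(n_per_class, size = 32, jitter = 0.04,
                                rot_sd = 0.15, scale_sd = 0.08, seed = 1) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  tmpl <- .glyph_templates()
  n <- 10L * n_per_class
  imgs <- array(0, c(size, size, n))
  labels <- integer(n)
  i <- 0L
  for (cls in 0:9) {
    for (r in seq_len(n_per_class)) {
      i <- i + 1L
      segs <- tmpl[[cls + 1]]
      th <- stats::rnorm(1, 0, rot_sd)
      sc <- exp(stats::rnorm(1, 0, scale_sd))
      dx <- stats::rnorm(1, 0, jitter); dy <- stats::rnorm(1, 0, jitter)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      tf <- function(p) {
        p <- sweep(p, 2, c(.5, .5))
        p <- sc * p %*% t(R)
        sweep(p, 2, c(.5 + dx, .5 + dy), "+")
      }
      s2 <- cbind(tf(segs[, 1:2, drop = FALSE]), tf(segs[, 3:4, drop = FALSE]))
      imgs[, , i] <- .render_strokes(s2, size, stroke_sd = 0.03)
      labels[i] <- cls
    }
  }
  list(images = imgs * 255, labels = labels)
}

#' Write a fixture manifest
#'
#' Records kind, parameters and seed of a generated fixture as JSON so any
#' fixture file can be regenerated from its manifest.
#'
#' @param path Output JSON path.
#' @param kind Fixture kind string.
#' @param parameters Named list of parameters.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
write_fixture_manifest <- function(path, kind, parameters, seed) {
  jsonlite::write_json(list(kind = kind, parameters = parameters, seed = seed),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
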