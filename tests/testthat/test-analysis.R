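# Coding analyses: cvPCA vs PCA oracle, power-law recovery, PLS, d-prime
# identities and invariances, branching-ratio estimation, Fano factors.

test_that("cvPCA equals ordinary PCA when repeats coincide", {
  set.seed(1)
  X <- matrix(rnorm(80 * 30), 80, 30) %*% diag(seq(3, 0.1, length.out = 30))
  lam <- cvpca(X, X)
  pca_var <- prcomp(X, center = TRUE, scale. = FALSE)$sdev^2
  expect_equal(lam, pca_var, tolerance = 1e-10)
  # rotation-invariant trace identity (centered with X1 means)
  set.seed(2)
  Y <- X + matrix(rnorm(80 * 30), 80, 30)
  lam2 <- cvpca(X, Y)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu); Yc <- sweep(Y, 2, mu)
  expect_equal(sum(lam2), sum(Xc * Yc) / (nrow(X) - 1), tolerance = 1e-10)
  expect_error(cvpca(X, Y[1:10, ]), "shape")
})

test_that("trial-split cvPCA recovers a planted spectrum from repeats", {
  set.seed(20)
  pl <- make_planted_spectrum_responses(S = 80, N = 40, alpha = 1,
                                        noise_level = 0, rank = 10, seed = 21)
  # six noisy trials around the same signal; half-splits average the noise
  resp <- array(0, c(80, 40, 6))
  for (r in 1:6) resp[, , r] <- pl$X1 + 0.3 * matrix(rnorm(80 * 40), 80)
  lam <- cvpca_repeats(resp, n_splits = 5, seed = 22)
  expect_equal(lam[1:10], (1:10)^(-1), tolerance = 0.1)
  expect_lt(mean(abs(lam[20:39])), 0.02)
})

test_that("power-law fitter is exact on pure power laws", {
  lam <- (1:500)^(-1)
  fit <- fit_power_law(lam)
  expect_equal(fit$alpha, 1, tolerance = 1e-10)
  expect_gt(fit$r2, 1 - 1e-12)
  expect_false(fit$flagged)
  fit2 <- fit_power_law((1:400)^(-1.5))
  expect_equal(fit2$alpha, 1.5, tolerance = 1e-10)
})

test_that("power-law fitter recovers planted exponents within 0.05 at 1% noise", {
  set.seed(3)
  for (alpha in c(0.8, 1, 1.0625, 1.5)) {
    lam <- (1:600)^(-alpha) * exp(rnorm(600, 0, 0.01))
    fit <- fit_power_law(lam)
    expect_lt(abs(fit$alpha - alpha), 0.05)
  }
})

test_that("end-to-end planted spectrum -> cvPCA -> power-law fit recovers alpha", {
  pl <- make_planted_spectrum_responses(S = 700, N = 500, alpha = 1.0625,
                                        noise_level = 0.01, rank = 450,
                                        seed = 4)
  lam <- cvpca(pl$X1, pl$X2)
  fit <- fit_power_law(lam[lam > 0], nmin_grid = 1:10,
                       nmax_grid = 200:400)
  expect_lt(abs(fit$alpha - 1.0625), 0.05)
})

test_that("PLS recovers a planted informative direction", {
  set.seed(5)
  n <- 300; p <- 100
  w <- rnorm(p); w <- w / sqrt(sum(w^2))
  y <- rep(0:1, each = n / 2)
  X <- 2 * outer(2 * y - 1, w) + matrix(rnorm(n * p), n, p)
  red <- pls_reduce(X, y, n_components = 5)
  expect_equal(dim(red$scores), c(n, 5))
  cosang <- abs(sum(red$loadings[, 1] * w)) /
    sqrt(sum(red$loadings[, 1]^2))
  expect_gt(cosang, 0.9)
  # identical class distributions: held-out projections do not separate
  X0 <- matrix(rnorm(n * p), n, p)
  red0 <- pls_reduce(X0, y, n_components = 5)
  Xte <- matrix(rnorm(n * p), n, p)
  proj <- Xte %*% red0$loadings[, 1]
  sep <- abs(mean(proj[y == 1]) - mean(proj[y == 0])) / stats::sd(proj)
  expect_lt(sep, 0.5)
  expect_error(pls_reduce(X[1:4, ], y[1:4], n_components = 5), "fewer trials")
})

test_that("(d')^2 matches the 1-D closed form and its decomposition identity", {
  set.seed(6)
  A <- matrix(rnorm(500, 0, 0.5), 500, 1)
  B <- matrix(rnorm(500, 1, 0.5), 500, 1)
  dp <- dprime(A, B)
  expect_equal(dp$dprime2, 4, tolerance = 0.35)  # (1/0.5)^2, sampling error
  # Eq.-style identity: quadratic form == SNR decomposition, machine precision
  set.seed(7)
  A5 <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5)
  B5 <- sweep(matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5), 2, -1)
  dp5 <- dprime(A5, B5)
  expect_equal(dp5$dprime2, sum(dp5$snr_terms), tolerance = 1e-10)
  expect_equal(as.numeric(dp5$Sigma %*% dp5$w_opt), dp5$dmu,
               tolerance = 1e-8)
  # identical means: zero discriminability
  set.seed(8)
  C <- matrix(rnorm(100 * 3), 100, 3)
  dp0 <- dprime(C, C)
  expect_equal(dp0$dprime2, 0)
})

test_that("(d')^2 is invariant under common invertible linear maps", {
  set.seed(9)
  A <- matrix(rnorm(300 * 4), 300, 4)
  B <- sweep(matrix(rnorm(300 * 4), 300, 4), 2, c(1, 0, -1, 2), "+")
  d0 <- dprime(A, B)$dprime2
  for (k in 1:5) {
    M <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
    dk <- dprime(A %*% M, B %*% M)$dprime2
    expect_equal(dk, d0, tolerance = 1e-6)
  }
})

test_that("shuffling removes information-limiting correlations", {
  # shared noise along dmu limits d'; per-neuron trial shuffling removes it
  set.seed(10)
  n <- 400; p <- 20
  dmu <- rep(1 / sqrt(p), p)
  common <- rnorm(2 * n, 0, 1.5)   # shared fluctuation along dmu
  E <- matrix(rnorm(2 * n * p, 0, 0.5), 2 * n, p)
  X <- outer(common, dmu) + E
  A <- X[1:n, ]
  B <- sweep(X[(n + 1):(2 * n), ], 2, dmu, "+")
  dp <- dprime(A, B, shuffle = TRUE, seed = 2)
  expect_gt(dp$dprime2_shuffled, dp$dprime2)
})

test_that("noise-signal geometry profile behaves as constructed", {
  # anisotropic noise with the signal along the smallest eigenvector
  set.seed(11)
  n <- 2000
  sds <- c(4, 2, 1, 0.5, 0.25)
  E1 <- sapply(sds, function(s) rnorm(n, 0, s))
  E2 <- sapply(sds, function(s) rnorm(n, 0, s))
  dmu <- c(0, 0, 0, 0, 3)
  dp <- dprime(E1, sweep(E2, 2, dmu, "+"))
  geo <- noise_signal_geometry(dp, normalize = FALSE)
  expect_true(all(diff(geo$evalue) <= 0))
  # projections bounded by |dmu| (Cauchy-Schwarz, unit eigenvectors)
  expect_true(all(geo$projection <= sqrt(sum(dp$dmu^2)) + 1e-8))
  # profile concentrated on the smallest-eigenvalue component
  expect_equal(which.max(geo$projection), 5)
  expect_lt(max(geo$projection[1:4]), 0.2 * geo$projection[5])
})

test_that("branching ratio is exact on a noiseless geometric sequence", {
  m0 <- 0.8
  a <- 1000 * m0^(0:200) + 1e-9
  fit <- branching_ratio(a, k_max = 20)
  expect_equal(fit$m, m0, tolerance = 1e-6)
  expect_false(fit$failed)
})

test_that("multi-lag estimator survives subsampling where lag-1 slope is biased", {
  ms <- sapply(1:5, function(s) {
    bp <- make_branching_process(m = 0.9, h = 10, T = 1e5,
                                 subsample_prob = 0.05, seed = s)
    c(branching_ratio(bp$a, k_max = 40)$m, branching_ratio_naive(bp$a))
  })
  expect_gt(mean(ms[1, ]), 0.88)
  expect_lt(mean(ms[1, ]), 0.92)
  expect_lt(mean(ms[2, ]), 0.6)   # naive lag-1 estimate biased far low
})

test_that("branching estimate is stable across subsampling fractions", {
  est <- sapply(c(0.02, 0.1, 0.5), function(p) {
    mean(sapply(1:3, function(s) {
      bp <- make_branching_process(m = 0.85, h = 20, T = 6e4,
                                   subsample_prob = p, seed = 10 * s)
      branching_ratio(bp$a, k_max = 40)$m
    }))
  })
  expect_true(all(abs(est - 0.85) < 0.03))
})

test_that("Fano factor: Poisson ~ 1, deterministic = 0, rate mixture > 1", {
  r <- poisson_rasters(n = 60, T = 600, R = 20, rate_hz = 40, seed = 12)
  ff <- fano_factor(r, window = 10)
  expect_equal(ff$fano, 1, tolerance = 0.05)
  # identical trials: zero variance
  one <- matrix(rbinom(60 * 200, 1, 0.05), 60, 200)
  det <- array(rep(one, 5), c(60, 200, 5))
  expect_equal(fano_factor(det)$fano, 0)
  # rate mixing: half the trials at rate 2p, half at 0: Fano = 1 + mu_half
  set.seed(13)
  lo <- 20 / 1000; hi <- 60 / 1000
  mix <- array(0, c(40, 500, 10))
  for (k in 1:10) {
    p <- if (k <= 5) lo else hi
    mix[, , k] <- matrix(rbinom(40 * 500, 1, p), 40, 500)
  }
  ffm <- fano_factor(mix, window = 10)
  # analytic: window counts ~ mixture of Bin(10, lo) and Bin(10, hi)
  mu <- 10 * (lo + hi) / 2
  va <- mean(c(10 * lo * (1 - lo), 10 * hi * (1 - hi))) +
    (10 * lo - mu)^2
  expect_equal(ffm$fano, va / mu, tolerance = 0.1)
})

test_that("rate distribution: arithmetic and conservation", {
  r <- matrix(0, 5, 600)
  r[2, 100] <- 1
  rd <- rate_distribution(r)
  expect_equal(rd$rates_hz[2], 1 / 0.6, tolerance = 1e-10)
  expect_equal(rd$rates_hz[1], 0)
  set.seed(14)
  r2 <- matrix(rbinom(50 * 400, 1, 0.02), 50, 400)
  rd2 <- rate_distribution(r2)
  expect_equal(sum(rd2$rates_hz) * 0.4, sum(r2), tolerance = 1e-9)
})

test_that("global linear readout separates linearly separable counts", {
  set.seed(15)
  X <- rbind(matrix(rpois(200 * 20, 3), 200, 20),
             matrix(rpois(200 * 20, 6), 200, 20))
  y <- rep(c("a", "b"), each = 200)
  glr <- global_linear_readout(X, y)
  expect_gt(glr$accuracy, 0.9)
})
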