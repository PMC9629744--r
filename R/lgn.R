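# LGN-style front end: grayscale movies -> nonnegative firing-rate traces
# through a small bank of center-surround spatiotemporal filters.

#' Visual stimulus container
#'
#' @param frames `H x W x T` array (or `npix x T` matrix) of pixel values at
#'   1-ms resolution.
#' @param H,W Raster dimensions (required when `frames` is a matrix).
#' @return List of class `visual_stimulus` with `frames` (npix x T matrix),
#'   `H`, `W`, `duration`.
#' @export
visual_stimulus <- function(frames, H = NULL, W = NULL) {
  if (length(dim(frames)) == 3) {
    H <- dim(frames)[1]; W <- dim(frames)[2]
    frames <- matrix(frames, H * W, dim(frames)[3])
  }
  stopifnot(!is.null(H), !is.null(W), nrow(frames) == H * W)
  structure(list(frames = frames, H = H, W = W, duration = ncol(frames)),
            class = "visual_stimulus")
}

#' Scale raw pixel values into a symmetric interval
#'
#' Affine map \[0, 255\] -> \[-Int, +Int\]; multi-channel input is converted
#' to grayscale first by averaging channels. Mid-gray (127.5) maps to 0.
#'
#' @param raw Matrix/array of raw pixel values in \[0, 255\]; an `H x W x 3`
#'   array is treated as a color image.
#' @param Int Half-width of the target interval (> 0). Default 2.
#' @return Scaled values in \[-Int, Int\], same spatial shape.
#' @export
scale_image <- function(raw, Int = 2) {
  stopifnot(Int > 0)
  if (length(dim(raw)) == 3 && dim(raw)[3] %in% c(3, 4)) {
    raw <- apply(raw[, , 1:3, drop = FALSE], c(1, 2), mean)
  }
  (raw / 255 * 2 - 1) * Int
}

#' Build an LGN-style filter bank
#'
#' Units of four classes (sustained-ON, sustained-OFF, transient-ON/OFF,
#' transient-OFF/ON) tile an oval in the central part of the raster on an
#' `n_grid x n_grid` lattice. Spatial receptive fields are
#' difference-of-Gaussians (center minus surround, integrating to ~0);
#' temporal kernels are an exponential low-pass (sustained, time constant
#' `tau_sus` ms) or a biphasic difference of exponentials (transient,
#' `tau_fast`/`tau_slow` ms). Outputs are rectified at 0.
#'
#' @param H,W Raster dimensions in pixels.
#' @param n_grid Lattice side; the bank has `4 * n_grid^2` units. Default 8.
#' @param sigma_c,sigma_s Center/surround SD in pixels. Defaults 1.2 / 2.8.
#' @param tau_sus Sustained low-pass time constant (ms). Default 50.
#' @param tau_fast,tau_slow Transient biphasic time constants (ms). 20 / 40.
#' @param kernel_len Temporal kernel length (ms). Default 150.
#' @param gain Output gain mapping filter drive to firing rate in Hz;
#'   the default (1000) puts peak responses to full-contrast stimuli in the
#'   tens-to-hundreds of Hz.
#' @return List of class `lgn_filter_bank`: spatial matrix `K`
#'   (units x npix), per-unit `class`, unit centers, temporal kernels.
#' @export
lgn_filter_bank <- function(H = 32, W = 32, n_grid = 8,
                            sigma_c = 1.2, sigma_s = 2.8,
                            tau_sus = 50, tau_fast = 20, tau_slow = 40,
                            kernel_len = 150, gain = 1000) {
  classes <- c("sustained_on", "sustained_off", "transient_onoff",
               "transient_offon")
  # unit centers on a lattice inside the central oval
  cx <- W / 2 + (W / 2 - 2) * seq(-0.8, 0.8, length.out = n_grid)
  cy <- H / 2 + (H / 2 - 2) * seq(-0.8, 0.8, length.out = n_grid)
  grid <- expand.grid(y = cy, x = cx)
  inside <- ((grid$x - W / 2) / (W / 2 - 1))^2 +
    ((grid$y - H / 2) / (H / 2 - 1))^2 <= 0.82^2
  grid <- grid[inside, ]
  px <- expand.grid(row = seq_len(H), col = seq_len(W))
  dog <- function(cx0, cy0) {
    r2 <- (px$col - cx0)^2 + (px$row - cy0)^2
    k <- exp(-r2 / (2 * sigma_c^2)) / (2 * pi * sigma_c^2) -
      exp(-r2 / (2 * sigma_s^2)) / (2 * pi * sigma_s^2)
    k - mean(k)  # exact zero integral on the finite raster
  }
  nu <- nrow(grid) * 4L
  K <- matrix(0, nu, H * W)
  cls <- character(nu); centers <- matrix(0, nu, 2)
  i <- 0L
  for (u in seq_len(nrow(grid))) {
    k0 <- dog(grid$x[u], grid$y[u])
    for (cl in classes) {
      i <- i + 1L
      sgn <- if (cl %in% c("sustained_off", "transient_offon")) -1 else 1
      K[i, ] <- gain * sgn * k0
      cls[i] <- cl
      centers[i, ] <- c(grid$x[u], grid$y[u])
    }
  }
  u <- seq_len(kernel_len) - 1
  k_sus <- exp(-u / tau_sus); k_sus <- k_sus / sum(k_sus)  # unit DC gain
  e1 <- exp(-u / tau_fast); e2 <- exp(-u / tau_slow)
  k_tr <- e1 / sum(e1) - e2 / sum(e2)                      # exact zero DC
  structure(list(K = K, class = cls, centers = centers,
                 H = H, W = W,
                 kernels = list(sustained = k_sus, transient = k_tr)),
            class = "lgn_filter_bank")
}

# causal convolution of each column of x (T x m) with kernel k, zero-padded
.causal_filter <- function(x, k) {
  pad <- matrix(0, length(k) - 1, ncol(x))
  y <- stats::filter(rbind(pad, x), k, method = "convolution", sides = 1)
  matrix(y[-seq_len(length(k) - 1), ], ncol = ncol(x))
}

#' LGN filter-bank response to a stimulus
#'
#' Per unit: spatial inner product with each frame, causal temporal
#' convolution with the class kernel, then rectification at zero. The
#' pre-rectification traces are linear in the stimulus.
#'
#' @param bank An [lgn_filter_bank()].
#' @param stimulus A [visual_stimulus()] with *scaled* frames
#'   (see [scale_image()]).
#' @param rectify Rectify the output at 0 (default TRUE). `FALSE` exposes the
#'   linear drive, e.g. for superposition checks.
#' @return `units x T` matrix of rates (per ms, >= 0 when rectified).
#' @export
lgn_response <- function(bank, stimulus, rectify = TRUE) {
  stopifnot(inherits(bank, "lgn_filter_bank"),
            inherits(stimulus, "visual_stimulus"),
            bank$H == stimulus$H, bank$W == stimulus$W)
  drive <- bank$K %*% stimulus$frames           # units x T
  out <- matrix(0, nrow(drive), ncol(drive))
  sus <- grepl("^sustained", bank$class)
  if (any(sus)) {
    out[sus, ] <- t(.causal_filter(t(drive[sus, , drop = FALSE]),
                                   bank$kernels$sustained))
  }
  if (any(!sus)) {
    out[!sus, ] <- t(.causal_filter(t(drive[!sus, , drop = FALSE]),
                                    bank$kernels$transient))
  }
  if (rectify) out <- pmax(out, 0)
  out
}

#' Convert front-end rates into per-neuron input currents
#'
#' `I_sti(t) = W_in %*% rates(t)`. In bypass mode (the no-LGN control) the
#' *scaled pixel values* are injected directly: the sparsity pattern of
#' `W_in` selects which pixels reach which neuron, each with unit weight
#' multiplied by `bypass_scale` (default 0.04).
#'
#' @param W_in Input weight matrix, neurons x units (or neurons x pixels in
#'   bypass mode).
#' @param rates `units x T` rate matrix (or `npix x T` scaled pixels).
#' @param bypass Inject pixels directly. Default FALSE.
#' @param bypass_scale Pixel scale factor in bypass mode. Default 0.04.
#' @return `neurons x T` matrix of currents (pA).
#' @export
input_currents <- function(W_in, rates, bypass = FALSE, bypass_scale = 0.04) {
  if (ncol(W_in) != nrow(rates)) stop("W_in columns must match rate rows")
  if (bypass) {
    W_in <- (W_in != 0) * 1
    rates <- bypass_scale * rates
  }
  as.matrix(W_in %*% rates)
}

#' Stimulus currents for a network
#'
#' Convenience wrapper: runs the front end appropriate for the network's
#' input mode (`"lgn"`: filter bank responses; `"pixels"`: direct scaled
#' pixel injection) and maps the result through the network's input weights.
#'
#' @param network A `glif_network`.
#' @param stimulus A [visual_stimulus()] with scaled frames.
#' @param bank An [lgn_filter_bank()] (ignored in pixel mode).
#' @return `neurons x T` current matrix (pA).
#' @export
stimulus_currents <- function(network, stimulus, bank) {
  tnW <- Matrix::sparseMatrix(i = network$input$post, j = network$input$unit,
                              x = network$input$weight,
                              dims = c(nrow(network$neurons), network$n_inputs))
  if (identical(network$input_mode, "pixels")) {
    input_currents(tnW, stimulus$frames, bypass = TRUE,
                   bypass_scale = network$bypass_scale)
  } else {
    input_currents(tnW, lgn_response(bank, stimulus))
  }
}
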