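# Independent oracles used across tests: scalar-loop reimplementations of the
# update equations, closed forms, and small hand-built networks.

# Scalar brute-force simulation of a single neuron (no synapses): literal
# loops over the membrane / after-spike-current / refractory equations.
scalar_glif_oracle <- function(p, Ie, T) {
  alpha <- exp(-1 / (p$C / p$g))
  beta <- (1 - alpha) / p$g
  f1 <- exp(-p$k1); f2 <- exp(-p$k2)
  v <- p$E_L; i1 <- 0; i2 <- 0; cnt <- 0L
  z_out <- numeric(T); v_out <- numeric(T)
  for (t in 1:T) {
    v_out[t] <- v
    z <- as.numeric(v >= p$v_th && cnt == 0)
    cnt <- max(cnt - 1L, 0L)
    if (z == 1) cnt <- as.integer(ceiling(p$t_ref))
    i1 <- f1 * i1 + p$dI1 * z
    i2 <- f2 * i2 + p$dI2 * z
    ie <- if (t < T) Ie[t + 1] else 0
    v <- alpha * v + beta * (ie + i1 + i2 + p$g * p$E_L + 0) -
      z * (p$v_th - p$E_L)
    z_out[t] <- z
  }
  list(z = z_out, v = v_out)
}

# Hand iteration of the two synaptic recursions for a single presynaptic
# spike train (weights w, delay d, time constant tau): literal transcription.
scalar_alpha_synapse <- function(z_pre, w, d, tau, T) {
  kap <- exp(-1 / tau)
  cr <- 0; is <- 0
  out <- numeric(T)
  for (t in 1:T) {
    out[t] <- is
    zd <- if (t + 1 - d >= 1 && t + 1 - d <= length(z_pre)) {
      z_pre[t + 1 - d]
    } else 0
    is_new <- kap * (is + cr)
    cr <- kap * cr + w * zd * exp(1) / tau
    is <- is_new
  }
  out
}

# minimal hand-built two-neuron network (1 -> 2), for step-level tests
tiny_two_neuron_net <- function(w = 5, delay = 2L, tau_syn = 5,
                                win = c(3, 3)) {
  lib <- glif3_parameter_library("minimal")
  structure(list(
    neurons = data.frame(id = 1:2, class = c("L4e", "L5e"),
                         layer = c("L4", "L5"), sign = 1L, x = c(0, 50),
                         y = 0, param_type = 1L),
    edges = data.frame(pre = 1L, post = 2L, weight = w, delay = delay,
                       tau_syn = tau_syn),
    input = data.frame(unit = 1:2, post = 1:2, weight = win),
    params = lib, config = NULL, seed = 1, n_inputs = 2L,
    input_mode = "lgn", bypass_scale = 0.04, sign_constrained = TRUE,
    variant = "laminar"), class = "glif_network")
}

# small laminar config used by many tests
small_config <- function(n = 40, ...) {
  network_config(layers = c("L2/3" = n, "L4" = n, "L5" = n), ...)
}

# Poisson raster fixture: n neurons x T ms x R trials at rate_hz
poisson_rasters <- function(n, T, R, rate_hz, seed = 1) {
  set.seed(seed)
  array(stats::rbinom(n * T * R, 1, rate_hz / 1000), c(n, T, R))
}
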