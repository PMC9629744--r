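# Discrete-time (1-ms) GLIF_3 dynamics: exponential-Euler membrane update
# with soft reset, two after-spike currents, alpha-function synapses with
# integer conduction delays, refractoriness, and two-timescale noise.

#' Two-timescale noise model
#'
#' Noise currents are drawn from a zero-centered heavy-tailed base
#' distribution `dist` and injected at two timescales: *quick* noise (scale
#' `q`) is redrawn independently for every neuron in every 1-ms step, *slow*
#' noise (scale `s`) is drawn once per neuron at trial start and frozen for
#' the whole trial. Defaults are `q = 2`, `s = 2`.
#'
#' @param q Quick-noise scale (>= 0). @param s Slow-noise scale (>= 0).
#' @param dist Base sampler, see [make_noise_distribution()].
#' @return A list of class `glif_noise_model`.
#' @export
noise_model <- function(q = 2, s = 2, dist = make_noise_distribution()) {
  if (q < 0 || s < 0) stop("noise scales must be non-negative")
  structure(list(q = q, s = s, dist = dist), class = "glif_noise_model")
}

#' Draw the noise currents for a trial
#'
#' @param model A [noise_model()].
#' @param n_neurons Number of neurons.
#' @param T Trial length in ms.
#' @param seed Integer seed.
#' @return List: `quick` (n x T matrix, pA, i.i.d. per entry) and `slow`
#'   (length-n vector, pA, frozen for the trial). Both are exactly zero when
#'   the corresponding scale is zero.
#' @export
draw_noise <- function(model, n_neurons, T, seed = 1) {
  stopifnot(inherits(model, "glif_noise_model"))
  set.seed(seed)
  quick <- if (model$q > 0) {
    matrix(model$q * model$dist(n_neurons * T), n_neurons, T)
  } else matrix(0, n_neurons, T)
  slow <- if (model$s > 0) model$s * model$dist(n_neurons) else numeric(n_neurons)
  list(quick = quick, slow = slow)
}

# ---- tensor form -----------------------------------------------------------

# Flatten a network into the arrays the simulator consumes: per-neuron
# parameter vectors, and weight matrices grouped by (tau_syn group, delay).
# dense = TRUE uses base matrices (small training networks), FALSE sparse.
glif_tensors <- function(network, dense = FALSE) {
  nr <- network$neurons
  n <- nrow(nr)
  p <- network$params[match(nr$param_type, network$params$param_type), ]
  tau <- p$C / p$g
  alpha <- exp(-1 / tau)
  e <- network$edges
  tg <- sort(unique(e$tau_syn))
  if (length(tg) == 0) tg <- 5
  delays <- sort(unique(e$delay))
  if (length(delays) == 0) delays <- 1L
  W <- lapply(seq_along(tg), function(g) {
    lapply(seq_len(max(delays)), function(d) {
      sel <- e$tau_syn == tg[g] & e$delay == d
      if (!any(sel)) return(NULL)
      m <- Matrix::sparseMatrix(i = e$post[sel], j = e$pre[sel],
                                x = e$weight[sel], dims = c(n, n))
      if (dense) as.matrix(m) else m
    })
  })
  Win <- Matrix::sparseMatrix(i = network$input$post, j = network$input$unit,
                              x = network$input$weight,
                              dims = c(n, network$n_inputs))
  if (dense) Win <- as.matrix(Win)
  list(n = n, dense = dense,
       C = p$C, g = p$g, E_L = p$E_L, v_th = p$v_th, tau_m = tau,
       alpha = alpha, beta = (1 - alpha) / p$g,
       tref = as.integer(ceiling(p$t_ref)),
       f1 = exp(-p$k1), f2 = exp(-p$k2), dI1 = p$dI1, dI2 = p$dI2,
       tau_groups = tg, kappa = exp(-1 / tg), eot = exp(1) / tg,
       max_delay = max(delays), W = W, W_in = Win,
       sign = nr$sign, sign_constrained = network$sign_constrained)
}

#' Initialize the simulator state
#'
#' All state variables start at zero except the membrane potential, which
#' starts at the resting potential `E_L` (zero in resting-relative units).
#'
#' @param tn Tensor form of a network (internal; produced by the simulator).
#' @param B Number of trials simulated side by side.
#' @return State list: `v`, after-spike currents `Ia1`, `Ia2`, per-group
#'   synaptic accumulators `Cr`, `Is`, refractory counters `cnt`.
#' @keywords internal
glif3_init_state <- function(tn, B = 1) {
  z0 <- matrix(0, tn$n, B)
  G <- length(tn$tau_groups)
  list(v = matrix(tn$E_L, tn$n, B), Ia1 = z0, Ia2 = z0,
       Cr = rep(list(z0), G), Is = rep(list(z0), G),
       cnt = matrix(0L, tn$n, B))
}

# smooth spike surrogate whose derivative is the Gaussian pseudo-derivative
.soft_spike <- function(v, tn, surr) {
  vsc <- (v - tn$v_th) / (tn$v_th - tn$E_L)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  surr$gamma_pd * surr$sigma_p * sqrt(pi) / 2 * (erf(vsc / surr$sigma_p) + 1)
}

#' One integration step of the GLIF_3 membrane equations
#'
#' Evaluates spikes `z(t) = H(v(t) - v_th)` (forced to 0 inside the
#' refractory period), then advances membrane potential and after-spike
#' currents one step:
#' `v(t+1) = alpha v(t) + (1-alpha)/g * (Ie(t+1) + sum_m I_m(t+1) + g E_L +
#' I_syn(t)) - z(t) (v_th - E_L)` with `alpha = exp(-dt/tau)`, and
#' `I_m(t+1) = f_m I_m(t) + z(t) dI_m`. Spiking starts a refractory counter
#' of `ceiling(t_ref)` steps. Synaptic accumulators are advanced separately
#' by [propagate_synapses()].
#'
#' @param state State list from [glif3_init_state()].
#' @param Ie External current at the *next* step (n x B matrix or vector, pA).
#' @param tn Tensor form of the network.
#' @param surr Optional surrogate config; when given, spikes are the smooth
#'   surrogate activation instead of the hard threshold and refractoriness is
#'   disabled (used for gradient checking).
#' @return List `state` (advanced state) and `z` (spike output at time t).
#' @keywords internal
glif3_step <- function(state, Ie, tn, surr = NULL) {
  v <- state$v
  if (any(!is.finite(v))) stop("non-finite membrane potential: diverged state")
  if (is.null(surr)) {
    z <- (v >= tn$v_th) * (state$cnt == 0)
    cnt <- pmax(state$cnt - 1L, 0L)
    spk <- z > 0
    if (any(spk)) cnt[spk] <- matrix(tn$tref, tn$n, ncol(v))[spk]
  } else {
    z <- .soft_spike(v, tn, surr)
    cnt <- state$cnt
  }
  Ia1 <- tn$f1 * state$Ia1 + tn$dI1 * z
  Ia2 <- tn$f2 * state$Ia2 + tn$dI2 * z
  syn_tot <- Reduce(`+`, state$Is)
  v_new <- tn$alpha * v +
    tn$beta * (Ie + Ia1 + Ia2 + tn$g * tn$E_L + syn_tot) -
    z * (tn$v_th - tn$E_L)
  state$v <- v_new; state$Ia1 <- Ia1; state$Ia2 <- Ia2; state$cnt <- cnt
  list(state = state, z = z)
}

#' Advance the alpha-synapse accumulators one step
#'
#' Implements, per synaptic time-constant group,
#' `C_rise(t+1) = exp(-1/tau_syn) C_rise(t) + (e / tau_syn) * W z_delayed` and
#' `I_syn(t+1) = exp(-1/tau_syn) (I_syn(t) + C_rise(t))`, the discrete
#' alpha-function synapse. `spike_buffer[[d]]` must hold the presynaptic
#' spike vector emitted `d - 1` steps ago (i.e. entry 1 is the current step's
#' spikes), so that an edge with delay `d` first contributes `d` steps after
#' the spike.
#'
#' @param state State list. @param spike_buffer List of n x B spike matrices.
#' @param tn Tensor form of the network.
#' @return The advanced state.
#' @keywords internal
propagate_synapses <- function(state, spike_buffer, tn) {
  if (tn$max_delay > length(spike_buffer)) {
    stop("spike buffer shorter than the maximal delay")
  }
  for (g in seq_along(tn$tau_groups)) {
    inS <- NULL
    for (d in seq_len(tn$max_delay)) {
      Wgd <- tn$W[[g]][[d]]
      if (is.null(Wgd) || is.null(spike_buffer[[d]])) next
      contrib <- as.matrix(Wgd %*% spike_buffer[[d]])
      inS <- if (is.null(inS)) contrib else inS + contrib
    }
    Cr_old <- state$Cr[[g]]
    state$Is[[g]] <- tn$kappa[g] * (state$Is[[g]] + Cr_old)
    state$Cr[[g]] <- tn$kappa[g] * Cr_old +
      (if (is.null(inS)) 0 else tn$eot[g] * inS)
  }
  state
}

# Full forward pass over T steps for B stacked trials (internal engine).
# Ie: n x T x B array, n x T matrix (B = 1), or function(t) -> n x B matrix
# of total external current (stimulus + noise). Records spikes, and
# optionally voltages and refractory masks (needed for backpropagation).
glif_forward <- function(tn, Ie, T, B = 1, init = NULL, surr = NULL,
                         record_v = FALSE, record_refr = FALSE) {
  get_Ie <- if (is.function(Ie)) {
    Ie
  } else if (is.matrix(Ie)) {
    function(t) Ie[, t, drop = FALSE]
  } else {
    function(t) matrix(Ie[, t, ], tn$n, B)
  }
  st <- if (is.null(init)) glif3_init_state(tn, B) else init
  Z <- array(0, c(tn$n, B, T))
  V <- if (record_v) array(0, c(tn$n, B, T)) else NULL
  R <- if (record_refr) array(FALSE, c(tn$n, B, T)) else NULL
  buffer <- vector("list", tn$max_delay)
  for (t in seq_len(T)) {
    if (record_v) V[, , t] <- st$v
    if (record_refr) R[, , t] <- st$cnt > 0
    res <- glif3_step(st, if (t < T) get_Ie(t + 1) else 0, tn, surr)
    Z[, , t] <- res$z
    if (t < T) {
      buffer <- c(list(res$z), buffer[seq_len(tn$max_delay - 1)])
      st <- propagate_synapses(res$state, buffer, tn)
    }
  }
  list(Z = Z, V = V, refr = R, state = st)
}

#' Simulate a network
#'
#' Runs the full forward simulation (membrane, after-spike currents, delayed
#' alpha synapses, refractoriness, quick/slow noise) on a 1-ms grid for `T`
#' ms. Initial spikes, synaptic currents and after-spike currents are zero
#' and the membrane starts at rest, unless `init` is given (e.g. to chain
#' change-detection trials without a state reset).
#'
#' @param network A `glif_network`.
#' @param input `n x T` matrix of stimulus currents (pA), or `NULL` for none.
#' @param noise A [noise_model()]; use `noise_model(q = 0, s = 0)` for a
#'   noiseless run.
#' @param T Trial duration in ms. Default 600.
#' @param seed Integer seed for the noise draws.
#' @param record Any of `"spikes"`, `"voltage"`, `"counts"`.
#' @param init Optional initial state (from a previous run's `$state`).
#' @return List with `spikes` (n x T 0/1 matrix, if recorded), `voltage`
#'   (n x T, if recorded), `counts` (population spike count per ms), and the
#'   final `state`.
#' @export
simulate_network <- function(network, input = NULL, noise = noise_model(),
                             T = 600, seed = 1, record = "spikes",
                             init = NULL) {
  tn <- glif_tensors(network, dense = FALSE)
  n <- tn$n
  if (!is.null(input)) {
    stopifnot(nrow(input) == n)
    if (ncol(input) < T) {
      input <- cbind(input, matrix(0, n, T - ncol(input)))
    }
  }
  set.seed(seed)
  slow <- if (noise$s > 0) noise$s * noise$dist(n) else numeric(n)
  dist <- noise$dist; q <- noise$q
  Ie_fun <- function(t) {
    cur <- slow + if (q > 0) q * dist(n) else 0
    if (!is.null(input)) cur <- cur + input[, t]
    matrix(cur, n, 1)
  }
  fwd <- glif_forward(tn, Ie_fun, T, B = 1, init = init,
                      record_v = "voltage" %in% record)
  spikes <- matrix(fwd$Z, n, T)
  out <- list(counts = colSums(spikes), state = fwd$state)
  if ("spikes" %in% record) out$spikes <- spikes
  if ("voltage" %in% record) out$voltage <- matrix(fwd$V, n, T)
  out
}
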