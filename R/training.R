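# Surrogate-gradient training: backpropagation through the spiking dynamics
# with a Gaussian pseudo-derivative, composite loss (cross-entropy +
# rate/voltage regularization), SGD with Dale's-law sign clipping.

#' Surrogate-gradient configuration
#' @param gamma_pd Dampening factor of the pseudo-derivative. Default 0.5.
#' @param sigma_p Gaussian kernel width (in threshold-normalized voltage
#'   units). Default 0.28.
#' @return List of class `surrogate_config`.
#' @export
surrogate_config <- function(gamma_pd = 0.5, sigma_p = 0.28) {
  stopifnot(gamma_pd > 0, sigma_p > 0)
  structure(list(gamma_pd = gamma_pd, sigma_p = sigma_p),
            class = "surrogate_config")
}

#' Loss configuration
#'
#' @param lambda_f Weight of the firing-rate regularizer. Default 0.1.
#' @param lambda_v Weight of the voltage regularizer. Default 1e-5.
#' @param kappa Huber width of the rate regularizer. Default 0.002.
#' @param r0 Baseline readout rate (spikes/neuron/ms). Default 0.01.
#' @param theta Initial trainable rate scale (> 0). Default 100.
#' @param target_rate_median Median of the log-normal target-rate
#'   distribution, spikes/ms (0.004 = 4 Hz). Default 0.004.
#' @param target_rate_sdlog Log-SD of the target-rate distribution. Default 1.
#' @return List of class `loss_config`.
#' @export
loss_config <- function(lambda_f = 0.1, lambda_v = 1e-5, kappa = 0.002,
                        r0 = 0.01, theta = 100,
                        target_rate_median = 0.004, target_rate_sdlog = 1) {
  stopifnot(lambda_f >= 0, lambda_v >= 0, kappa > 0, theta > 0)
  structure(list(lambda_f = lambda_f, lambda_v = lambda_v, kappa = kappa,
                 r0 = r0, theta = theta,
                 target_rate_median = target_rate_median,
                 target_rate_sdlog = target_rate_sdlog),
            class = "loss_config")
}

#' Pseudo-derivative of the spike nonlinearity
#'
#' `psi = gamma_pd / (v_th - E_L) * exp(-v_sc^2 / sigma_p^2)` with
#' `v_sc = (v - v_th) / (v_th - E_L)`; zero inside the refractory period.
#' At threshold, `psi * (v_th - E_L) = gamma_pd`.
#'
#' @param v Membrane potential(s), mV.
#' @param v_th,E_L Threshold and resting potential (scalars or per-neuron).
#' @param surr A [surrogate_config()].
#' @param refractory Logical (same shape as `v`): TRUE forces 0.
#' @return Pseudo-derivative values (1/mV).
#' @export
pseudo_derivative <- function(v, v_th, E_L, surr = surrogate_config(),
                              refractory = FALSE) {
  den <- v_th - E_L
  if (any(den == 0)) stop("degenerate normalization: v_th equals E_L")
  vsc <- (v - v_th) / den
  psi <- surr$gamma_pd / den * exp(-vsc^2 / surr$sigma_p^2)
  psi * !refractory
}

#' Cross-entropy loss on readout rates
#'
#' Binary (threshold) form:
#' `-sum_m [T_m log sigmoid(theta (r_m - r0)) +
#' (1 - T_m) log sigmoid(theta (r0 - r_m))]`. Multi-pool (argmax) form:
#' categorical cross-entropy of the softmax over `theta * r`.
#'
#' @param r Readout rates: vector over windows (binary) or vector over pools
#'   (argmax).
#' @param target 0/1 per window (binary) or 0-based class index (argmax).
#' @param theta Rate scale (> 0). @param r0 Baseline rate.
#' @param type `"binary"` or `"argmax"`.
#' @return List: `loss`, `grad_r` (dL/dr), `grad_theta`.
#' @export
cross_entropy_loss <- function(r, target, theta, r0 = 0.01,
                               type = c("binary", "argmax")) {
  type <- match.arg(type)
  if (any(r < 0 | r > 1)) stop("readout rates must lie in [0, 1]")
  if (type == "binary") {
    u <- theta * (r - r0)
    loss <- -sum(target * stats::plogis(u, log.p = TRUE) +
                   (1 - target) * stats::plogis(-u, log.p = TRUE))
    s <- stats::plogis(u)
    list(loss = loss, grad_r = theta * (s - target),
         grad_theta = sum((s - target) * (r - r0)))
  } else {
    u <- theta * r
    u <- u - max(u)
    p <- exp(u) / sum(exp(u))
    y <- as.numeric(seq_along(r) == target + 1)
    list(loss = -log(p[target + 1]),
         grad_r = theta * (p - y),
         grad_theta = sum((p - y) * r))
  }
}

#' Quantile-weighted Huber rate regularizer
#'
#' Compares the sorted per-neuron mean rates against a sorted sample of
#' target rates: `sum_j |tau_j - 1{delta_j < 0}| L_kappa(delta_j) kappa`
#' with `tau_j = j/N`, `delta_j = r_(j) - r_(j)^target` and `L_kappa` the
#' Huber function of width `kappa`.
#'
#' @param rates Per-neuron mean rates (spikes/ms).
#' @param target_rates Target rates, same length.
#' @param kappa Huber width. Default 0.002.
#' @return List: `loss`, `grad` (dL/d rates, in the original neuron order;
#'   the quantile weight is treated as locally constant).
#' @export
rate_regularizer <- function(rates, target_rates, kappa = 0.002) {
  N <- length(rates)
  if (length(target_rates) != N) stop("rates and target_rates length mismatch")
  o <- order(rates)
  delta <- rates[o] - sort(target_rates)
  tau <- seq_len(N) / N
  w <- abs(tau - (delta < 0))
  small <- abs(delta) <= kappa
  Lk <- ifelse(small, delta^2 / 2, kappa * (abs(delta) - kappa / 2))
  dLk <- ifelse(small, delta, kappa * sign(delta))
  grad <- numeric(N)
  grad[o] <- w * dLk * kappa
  list(loss = sum(w * Lk * kappa), grad = grad)
}

#' Voltage regularizer
#'
#' Penalizes excursions beyond one resting-potential magnitude around rest:
#' mean over all entries of `relu(u - 1)^2 + relu(-u - 1)^2` with
#' `u = (v - E_L) / |E_L|`; zero whenever `|v - E_L| <= |E_L|`.
#'
#' @param v Membrane potentials (vector, matrix or array; first dimension =
#'   neurons).
#' @param E_L Resting potential(s), nonzero.
#' @return List: `loss`, `grad` (same shape as `v`).
#' @export
voltage_regularizer <- function(v, E_L) {
  if (any(E_L == 0)) stop("E_L must be nonzero")
  u <- (v - E_L) / abs(E_L)
  hi <- pmax(u - 1, 0); lo <- pmax(-u - 1, 0)
  m <- length(v)
  list(loss = sum(hi^2 + lo^2) / m,
       grad = (2 * (hi - lo) / abs(E_L)) / m)
}

# ---- BPTT core -------------------------------------------------------------

# Forward + adjoint backward pass through the unrolled GLIF dynamics.
#   tn        tensor form (dense for training-sized networks)
#   x         front-end rates, K x T x B array (or NULL)
#   Ie_extra  additional external current (noise), n x T x B array or 0
#   trial_losses  list per batch lane b: list(windows = data.frame(t0, t1,
#                 target), decision = "threshold"/"argmax", pools = list of
#                 neuron-id vectors for this task's pools)
#   cfg       loss_config (cfg$theta used and differentiated)
#   surr      surrogate_config
#   mode      "hard" (spiking, pseudo-derivative) or "soft" (smooth surrogate
#             forward; its BPTT gradient is exact, used for finite-difference
#             verification)
#   horizon   NULL for the full pass, else number of final ms to backpropagate
#   target_rates  per-neuron target rates (NULL disables rate regularization)
.bptt <- function(tn, x, Ie_extra, T, B, trial_losses, cfg, surr,
                  mode = c("hard", "soft"), horizon = NULL,
                  target_rates = NULL) {
  mode <- match.arg(mode)
  n <- tn$n
  G <- length(tn$tau_groups); D <- tn$max_delay
  Ie <- if (is.null(x)) {
    if (is.array(Ie_extra)) Ie_extra else array(0, c(n, T, B))
  } else {
    arr <- array(0, c(n, T, B))
    for (b in seq_len(B)) {
      arr[, , b] <- as.matrix(tn$W_in %*% x[, , b])
    }
    if (is.array(Ie_extra)) arr + Ie_extra else arr
  }
  fwd <- glif_forward(tn, Ie, T, B,
                      surr = if (mode == "soft") surr else NULL,
                      record_v = TRUE, record_refr = (mode == "hard"))
  Z <- fwd$Z; V <- fwd$V
  psi <- pseudo_derivative(V, tn$v_th, tn$E_L, surr,
                           refractory = if (mode == "hard") fwd$refr else FALSE)

  # ---- loss and direct gradients ----
  gz_dir <- array(0, c(n, B, T))
  ce_loss <- 0; g_theta <- 0
  for (b in seq_len(B)) {
    tl <- trial_losses[[b]]
    if (is.null(tl)) next
    for (w in seq_len(nrow(tl$windows))) {
      t0 <- tl$windows$t0[w]; t1 <- tl$windows$t1[w]
      cols <- (t0 + 1):t1
      if (tl$decision == "threshold") {
        pool <- tl$pools[[1]]
        r <- sum(Z[pool, b, cols]) / (length(cols) * length(pool))
        ce <- cross_entropy_loss(r, tl$windows$target[w], cfg$theta, cfg$r0,
                                 "binary")
        gz_dir[pool, b, cols] <- gz_dir[pool, b, cols] +
          ce$grad_r / (B * length(cols) * length(pool))
      } else {
        rates <- vapply(tl$pools, function(p) {
          sum(Z[p, b, cols]) / (length(cols) * length(p))
        }, numeric(1))
        ce <- cross_entropy_loss(rates, tl$windows$target[w], cfg$theta,
                                 cfg$r0, "argmax")
        for (k in seq_along(tl$pools)) {
          p <- tl$pools[[k]]
          gz_dir[p, b, cols] <- gz_dir[p, b, cols] +
            ce$grad_r[k] / (B * length(cols) * length(p))
        }
      }
      ce_loss <- ce_loss + ce$loss / B
      g_theta <- g_theta + ce$grad_theta / B
    }
  }
  rate_loss <- 0
  if (!is.null(target_rates) && cfg$lambda_f > 0) {
    mean_rates <- apply(Z, 1, mean)
    rr <- rate_regularizer(mean_rates, target_rates, cfg$kappa)
    rate_loss <- rr$loss
    gz_dir <- gz_dir + cfg$lambda_f * array(rr$grad / (B * T), c(n, B, T))
  }
  vr <- voltage_regularizer(V, tn$E_L)
  v_loss <- vr$loss
  gv_dir <- cfg$lambda_v * vr$grad                     # n x B x T

  # ---- adjoint recursion (t = T .. 1) ----
  zmat <- function(t) matrix(Z[, , t], n, B)
  z0 <- matrix(0, n, B)
  gv_next <- z0; ga1_next <- z0; ga2_next <- z0
  gs_next <- rep(list(z0), G)
  gclag <- rep(list(rep(list(z0), D)), G)   # gclag[[g]][[d]] = gc_{t+d}
  gW <- lapply(seq_len(G), function(g) lapply(seq_len(D), function(d) {
    if (is.null(tn$W[[g]][[d]])) NULL else matrix(0, n, n)
  }))
  gWin <- matrix(0, n, ncol(tn$W_in))
  dreset <- tn$v_th - tn$E_L
  t_lo <- if (is.null(horizon)) 1L else max(1L, T - as.integer(horizon))
  gz_norm2 <- numeric(n)
  for (t in T:t_lo) {
    gc_t <- vector("list", G); gs_t <- vector("list", G)
    for (g in seq_len(G)) {
      gc_t[[g]] <- tn$kappa[g] * (gclag[[g]][[1]] + gs_next[[g]])
      gs_t[[g]] <- tn$beta * gv_next + tn$kappa[g] * gs_next[[g]]
    }
    gz <- matrix(gz_dir[, , t], n, B) - dreset * gv_next +
      tn$dI1 * ga1_next + tn$dI2 * ga2_next
    for (g in seq_len(G)) {
      for (d in seq_len(D)) {
        Wgd <- tn$W[[g]][[d]]
        if (is.null(Wgd)) next
        gz <- gz + tn$eot[g] * as.matrix(Matrix::crossprod(Wgd, gclag[[g]][[d]]))
      }
    }
    gz_norm2 <- gz_norm2 + rowSums(gz^2)
    gv <- matrix(gv_dir[, , t], n, B) + tn$alpha * gv_next +
      matrix(psi[, , t], n, B) * gz
    ga1 <- tn$beta * gv + tn$f1 * ga1_next
    ga2 <- tn$beta * gv + tn$f2 * ga2_next
    for (g in seq_len(G)) {
      for (d in seq_len(D)) {
        if (is.null(gW[[g]][[d]]) || t - d < 1) next
        gW[[g]][[d]] <- gW[[g]][[d]] +
          (tn$eot[g] * gc_t[[g]]) %*% t(zmat(t - d))
      }
    }
    if (t >= 2 && !is.null(x)) {
      gWin <- gWin + (tn$beta * gv) %*% t(matrix(x[, t, ], ncol(tn$W_in), B))
    }
    gv_next <- gv; ga1_next <- ga1; ga2_next <- ga2; gs_next <- gs_t
    for (g in seq_len(G)) {
      gclag[[g]] <- c(gc_t[g], gclag[[g]][seq_len(D - 1)])
    }
  }
  list(loss = ce_loss + cfg$lambda_f * rate_loss + cfg$lambda_v * v_loss,
       ce_loss = ce_loss, rate_loss = rate_loss, v_loss = v_loss,
       gW = gW, gWin = gWin, g_theta = g_theta,
       gz_norm = sqrt(gz_norm2),
       mean_rate = mean(Z), Z = Z)
}

#' Loss and exact/surrogate BPTT gradients for a batch
#'
#' Low-level entry point exposing the backpropagation-through-time gradients
#' of the composite loss with respect to the recurrent weights, input weights
#' and the rate scale theta. In `"soft"` mode the forward pass replaces the
#' hard threshold by the smooth surrogate activation whose derivative is the
#' pseudo-derivative; the returned gradient is then the exact gradient of
#' that differentiable system (verifiable by finite differences). In
#' `"hard"` mode the forward is the spiking dynamics and the backward
#' substitutes the pseudo-derivative.
#'
#' @param network A `glif_network`.
#' @param x Front-end rates, `units x T x B` array (or NULL).
#' @param trial_losses Per-lane loss spec: list of `list(windows, decision,
#'   pools)` (see [decide_trial()] for the window format; `pools` are
#'   neuron-id vectors).
#' @param T,B Unroll length (ms) and batch size.
#' @param cfg A [loss_config()]. @param surr A [surrogate_config()].
#' @param mode `"hard"` or `"soft"`.
#' @param Ie_extra Optional additional current array (`n x T x B`).
#' @param target_rates Optional per-neuron target rates for the rate
#'   regularizer.
#' @return List with loss components and gradients (`gW` per tau/delay group,
#'   `gWin`, `g_theta`).
#' @export
bptt_gradient <- function(network, x, trial_losses, T, B,
                          cfg = loss_config(), surr = surrogate_config(),
                          mode = c("hard", "soft"), Ie_extra = 0,
                          target_rates = NULL) {
  tn <- glif_tensors(network, dense = TRUE)
  .bptt(tn, x, Ie_extra, T, B, trial_losses, cfg, surr, match.arg(mode),
        target_rates = target_rates)
}

# Dale clipping: zero any weight whose sign would flip relative to the
# presynaptic neuron's sign. Columns index presynaptic neurons.
.dale_clip <- function(W, sign) {
  exc <- sign > 0
  W[, exc][W[, exc] < 0] <- 0
  W[, !exc][W[, !exc] > 0] <- 0
  W
}

#' Train a network with surrogate-gradient descent
#'
#' Stochastic gradient descent through the unrolled spiking dynamics:
#' interleaved task batches, composite loss (cross-entropy + rate + voltage
#' regularization), pseudo-derivative backward pass, plain SGD updates with
#' Dale's-law sign clipping after every step (an excitatory weight updated to
#' a negative value is set to 0, and vice versa; input weights are kept
#' nonnegative; skipped entirely for sign-unconstrained networks). The rate
#' scale theta is trained jointly and kept positive. Training is noiseless
#' by default (noise is applied at test time); pass a [noise_model()] to
#' train with noise.
#'
#' @param network A `glif_network`.
#' @param pools A [readout_pools()]. @param assignment [readout_assignment()].
#' @param tasks Tasks to interleave. Default all five.
#' @param steps Number of weight updates.
#' @param batch_per_task Trials per task per batch. Default 2.
#' @param lr Learning rate for weights. @param lr_theta For theta.
#' @param max_dw Element-wise cap (pA) on a single weight update, guarding
#'   against the occasional huge gradients produced by heavy-tailed noise
#'   trials. Default 0.5; `Inf` disables.
#' @param duration Trial length in ms (the trial generators place all
#'   response windows within the first 600 ms; shorter durations are for
#'   truncated curricula).
#' @param cfg A [loss_config()]. @param surr A [surrogate_config()].
#' @param bank An [lgn_filter_bank()] matching the stimuli.
#' @param glyphs,ensemble Stimulus ensembles where needed.
#' @param noise Optional [noise_model()] applied during training.
#' @param trial_args Named list of extra arguments per task passed to
#'   [sample_trial()] (e.g. `list(orientation = list(orientations = c(43, 47)))`).
#' @param seed Integer seed.
#' @param verbose Print progress every 20 steps.
#' @return List: `network` (trained weights written back to the edge list),
#'   `theta`, `metrics` (per-step data.frame: loss components, mean rate),
#'   `target_rates`.
#' @export
train_network <- function(network, pools, assignment,
                          tasks = names(assignment), steps = 100,
                          batch_per_task = 2, lr = 3e3, lr_theta = 1,
                          max_dw = 0.5,
                          duration = 600, cfg = loss_config(),
                          surr = surrogate_config(),
                          bank = NULL, glyphs = NULL, ensemble = NULL,
                          noise = NULL, trial_args = list(), seed = 1,
                          verbose = FALSE) {
  tn <- glif_tensors(network, dense = TRUE)
  G <- length(tn$tau_groups); D <- tn$max_delay
  masks <- lapply(tn$W, function(ws) lapply(ws, function(w) {
    if (is.null(w)) NULL else (w != 0) * 1
  }))
  mask_in <- (tn$W_in != 0) * 1
  if (is.null(bank)) {
    H <- if (!is.null(glyphs)) dim(glyphs$images)[1] else 32
    bank <- lgn_filter_bank(H = H, W = H)
  }
  set.seed(seed)
  target_rates <- cfg$target_rate_median *
    exp(stats::rnorm(tn$n, 0, cfg$target_rate_sdlog))
  theta <- cfg$theta
  B <- length(tasks) * batch_per_task
  metrics <- vector("list", steps)
  for (step in seq_len(steps)) {
    x <- array(0, c(ncol(tn$W_in), duration, B))
    trial_losses <- vector("list", B)
    b <- 0L
    for (tk in tasks) {
      for (rep in seq_len(batch_per_task)) {
        b <- b + 1L
        tseed <- seed + 7919L * step + 101L * b
        args <- c(list(task = tk, seed = tseed, glyphs = glyphs,
                       ensemble = ensemble, duration = duration),
                  trial_args[[tk]])
        trial <- do.call(sample_trial, args)
        x[, , b] <- if (identical(network$input_mode, "pixels")) {
          network$bypass_scale * trial$stimulus$frames
        } else {
          lgn_response(bank, trial$stimulus)
        }
        trial_losses[[b]] <- list(
          windows = trial$windows, decision = trial$decision,
          pools = pools$pools[assignment[[tk]]])
      }
    }
    Ie_extra <- 0
    if (!is.null(noise)) {
      Ie_extra <- array(0, c(tn$n, duration, B))
      for (bb in seq_len(B)) {
        nd <- draw_noise(noise, tn$n, duration, seed = seed + step * 631L + bb)
        Ie_extra[, , bb] <- nd$quick + nd$slow
      }
    }
    cfg$theta <- theta
    res <- .bptt(tn, x, Ie_extra, duration, B, trial_losses, cfg, surr,
                 "hard", target_rates = target_rates)
    if (!is.finite(res$loss)) stop("non-finite loss at step ", step)
    cap <- function(dw) pmin(pmax(dw, -max_dw), max_dw)
    for (g in seq_len(G)) {
      for (d in seq_len(D)) {
        if (is.null(tn$W[[g]][[d]])) next
        Wnew <- tn$W[[g]][[d]] - cap(lr * res$gW[[g]][[d]]) * masks[[g]][[d]]
        if (tn$sign_constrained) Wnew <- .dale_clip(Wnew, tn$sign)
        tn$W[[g]][[d]] <- Wnew
      }
    }
    Win_new <- tn$W_in - cap(lr * res$gWin) * mask_in
    Win_new[Win_new < 0] <- 0          # front-end inputs are excitatory
    tn$W_in <- Win_new
    theta <- max(theta - lr_theta * res$g_theta, 1e-3)
    metrics[[step]] <- data.frame(step = step, loss = res$loss,
                                  ce = res$ce_loss, rate = res$rate_loss,
                                  voltage = res$v_loss,
                                  mean_rate = res$mean_rate, theta = theta)
    if (verbose && step %% 20 == 0) {
      message(sprintf("step %d: loss %.4f (ce %.4f) rate %.4f /ms",
                      step, res$loss, res$ce_loss, res$mean_rate))
    }
  }
  out_net <- .write_back_weights(network, tn)
  list(network = out_net, theta = theta,
       metrics = do.call(rbind, metrics), target_rates = target_rates)
}

# copy trained tensor weights back into the network's edge list / input table
.write_back_weights <- function(network, tn) {
  e <- network$edges
  tg <- tn$tau_groups
  for (g in seq_along(tg)) {
    for (d in seq_len(tn$max_delay)) {
      if (is.null(tn$W[[g]][[d]])) next
      sel <- which(e$tau_syn == tg[g] & e$delay == d)
      e$weight[sel] <- tn$W[[g]][[d]][cbind(e$post[sel], e$pre[sel])]
    }
  }
  network$edges <- e
  network$input$weight <- tn$W_in[cbind(network$input$post,
                                        network$input$unit)]
  network
}

#' Evaluate task accuracy of a network
#'
#' Simulates fresh trials with the given noise model and scores the decision
#' rules against the targets. Change-detection trials are chained: stimulus
#' identity and network state carry over between consecutive trials.
#'
#' @param network A `glif_network`.
#' @param pools,assignment Readout pools and task assignment.
#' @param tasks Tasks to evaluate.
#' @param n_trials Trials per task.
#' @param noise A [noise_model()] (the data-driven default q = s = 2, or
#'   `noise_model(q = 0, s = 0)` for noiseless evaluation).
#' @param duration Trial length in ms.
#' @param bank,glyphs,ensemble Front end and stimulus ensembles.
#' @param trial_args Extra per-task arguments for [sample_trial()].
#' @param seed Integer seed.
#' @return data.frame: task, accuracy, n_windows.
#' @export
evaluate_accuracy <- function(network, pools, assignment,
                              tasks = names(assignment), n_trials = 10,
                              noise = noise_model(), duration = 600,
                              bank = NULL, glyphs = NULL, ensemble = NULL,
                              trial_args = list(), seed = 1) {
  if (is.null(bank)) {
    H <- if (!is.null(glyphs)) dim(glyphs$images)[1] else 32
    bank <- lgn_filter_bank(H = H, W = H)
  }
  rows <- list()
  for (tk in tasks) {
    correct <- 0L; total <- 0L
    carry <- NULL; state <- NULL
    for (i in seq_len(n_trials)) {
      tseed <- seed + 7919L * i + match(tk, task_names()) * 65537L
      args <- c(list(task = tk, seed = tseed, glyphs = glyphs,
                     ensemble = ensemble, duration = duration),
                trial_args[[tk]])
      if (tk %in% c("change_images", "change_gratings") && !is.null(carry)) {
        args$carryover <- carry
      }
      trial <- do.call(sample_trial, args)
      cur <- stimulus_currents(network, trial$stimulus, bank)
      sim <- simulate_network(network, cur, noise, T = duration,
                              seed = tseed + 1L,
                              init = if (!trial$reset_state) state else NULL)
      if (!trial$reset_state) {
        state <- sim$state
        carry <- if (tk == "change_images") trial$meta$last_id
                 else trial$meta$last_orientation
      }
      dec <- decide_trial(trial, sim$spikes, pools, assignment[[tk]])
      correct <- correct + sum(dec$correct); total <- total + nrow(dec)
    }
    rows[[tk]] <- data.frame(task = tk, accuracy = correct / total,
                             n_windows = total)
  }
  do.call(rbind, rows)
}

#' Spread of gradient information from a single readout neuron
#'
#' Backpropagates the cross-entropy loss of a *single* readout neuron
#' (response window at the trial end) for a limited number of milliseconds
#' and returns, per neuron, the norm over time of the spike-adjoint it
#' receives. In a distance-dependent network this magnitude falls off with
#' lateral distance from the readout neuron; in a randomly connected network
#' it does not.
#'
#' @param network A `glif_network`.
#' @param horizon Backpropagation depth in ms (0 reaches only the readout
#'   neuron's immediate synaptic neighborhood).
#' @param readout_neuron Neuron id; default: the most strongly innervated
#'   excitatory L5 neuron (ties broken toward the sheet center), so the
#'   backpropagated signal has synaptic partners to reach.
#' @param duration Trial length in ms. Default 300.
#' @param drive_frac Background drive per neuron as a fraction of its
#'   rheobase current `g (v_th - E_L)`, keeping every type near threshold
#'   where the pseudo-derivative is responsive. Default 0.92.
#' @param drive_sd Relative SD of the per-ms drive jitter. Default 0.04.
#' @param seed Integer seed.
#' @return data.frame: neuron id, lateral `distance` to the readout neuron,
#'   gradient `magnitude`.
#' @export
gradient_flow_map <- function(network, horizon = 100, readout_neuron = NULL,
                              duration = 300, drive_frac = 0.92,
                              drive_sd = 0.04, seed = 1) {
  if (horizon > duration) stop("horizon exceeds the trial length")
  if (is.null(readout_neuron)) {
    l5e <- network$neurons[network$neurons$layer == "L5" &
                             network$neurons$sign > 0, ]
    if (nrow(l5e) == 0) l5e <- network$neurons[network$neurons$sign > 0, ]
    indeg <- tabulate(network$edges$post, nrow(network$neurons))[l5e$id]
    cen <- sqrt(l5e$x^2 + l5e$y^2)
    readout_neuron <- l5e$id[order(-indeg, cen)][1]
  }
  tn <- glif_tensors(network, dense = TRUE)
  set.seed(seed)
  rheo <- tn$g * (tn$v_th - tn$E_L)
  Ie <- array(drive_frac * rheo * (1 + stats::rnorm(tn$n * duration, 0,
                                                    drive_sd)),
              c(tn$n, duration, 1))
  trial_losses <- list(list(
    windows = data.frame(t0 = duration - 50, t1 = duration, target = 1L),
    decision = "threshold", pools = list(readout_neuron)))
  res <- .bptt(tn, NULL, Ie, duration, 1, trial_losses,
               loss_config(lambda_f = 0, lambda_v = 0), surrogate_config(),
               "hard", horizon = horizon)
  nr <- network$neurons
  data.frame(id = nr$id,
             distance = sqrt((nr$x - nr$x[readout_neuron])^2 +
                               (nr$y - nr$y[readout_neuron])^2),
             magnitude = res$gz_norm)
}
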