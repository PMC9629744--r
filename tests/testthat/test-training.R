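# Surrogate-gradient machinery: pseudo-derivative, loss components,
# BPTT gradient correctness, Dale preservation, optimization on toy tasks,
# gradient spread.

test_that("pseudo-derivative: peak value, symmetry, refractory gating, tails", {
  surr <- surrogate_config()
  vth <- -45; EL <- -70
  # at threshold, psi * (v_th - E_L) equals the dampening factor 0.5
  expect_equal(pseudo_derivative(vth, vth, EL, surr) * (vth - EL), 0.5)
  expect_equal(pseudo_derivative(vth, vth, EL, surr, refractory = TRUE), 0)
  # symmetric in the scaled voltage around threshold
  expect_equal(pseudo_derivative(vth + 3, vth, EL, surr),
               pseudo_derivative(vth - 3, vth, EL, surr))
  # maximal at threshold; vanishing far below
  expect_gt(pseudo_derivative(vth, vth, EL, surr),
            pseudo_derivative(vth - 5, vth, EL, surr))
  expect_lt(pseudo_derivative(-200, vth, EL, surr), 1e-30)
  expect_error(pseudo_derivative(0, -50, -50, surr), "degenerate")
})

test_that("cross-entropy loss: plug-in values, saturation, symmetry", {
  # r = r0: per-chunk loss log 2 regardless of target
  for (targ in 0:1) {
    ce <- cross_entropy_loss(0.01, targ, theta = 123, r0 = 0.01)
    expect_equal(ce$loss, log(2))
  }
  # saturation: huge positive margin with target 1 -> loss ~ 0
  expect_lt(cross_entropy_loss(0.9, 1, theta = 1000, r0 = 0.01)$loss, 1e-6)
  # sigma(-x) = 1 - sigma(x): loss(T=1) at margin u equals loss(T=0) at -u
  l1 <- cross_entropy_loss(0.03, 1, theta = 70, r0 = 0.01)$loss
  expect_equal(l1, cross_entropy_loss(0.01, 0, theta = 70, r0 = 0.03)$loss)
  expect_error(cross_entropy_loss(1.2, 1, theta = 1), "rates")
  # argmax form: softmax cross-entropy, gradients sum to zero
  ce <- cross_entropy_loss(c(0.02, 0.05, 0.01), 1, theta = 50, type = "argmax")
  expect_equal(sum(ce$grad_r), 0, tolerance = 1e-12)
  expect_gt(ce$loss, 0)
})

test_that("rate regularizer: zero at target, hand value, nonnegativity", {
  r <- c(0.004, 0.002, 0.01)
  expect_equal(rate_regularizer(r, r, kappa = 0.002)$loss, 0)
  # N = 1, tau = 1, delta = 0.001 <= kappa: |1-0| * (0.001^2/2) * 0.002
  rr <- rate_regularizer(0.005, 0.004, kappa = 0.002)
  expect_equal(rr$loss, 1e-9)
  set.seed(1)
  for (k in 1:10) {
    a <- runif(20, 0, 0.02); b <- runif(20, 0, 0.02)
    expect_gte(rate_regularizer(a, b)$loss, 0)
  }
  expect_error(rate_regularizer(1:3 / 100, 1:4 / 100), "mismatch")
})

test_that("voltage regularizer: dead zone and quadratic flanks", {
  EL <- -70
  expect_equal(voltage_regularizer(rep(EL, 10), EL)$loss, 0)
  # u = 2 and u = -2 each contribute (|u|-1)^2 = 1
  expect_equal(voltage_regularizer(EL + 2 * abs(EL), EL)$loss, 1)
  expect_equal(voltage_regularizer(EL - 2 * abs(EL), EL)$loss, 1)
  # anywhere inside the band: exactly zero
  expect_equal(voltage_regularizer(EL + 0.99 * abs(EL), EL)$loss, 0)
  expect_error(voltage_regularizer(1, 0), "nonzero")
})

test_that("total loss is the stated weighted sum of its components", {
  net <- build_network(small_config(30), seed = 2)
  T <- 40; B <- 2
  set.seed(3)
  x <- array(runif(net$n_inputs * T * B, 0, 60), c(net$n_inputs, T, B))
  pool <- net$neurons$id[net$neurons$layer == "L5" & net$neurons$sign > 0][1:3]
  tl <- list(windows = data.frame(t0 = 20, t1 = 40, target = 1L),
             decision = "threshold", pools = list(pool))
  cfg <- loss_config(lambda_f = 0.1, lambda_v = 1e-5)
  res <- bptt_gradient(net, x, list(tl, tl), T, B, cfg,
                       target_rates = rep(0.004, nrow(net$neurons)))
  expect_equal(res$loss,
               res$ce_loss + 0.1 * res$rate_loss + 1e-5 * res$v_loss,
               tolerance = 1e-12)
  expect_gte(res$ce_loss, 0)
  expect_gte(res$rate_loss, 0)
  expect_gte(res$v_loss, 0)
})

test_that("BPTT gradient matches finite differences of the surrogate forward", {
  set.seed(9)
  cfg <- network_config(layers = c("L4" = 5, "L5" = 5), n_lgn_units = 6,
                        input_n_per_neuron = 3)
  net <- build_network(cfg, seed = 3)
  T <- 20; B <- 2
  x <- array(runif(6 * T * B, 30, 90), c(6, T, B))
  pool <- net$neurons$id[net$neurons$layer == "L5" & net$neurons$sign > 0][1:2]
  tl <- list(windows = data.frame(t0 = 10, t1 = 15, target = 1L),
             decision = "threshold", pools = list(pool))
  tls <- list(tl, tl)
  cfg_l <- loss_config(lambda_f = 0, lambda_v = 1e-3, theta = 300)
  g <- bptt_gradient(net, x, tls, T, B, cfg_l, mode = "soft")
  tn <- glifnet:::glif_tensors(net, dense = TRUE)
  ge <- sapply(seq_len(nrow(net$edges)), function(k) {
    e <- net$edges[k, ]
    g$gW[[match(e$tau_syn, tn$tau_groups)]][[e$delay]][e$post, e$pre]
  })
  gi <- g$gWin[cbind(net$input$post, net$input$unit)]
  nrm <- sqrt(sum(ge^2) + sum(gi^2))
  ue <- ge / nrm; ui <- gi / nrm
  lossfn <- function(h) {
    n2 <- net
    n2$edges$weight <- net$edges$weight + h * ue
    n2$input$weight <- net$input$weight + h * ui
    bptt_gradient(n2, x, tls, T, B, cfg_l, mode = "soft")$loss
  }
  h <- 1e-3
  fd <- (lossfn(h) - lossfn(-h)) / (2 * h)
  expect_lt(abs(fd - nrm) / abs(fd), 1e-4)
  # theta gradient against central differences
  lossth <- function(th) {
    c2 <- cfg_l; c2$theta <- th
    bptt_gradient(net, x, tls, T, B, c2, mode = "soft")$loss
  }
  fd_th <- (lossth(300 + 1e-4) - lossth(300 - 1e-4)) / 2e-4
  expect_lt(abs(g$g_theta - fd_th) / abs(fd_th), 1e-4)
})

test_that("Dale's law is preserved by every training update", {
  net <- build_network(small_config(40), seed = 4)
  pools <- readout_pools(net, n_pools = 1, pool_size = 4,
                         placement = "distributed", seed = 5)
  tr <- train_network(net, pools, list(orientation = 1L),
                      tasks = "orientation", steps = 3, batch_per_task = 2,
                      lr = 1e5, duration = 200, noise = noise_model(),
                      seed = 6)
  e <- tr$network$edges
  sgn <- tr$network$neurons$sign[e$pre]
  expect_true(all(e$weight * sgn >= 0))
  expect_true(all(tr$network$input$weight >= 0))
  # clipping rule directly: an excitatory weight pushed negative becomes 0
  W <- matrix(c(0.5, -0.3, 0.2, -0.1), 2, 2)
  clipped <- glifnet:::.dale_clip(W, sign = c(1, -1))
  expect_equal(clipped, matrix(c(0.5, 0, 0, -0.1), 2, 2))
})

test_that("gradient descent monotonically reduces loss on a separable toy task", {
  # 20 neurons, two input channels; class 1 drives channel 1, class 0
  # channel 2; a fixed batch makes the optimization deterministic
  lib <- glif3_parameter_library("minimal")
  n <- 20
  set.seed(7)
  net <- structure(list(
    neurons = data.frame(id = 1:n, class = "L5e", layer = "L5", sign = 1L,
                         x = runif(n, -50, 50), y = runif(n, -50, 50),
                         param_type = 1L),
    edges = data.frame(pre = rep(1:5, 2), post = rep(11:12, each = 5),
                       weight = 2, delay = 1L, tau_syn = 5),
    input = data.frame(unit = rep(1:2, n), post = rep(1:n, each = 2),
                       weight = 6),
    params = lib, config = NULL, seed = 1, n_inputs = 2L,
    input_mode = "lgn", bypass_scale = 0.04, sign_constrained = TRUE,
    variant = "laminar"), class = "glif_network")
  T <- 60; B <- 2
  x <- array(0, c(2, T, B))
  x[1, , 1] <- 30; x[2, , 1] <- 12    # class 1
  x[1, , 2] <- 12; x[2, , 2] <- 30    # class 0
  pool <- 1:5
  tls <- list(
    list(windows = data.frame(t0 = 20, t1 = 60, target = 1L),
         decision = "threshold", pools = list(pool)),
    list(windows = data.frame(t0 = 20, t1 = 60, target = 0L),
         decision = "threshold", pools = list(pool)))
  cfg <- loss_config(lambda_f = 0, lambda_v = 0, theta = 150)
  cur <- net
  losses <- numeric(50)
  for (s in 1:50) {
    g <- bptt_gradient(cur, x, tls, T, B, cfg)
    losses[s] <- g$loss
    tn <- glifnet:::glif_tensors(cur, dense = TRUE)
    gi <- g$gWin[cbind(cur$input$post, cur$input$unit)]
    cur$input$weight <- pmax(cur$input$weight - 500 * gi, 0)
    ge <- sapply(seq_len(nrow(cur$edges)), function(k) {
      e <- cur$edges[k, ]
      g$gW[[match(e$tau_syn, tn$tau_groups)]][[e$delay]][e$post, e$pre]
    })
    cur$edges$weight <- pmax(cur$edges$weight - 500 * ge, 0)
  }
  sm <- stats::filter(losses, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(losses[50], losses[1] * 0.6)
  # smoothed curve strictly decreasing up to spike-quantization jitter
  expect_true(all(diff(sm) < 0.02))
})

test_that("surrogate training lifts orientation accuracy well above chance", {
  # 200-neuron laminar net, orientation extremes (43 vs 47 degrees),
  # 200 SGD steps; deterministic under noiseless training and evaluation.
  # The vignette discusses the information ceiling of the desk-scale front
  # end that bounds the attainable held-out accuracy.
  cfg <- network_config(layers = c("L2/3" = 60, "L4" = 80, "L5" = 60))
  net <- build_network(cfg, seed = 1)
  pools <- readout_pools(net, n_pools = 1, pool_size = 10,
                         placement = "distributed", seed = 2)
  asg <- list(orientation = 1L)
  bank <- lgn_filter_bank()
  targs <- list(orientation = list(orientations = c(43, 47)))
  acc0 <- evaluate_accuracy(net, pools, asg, n_trials = 60,
                            noise = noise_model(q = 0, s = 0),
                            duration = 200, bank = bank, trial_args = targs,
                            seed = 999)$accuracy
  tr <- train_network(net, pools, asg, tasks = "orientation", steps = 200,
                      batch_per_task = 8, lr = 30, duration = 200,
                      bank = bank, trial_args = targs, seed = 5)
  acc1 <- evaluate_accuracy(tr$network, pools, asg, n_trials = 60,
                            noise = noise_model(q = 0, s = 0),
                            duration = 200, bank = bank, trial_args = targs,
                            seed = 999)$accuracy
  expect_gt(acc1, acc0)
  expect_gt(acc1, 0.55)   # clearly above the 0.5 chance level
  # the trained scale stays positive and the loss ends below its start
  expect_gt(tr$theta, 0)
  expect_lt(mean(tr$metrics$ce[151:200]), tr$metrics$ce[1])
})

test_that("gradient information stays local at short horizons", {
  net <- build_network(small_config(50), seed = 8)
  gf <- gradient_flow_map(net, horizon = 4, duration = 100, seed = 9)
  ro <- gf$id[gf$distance == 0]
  presyn <- net$edges$pre[net$edges$post == ro]
  nz <- gf$id[gf$magnitude > 0]
  expect_true(ro %in% nz)
  expect_true(all(nz %in% c(ro, presyn)))
})

test_that("gradient magnitude decays with distance in laminar nets, not in RSNNs", {
  cfg <- network_config(layers = c("L2/3" = 80, "L4" = 80, "L5" = 80),
                        sheet_radius = 300)
  rho <- sapply(c(10, 20), function(sd) {
    lam <- build_network(cfg, seed = sd)
    rsn <- build_control_variant("rsnn", cfg, seed = sd)
    gl <- gradient_flow_map(lam, horizon = 40, duration = 120, seed = sd + 1)
    gr <- gradient_flow_map(rsn, horizon = 40, duration = 120, seed = sd + 1)
    keep_l <- gl$magnitude > 0 & gl$distance > 0
    keep_r <- gr$magnitude > 0 & gr$distance > 0
    c(stats::cor(gl$distance[keep_l], gl$magnitude[keep_l],
                 method = "spearman"),
      stats::cor(gr$distance[keep_r], gr$magnitude[keep_r],
                 method = "spearman"))
  })
  expect_lt(mean(rho[1, ]), -0.25)          # laminar: decays with distance
  expect_gt(mean(rho[2, ]), mean(rho[1, ]) + 0.2)  # RSNN: no such decay
  expect_lt(abs(mean(rho[2, ])), 0.15)
  expect_error(gradient_flow_map(lam, horizon = 500, duration = 100),
               "horizon")
})
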