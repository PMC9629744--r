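#' GLIF_3 parameter library
#'
#' A small library of hand-specified generalized leaky integrate-and-fire
#' (GLIF_3) parameter sets: four excitatory and four inhibitory types spanning
#' membrane time constants of 5--30 ms, refractory periods of 2--5 ms, and two
#' after-spike currents per neuron with slow (1/300 per ms) and fast (1/30 per
#' ms) decay rates and signed increments. The library stands in for large
#' atlas-derived fit collections and provides the neuron-type diversity of the
#' laminar model.
#'
#' Columns: `param_type` (id), `name`, `sign` (+1 excitatory, -1 inhibitory),
#' `C` (pF), `g` (nS), `E_L` (mV), `v_th` (mV), `tau_m` (ms, = C/g),
#' `t_ref` (ms), `k1`, `k2` (1/ms after-spike decay rates), `dI1`, `dI2`
#' (pA after-spike increments).
#'
#' @param diversity `"full"` for all 8 types, `"minimal"` for one excitatory
#'   and one inhibitory type (the no-diversity control), `"lif"` for a single
#'   plain LIF type with a 10-ms membrane constant, 5-ms refractory period and
#'   no after-spike currents (the RSNN controls).
#' @return A `data.frame`, one row per parameter type.
#' @export
glif3_parameter_library <- function(diversity = c("full", "minimal", "lif")) {
  diversity <- match.arg(diversity)
  full <- data.frame(
    param_type = 1:8,
    name = c("exc_slow", "exc_fast", "exc_adapt", "exc_burst",
             "inh_fast", "inh_slow", "inh_adapt", "inh_facil"),
    sign  = c(1, 1, 1, 1, -1, -1, -1, -1),
    C     = c(200, 120, 180, 150,  80, 120, 100,  90),
    g     = c(10, 12, 6, 15, 16, 6, 10, 6),
    E_L   = c(-70, -72, -68, -71, -67, -70, -69, -68),
    v_th  = c(-45, -48, -44, -47, -50, -46, -48, -47),
    t_ref = c(3, 2, 4, 3, 2, 3, 2, 5),
    k1    = c(1/300, 1/300, 1/300, 1/30, 1/300, 1/300, 1/30, 1/300),
    k2    = c(1/30, 1/30, 1/30, 1/300, 1/30, 1/30, 1/300, 1/30),
    dI1   = c(-8, -4, -15, 5, -5, -6, -10, 6),
    dI2   = c(-20, -10, -35, 12, -12, -15, 8, 15),
    stringsAsFactors = FALSE
  )
  full$tau_m <- full$C / full$g
  switch(diversity,
    full = full,
    minimal = {
      out <- full[full$name %in% c("exc_slow", "inh_fast"), ]
      out$param_type <- seq_len(nrow(out))
      rownames(out) <- NULL
      out
    },
    lif = {
      out <- full[1, ]
      out$name <- "lif"
      out$sign <- 1            # sign handled at the network level
      out$C <- 100; out$g <- 10            # tau_m = 10 ms
      out$E_L <- -70; out$v_th <- -50
      out$t_ref <- 5
      out$k1 <- out$k2 <- 1/30
      out$dI1 <- out$dI2 <- 0              # no after-spike currents
      out$tau_m <- out$C / out$g
      out$param_type <- 1L
      rownames(out) <- NULL
      out
    })
}

#' Default synaptic time-constant table
#'
#' Synaptic time constants (ms) depend on the classes of the pre- and
#' postsynaptic neuron. The default assigns tau_syn = 5 ms to excitatory
#' presynaptic classes and 8 ms to inhibitory ones, for every postsynaptic
#' class; any class-pair matrix of positive values may be supplied in a
#' network config to override it.
#'
#' @param classes Character vector of class names.
#' @param signs Integer vector of +1/-1 per class.
#' @return Matrix `classes x classes` of tau_syn values (rows = presynaptic).
#' @export
default_tau_syn_table <- function(classes, signs) {
  stopifnot(length(classes) == length(signs))
  tau <- ifelse(signs > 0, 5, 8)
  m <- matrix(rep(tau, times = length(classes)), nrow = length(classes),
              dimnames = list(pre = classes, post = classes))
  m
}
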