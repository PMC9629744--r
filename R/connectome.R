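# Synthetic laminar connectomes: layered classes, distance-dependent
# connection probabilities, Dale's law, integer conduction delays.

#' Network configuration
#'
#' Builds the configuration for a scaled-down laminar network. Each layer
#' holds one excitatory and one inhibitory class (classes named e.g. `"L4e"`,
#' `"L4i"`). Connection probability for a pair at lateral distance `d` is
#' `base_prob[pre, post] * exp(-d / sigma_d)`: `base_prob` is anchored at
#' distance 0 and decays exponentially with the horizontal intersomatic
#' distance. `NA` entries of `base_prob` mark unknown class pairs, which are
#' never connected. Weight magnitudes are log-normal per presynaptic sign and
#' signed by the presynaptic class (Dale's law); delays are uniform integers
#' in `delay_range` (ms).
#'
#' @param layers Named integer vector of neurons per layer.
#'   Default `c("L2/3" = 200, "L4" = 200, "L5" = 200)`.
#' @param exc_frac Fraction of excitatory neurons per layer. Default 0.8.
#' @param sheet_radius Radius (um) of the disc each layer occupies. Default 300.
#' @param sigma_d Lateral decay length (um), > 0. Default 75.
#' @param delay_range Integer delay interval (ms), within \[1, 4\].
#' @param base_prob Optional class x class matrix of distance-0 connection
#'   probabilities (rows = presynaptic). Defaults to a generic laminar motif
#'   with stronger within-layer and inhibitory connectivity.
#' @param weight_meanlog,weight_sdlog Named lists/numerics with `exc` and
#'   `inh` components: log-normal parameters of weight magnitudes (pA).
#' @param tau_syn Optional class x class matrix of synaptic time constants
#'   (ms); default [default_tau_syn_table()].
#' @param n_lgn_units Number of LGN front-end units the network expects; must
#'   match the filter bank used (the default [lgn_filter_bank()] has 208
#'   units: the 4 classes on the 52 lattice points inside the central oval).
#' @param input_layers Named vector: fraction of each layer's neurons that
#'   receive direct LGN input. The default mirrors the thalamocortical
#'   innervation pattern (dense in L4, sparser elsewhere):
#'   `c("L4" = 1, "L2/3" = 0.5, "L5" = 0.5)`.
#' @param input_n_per_neuron LGN units sampled per input-receiving neuron.
#' @param input_weight_meanlog,input_weight_sdlog Log-normal parameters of the
#'   (positive) input weights (pA per unit rate).
#' @return A list of class `glif_network_config`.
#' @export
network_config <- function(layers = c("L2/3" = 200, "L4" = 200, "L5" = 200),
                           exc_frac = 0.8,
                           sheet_radius = 150,
                           sigma_d = 75,
                           delay_range = c(1L, 4L),
                           base_prob = NULL,
                           weight_meanlog = list(exc = log(5), inh = log(20)),
                           weight_sdlog = list(exc = 0.6, inh = 0.6),
                           tau_syn = NULL,
                           n_lgn_units = 208,
                           input_layers = c("L4" = 1, "L2/3" = 0.5,
                                            "L5" = 0.5),
                           input_n_per_neuron = 12,
                           input_weight_meanlog = log(2),
                           input_weight_sdlog = 0.4) {
  stopifnot(all(layers > 0), exc_frac > 0, exc_frac < 1)
  if (!is.finite(sigma_d) || sigma_d <= 0) stop("sigma_d must be > 0")
  delay_range <- as.integer(delay_range)
  stopifnot(length(delay_range) == 2, delay_range[1] >= 1L,
            delay_range[2] <= 4L, delay_range[1] <= delay_range[2])
  lnames <- names(layers)
  classes <- as.vector(rbind(paste0(lnames, "e"), paste0(lnames, "i")))
  class_layer <- rep(lnames, each = 2)
  class_sign <- rep(c(1L, -1L), times = length(lnames))
  nc <- length(classes)
  if (is.null(base_prob)) {
    base_prob <- matrix(0.08, nc, nc, dimnames = list(classes, classes))
    for (k in seq_along(lnames)) {
      idx <- which(class_layer == lnames[k])
      base_prob[idx, idx] <- 0.25
      base_prob[idx[2], idx] <- 0.5           # within-layer inhibition
      base_prob[idx[1], idx[2]] <- 0.4        # local E -> I
    }
    # feedforward excitatory motif L4e -> L2/3e -> L5e when layers present
    bump <- function(a, b) {
      if (a %in% classes && b %in% classes) base_prob[a, b] <<- 0.3
    }
    bump("L4e", "L2/3e"); bump("L2/3e", "L5e"); bump("L4e", "L5e")
    # a couple of unknown (never-connected) pairs, as in measured tables
    if ("L5i" %in% classes && "L2/3e" %in% classes) {
      base_prob["L5i", "L2/3e"] <- NA
    }
  } else {
    base_prob <- as.matrix(base_prob)
    stopifnot(nrow(base_prob) == nc, ncol(base_prob) == nc)
  }
  known <- base_prob[!is.na(base_prob)]
  if (any(!is.finite(known)) || any(known < 0) || any(known > 1)) {
    stop("base_prob entries must be probabilities in [0, 1] (or NA = unknown)")
  }
  if (is.null(tau_syn)) tau_syn <- default_tau_syn_table(classes, class_sign)
  structure(list(
    layers = layers, exc_frac = exc_frac, sheet_radius = sheet_radius,
    sigma_d = sigma_d, delay_range = delay_range,
    classes = classes, class_layer = class_layer, class_sign = class_sign,
    base_prob = base_prob,
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    tau_syn = tau_syn,
    n_lgn_units = n_lgn_units, input_layers = input_layers,
    input_n_per_neuron = input_n_per_neuron,
    input_weight_meanlog = input_weight_meanlog,
    input_weight_sdlog = input_weight_sdlog,
    diversity = "full"
  ), class = "glif_network_config")
}

# assign parameter types from the library to neurons, matching class sign;
# excitatory neurons cycle through excitatory types (and likewise inhibitory)
.assign_param_types <- function(sign, class, lib) {
  out <- integer(length(sign))
  for (s in c(1L, -1L)) {
    cand <- lib$param_type[lib$sign == s]
    if (length(cand) == 0) cand <- lib$param_type  # single-type (LIF) library
    idx <- which(sign == s)
    if (length(idx)) out[idx] <- cand[1 + (seq_along(idx) - 1L) %% length(cand)]
  }
  out
}

.sample_positions <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

.sample_edges <- function(neurons, config) {
  n <- nrow(neurons)
  cls_idx <- match(neurons$class, config$classes)
  bp <- config$base_prob
  bp[is.na(bp)] <- 0
  pre_all <- integer(0); post_all <- integer(0); dist_all <- numeric(0)
  block <- 512L
  for (start in seq(1L, n, by = block)) {
    ii <- start:min(start + block - 1L, n)
    dx <- outer(neurons$x[ii], neurons$x, "-")
    dy <- outer(neurons$y[ii], neurons$y, "-")
    d <- sqrt(dx * dx + dy * dy)
    p <- bp[cls_idx[ii], cls_idx, drop = FALSE] * exp(-d / config$sigma_d)
    # no self-connections
    p[cbind(seq_along(ii), ii)] <- 0
    hit <- which(matrix(stats::runif(length(p)), nrow(p)) < p, arr.ind = TRUE)
    pre_all <- c(pre_all, ii[hit[, 1]])
    post_all <- c(post_all, hit[, 2])
    dist_all <- c(dist_all, d[hit])
  }
  data.frame(pre = pre_all, post = post_all, dist = dist_all)
}

.draw_weights <- function(pre_sign, config) {
  n <- length(pre_sign)
  ml <- ifelse(pre_sign > 0, config$weight_meanlog$exc, config$weight_meanlog$inh)
  sl <- ifelse(pre_sign > 0, config$weight_sdlog$exc, config$weight_sdlog$inh)
  pre_sign * stats::rlnorm(n, ml, sl)
}

.build_input <- function(neurons, config) {
  il <- config$input_layers
  if (is.null(names(il))) il <- stats::setNames(rep(1, length(il)), il)
  targets <- integer(0)
  for (ln in names(il)) {
    cand <- which(neurons$layer == ln)
    keep <- cand[stats::runif(length(cand)) < il[[ln]]]
    targets <- c(targets, keep)
  }
  targets <- sort(targets)
  k <- config$input_n_per_neuron
  unit <- integer(0); post <- integer(0)
  for (j in targets) {
    u <- sample.int(config$n_lgn_units, min(k, config$n_lgn_units))
    unit <- c(unit, u); post <- c(post, rep(j, length(u)))
  }
  data.frame(unit = unit, post = post,
             weight = stats::rlnorm(length(unit), config$input_weight_meanlog,
                                    config$input_weight_sdlog))
}

#' Build a synthetic laminar network
#'
#' Samples neuron positions (uniform over a disc per layer), classes, GLIF_3
#' parameter types, distance-dependent recurrent connectivity, signed
#' log-normal weights, integer delays, and positive LGN-input weights. The
#' connection for pair (i, j) is drawn independently with probability
#' `base_prob[class_i, class_j] * exp(-d_ij / sigma_d)` with `d_ij` the
#' lateral Euclidean distance. The build is reproducible from `seed`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return An object of class `glif_network`: list with `neurons` (data.frame
#'   id, class, layer, sign, param_type, x, y), `edges` (pre, post, weight pA,
#'   delay ms, tau_syn ms), `input` (unit, post, weight), `params` (parameter
#'   library rows in use), plus config, seed and bookkeeping fields.
#' @export
build_network <- function(config, seed = 1) {
  stopifnot(inherits(config, "glif_network_config"))
  set.seed(seed)
  lib <- glif3_parameter_library(config$diversity)
  lnames <- names(config$layers)
  neurons <- do.call(rbind, lapply(lnames, function(ln) {
    nl <- config$layers[[ln]]
    ne <- round(nl * config$exc_frac)
    sign <- c(rep(1L, ne), rep(-1L, nl - ne))
    pos <- .sample_positions(nl, config$sheet_radius)
    data.frame(class = paste0(ln, ifelse(sign > 0, "e", "i")),
               layer = ln, sign = sign, x = pos[, 1], y = pos[, 2])
  }))
  neurons$id <- seq_len(nrow(neurons))
  neurons <- neurons[, c("id", "class", "layer", "sign", "x", "y")]
  neurons$param_type <- .assign_param_types(neurons$sign, neurons$class, lib)
  edges <- .sample_edges(neurons, config)
  edges$weight <- .draw_weights(neurons$sign[edges$pre], config)
  edges$delay <- sample(seq(config$delay_range[1], config$delay_range[2]),
                        nrow(edges), replace = TRUE)
  edges$tau_syn <- config$tau_syn[cbind(match(neurons$class[edges$pre], config$classes),
                                        match(neurons$class[edges$post], config$classes))]
  edges$dist <- NULL
  input <- .build_input(neurons, config)
  structure(list(neurons = neurons, edges = edges, input = input,
                 params = lib, config = config, seed = seed,
                 n_inputs = config$n_lgn_units,
                 input_mode = "lgn", bypass_scale = 0.04,
                 sign_constrained = TRUE, variant = "laminar"),
            class = "glif_network")
}

#' Build a control-model variant
#'
#' Produces the standard ablation controls of the laminar model:
#' \describe{
#'   \item{`no_lgn`}{identical network, but flagged to receive scaled pixel
#'     values directly instead of LGN filter outputs (bypass scale 0.04).}
#'   \item{`no_diversity`}{one generic excitatory and one generic inhibitory
#'     parameter type instead of the full library.}
#'   \item{`no_laminar`}{same neurons and *the same number* of connections,
#'     but uniformly random pre/post pairs (no distance dependence).}
#'   \item{`rsnn`}{uniformly random connectivity, a single LIF type (10-ms
#'     membrane constant, 5-ms refractory period, no after-spike currents),
#'     and no sign constraint: edge signs are random with P(+) = `exc_frac`.}
#'   \item{`rsnn_ei`}{like `rsnn` but neurons keep their E/I identity and
#'     Dale's law holds.}
#' }
#'
#' @param variant One of `"no_lgn"`, `"no_diversity"`, `"no_laminar"`,
#'   `"rsnn"`, `"rsnn_ei"`.
#' @param config A [network_config()].
#' @param seed Integer seed (the matched base network uses the same seed).
#' @return A `glif_network`.
#' @export
build_control_variant <- function(variant, config, seed = 1) {
  variant <- match.arg(variant,
    c("no_lgn", "no_diversity", "no_laminar", "rsnn", "rsnn_ei"))
  if (variant == "no_diversity") {
    cfg <- config
    cfg$diversity <- "minimal"
    net <- build_network(cfg, seed)
    net$variant <- variant
    return(net)
  }
  net <- build_network(config, seed)
  net$variant <- variant
  if (variant == "no_lgn") {
    net$input_mode <- "pixels"
    return(net)
  }
  # uniformly random rewiring with the same edge count, no self-connections
  set.seed(seed + 1L)
  n <- nrow(net$neurons); ne <- nrow(net$edges)
  pre <- sample.int(n, ne, replace = TRUE)
  post <- sample.int(n, ne, replace = TRUE)
  loop <- which(pre == post)
  while (length(loop)) {
    post[loop] <- sample.int(n, length(loop), replace = TRUE)
    loop <- loop[pre[loop] == post[loop]]
  }
  net$edges$pre <- pre
  net$edges$post <- post
  mag <- abs(net$edges$weight)
  if (variant %in% c("rsnn", "rsnn_ei")) {
    lib <- glif3_parameter_library("lif")
    net$params <- lib
    net$neurons$param_type <- 1L
    net$edges$tau_syn <- 5
  }
  if (variant == "rsnn") {
    net$sign_constrained <- FALSE
    net$edges$weight <- mag * ifelse(stats::runif(ne) < config$exc_frac, 1, -1)
  } else {
    net$edges$weight <- mag * net$neurons$sign[pre]
  }
  net
}

#' Lateral distance between two neurons
#' @param network A `glif_network`. @param i,j Neuron ids.
#' @return Euclidean lateral distance in um.
#' @export
lateral_distance <- function(network, i, j) {
  with(network$neurons,
       sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
}
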