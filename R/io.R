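# Plain-text serialization: networks as CSV tables + YAML metadata,
# edge lists as MatrixMarket, rasters as event CSV, images as PNG.

#' Write a network to a directory
#'
#' Serializes a `glif_network` as plain text: `neurons.csv`, `edges.csv`,
#' `input.csv`, `params.csv` and `meta.yaml` (config scalars and the build
#' seed, so the network is regenerable).
#'
#' @param network A `glif_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(network$neurons, file.path(dir, "neurons.csv"), row.names = FALSE)
  utils::write.csv(network$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(network$input, file.path(dir, "input.csv"), row.names = FALSE)
  utils::write.csv(network$params, file.path(dir, "params.csv"), row.names = FALSE)
  cfg <- network$config
  meta <- list(
    seed = network$seed, variant = network$variant,
    input_mode = network$input_mode, bypass_scale = network$bypass_scale,
    sign_constrained = network$sign_constrained,
    n_inputs = network$n_inputs,
    config = list(
      layers = as.list(cfg$layers), exc_frac = cfg$exc_frac,
      sheet_radius = cfg$sheet_radius, sigma_d = cfg$sigma_d,
      delay_range = cfg$delay_range, diversity = cfg$diversity,
      classes = cfg$classes,
      base_prob = apply(cfg$base_prob, 1, as.list, simplify = FALSE),
      tau_syn = apply(cfg$tau_syn, 1, as.list, simplify = FALSE),
      n_lgn_units = cfg$n_lgn_units,
      input_layers = as.list(cfg$input_layers),
      input_n_per_neuron = cfg$input_n_per_neuron,
      weight_meanlog = cfg$weight_meanlog, weight_sdlog = cfg$weight_sdlog,
      input_weight_meanlog = cfg$input_weight_meanlog,
      input_weight_sdlog = cfg$input_weight_sdlog
    )
  )
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a network written by [write_network()]
#' @param dir Directory containing the serialized network.
#' @return A `glif_network`.
#' @export
read_network <- function(dir) {
  neurons <- utils::read.csv(file.path(dir, "neurons.csv"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  input <- utils::read.csv(file.path(dir, "input.csv"))
  params <- utils::read.csv(file.path(dir, "params.csv"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  cls <- unlist(meta$config$classes)
  as_mat <- function(x) {
    m <- do.call(rbind, lapply(x, function(r) unlist(lapply(r, function(v) {
      if (is.null(v)) NA_real_ else as.numeric(v)
    }))))
    dimnames(m) <- list(cls, cls)
    m
  }
  cfg <- structure(list(
    layers = unlist(meta$config$layers), exc_frac = meta$config$exc_frac,
    sheet_radius = meta$config$sheet_radius, sigma_d = meta$config$sigma_d,
    delay_range = as.integer(unlist(meta$config$delay_range)),
    classes = cls,
    class_layer = sub("[ei]$", "", cls),
    class_sign = ifelse(grepl("e$", cls), 1L, -1L),
    base_prob = as_mat(meta$config$base_prob),
    tau_syn = as_mat(meta$config$tau_syn),
    n_lgn_units = meta$config$n_lgn_units,
    input_layers = unlist(meta$config$input_layers),
    input_n_per_neuron = meta$config$input_n_per_neuron,
    weight_meanlog = meta$config$weight_meanlog,
    weight_sdlog = meta$config$weight_sdlog,
    input_weight_meanlog = meta$config$input_weight_meanlog,
    input_weight_sdlog = meta$config$input_weight_sdlog,
    diversity = meta$config$diversity
  ), class = "glif_network_config")
  structure(list(neurons = neurons, edges = edges, input = input,
                 params = params, config = cfg, seed = meta$seed,
                 n_inputs = meta$n_inputs, input_mode = meta$input_mode,
                 bypass_scale = meta$bypass_scale,
                 sign_constrained = meta$sign_constrained,
                 variant = meta$variant),
            class = "glif_network")
}

#' Export the recurrent weight matrix as MatrixMarket
#'
#' Writes the signed weight matrix (rows = postsynaptic) to `<path>` and the
#' integer delay matrix to `<path>.delays` in MatrixMarket coordinate format.
#'
#' @param network A `glif_network`.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
export_edges_mtx <- function(network, path) {
  n <- nrow(network$neurons)
  e <- network$edges
  W <- Matrix::sparseMatrix(i = e$post, j = e$pre, x = e$weight, dims = c(n, n))
  Matrix::writeMM(W, path)
  D <- Matrix::sparseMatrix(i = e$post, j = e$pre, x = as.numeric(e$delay),
                            dims = c(n, n))
  Matrix::writeMM(D, paste0(path, ".delays"))
  invisible(path)
}

#' Write / read a spike raster as an event list
#'
#' Events are `(neuron_id, time_ms)` rows in CSV; the header records the
#' raster dimensions so silent neurons and trailing silent time are kept.
#'
#' @param raster Binary matrix, neurons x time.
#' @param path CSV path.
#' @return `path` invisibly for the writer; the raster for the reader.
#' @export
write_raster_csv <- function(raster, path) {
  idx <- which(raster != 0, arr.ind = TRUE)
  df <- data.frame(neuron_id = idx[, 1], time_ms = idx[, 2])
  df <- df[order(df$time_ms, df$neuron_id), ]
  con <- file(path, "w")
  writeLines(sprintf("# n_neurons=%d n_time=%d", nrow(raster), ncol(raster)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  dims <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  df <- utils::read.csv(path, skip = 1)
  r <- matrix(0L, dims[1], dims[2])
  if (nrow(df)) r[cbind(df$neuron_id, df$time_ms)] <- 1L
  r
}

#' Write a grayscale image as PNG
#' @param image Matrix with values in \[0, 255\].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Read a PNG as a grayscale \[0, 255\] matrix
#' @param path PNG path.
#' @return Matrix in \[0, 255\] (multi-channel images are luminance-averaged).
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE],
                                          c(1, 2), mean)
  img * 255
}
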