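# End-to-end orchestration: robustness sweeps over internal and pixel noise,
# and a build -> train -> test -> analyze pipeline with seed provenance.

#' Accuracy over a grid of internal-noise amplitudes
#'
#' Evaluates task accuracy for every `(q, s)` combination of quick/slow noise
#' scales, averaging over tasks and trials.
#'
#' @param network A (typically trained) `glif_network`.
#' @param pools,assignment Readout pools and task assignment.
#' @param tasks Tasks to average over.
#' @param q_values,s_values Noise-scale grids (defaults include the standard
#'   q = s = 2 operating point).
#' @param n_trials Trials per task per cell.
#' @param seed Integer seed.
#' @param ... Passed to [evaluate_accuracy()] (bank, glyphs, ensemble,
#'   duration, trial_args).
#' @return data.frame: `q`, `s`, `accuracy`.
#' @export
run_robustness_sweep <- function(network, pools, assignment,
                                 tasks = names(assignment),
                                 q_values = c(0, 2, 20),
                                 s_values = c(0, 2, 20),
                                 n_trials = 5, seed = 1, ...) {
  grid <- expand.grid(q = q_values, s = s_values)
  grid$accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    acc <- evaluate_accuracy(network, pools, assignment, tasks = tasks,
                             n_trials = n_trials,
                             noise = noise_model(q = grid$q[i], s = grid$s[i]),
                             seed = seed, ...)
    grid$accuracy[i] <- mean(acc$accuracy)
  }
  grid
}

#' Accuracy versus pixel-noise SD
#'
#' Evaluates the classification task with i.i.d. Gaussian pixel noise of
#' increasing SD added to the images before scaling.
#'
#' @param network A `glif_network`. @param pools,assignment Readouts.
#' @param glyphs Glyph ensemble for the classification task.
#' @param sd_values Pixel-noise SDs (raw pixel units).
#' @param n_trials Trials per SD.
#' @param noise Internal [noise_model()] during evaluation.
#' @param seed Integer seed.
#' @param ... Passed to [evaluate_accuracy()].
#' @return data.frame: `sd`, `accuracy`.
#' @export
run_pixel_noise_sweep <- function(network, pools, assignment, glyphs,
                                  sd_values = c(0, 16, 32, 64),
                                  n_trials = 10, noise = noise_model(),
                                  seed = 1, ...) {
  out <- data.frame(sd = sd_values, accuracy = NA_real_)
  for (i in seq_along(sd_values)) {
    acc <- evaluate_accuracy(
      network, pools, assignment, tasks = "classification",
      n_trials = n_trials, noise = noise, glyphs = glyphs, seed = seed,
      trial_args = list(classification = list(pixel_noise_sd = sd_values[i])),
      ...)
    out$accuracy[i] <- acc$accuracy[1]
  }
  out
}

#' Experiment configuration
#'
#' Bundles the settings of an end-to-end run; every sub-seed is derived
#' deterministically from `master_seed`.
#'
#' @param network_config A [network_config()].
#' @param tasks Tasks to train and evaluate.
#' @param train_steps Weight updates. @param batch_per_task Trials/task/batch.
#' @param n_pools,pool_size Readout-pool geometry.
#' @param duration Trial length (ms).
#' @param eval_trials Test trials per task.
#' @param analysis_images Stimuli for the eigenspectrum analysis.
#' @param branching_T Duration (ms) of the criticality run.
#' @param master_seed Master seed.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(network_config = NULL,
                              tasks = c("orientation", "change_gratings"),
                              train_steps = 30, batch_per_task = 2,
                              n_pools = 3, pool_size = 10,
                              duration = 300, eval_trials = 5,
                              analysis_images = 24, branching_T = 3000,
                              master_seed = 1) {
  if (is.null(network_config)) network_config <- network_config()
  structure(list(network_config = network_config, tasks = tasks,
                 train_steps = train_steps, batch_per_task = batch_per_task,
                 n_pools = n_pools, pool_size = pool_size,
                 duration = duration, eval_trials = eval_trials,
                 analysis_images = analysis_images,
                 branching_T = branching_T, master_seed = master_seed),
            class = "experiment_config")
}

#' Run a scaled-down end-to-end experiment
#'
#' Builds the network (and optionally control variants), trains it on the
#' configured tasks, evaluates test accuracy under the data-driven noise
#' model, and runs the coding analyses: eigenspectrum + power-law fit,
#' branching ratio, Fano factor and rate distribution. All stage seeds are
#' derived from the master seed and recorded in the report.
#'
#' @param config An [experiment_config()].
#' @param variants Control variants to include (e.g. `"rsnn"`); default none.
#' @param outdir Optional directory for CSV/JSON outputs.
#' @return List of class `experiment_report`.
#' @export
run_end_to_end <- function(config = experiment_config(), variants = character(0),
                           outdir = NULL) {
  ms <- config$master_seed
  seeds <- list(build = ms + 1L, pools = ms + 2L, train = ms + 3L,
                eval = ms + 4L, analysis = ms + 5L)
  models <- list(laminar = build_network(config$network_config, seeds$build))
  for (v in variants) {
    models[[v]] <- build_control_variant(v, config$network_config, seeds$build)
  }
  bank <- lgn_filter_bank()
  glyphs <- if ("classification" %in% config$tasks) {
    make_glyph_ensemble(4, seed = ms + 6L)
  } else NULL
  ensemble <- if (any(c("change_images") %in% config$tasks)) {
    make_image_ensemble(40, seed = ms + 7L)
  } else NULL
  report <- list(config = config, seeds = seeds, models = list())
  for (nm in names(models)) {
    net <- models[[nm]]
    pools <- readout_pools(net, n_pools = config$n_pools,
                           pool_size = config$pool_size,
                           placement = "distributed", seed = seeds$pools)
    assignment <- readout_assignment_subset(pools, config$tasks)
    tr <- train_network(net, pools, assignment, tasks = config$tasks,
                        steps = config$train_steps,
                        batch_per_task = config$batch_per_task,
                        duration = config$duration, bank = bank,
                        glyphs = glyphs, ensemble = ensemble,
                        seed = seeds$train)
    acc <- evaluate_accuracy(tr$network, pools, assignment,
                             tasks = config$tasks,
                             n_trials = config$eval_trials,
                             duration = config$duration, bank = bank,
                             glyphs = glyphs, ensemble = ensemble,
                             seed = seeds$eval)
    # criticality: population counts under an image-sequence drive
    ens_b <- if (is.null(ensemble)) make_image_ensemble(8, seed = ms + 8L)
             else ensemble
    drive_img <- scale_image(ens_b[, , 1])
    frames <- matrix(as.vector(drive_img), nrow = length(drive_img),
                     ncol = config$branching_T)
    stim <- visual_stimulus(frames, H = dim(ens_b)[1], W = dim(ens_b)[2])
    cur <- stimulus_currents(tr$network, stim, bank)
    simb <- simulate_network(tr$network, cur, noise_model(),
                             T = config$branching_T, seed = seeds$analysis,
                             record = "counts")
    br <- branching_ratio(simb$counts[-(1:200)])
    # Fano + rates on repeated identical trials
    n_rep <- 5
    rasters <- lapply(seq_len(n_rep), function(r) {
      simulate_network(tr$network, cur[, 1:config$duration], noise_model(),
                       T = config$duration,
                       seed = seeds$analysis + r)$spikes
    })
    ff <- fano_factor(rasters)
    rd <- rate_distribution(rasters[[1]])
    # eigenspectrum on a small image ensemble
    ens_s <- make_image_ensemble(config$analysis_images,
                                 seed = ms + 9L)
    rm_ <- response_matrices(tr$network, ens_s, bank, seed = seeds$analysis)
    lam <- cvpca(rm_$X1, rm_$X2)
    pl <- tryCatch(fit_power_law(lam[lam > 0]), error = function(e) NULL)
    report$models[[nm]] <- list(
      accuracy = acc, final_loss = utils::tail(tr$metrics$loss, 1),
      metrics = tr$metrics,
      branching = list(m = br$m, failed = br$failed),
      fano = ff$fano, mean_rate_hz = mean(rd$rates_hz),
      eigenspectrum = lam,
      power_law = if (!is.null(pl)) {
        list(alpha = pl$alpha, r2 = pl$r2, flagged = pl$flagged)
      } else NULL)
  }
  class(report) <- "experiment_report"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(report$models)) {
      m <- report$models[[nm]]
      utils::write.csv(m$accuracy,
                       file.path(outdir, paste0(nm, "_accuracy.csv")),
                       row.names = FALSE)
      utils::write.csv(m$metrics,
                       file.path(outdir, paste0(nm, "_training.csv")),
                       row.names = FALSE)
    }
    summary_list <- lapply(report$models, function(m) {
      list(mean_accuracy = mean(m$accuracy$accuracy),
           branching_m = m$branching$m, fano = m$fano,
           mean_rate_hz = m$mean_rate_hz,
           power_law_alpha = if (!is.null(m$power_law)) m$power_law$alpha
                             else NA)
    })
    jsonlite::write_json(list(seeds = seeds, models = summary_list),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# pool assignment for a subset of tasks using however many pools exist:
# tasks get their required pool counts in order, reusing the smaller pool set
readout_assignment_subset <- function(pools, tasks) {
  req <- task_pool_requirements()[tasks]
  need <- sum(req)
  have <- length(pools$pools)
  if (have >= need) return(readout_assignment(pools, tasks))
  # desk-scale fallback: argmax tasks get min(required, available) pools
  out <- list(); i <- 0L
  for (tk in tasks) {
    k <- min(req[[tk]], max(1L, have - i))
    if (tk == "classification" && k < 10) {
      stop("classification needs 10 pools; increase n_pools")
    }
    if (tk == "evidence" && k < 2) stop("evidence needs 2 pools")
    if (i + k > have) stop("not enough pools for the requested tasks")
    out[[tk]] <- (i + 1):(i + k)
    i <- i + k
  }
  out
}
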