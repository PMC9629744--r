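# Trial generators for the five visual tasks, readout-pool assignment,
# and decision rules computed from readout-pool firing.

#' Names of the five tasks
#' @return Character vector of task ids.
#' @export
task_names <- function() {
  c("orientation", "classification", "change_images", "change_gratings",
    "evidence")
}

#' Number of readout pools each task requires
#' @return Named integer vector (15 pools in total).
#' @export
task_pool_requirements <- function() {
  c(orientation = 1L, classification = 10L, change_images = 1L,
    change_gratings = 1L, evidence = 2L)
}

#' Chance level of a task
#'
#' The analytic accuracy of uninformed guessing: `1/2` for the binary tasks
#' (orientation side, change/no-change, left/right evidence) and `1/10` for
#' the 10-way classification task.
#'
#' @param task A task id from [task_names()], or missing for all tasks.
#' @return Named numeric vector of chance accuracies.
#' @export
chance_level <- function(task = task_names()) {
  n_alt <- c(orientation = 2, classification = 10, change_images = 2,
             change_gratings = 2, evidence = 2)
  1 / n_alt[match.arg(task, task_names(), several.ok = TRUE)]
}

# ---- stimulus builders -----------------------------------------------------

#' Drifting sinusoidal grating movie
#'
#' Luminance follows a sinusoid of the given orientation and spatial
#' frequency, drifting at `drift_hz` cycles per second (phase advances
#' `drift_hz / 1000` cycles per ms). The degrees-to-pixels conversion is
#' `px_per_deg` pixels per degree of visual angle (default 4), so the
#' default 0.05 cycles/degree becomes 0.0125 cycles/pixel. Values are
#' returned already scaled to \[-Int, Int\].
#'
#' @param orientation_deg Grating orientation in degrees.
#' @param T Duration in ms.
#' @param H,W Raster size. @param spatial_freq_cpd Cycles per degree.
#' @param drift_hz Drift rate (Hz); 0 gives a static grating.
#' @param phase0 Initial phase in cycles.
#' @param px_per_deg Pixels per degree. @param Int Scaled amplitude.
#' @return `npix x T` matrix of scaled luminance.
#' @export
grating_movie <- function(orientation_deg, T, H = 32, W = 32,
                          spatial_freq_cpd = 0.05, drift_hz = 2,
                          phase0 = 0, px_per_deg = 4, Int = 2) {
  f_px <- spatial_freq_cpd / px_per_deg
  th <- orientation_deg * pi / 180
  px <- expand.grid(row = seq_len(H), col = seq_len(W))
  proj <- f_px * (px$col * cos(th) + px$row * sin(th))
  phase_t <- phase0 + (drift_hz / 1000) * (seq_len(T) - 1)
  Int * sin(2 * pi * outer(proj, phase_t, "+"))
}

# embed a static scaled image into columns [t0+1, t1] of a npix x T movie
.place_image <- function(movie, img_scaled, t0, t1) {
  movie[, (t0 + 1):t1] <- as.vector(img_scaled)
  movie
}

# ---- readout pools ---------------------------------------------------------

#' Select readout pools of excitatory L5 neurons
#'
#' Pools are disjoint sets of `pool_size` excitatory neurons in layer L5.
#' `"colocated"` placement draws each pool from a sphere of radius
#' `radius` um around centers at least `min_spacing` um apart;
#' `"distributed"` samples uniformly from all excitatory L5 neurons.
#'
#' @param network A `glif_network`.
#' @param n_pools Number of pools. Default 15 (the five-task requirement).
#' @param pool_size Neurons per pool. Default 30.
#' @param placement `"colocated"` or `"distributed"`.
#' @param radius Sphere radius (um) for colocated pools. Default 55.
#' @param min_spacing Minimal center spacing (um). Default 150.
#' @param seed Integer seed.
#' @return List of class `readout_pools`: `pools` (list of id vectors),
#'   `r0` threshold (0.01 spikes/neuron/ms), placement metadata.
#' @export
readout_pools <- function(network, n_pools = 15, pool_size = 30,
                          placement = c("colocated", "distributed"),
                          radius = 55, min_spacing = 150, seed = 1) {
  placement <- match.arg(placement)
  set.seed(seed)
  cand <- network$neurons[network$neurons$layer == "L5" &
                            network$neurons$sign > 0, ]
  if (nrow(cand) < n_pools * pool_size) {
    stop(sprintf("need %d excitatory L5 neurons for %d pools of %d, have %d",
                 n_pools * pool_size, n_pools, pool_size, nrow(cand)))
  }
  pools <- vector("list", n_pools)
  if (placement == "distributed") {
    picked <- sample(cand$id, n_pools * pool_size)
    for (k in seq_len(n_pools)) {
      pools[[k]] <- picked[((k - 1) * pool_size + 1):(k * pool_size)]
    }
  } else {
    centers <- matrix(NA_real_, 0, 2)
    avail <- cand
    for (k in seq_len(n_pools)) {
      ok <- FALSE
      for (try in seq_len(500)) {
        ci <- avail[sample.int(nrow(avail), 1), ]
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - ci$x)^2 + (centers[, 2] - ci$y)^2) >=
                min_spacing)) {
          d <- sqrt((avail$x - ci$x)^2 + (avail$y - ci$y)^2)
          near <- avail$id[d <= radius]
          if (length(near) >= pool_size) {
            pools[[k]] <- sample(near, pool_size)
            centers <- rbind(centers, c(ci$x, ci$y))
            avail <- avail[!(avail$id %in% pools[[k]]), ]
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) stop("could not place colocated pools; ",
                    "reduce n_pools/pool_size or min_spacing")
    }
  }
  structure(list(pools = pools, r0 = 0.01, pool_size = pool_size,
                 placement = placement, radius = radius,
                 min_spacing = min_spacing),
            class = "readout_pools")
}

#' Assign pools to tasks
#'
#' Splits a pool set among the five tasks in the order of
#' [task_pool_requirements()] (1 + 10 + 1 + 1 + 2 = 15 pools by default).
#'
#' @param pools A [readout_pools()] object.
#' @param tasks Task ids to serve. Default all five.
#' @return Named list mapping task id to pool indices.
#' @export
readout_assignment <- function(pools, tasks = task_names()) {
  req <- task_pool_requirements()[tasks]
  if (sum(req) > length(pools$pools)) {
    stop("not enough pools for the requested tasks")
  }
  out <- list(); i <- 0L
  for (tk in tasks) {
    out[[tk]] <- (i + 1):(i + req[[tk]])
    i <- i + req[[tk]]
  }
  out
}

# ---- trial generators ------------------------------------------------------

.trial_spec <- function(task, frames, H, W, windows, decision, n_classes,
                        reset_state, schedule, meta = list()) {
  stopifnot(all(windows$t1 - windows$t0 == 50))
  structure(list(task = task,
                 stimulus = visual_stimulus(frames, H = H, W = W),
                 duration = ncol(frames), windows = windows,
                 decision = decision, n_classes = n_classes,
                 reset_state = reset_state, schedule = schedule, meta = meta),
            class = "trial_spec")
}

#' Fine orientation discrimination trial
#'
#' 50-ms blank, 100-ms drifting grating (spatial frequency 0.05 cycles per
#' degree, drift 2 Hz, random initial phase), 50-ms response window. The
#' orientation is uniform on \{43.0, 43.1, ..., 47.0\} degrees; the target is
#' whether it exceeds 45 degrees (threshold decision on one pool).
#'
#' @param seed Integer seed.
#' @param duration Trial length in ms (>= 200). Default 600.
#' @param H,W Raster size.
#' @param orientations Optional vector to restrict the sampled orientations
#'   (e.g. `c(43, 47)` for the extreme-contrast curriculum).
#' @return A `trial_spec`.
#' @export
make_orientation_trial <- function(seed = 1, duration = 600, H = 32, W = 32,
                                   orientations = NULL) {
  stopifnot(duration >= 200)
  set.seed(seed)
  ori <- if (is.null(orientations)) {
    43 + sample.int(41, 1) / 10 - 0.1
  } else sample(orientations, 1)
  phase0 <- stats::runif(1)
  frames <- matrix(0, H * W, duration)
  frames[, 51:150] <- grating_movie(ori, 100, H, W, phase0 = phase0)
  windows <- data.frame(t0 = 150, t1 = 200, target = as.integer(ori > 45))
  sched <- data.frame(kind = c("blank", "grating", "response", "blank"),
                      t0 = c(0, 50, 150, 200), t1 = c(50, 150, 200, duration))
  sched <- sched[sched$t1 > sched$t0, ]
  .trial_spec("orientation", frames, H, W, windows, "threshold", 2, TRUE,
              sched, meta = list(orientation = ori, phase0 = phase0))
}

#' Image classification trial (10-class glyphs)
#'
#' Same timing as the orientation task: 50-ms blank, 100-ms image, 50-ms
#' response window. The target is the glyph class (0..9); the decision is the
#' most active of the task's 10 pools during the response window.
#'
#' @param glyphs A [make_glyph_ensemble()] result.
#' @param seed Integer seed.
#' @param duration Trial length in ms. Default 600.
#' @param pixel_noise_sd Optional Gaussian pixel-noise SD (raw units) added
#'   to the image before scaling. Default 0.
#' @return A `trial_spec`.
#' @export
make_classification_trial <- function(glyphs, seed = 1, duration = 600,
                                      pixel_noise_sd = 0) {
  stopifnot(duration >= 200)
  set.seed(seed)
  i <- sample.int(length(glyphs$labels), 1)
  img <- glyphs$images[, , i]
  if (pixel_noise_sd > 0) {
    img <- add_pixel_noise(img, pixel_noise_sd, seed = seed + 10^6)
  }
  H <- nrow(img); W <- ncol(img)
  frames <- matrix(0, H * W, duration)
  frames <- .place_image(frames, scale_image(img), 50, 150)
  windows <- data.frame(t0 = 150, t1 = 200, target = glyphs$labels[i])
  sched <- data.frame(kind = c("blank", "image", "response", "blank"),
                      t0 = c(0, 50, 150, 200), t1 = c(50, 150, 200, duration))
  sched <- sched[sched$t1 > sched$t0, ]
  .trial_spec("classification", frames, H, W, windows, "argmax", 10, TRUE,
              sched, meta = list(class = glyphs$labels[i], index = i))
}

#' Identity sequence for change detection
#'
#' Draws a sequence of presentation identities where each presentation
#' differs from its predecessor with probability `p_change`; when it changes,
#' the new identity is uniform over the remaining ones.
#'
#' @param n_presentations Sequence length.
#' @param n_images Ensemble size. Default 40.
#' @param p_change Change probability. Default 0.5.
#' @param seed Integer seed.
#' @param first Optional fixed first identity (e.g. carried over from the
#'   previous trial); when given, the first presentation also flips with
#'   probability `p_change`, otherwise it is an unchanged start.
#' @return data.frame with `id` and logical `changed` per presentation.
#' @export
change_detection_sequence <- function(n_presentations, n_images = 40,
                                      p_change = 0.5, seed = 1, first = NULL) {
  set.seed(seed)
  id <- integer(n_presentations); changed <- logical(n_presentations)
  prev <- first
  for (k in seq_len(n_presentations)) {
    if (is.null(prev)) {
      id[k] <- sample.int(n_images, 1); changed[k] <- FALSE
    } else if (stats::runif(1) < p_change) {
      id[k] <- sample(setdiff(seq_len(n_images), prev), 1); changed[k] <- TRUE
    } else {
      id[k] <- prev; changed[k] <- FALSE
    }
    prev <- id[k]
  }
  data.frame(id = id, changed = changed)
}

#' Visual change detection trial
#'
#' The first image appears at 50 ms; 100-ms presentations alternate with
#' 200-ms gray screens (onsets at 50 and 350 ms within a 600-ms trial). Each
#' presentation differs from its predecessor with probability 50%. The
#' response window is 50 ms long, starting 150 ms after image onset; the
#' target per window is changed/unchanged and the decision is the threshold
#' rule on one pool. State is *not* reset between consecutive trials
#' (`reset_state = FALSE`); pass the previous trial's `meta$last_id` (and for
#' gratings `meta$last_orientation`) as `carryover` to chain trials.
#'
#' @param kind `"images"` (texture ensemble) or `"gratings"` (static gratings
#'   with orientation uniform on \[120, 150\] degrees at 0.1 precision).
#' @param ensemble For `"images"`: array from [make_image_ensemble()]
#'   (40 images by default elsewhere).
#' @param seed Integer seed.
#' @param carryover Previous-trial identity (image index, or orientation in
#'   degrees for gratings), or `NULL`.
#' @param duration Trial length in ms. Default 600.
#' @param H,W Raster size used for gratings.
#' @return A `trial_spec`; `meta$last_id` / `meta$last_orientation` carry the
#'   final identity for chaining.
#' @export
make_change_detection_trial <- function(kind = c("images", "gratings"),
                                        ensemble = NULL, seed = 1,
                                        carryover = NULL, duration = 600,
                                        H = 32, W = 32) {
  kind <- match.arg(kind)
  onsets <- seq(50, duration - 250, by = 300)
  if (kind == "images") {
    stopifnot(!is.null(ensemble))
    n_im <- dim(ensemble)[3]
    H <- dim(ensemble)[1]; W <- dim(ensemble)[2]
    seqd <- change_detection_sequence(length(onsets), n_im, seed = seed,
                                      first = carryover)
    frames <- matrix(0, H * W, duration)
    for (k in seq_along(onsets)) {
      frames <- .place_image(frames, scale_image(ensemble[, , seqd$id[k]]),
                             onsets[k], onsets[k] + 100)
    }
    last <- seqd$id[length(onsets)]
    meta <- list(ids = seqd$id, last_id = last)
  } else {
    set.seed(seed)
    oris <- numeric(length(onsets)); changed <- logical(length(onsets))
    grid <- seq(120, 150, by = 0.1)
    prev <- carryover
    for (k in seq_along(onsets)) {
      if (is.null(prev)) {
        oris[k] <- sample(grid, 1); changed[k] <- FALSE
      } else if (stats::runif(1) < 0.5) {
        oris[k] <- sample(setdiff(grid, prev), 1); changed[k] <- TRUE
      } else {
        oris[k] <- prev; changed[k] <- FALSE
      }
      prev <- oris[k]
    }
    seqd <- data.frame(id = oris, changed = changed)
    frames <- matrix(0, H * W, duration)
    for (k in seq_along(onsets)) {
      frames[, (onsets[k] + 1):(onsets[k] + 100)] <-
        grating_movie(oris[k], 100, H, W, drift_hz = 0)
    }
    meta <- list(orientations = oris, last_orientation = oris[length(onsets)])
  }
  windows <- data.frame(t0 = onsets + 150, t1 = onsets + 200,
                        target = as.integer(seqd$changed))
  sched <- data.frame(kind = "gray", t0 = 0, t1 = duration)
  task <- if (kind == "images") "change_images" else "change_gratings"
  .trial_spec(task, frames, H, W, windows, "threshold", 2, FALSE, sched, meta)
}

#' Evidence accumulation trial
#'
#' Seven 50-ms left/right cues separated by 10-ms blanks (cue k starts at
#' `60 k` ms), followed by a delay and a 50-ms response window ending at
#' trial end; the target is the side with the cue majority and the decision
#' is the more active of the task's two pools. The delay is whatever remains
#' between the last cue offset (410 ms) and the response window, 140 ms for
#' the default 600-ms trial.
#'
#' @param seed Integer seed.
#' @param duration Trial length in ms (>= 470). Default 600.
#' @param H,W Raster size.
#' @return A `trial_spec`; `meta$cues` holds the cue sides (0 left, 1 right).
#' @export
make_evidence_trial <- function(seed = 1, duration = 600, H = 32, W = 32) {
  stopifnot(duration >= 470)
  set.seed(seed)
  cues <- stats::rbinom(7, 1, 0.5)   # 0 = left, 1 = right
  frames <- matrix(0, H * W, duration)
  # cue image: a column of dark dots on the cued side of a gray corridor
  dot_rows <- round(seq(H * 0.2, H * 0.8, length.out = 4))
  cue_img <- function(side) {
    img <- matrix(0, H, W)
    colc <- if (side == 0) round(W * 0.2) else round(W * 0.8)
    for (r in dot_rows) {
      img[max(1, r - 1):min(H, r + 1), max(1, colc - 1):min(W, colc + 1)] <- -2
    }
    img
  }
  for (k in 0:6) {
    t0 <- 60 * k
    frames[, (t0 + 51):(t0 + 100)] <- as.vector(cue_img(cues[k + 1]))
  }
  # cue epochs start at 50 + 60k in the movie (50-ms lead-in blank)
  windows <- data.frame(t0 = duration - 50, t1 = duration,
                        target = as.integer(sum(cues) > 3.5))
  sched <- data.frame(kind = c("cues", "delay", "response"),
                      t0 = c(0, 470, duration - 50),
                      t1 = c(470, duration - 50, duration))
  .trial_spec("evidence", frames, H, W, windows, "argmax", 2, TRUE, sched,
              meta = list(cues = cues))
}

# ---- decisions -------------------------------------------------------------

#' Mean firing rate of a readout population
#'
#' `r = 1 / (T_resp * N_readout) * sum over window, pool of z_j(t)`, in
#' spikes per neuron per ms.
#'
#' @param raster Binary spike matrix, neurons x time.
#' @param pool Vector of neuron ids.
#' @param window `c(t0, t1)`: the window covers ms `t0+1 .. t1`.
#' @return Scalar rate.
#' @export
readout_rate <- function(raster, pool, window) {
  if (length(pool) == 0) stop("empty readout pool")
  cols <- (window[1] + 1):window[2]
  sum(raster[pool, cols, drop = FALSE]) / (length(cols) * length(pool))
}

#' Network decision(s) for a trial
#'
#' Threshold tasks: per response window, report 1 iff the pool rate exceeds
#' `r0 = 0.01`. Argmax tasks: report the index (0-based) of the most active
#' pool in the response window.
#'
#' @param trial A `trial_spec`.
#' @param raster Spike raster of the trial.
#' @param pools A [readout_pools()] object.
#' @param pool_idx Indices of the pools assigned to this task (from
#'   [readout_assignment()]).
#' @return data.frame with one row per response window: `target`, `decision`,
#'   `correct`.
#' @export
decide_trial <- function(trial, raster, pools, pool_idx) {
  out <- trial$windows
  out$decision <- NA_integer_
  for (w in seq_len(nrow(out))) {
    win <- c(out$t0[w], out$t1[w])
    if (trial$decision == "threshold") {
      r <- readout_rate(raster, pools$pools[[pool_idx[1]]], win)
      out$decision[w] <- as.integer(r > pools$r0)
    } else {
      rates <- vapply(pool_idx, function(k) {
        readout_rate(raster, pools$pools[[k]], win)
      }, numeric(1))
      out$decision[w] <- which.max(rates) - 1L
    }
  }
  out$correct <- out$decision == out$target
  out
}

#' Add Gaussian pixel noise to an image
#'
#' i.i.d. `Normal(0, SD)` per pixel, added to raw pixel values before
#' scaling. No clipping by default.
#'
#' @param image Matrix of raw pixel values.
#' @param sd Noise SD (>= 0). @param seed Integer seed.
#' @param clip Optional `c(lo, hi)` clipping bounds.
#' @return Noisy image, same shape.
#' @export
add_pixel_noise <- function(image, sd, seed = 1, clip = NULL) {
  stopifnot(sd >= 0)
  if (sd == 0) return(image)
  set.seed(seed)
  out <- image + matrix(stats::rnorm(length(image), 0, sd),
                        nrow(image), ncol(image))
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  out
}

#' Sample a trial for a task
#'
#' Uniform front end over the five generators, used by training and sweeps.
#'
#' @param task Task id.
#' @param seed Integer seed.
#' @param glyphs,ensemble Ensembles for classification / image change
#'   detection (built once and passed in).
#' @param duration Trial length in ms.
#' @param ... Passed through to the generator.
#' @return A `trial_spec`.
#' @export
sample_trial <- function(task, seed, glyphs = NULL, ensemble = NULL,
                         duration = 600, ...) {
  switch(task,
    orientation = make_orientation_trial(seed, duration = duration, ...),
    classification = make_classification_trial(glyphs, seed,
                                               duration = duration, ...),
    change_images = make_change_detection_trial("images", ensemble, seed,
                                                duration = duration, ...),
    change_gratings = make_change_detection_trial("gratings", seed = seed,
                                                  duration = duration, ...),
    evidence = make_evidence_trial(seed, duration = duration, ...),
    stop("unknown task: ", task))
}
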