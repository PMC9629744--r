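# Task suite: trial schedules, label statistics, readout pools and decisions.

test_that("orientation trials have the stated schedule and label rule", {
  oris <- sapply(1:200, function(s) {
    make_orientation_trial(seed = s, duration = 200)$meta$orientation
  })
  expect_true(all(oris >= 43 & oris <= 47))
  # 0.1-degree precision grid
  expect_true(all(abs(oris * 10 - round(oris * 10)) < 1e-9))
  expect_gt(length(unique(oris)), 20)
  tr <- make_orientation_trial(seed = 3)
  expect_equal(tr$duration, 600)
  expect_equal(tr$windows$t1 - tr$windows$t0, 50)
  expect_equal(tr$windows$target, as.integer(tr$meta$orientation > 45))
  # schedule tiles the trial exactly
  sch <- tr$schedule
  expect_equal(sch$t0[1], 0)
  expect_equal(sch$t1[nrow(sch)], 600)
  expect_true(all(sch$t0[-1] == sch$t1[-nrow(sch)]))
  # grating is blank before onset, active during presentation
  expect_true(all(tr$stimulus$frames[, 1:50] == 0))
  expect_gt(max(abs(tr$stimulus$frames[, 100])), 1)
})

test_that("grating drift advances phase by drift_hz/1000 cycles per ms", {
  m <- grating_movie(45, T = 3, H = 8, W = 8, drift_hz = 2, phase0 = 0.1)
  # recompute frame 3 from the stated phase increment
  m1 <- grating_movie(45, T = 1, H = 8, W = 8, drift_hz = 0,
                      phase0 = 0.1 + 2 * 0.002)
  expect_equal(m[, 3], m1[, 1], tolerance = 1e-12)
})

test_that("classification trials carry the glyph label and argmax decision", {
  g <- make_glyph_ensemble(3, size = 16, seed = 1)
  cls <- sapply(1:300, function(s) {
    make_classification_trial(g, seed = s, duration = 200)$windows$target
  })
  expect_setequal(unique(cls), 0:9)
  # uniform class sampling: multinomial 99.9% band around 1/10
  freq <- table(factor(cls, levels = 0:9)) / 300
  expect_true(all(abs(freq - 0.1) < 3.3 * sqrt(0.1 * 0.9 / 300)))
  tr <- make_classification_trial(g, seed = 7, duration = 200)
  expect_identical(tr$decision, "argmax")
  expect_equal(tr$n_classes, 10)
})

test_that("change-detection sequences change with probability 1/2", {
  seqd <- change_detection_sequence(5000, n_images = 40, seed = 2)
  p <- mean(seqd$changed[-1])
  expect_lt(abs(p - 0.5), 2.6 * sqrt(0.25 / 4999))
  # changed flag is consistent with the identity sequence
  expect_equal(seqd$changed[-1], seqd$id[-1] != seqd$id[-5000])
  # unchanged -> same id
  expect_true(all(seqd$id[-1][!seqd$changed[-1]] == seqd$id[-5000][!seqd$changed[-1]]))
})

test_that("change-detection trials: timing, targets, carryover chaining", {
  ens <- make_image_ensemble(40, size = 16, seed = 3)
  tr <- make_change_detection_trial("images", ens, seed = 4)
  expect_false(tr$reset_state)
  # presentations at 50 and 350 ms; response windows 150 ms after onset
  expect_equal(tr$windows$t0, c(200, 500))
  expect_equal(tr$windows$t1 - tr$windows$t0, c(50, 50))
  # identical consecutive images -> no change; different -> change
  expect_equal(tr$windows$target[2],
               as.integer(tr$meta$ids[2] != tr$meta$ids[1]))
  # carryover: first presentation compared against the carried identity
  tr2 <- make_change_detection_trial("images", ens, seed = 5,
                                     carryover = tr$meta$last_id)
  reps <- sapply(1:200, function(s) {
    t2 <- make_change_detection_trial("images", ens, seed = s, carryover = 1)
    t2$windows$target[1]
  })
  expect_gt(mean(reps), 0.3); expect_lt(mean(reps), 0.7)
  # grating variant: orientations on the [120, 150] grid at 0.1 precision
  tg <- make_change_detection_trial("gratings", seed = 6)
  oris <- tg$meta$orientations
  expect_true(all(oris >= 120 & oris <= 150))
  expect_true(all(abs(oris * 10 - round(oris * 10)) < 1e-9))
})

test_that("evidence trials follow the cue schedule and majority rule", {
  tr <- make_evidence_trial(seed = 7)
  expect_equal(tr$windows$target, as.integer(sum(tr$meta$cues) > 3.5))
  expect_length(tr$meta$cues, 7)
  # cue k occupies movie ms 60k+51 .. 60k+100 (50-ms cues, 10-ms gaps)
  f <- tr$stimulus$frames
  for (k in 0:6) {
    expect_gt(sum(abs(f[, 60 * k + 75])), 0)       # mid-cue: content
    if (k < 6) expect_equal(sum(abs(f[, 60 * k + 105])), 0)  # gap: blank
  }
  # response window is the final 50 ms
  expect_equal(unlist(tr$windows[1, c("t0", "t1")], use.names = FALSE),
               c(550, 600))
  # majority rule over many seeds is balanced
  targ <- sapply(1:400, function(s) make_evidence_trial(seed = s)$windows$target)
  expect_lt(abs(mean(targ) - 0.5), 2.6 * sqrt(0.25 / 400))
})

test_that("readout rate implements the window-mean formula and threshold", {
  r <- matrix(0, 40, 300)
  pool <- 1:30
  expect_equal(readout_rate(r, pool, c(100, 150)), 0)
  # 30 neurons each spiking once in 50 ms: r = 30/(50*30) = 0.02 > r0
  for (j in pool) r[j, 100 + j] <- 1
  expect_equal(readout_rate(r, pool, c(100, 150)), 0.02)
  expect_error(readout_rate(r, integer(0), c(100, 150)), "empty")
})

test_that("decisions are deterministic and respect the rules", {
  net <- build_network(small_config(80), seed = 1)
  pools <- readout_pools(net, n_pools = 3, pool_size = 5,
                         placement = "distributed", seed = 2)
  expect_equal(pools$r0, 0.01)
  tr <- make_evidence_trial(seed = 1)
  raster <- matrix(0, nrow(net$neurons), 600)
  # make pool 2 the most active in the window
  raster[pools$pools[[2]], 551:600] <- 1
  d1 <- decide_trial(tr, raster, pools, c(1, 2))
  expect_equal(d1$decision, 1L)
  d2 <- decide_trial(tr, raster, pools, c(1, 2))
  expect_identical(d1, d2)
  # silent raster: threshold tasks report "no"
  ens <- make_image_ensemble(4, size = 16, seed = 1)
  trc <- make_change_detection_trial("images", ens, seed = 2)
  d0 <- decide_trial(trc, matrix(0, nrow(net$neurons), 600), pools, 1)
  expect_true(all(d0$decision == 0))
})

test_that("pools are disjoint excitatory L5 neurons; colocated pools compact", {
  net <- build_network(network_config(layers = c("L2/3" = 100, "L4" = 100,
                                                 "L5" = 400)), seed = 3)
  pools <- readout_pools(net, n_pools = 4, pool_size = 12,
                         placement = "colocated", radius = 55,
                         min_spacing = 80, seed = 4)
  ids <- unlist(pools$pools)
  expect_equal(length(ids), length(unique(ids)))
  nr <- net$neurons
  expect_true(all(nr$layer[ids] == "L5" & nr$sign[ids] > 0))
  for (p in pools$pools) {
    cx <- mean(nr$x[p]); cy <- mean(nr$y[p])
    expect_true(all(sqrt((nr$x[p] - cx)^2 + (nr$y[p] - cy)^2) <= 2 * 55))
  }
  expect_error(readout_pools(net, n_pools = 100, pool_size = 30), "need")
})

test_that("pixel noise has the stated SD and independence; SD 0 is identity", {
  img <- matrix(100, 100, 100)
  expect_identical(add_pixel_noise(img, 0), img)
  noisy <- add_pixel_noise(img, 1, seed = 5)
  d <- as.vector(noisy - img)
  # chi-square 99% band for the sample SD at n = 1e4
  expect_gt(stats::sd(d), 0.97); expect_lt(stats::sd(d), 1.03)
  nb <- noisy - img
  expect_lt(abs(stats::cor(as.vector(nb[, -1]), as.vector(nb[, -100]))), 0.03)
})

test_that("chance levels: 10% for classification, 42% average over the tasks", {
  expect_equal(unname(chance_level("classification")), 0.1)
  expect_equal(mean(chance_level()), 0.42)
})

test_that("task pool requirements sum to the 15-pool convention", {
  req <- task_pool_requirements()
  expect_equal(sum(req), 15L)
  net <- build_network(network_config(layers = c("L2/3" = 60, "L4" = 60,
                                                 "L5" = 500)), seed = 5)
  pools <- readout_pools(net, n_pools = 15, pool_size = 10,
                         placement = "distributed", seed = 6)
  asg <- readout_assignment(pools)
  expect_length(unlist(asg), 15)
  expect_equal(anyDuplicated(unlist(asg)), 0L)
  expect_length(asg$classification, 10)
})
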