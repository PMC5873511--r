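test_that("each hemicircle holds exactly 11 offsets on the null side", {
  for (d in c("right", "up", "left", "down")) {
    off <- hemicircle_offsets(d)
    expect_equal(nrow(off), 11, info = d)
    expect_true(all(off$d <= 3 & off$d > 0))
  }
  expect_true(all(hemicircle_offsets("right")$dx >= 1))
  expect_true(all(hemicircle_offsets("left")$dx <= -1))
  expect_true(all(hemicircle_offsets("up")$dy <= -1))
  expect_true(all(hemicircle_offsets("down")$dy >= 1))
  # radius 1 leaves only the adjacent element
  expect_equal(nrow(hemicircle_offsets("right", radius = 1)), 1)
  # the up hemicircle is the 90-degree rotation of the right one
  r <- hemicircle_offsets("right")
  u <- hemicircle_offsets("up")
  expect_equal(u$dx, r$dy)
  expect_equal(u$dy, -r$dx)
  expect_equal(u$d, r$d)
})

test_that("distance-weighted inhibition divides by offset length with border clipping", {
  lay <- inhibitory_layer(c(9, 9), "right")
  ez <- matrix(0, 9, 9)
  expect_equal(distance_weighted_inhibition(ez, lay), matrix(0, 9, 9))
  # single inhibitor one step into the preferred side
  e <- matrix(0, 9, 9)
  e[5, 6] <- 2 # offset (dx=1, dy=0) from the focal (5,5)
  idist <- distance_weighted_inhibition(e, lay)
  expect_equal(idist[5, 5], 0.35 * 2 / 1)
  # uniform field: interior value equals 0.35 * sum over the 11 offsets of 1/d
  e1 <- matrix(1, 9, 9)
  lattice_sum <- sum(1 / hemicircle_offsets("right")$d)
  expect_equal(distance_weighted_inhibition(e1, lay)[5, 5], 0.35 * lattice_sum)
  # at the right border the hemicircle is clipped to nothing
  expect_equal(distance_weighted_inhibition(e1, lay)[5, 9], 0)
})

test_that("stored inhibition decays by two per elapsed step and clamps at zero", {
  lay <- inhibitory_layer(c(2, 2), "right")
  lay$stored_inhibition <- matrix(5, 2, 2)
  lay$decay_counter <- matrix(c(0, 1, 3, 10), 2, 2)
  out <- decay_inhibition(lay)
  expect_equal(out[1, 1], 5) # counter 0: undecayed
  expect_equal(out[2, 1], 3)
  expect_equal(out[1, 2], 0) # clamped
  expect_equal(out[2, 2], 0)
})

test_that("i-potentials subtract decayed inhibition with reset bookkeeping", {
  lay <- inhibitory_layer(c(5, 9), "right")
  # step 1: e appears; no history so i = e
  e1 <- matrix(0, 5, 9)
  e1[3, 4] <- 6
  lay <- update_i_potentials(e1, matrix(0, 5, 9), lay)
  expect_equal(lay$i_potentials[3, 4], 6)
  # step 2: fresh inhibition from e1 exceeds the (zero) decayed store by
  # more than 1.5, so it is saved, the counter resets, and it applies now
  e2 <- matrix(0, 5, 9)
  e2[3, 3] <- 5 # focal with e1's element at offset (1,0)
  lay <- update_i_potentials(e2, e1, lay)
  expect_equal(lay$decay_counter[3, 3], 0)
  expect_equal(lay$stored_inhibition[3, 3], 0.35 * 6)
  expect_equal(lay$i_potentials[3, 3], 5 - 2.1)
  # weak fresh inhibition (below the 1.5 reset margin) is not saved
  layw <- inhibitory_layer(c(5, 9), "right")
  ew <- matrix(0, 5, 9)
  ew[3, 4] <- 2 # I_dist = 0.7 < 1.5
  layw <- update_i_potentials(matrix(0, 5, 9), ew, layw)
  expect_equal(layw$stored_inhibition[3, 3], 0)
  expect_equal(layw$decay_counter[3, 3], 1)
  # negative results clamp to zero (stored 4, one elapsed step -> applied 2)
  lay2 <- inhibitory_layer(c(3, 3), "right")
  lay2$stored_inhibition <- matrix(4, 3, 3)
  lay2$decay_counter <- matrix(0, 3, 3)
  out <- update_i_potentials(matrix(0.5, 3, 3), matrix(0, 3, 3), lay2)
  expect_equal(out$i_potentials, matrix(0, 3, 3))
  # without a reset the counter increments each step
  lay3 <- inhibitory_layer(c(3, 3), "right")
  lay3 <- update_i_potentials(matrix(0, 3, 3), matrix(0, 3, 3), lay3)
  lay3 <- update_i_potentials(matrix(0, 3, 3), matrix(0, 3, 3), lay3)
  expect_equal(lay3$decay_counter, matrix(2, 3, 3))
})

test_that("layer excitation weights supra-0.1 sums by the strong-member fraction", {
  z <- build_zone(c(30, 30), radius = 10, top_exclusion = 0, bottom_exclusion = 0)
  lay <- inhibitory_layer(c(30, 30), "right")
  lay$i_potentials[z$mask] <- 0.1
  expect_equal(layer_excitation(lay, z)$e_layer, 0) # 0.1 itself excluded
  # 10 members at 2.0 in a zone scaled to the example
  lay$i_potentials <- matrix(0, 30, 30)
  lay$i_potentials[which(z$mask)[1:10]] <- 2
  out <- layer_excitation(lay, z)
  expect_equal(out$m, 10L)
  expect_equal(out$e_layer, (10 / z$s) * 20)
  # i-potentials between 0.1 and 1.0 alone leave m = 0 and kill the weight
  lay$i_potentials <- matrix(0, 30, 30)
  lay$i_potentials[z$mask] <- 0.8
  expect_equal(layer_excitation(lay, z)$e_layer, 0)
})

test_that("inhibition and excitation match loop oracles on random layers", {
  z <- build_zone(c(48, 64), radius = 20)
  lay <- inhibitory_layer(c(48, 64), "right")
  for (seed in 1:20) {
    e_prev <- random_layer(seed)
    expect_equal(
      distance_weighted_inhibition(e_prev, lay),
      oracle_idist(e_prev, lay$offsets),
      tolerance = 1e-9
    )
    e_now <- random_layer(seed + 100)
    lay$stored_inhibition <- random_layer(seed + 200, max_e = 3)
    lay$decay_counter <- matrix(seed %% 3, 48, 64)
    i_decay <- decay_inhibition(lay)
    upd <- update_i_potentials(e_now, e_prev, lay)
    # Eq. 7 applies the refreshed decayed inhibition
    i_dist <- oracle_idist(e_prev, lay$offsets)
    reset <- i_dist > i_decay + 1.5
    applied <- ifelse(reset, i_dist, pmax(i_decay - 2, 0))
    expect_equal(upd$i_potentials, oracle_ipot(e_now, applied), tolerance = 1e-9)
    expect_equal(
      layer_excitation(upd, z)$e_layer,
      oracle_layer_exc(upd$i_potentials, z),
      tolerance = 1e-9
    )
  }
})

test_that("a rightward bar drives the right-preferring layer above the left", {
  stim <- translating_bar(n_frames = 30, start = 48, speed = 2)
  r <- process_sequence(stim$frames, cd_config(e_threshold = 0.7))
  d <- r$results[r$results$frame_index >= 5, ]
  expect_true(all(d$e_layer_right > d$e_layer_left))
  # mirrored for leftward motion
  stim_l <- translating_bar(n_frames = 30, direction = "left", start = 48, speed = 2)
  rl <- process_sequence(stim_l$frames, cd_config(e_threshold = 0.7))
  dl <- rl$results[rl$results$frame_index >= 5, ]
  expect_true(all(dl$e_layer_left > dl$e_layer_right))
})

test_that("whole-field activation is cancelled after the one-step delay", {
  # a single global step change excites every element for two steps; the
  # delayed inhibition from the first excited step suppresses the second
  frames <- c(rep(list(matrix(2, 20, 20)), 3), rep(list(matrix(6, 20, 20)), 3))
  out <- run_stack(frames, e_threshold = 0.7)
  step_t <- 4 # first frame after the luminance step
  expect_gt(sum(out$e[[step_t]]), 0)
  expect_gt(sum(out$e[[step_t + 1]]), 0)
  interior <- out$layers[[step_t + 1]]
  for (d in names(interior)) {
    expect_equal(max(interior[[d]][4:17, 4:17]), 0, info = d)
  }
})

test_that("the four layers are exact 90-degree rotations of one another", {
  set.seed(42)
  frames <- lapply(1:6, function(t) matrix(runif(30 * 24, 0, 9.9), 24, 30))
  a <- run_stack(frames)
  b <- run_stack(lapply(frames, rot90_ccw))
  map <- c(right = "up", up = "left", left = "down", down = "right")
  for (t in 3:6) {
    for (d in names(map)) {
      expect_identical(b$layers[[t]][[map[[d]]]], rot90_ccw(a$layers[[t]][[d]]))
    }
  }
})
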