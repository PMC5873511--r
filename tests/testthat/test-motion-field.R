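# helper: build a layer list whose i>0.1 counts around the focal element
# (8, 8) of a 15x15 grid are exactly as requested, by exciting that many
# in-disk elements per layer (disjoint positions are unnecessary: counts
# are per layer)
layers_with_counts <- function(right = 0, up = 0, left = 0, down = 0) {
  dims <- c(15, 15)
  counts <- c(right = right, up = up, left = left, down = down)
  off <- loomrisk:::disk_offsets(3)
  lay <- direction_layers(dims)
  for (d in names(counts)) {
    k <- counts[[d]]
    if (k > 0) {
      for (j in seq_len(k)) {
        lay[[d]]$i_potentials[8 + off$dy[j], 8 + off$dx[j]] <- 2
      }
    }
  }
  lay
}

test_that("local motion vectors follow the dominance rules", {
  f <- local_motion_vectors(layers_with_counts(right = 12, left = 2, up = 3, down = 1))
  expect_equal(f$direction[8, 8], 0) # rightward dominates
  # two layers 90 degrees apart dominating: bisecting diagonal
  f2 <- local_motion_vectors(layers_with_counts(right = 10, up = 10, left = 2, down = 2))
  expect_equal(f2$direction[8, 8], 45)
  f2b <- local_motion_vectors(layers_with_counts(down = 10, right = 10, left = 3, up = 3))
  expect_equal(f2b$direction[8, 8], 315)
  # opposed dominant layers are contradictory
  f3 <- local_motion_vectors(layers_with_counts(right = 12, left = 12))
  expect_true(is.na(f3$direction[8, 8]))
  # sparse excitation (total <= 9) suspends the calculation
  f4 <- local_motion_vectors(layers_with_counts(right = 9))
  expect_true(is.na(f4$direction[8, 8]))
  f5 <- local_motion_vectors(layers_with_counts(right = 10))
  expect_equal(f5$direction[8, 8], 0) # total 10 > 9, dominance by 10 > 4
  # unequal adjacent pair: both exceed the remaining layers, neither the
  # other -> still the bisecting diagonal
  f6 <- local_motion_vectors(layers_with_counts(right = 10, up = 6))
  expect_equal(f6$direction[8, 8], 45)
  # dominance margin is strict: exceeding by exactly 4 is not enough
  f7 <- local_motion_vectors(layers_with_counts(right = 9, up = 5, left = 1, down = 1))
  expect_true(is.na(f7$direction[8, 8]))
})

test_that("the coherence flag needs a strict majority within 45 degrees", {
  mk_field <- function(dirs) {
    d <- matrix(NA_real_, 10, 10)
    d[seq_along(dirs)] <- dirs
    list(direction = d)
  }
  expect_true(coherence_check(mk_field(rep(0, 12)))$flag)
  # uniform spread over the 8 directions: max window is 3/8
  u <- coherence_check(mk_field(rep(seq(0, 315, by = 45), 2)))
  expect_false(u$flag)
  expect_equal(u$coherence_fraction, 3 / 8)
  # no vectors at all: no flag
  expect_false(coherence_check(list(direction = matrix(NA_real_, 5, 5)))$flag)
  # exactly half in one direction, half in the opposite: strict rule silent
  half <- coherence_check(mk_field(rep(c(90, 270), 10)))
  expect_equal(half$coherence_fraction, 0.5)
  expect_false(half$flag)
  # one vector more tips it
  expect_true(coherence_check(mk_field(c(rep(c(90, 270), 10), 90)))$flag)
})

test_that("shadow suppression requires a strict 20 percent of the lower zone", {
  z <- build_zone(c(40, 40), radius = 10, top_exclusion = 0, bottom_exclusion = 0)
  lower_idx <- which(z$lower_half)
  n_lower <- length(lower_idx)
  e <- matrix(1, 40, 40)
  lay <- direction_layers(c(40, 40))
  for (d in names(lay)) lay[[d]]$i_potentials <- matrix(1, 40, 40)
  mk_field <- function(n_down) {
    d <- matrix(NA_real_, 40, 40)
    d[lower_idx[seq_len(n_down)]] <- 270
    list(direction = d)
  }
  # no downward vectors: nothing suppressed
  out0 <- shadow_suppression(mk_field(0), z, e, lay)
  expect_equal(sum(out0$shadow_mask), 0)
  expect_equal(out0$e, e)
  # exactly 20% downward: strict comparison keeps everything
  k <- floor(n_lower * 0.2)
  if (k / n_lower == 0.2) {
    expect_equal(sum(shadow_suppression(mk_field(k), z, e, lay)$shadow_mask), 0)
  }
  # above 20%: the downward lower-zone elements are zeroed everywhere
  k2 <- ceiling(n_lower * 0.2) + 1
  out2 <- shadow_suppression(mk_field(k2), z, e, lay)
  expect_equal(sum(out2$shadow_mask), k2)
  expect_true(all(out2$e[out2$shadow_mask] == 0))
  for (d in names(out2$layers)) {
    expect_true(all(out2$layers[[d]]$i_potentials[out2$shadow_mask] == 0))
  }
  # untouched outside the mask
  expect_true(all(out2$e[!out2$shadow_mask] == 1))
})

test_that("the vector field rotates with the input", {
  set.seed(9)
  frames <- lapply(1:6, function(t) matrix(runif(26 * 26, 0, 9.9), 26, 26))
  a <- run_stack(frames)
  b <- run_stack(lapply(frames, rot90_ccw))
  mk_layers <- function(ip) {
    lay <- direction_layers(dim(ip$right))
    for (d in names(lay)) lay[[d]]$i_potentials <- ip[[d]]
    lay
  }
  fa <- local_motion_vectors(mk_layers(a$layers[[6]]))
  fb <- local_motion_vectors(mk_layers(b$layers[[6]]))
  rot_dir <- (rot90_ccw(fa$direction) + 90) %% 360
  expect_equal(is.na(fb$direction), is.na(rot_dir))
  expect_equal(fb$direction[!is.na(fb$direction)], rot_dir[!is.na(rot_dir)])
})

test_that("shadow suppression never raises the per-frame risk on scene runs", {
  gs <- ground_shadow()
  on <- process_sequence(gs$frames, cd_config(e_threshold = 0.7, zone_radius = 30))
  off <- process_sequence(gs$frames, cd_config(e_threshold = 0.7, zone_radius = 30,
                                               shadow_suppression = FALSE))
  expect_true(all(on$results$total_risk <= off$results$total_risk + 1e-9))
})
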