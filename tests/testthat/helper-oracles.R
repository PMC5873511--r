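# Brute-force per-element loop oracles, independent of the vectorised
# implementation paths they are checked against.

oracle_pair_e <- function(pd, prev) abs(pd - prev)

# cluster rule: count excited elements within Euclidean radius (focal
# included) on the pre-filter layer; zero focal if count <= min_count
oracle_cluster <- function(e, radius = 3, min_count = 10) {
  nr <- nrow(e)
  nc <- ncol(e)
  out <- e
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (e[r, c] <= 0) next
      cnt <- 0
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          rr <- r + dr
          cc <- c + dc
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (sqrt(dr^2 + dc^2) <= radius && e[rr, cc] > 0) cnt <- cnt + 1
        }
      }
      if (cnt <= min_count) out[r, c] <- 0
    }
  }
  out
}

oracle_rcoll <- function(e, zone, threshold) {
  s <- 0
  w <- 0
  total <- 0
  for (r in seq_len(nrow(e))) {
    for (c in seq_len(ncol(e))) {
      if (!zone$mask[r, c]) next
      s <- s + 1
      if (e[r, c] > threshold) {
        w <- w + 1
        total <- total + e[r, c]
      }
    }
  }
  (w / zone$s) * total
}

oracle_rdist <- function(e, zone, threshold, gain = 10) {
  level <- max(0.5, threshold)
  acc <- 0
  n <- 0
  for (r in seq_len(nrow(e))) {
    for (c in seq_len(ncol(e))) {
      if (!zone$mask[r, c] || e[r, c] <= level) next
      d <- zone$dist[r, c]
      if (d > 0 && d < zone$radius / 2) {
        acc <- acc + 1 / d
        n <- n + 1
      }
    }
  }
  list(r_dist = gain * acc, n = n)
}

oracle_idist <- function(e_prev, offsets, weight = 0.35) {
  nr <- nrow(e_prev)
  nc <- ncol(e_prev)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (k in seq_len(nrow(offsets))) {
        rr <- r + offsets$dy[k]
        cc <- c + offsets$dx[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          acc <- acc + e_prev[rr, cc] / offsets$d[k]
        }
      }
      out[r, c] <- weight * acc
    }
  }
  out
}

oracle_ipot <- function(e_now, i_decay) {
  out <- e_now
  for (i in seq_along(out)) out[i] <- max(0, e_now[i] - i_decay[i])
  out
}

oracle_layer_exc <- function(i_pot, zone) {
  m <- 0
  total <- 0
  for (r in seq_len(nrow(i_pot))) {
    for (c in seq_len(ncol(i_pot))) {
      if (!zone$mask[r, c]) next
      if (i_pot[r, c] > 1.0) m <- m + 1
      if (i_pot[r, c] > 0.1) total <- total + i_pot[r, c]
    }
  }
  (m / zone$s) * total
}

# random e-potential layer with realistic sparsity: mostly zero, scattered
# supra-threshold patches
random_layer <- function(seed, dim = c(48, 64), density = 0.15, max_e = 5) {
  set.seed(seed)
  e <- matrix(0, dim[1], dim[2])
  n <- round(length(e) * density)
  idx <- sample(length(e), n)
  e[idx] <- runif(n, 0, max_e)
  e
}

# drive the full excitation + inhibition stack over a frame list, returning
# per-step e-layers and layer states (no zone-dependent steps)
run_stack <- function(frames, e_threshold = 0.7, config = cd_config()) {
  dims <- dim(frames[[1]])
  st <- excitatory_state(dims, e_threshold)
  lay <- direction_layers(dims)
  e_prev <- matrix(0, dims[1], dims[2])
  es <- list()
  layers_t <- list()
  for (t in seq_along(frames)) {
    if (t >= 2) {
      st <- update_e_potentials(st, pair_difference(frames[[t]], frames[[t - 1]]))
    }
    if (t <= 2) next
    st <- apply_threshold(st)
    st <- cluster_filter(st)
    for (d in names(lay)) {
      lay[[d]] <- update_i_potentials(st$e_potentials, e_prev, lay[[d]])
    }
    e_prev <- st$e_potentials
    es[[t]] <- st$e_potentials
    layers_t[[t]] <- lapply(lay, function(l) l$i_potentials)
  }
  list(e = es, layers = layers_t)
}
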