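# Independent oracles used across the suite.

# Brute-force total forces: plain double loops over all pairs using the
# exported scalar potential functions, no neighbour acceleration. This is
# the reference the compiled kernel must reproduce.
oracle_total_forces <- function(state, params, field_on = TRUE) {
  pos <- state$positions
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    # FENE bonds to chain neighbours
    for (j in c(i - 1, i + 1)) {
      if (j < 1 || j > n) next
      pr <- pair_distance(pos[i, ], pos[j, ])
      f[i, ] <- f[i, ] + fene_force(pr, params)
    }
    # WCA with every other bead
    for (j in seq_len(n)) {
      if (j == i) next
      pr <- pair_distance(pos[i, ], pos[j, ])
      f[i, ] <- f[i, ] + wca_force(pr, params)
    }
    # WCA with wall particles and obstacles
    wall <- state$geometry$wall
    for (k in seq_len(nrow(wall))) {
      pr <- pair_distance(pos[i, ], wall[k, ])
      if (pr$r < 2^(1 / 6) * params$sigma * 1.0001) {
        f[i, ] <- f[i, ] + wca_force(pr, params)
      }
    }
    om <- state$obstacles
    sig_o <- (params$sigma + params$d) / 2
    for (k in seq_len(nrow(om))) {
      pr <- pair_distance(pos[i, ], om[k, ])
      if (pr$r < 2^(1 / 6) * sig_o * 1.0001) {
        f[i, ] <- f[i, ] + wca_force(pr, params, sigma_pair = sig_o)
      }
    }
    # analytic membrane closure beyond the particle lattice
    if (nrow(state$geometry$wall) > 0) {
      rim <- state$geometry$membrane_extent - params$sigma
      if (sqrt(sum(pos[i, 1:2]^2)) > rim) {
        for (z0 in c(0, state$geometry$L)) {
          dz <- pos[i, 3] - z0
          if (abs(dz) < 2^(1 / 6) * params$sigma) {
            pr <- list(r = abs(dz), unit_vector = c(0, 0, sign(dz)))
            f[i, ] <- f[i, ] + wca_force(pr, params)
          }
        }
      }
    }
    # driving field on beads inside the channel
    if (field_on) {
      reg <- region_classify(pos[i, ], state$geometry)
      if (params$field_everywhere || reg == "channel") {
        f[i, 3] <- f[i, 3] + params$F
      }
    }
  }
  f
}

# Shape factor via an independently assembled gyration tensor: the
# pair-difference formula T_ab = sum_{i<j} (r_i - r_j)_a (r_i - r_j)_b / M^2
# avoids the centroid entirely.
oracle_shape_delta <- function(coords) {
  m <- nrow(coords)
  tensor <- matrix(0, 3, 3)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d <- coords[i, ] - coords[j, ]
      tensor <- tensor + outer(d, d)
    }
  }
  tensor <- tensor / m^2
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / sum(ev)^2
}

# Empty static environment: free space for single-bead and free-chain
# dynamics checks.
free_space_geometry <- function(params = sim_params()) {
  structure(list(L = params$L, R = params$R, d = params$d,
                 sigma = params$sigma, membrane_extent = 3 * params$R,
                 wall = matrix(numeric(0), ncol = 3)),
            class = "channel_geometry")
}

# A random valid (no overlap < 0.9 sigma, bonds ~ sigma) chain placed
# around the channel entrance, for force-oracle comparisons.
random_valid_state <- function(n, params, seed, with_obstacles = TRUE) {
  geom <- build_channel(params)
  obst <- if (with_obstacles) {
    place_obstacles(max(params$rho, 0.2), geom, params, seed = seed)
  } else {
    NULL
  }
  init_chain(params, geom, obst, seed = seed, index = 7L)
}
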