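p0 <- sim_params()
geom0 <- build_channel(p0)

test_that("obstacle counts follow rho * V_c / V_o with sphere volumes", {
  expect_identical(n_obstacles_for_rho(0, p0), 0L)
  expect_identical(n_obstacles_for_rho(0.4, p0), 48L)
  expect_identical(n_obstacles_for_rho(0.6, p0), 72L)
  expect_identical(n_obstacles_for_rho(0.8, p0), 96L)
  # monotone nondecreasing in rho
  rhos <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(n_obstacles_for_rho(rhos, p0)) >= 0))
  expect_error(n_obstacles_for_rho(1.2, p0), class = "crowdpore_config_error")
  expect_error(n_obstacles_for_rho(-0.1, p0), class = "crowdpore_config_error")
})

test_that("obstacle placement is uniform in the accessible cylinder and reproducible", {
  ob <- place_obstacles(0.8, geom0, p0, seed = 123)
  expect_equal(nrow(ob), 96)
  expect_true(all(ob$z >= 0 & ob$z <= p0$L))
  rad <- sqrt(ob$x^2 + ob$y^2)
  expect_true(all(rad <= p0$R - p0$d / 2 + 1e-12))
  # entrance mouth stays clear of the pinned first bead
  expect_true(all(sqrt(ob$x^2 + ob$y^2 + ob$z^2) >= 2^(1 / 6) * 1 - 1e-12))
  # same stream, same configuration; different stream differs
  ob2 <- place_obstacles(0.8, geom0, p0, seed = 123)
  expect_identical(as.data.frame(ob), as.data.frame(ob2))
  ob3 <- place_obstacles(0.8, geom0, p0, seed = 124)
  expect_false(isTRUE(all.equal(as.data.frame(ob), as.data.frame(ob3))))
  expect_equal(nrow(place_obstacles(0, geom0, p0, seed = 1)), 0)
})

test_that("wall construction is leak-tight", {
  wall <- geom0$wall
  # the axis is maximally far from the lining
  d_axis <- min(sqrt(colSums((t(wall) - c(0, 0, p0$L / 2))^2)))
  expect_gte(d_axis, p0$R)
  # probe ring just outside the lining: every point is within sigma of a
  # wall particle, so a bead cannot slip through the cylinder surface
  th <- seq(0, 2 * pi, length.out = 120)[-1]
  zs <- seq(0, p0$L, length.out = 90)
  rp <- p0$R + p0$sigma / 2 + 0.4 * p0$sigma
  probes <- cbind(rep(rp * cos(th), length(zs)),
                  rep(rp * sin(th), length(zs)),
                  rep(zs, each = length(th)))
  dmin <- apply(probes, 1, function(x) min(sqrt(colSums((t(wall) - x)^2))))
  expect_lt(max(dmin), p0$sigma)
  # membrane coverage: a bead approaching the plane feels repulsion
  d_mem <- min(sqrt(colSums((t(wall) - c(2 * p0$R, 0, -0.1))^2)))
  expect_lt(d_mem, 2^(1 / 6) * p0$sigma)
  # membrane plane scan between the lining and the membrane extent
  rr <- seq(p0$R + p0$sigma / 2, p0$membrane_extent - 0.5, length.out = 30)
  probes2 <- cbind(rep(rr, length(th)) * cos(rep(th, each = length(rr))),
                   rep(rr, length(th)) * sin(rep(th, each = length(rr))), 0)
  dmin2 <- apply(probes2, 1, function(x) min(sqrt(colSums((t(wall) - x)^2))))
  expect_lt(max(dmin2), p0$sigma)
})

test_that("positions classify into cis / channel / trans", {
  expect_identical(region_classify(c(0, 0, -1), geom0), "cis")
  expect_identical(region_classify(c(0.5, 0, 2.5), geom0), "channel")
  expect_identical(region_classify(c(0, 0, 5.01), geom0), "trans")
  expect_identical(region_classify(c(0, 0, 0), geom0), "channel")
  expect_identical(region_classify(c(0, 0, 5), geom0), "channel")
  # radially excluded points fall back to the z sign relative to L/2
  expect_identical(region_classify(c(3, 0, 1), geom0), "cis")
  expect_identical(region_classify(c(3, 0, 4), geom0), "trans")
  m <- region_classify(rbind(c(0, 0, -1), c(0, 0, 1), c(0, 0, 9)), geom0)
  expect_identical(m, c("cis", "channel", "trans"))
})

test_that("random obstacle coverage follows Poisson statistics and stays below rho", {
  rho <- 0.4
  n_o <- n_obstacles_for_rho(rho, p0)
  v_cen <- pi * (p0$R - p0$d / 2)^2 * p0$L       # centre region volume
  # minus the entrance clearance half-ball excluded from placement
  v_cen <- v_cen - (2 / 3) * pi * (2^(1 / 6) * p0$sigma)^3
  v_o <- (4 / 3) * pi * (p0$d / 2)^3
  p_interior <- 1 - (1 - v_o / v_cen)^n_o        # binomial coverage limit
  set.seed(42)
  pk <- numeric(0); covered_total <- 0L; m_total <- 0L
  for (k in 1:12) {
    ob <- as.matrix(place_obstacles(rho, geom0, p0, seed = 500 + k)[, 1:3])
    # interior probes: the whole covering ball of radius d/2 lies inside
    # the centre region, so the binomial prediction is exact
    nprobe <- 8000
    rr <- (p0$R - p0$d) * sqrt(runif(nprobe))
    ang <- runif(nprobe, 0, 2 * pi)
    pts <- cbind(rr * cos(ang), rr * sin(ang), runif(nprobe, 0.5, p0$L - 0.5))
    keep <- rowSums(pts^2) > (2^(1 / 6) + p0$d / 2 + 0.05)^2 # clear of the
    pts <- pts[keep, , drop = FALSE]                         # entrance gap
    cov <- vapply(seq_len(nrow(pts)), function(i) {
      any(colSums((t(ob) - pts[i, ])^2) < (p0$d / 2)^2)
    }, logical(1))
    pk <- c(pk, mean(cov))
    # whole-channel probes for the rho upper bound
    rr2 <- p0$R * sqrt(runif(nprobe))
    ang2 <- runif(nprobe, 0, 2 * pi)
    pts2 <- cbind(rr2 * cos(ang2), rr2 * sin(ang2), runif(nprobe, 0, p0$L))
    cov2 <- vapply(seq_len(nrow(pts2)), function(i) {
      any(colSums((t(ob) - pts2[i, ])^2) < (p0$d / 2)^2)
    }, logical(1))
    covered_total <- covered_total + sum(cov2); m_total <- m_total + length(cov2)
  }
  # the dominant error is placement-to-placement (48 shared spheres per
  # realisation), so the standard error comes from the replicate means
  phat <- mean(pk)
  se <- sd(pk) / sqrt(length(pk))
  expect_lt(abs(phat - p_interior), 3 * se + 0.005)
  # overlap-allowed placement can never cover more than the nominal rho
  expect_lt(covered_total / m_total, rho)
})

test_that("geometry exports as a tagged XYZ snapshot", {
  path <- withr::local_tempfile(fileext = ".xyz")
  ob <- place_obstacles(0.2, geom0, p0, seed = 5)
  write_geometry_xyz(geom0, path, obstacles = ob,
                     beads = rbind(c(0, 0, -1), c(0, 0, -2)))
  fr <- read_trajectory(path)
  expect_length(fr, 1)
  expect_equal(nrow(fr[[1]]$positions), nrow(geom0$wall) + nrow(ob) + 2)
  expect_setequal(unique(fr[[1]]$tags), c("W", "O", "C"))
  expect_equal(sum(fr[[1]]$tags == "O"), nrow(ob))
})
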