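# Synthetic event tables for the profile observables: hand-built tibbles
# shaped like run_translocation() output.
synthetic_ensemble <- function(entry, exit, n_in = NULL, gyr = NULL) {
  n <- length(entry[[1]])
  mk <- function(i) {
    tibble::tibble(
      run = i, success = TRUE, failure_mode = "none",
      tau = max(exit[[i]]), n_steps = 1000,
      entry_times = list(entry[[i]]), exit_times = list(exit[[i]]),
      exit_order_times = list(sort(exit[[i]])),
      n_in_at_exit = list(if (is.null(n_in)) rep(0L, n) else n_in[[i]]),
      gyr_whole = list(if (is.null(gyr)) matrix(1, n, 6) else gyr[[i]]),
      gyr_out = list(matrix(1, n, 6))
    )
  }
  out <- dplyr::bind_rows(lapply(seq_along(entry), mk))
  class(out) <- c("ensemble_result", class(tibble::tibble()))
  out
}

test_that("shape factor hits the rod, sphere and planar limits", {
  rod <- cbind(seq_len(10), 0, 0)
  expect_equal(shape_factor(rod)$delta, 1)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  expect_equal(shape_factor(oct)$delta, 0, tolerance = 1e-12)
  # planar with two equal in-plane moments: hexagon -> delta = 1/4
  th <- 2 * pi * (0:5) / 6
  hex <- cbind(cos(th), sin(th), 0)
  expect_equal(shape_factor(hex)$delta, 0.25, tolerance = 1e-12)
  expect_error(shape_factor(matrix(1, 1, 3)), class = "crowdpore_data_error")
  expect_error(shape_factor(matrix(1, 5, 3)), class = "crowdpore_data_error")
})

test_that("shape factor matches the pair-sum oracle and is rigid-motion invariant", {
  set.seed(7)
  for (k in 1:5) {
    x <- matrix(rnorm(60), 20, 3)
    sm <- shape_factor(x)
    expect_equal(sm$delta, oracle_shape_delta(x), tolerance = 1e-10)
    expect_equal(sm$S2, sum(sm$principal_components))
    expect_true(all(diff(sm$principal_components) >= 0))
    expect_true(sm$delta >= 0 && sm$delta <= 1)
    # rotation + translation + relabelling leave delta unchanged
    ang <- runif(3, 0, 2 * pi)
    rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                   sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                   -sin(ang[2]), 0, cos(ang[2])), 3, 3)
    xr <- x[sample(20), ] %*% (rz %*% ry)
    xr <- sweep(xr, 2, runif(3, -5, 5), `+`)
    expect_equal(shape_factor(xr)$delta, sm$delta, tolerance = 1e-10)
  }
})

test_that("translocation probability uses the Wilson interval", {
  ens <- tibble::tibble(success = c(rep(TRUE, 3), rep(FALSE, 97)))
  pr <- translocation_probability(ens)
  expect_equal(pr$p, 0.03)
  expect_true(pr$ci_lo < 0.03 && pr$ci_hi > 0.03)
  pr0 <- translocation_probability(tibble::tibble(success = rep(FALSE, 50)))
  expect_equal(pr0$p, 0)
  expect_gt(pr0$ci_hi, 0)
  pr1 <- translocation_probability(tibble::tibble(success = rep(TRUE, 20)))
  expect_equal(pr1$p, 1)
  expect_lt(pr1$ci_lo, 1)
  expect_true(all(c(pr$ci_lo, pr0$ci_lo, pr1$ci_lo) >= 0))
  expect_true(all(c(pr$ci_hi, pr0$ci_hi, pr1$ci_hi) <= 1))
})

test_that("translocation-time statistics average successes only", {
  ens <- synthetic_ensemble(list(c(0, 0)), list(c(5, 10)))
  st <- tau_statistics(ens)
  expect_equal(st$mean_tau, 10)
  expect_equal(st$sem, 0)
  ens2 <- dplyr::bind_rows(ens, ens)
  ens2$tau <- c(10, 20)
  class(ens2) <- class(ens)
  st2 <- tau_statistics(ens2)
  expect_equal(st2$mean_tau, 15)
  fail <- tibble::tibble(success = FALSE, tau = NA_real_)
  expect_error(tau_statistics(fail), class = "crowdpore_data_error")
})

test_that("per-bead profile reproduces hand-built residence times", {
  n <- 6
  entry <- list(as.numeric(1:n))
  exit <- list(as.numeric(1:n) + 5)
  ens <- synthetic_ensemble(entry, exit)
  prof <- tau_per_bead(ens)
  expect_equal(prof$tau, rep(5, n))
  expect_equal(prof$s, 1:n)
  # waiting times: first exit at 6, then unit gaps
  expect_equal(prof$tau_wait, c(6, rep(1, n - 1)))
  expect_equal(prof$tau_cum, as.numeric(1:n) + 5)
  # mean segment time consistency, exactly
  expect_identical(mean_segment_time(ens), mean(prof$tau))
  # alternating residence times average cleanly
  ens2 <- synthetic_ensemble(list(rep(0, 4)), list(c(2, 4, 2, 4) + c(0, 0, 0.0001, 0.0001) * 0))
  expect_equal(mean_segment_time(ens2), 3)
})

test_that("beads-in-channel profile averages the counts at each exit", {
  ens <- synthetic_ensemble(list(rep(0, 4)), list(1:4 + 0),
                            n_in = list(rep(4L, 4)))
  prof <- n_in_profile(ens)
  expect_equal(prof$n_in, rep(4, 4))
  expect_true(all(prof$n_in >= 0 & prof$n_in <= 4))
})

test_that("delta profile flattens for collinear snapshots", {
  # gyration tensor of a rod along z: only zz nonzero
  rodgyr <- matrix(0, 5, 6)
  rodgyr[, 3] <- 2
  ens <- synthetic_ensemble(list(rep(0, 5)), list(1:5 + 0),
                            gyr = list(rodgyr))
  prof <- delta_profile(ens)
  expect_equal(prof$delta, rep(1, 5))
  sph <- matrix(0, 5, 6)
  sph[, 1:3] <- 1
  ens2 <- synthetic_ensemble(list(rep(0, 5)), list(1:5 + 0),
                             gyr = list(sph))
  expect_equal(delta_profile(ens2)$delta, rep(0, 5))
})

test_that("scaling-exponent fit recovers exact and noisy power laws", {
  f <- c(10, 15, 20, 25, 30)
  pts <- tibble::tibble(F = f, mean_tau = 100 * f^-0.5)
  fit <- fit_scaling_exponent(pts)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit$prefactor, 100, tolerance = 1e-9)
  # constant tau: alpha = 0
  fit0 <- fit_scaling_exponent(tibble::tibble(F = f, mean_tau = rep(7, 5)))
  expect_equal(fit0$alpha, 0, tolerance = 1e-12)
  # prefactor invariance
  fit2 <- fit_scaling_exponent(tibble::tibble(F = f, mean_tau = 1e6 * f^-0.5))
  expect_equal(fit2$alpha, 0.5, tolerance = 1e-12)
  # noisy recovery within 2 standard errors
  set.seed(11)
  ok <- 0
  for (k in 1:10) {
    tau <- 50 * f^-0.6 * exp(rnorm(5, 0, 0.05))
    fitn <- fit_scaling_exponent(
      tibble::tibble(F = f, mean_tau = tau, sem = 0.05 * tau))
    if (abs(fitn$alpha - 0.6) <= 2 * fitn$alpha_stderr) ok <- ok + 1
  }
  expect_gte(ok, 8)
  expect_error(fit_scaling_exponent(pts[1:2, ]),
               class = "crowdpore_data_error")
})

test_that("scaling fits expose tidy, glance and autoplot methods", {
  f <- c(10, 15, 20, 25, 30)
  tau <- 100 * f^-0.5
  fit <- fit_scaling_exponent(tibble::tibble(F = f, mean_tau = tau,
                                             sem = 0.01 * tau))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[td$term == "alpha"], 0.5, tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$n_points, 5)
  expect_gt(gl$r.squared, 0.999)
  expect_s3_class(autoplot(fit), "ggplot")
  prof <- tau_per_bead(synthetic_ensemble(list(rep(0, 4)), list(1:4 + 0)))
  expect_s3_class(autoplot(prof), "ggplot")
})
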