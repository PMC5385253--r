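# Stream tags for seed splitting: 1 obstacles, 2 chain growth,
# 3 equilibration, 4 translocation run.

#' Initialise a chain at the channel entrance
#'
#' Places bead 1 at the entrance of the channel (the origin, on the axis)
#' and grows beads 2..N on the cis side (`z <= 0`) as a self-avoiding
#' random walk of bond length \eqn{\sigma}, rejecting placements that
#' overlap earlier beads, wall particles or obstacles. Bead 1 is tethered;
#' the chain is then ready for [equilibrate()].
#'
#' @param params A [sim_params()] object (supplies `N`).
#' @param geom A [build_channel()] geometry (built from `params` when
#'   omitted).
#' @param obstacles Obstacle set (default: placed from `params$rho`).
#' @param seed,index Stream seeding; a fixed stream reproduces the
#'   configuration exactly.
#' @return A [system_state()] with bead 1 tethered.
#' @export
init_chain <- function(params, geom = build_channel(params),
                       obstacles = place_obstacles(params$rho, geom, params,
                                                   seed = seed, index = index),
                       seed = params$seed, index = 0L) {
  pos <- cpp_grow_chain(params$N, geom$wall, obstacle_matrix(obstacles),
                        pars_for_cpp(params, geom), seed,
                        as.integer(index), 2L,
                        50L)
  system_state(pos, geometry = geom, obstacles = obstacles, tether = 1L)
}

#' Run one translocation attempt
#'
#' The full experiment protocol for a single run: build the static
#' environment, grow the chain with bead 1 at the entrance, equilibrate
#' with bead 1 tethered and the field off, release the tether, and
#' integrate under the driving force until one of
#' \itemize{
#'   \item success: every bead has crossed the exit plane `z > L`;
#'   \item retraction: every bead has returned to the cis side `z < 0`;
#'   \item timeout: the step cap `params$max_steps` is reached.
#' }
#' The event clock starts at tether release. First channel-entry and
#' first exit times are recorded per bead, and at each new exit count `s`
#' the beads-in-channel count and the gyration tensors of the whole chain
#' and of the translocated sub-chain are captured.
#'
#' @param params A [sim_params()] object.
#' @param run_index Run index within an ensemble; selects the independent
#'   random streams split from `params$seed`.
#' @param geom Prebuilt geometry (rebuilt from `params` when omitted).
#' @param obstacles Obstacle set override; by default obstacles are drawn
#'   from the run's own stream (or stream 0 when `params$fixed_obstacles`).
#' @param keep_snapshots Keep full chain snapshots at each exit count
#'   (memory-heavy; intended for single runs).
#' @return A one-row tibble of class `translocation_event` with scalar
#'   columns (`run`, `success`, `failure_mode`, `tau`, `n_steps`) and
#'   list-columns holding the per-bead arrays.
#' @examples
#' \donttest{
#' p <- sim_params(N = 8, F = 30, rho = 0, n_equil = 2000, max_steps = 2e5)
#' ev <- run_translocation(p)
#' ev$success
#' }
#' @export
run_translocation <- function(params, run_index = 1L, geom = NULL,
                              obstacles = NULL, keep_snapshots = FALSE) {
  validate_params(params)
  if (is.null(geom)) geom <- build_channel(params)
  idx <- as.integer(run_index)
  obst_index <- if (params$fixed_obstacles) 0L else idx
  if (is.null(obstacles)) {
    obstacles <- place_obstacles(params$rho, geom, params,
                                 seed = params$seed, index = obst_index)
  }
  state <- init_chain(params, geom, obstacles, seed = params$seed,
                      index = idx)
  state <- equilibrate(state, params, n_steps = params$n_equil,
                       seed = params$seed, index = idx,
                       check_convergence = FALSE)
  run_pars <- params
  run_pars$dt <- params$dt_run
  res <- cpp_run_event(state$positions, state$velocities, geom$wall,
                       state$obstacles, pars_for_cpp(run_pars, geom),
                       params$seed, idx, 4L, params$max_steps,
                       params$stall_time, keep_snapshots)
  check_integration_status(res)
  ev <- tibble(
    run = idx,
    success = res$success,
    failure_mode = res$failure_mode,
    tau = res$tau,
    n_steps = res$n_steps,
    entry_times = list(res$entry_times),
    exit_times = list(res$exit_times),
    exit_order_times = list(res$exit_order_times),
    n_in_at_exit = list(res$n_in_at_exit),
    gyr_whole = list(res$gyr_whole),
    gyr_out = list(res$gyr_out)
  )
  if (keep_snapshots) ev$snapshots <- list(res$snapshots)
  class(ev) <- c("translocation_event", class(ev))
  attr(ev, "params") <- params
  ev
}

#' Run an ensemble of independent translocation attempts
#'
#' Executes `n_runs` independent [run_translocation()] attempts with
#' per-run random streams split from the master seed by run index, so the
#' ensemble is reproducible and resumable at run granularity. Obstacle
#' configurations are redrawn per run (disorder averaging) unless
#' `params$fixed_obstacles` is set. A run aborted by an integration error
#' (broken bond) is logged and replaced by a fresh stream, up to
#' `retry_budget` replacements.
#'
#' @param params A [sim_params()] object.
#' @param n_runs Number of attempts (default `params$n_runs`).
#' @param start_index First run index (resume support).
#' @param checkpoint Optional path to a JSON-lines event store; completed
#'   runs found there are not recomputed and new runs are appended, so an
#'   interrupted ensemble resumes to an identical result.
#' @param retry_budget Maximum number of invalid-run replacements.
#' @param progress Print a one-line summary per run.
#' @return An `ensemble_result`: a tibble with one row per attempt (the
#'   columns of [run_translocation()]), with the parameters in attribute
#'   `"params"`.
#' @export
run_ensemble <- function(params, n_runs = params$n_runs, start_index = 1L,
                         checkpoint = NULL, retry_budget = 10L,
                         progress = FALSE) {
  validate_params(params)
  geom <- build_channel(params)
  indices <- seq.int(start_index, length.out = n_runs)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- read_events(checkpoint)
    indices <- setdiff(indices, done$run)
  }
  retries <- 0L
  events <- purrr::map(indices, function(i) {
    idx <- i
    repeat {
      ev <- tryCatch(run_translocation(params, run_index = idx, geom = geom),
                     crowdpore_bond_error = function(e) e,
                     crowdpore_overlap_error = function(e) e)
      if (!inherits(ev, "condition")) break
      retries <<- retries + 1L
      if (retries > retry_budget) {
        abort("retry budget exhausted replacing invalid runs",
              class = "crowdpore_run_error")
      }
      warn(sprintf("run %d invalid (%s); replacing with a fresh stream",
                   idx, conditionMessage(ev)))
      idx <- idx + 1000000L
    }
    ev$run <- i  # keep the ensemble slot stable even for replaced streams
    if (progress) {
      cat(sprintf("run %4d: %s tau = %s\n", i,
                  if (ev$success) "success " else ev$failure_mode,
                  format(ev$tau, digits = 4)))
    }
    if (!is.null(checkpoint)) write_events(ev, checkpoint, append = TRUE)
    ev
  })
  out <- dplyr::bind_rows(events)
  if (!is.null(done) && nrow(done) > 0) {
    out <- dplyr::bind_rows(done, out)
    out <- dplyr::arrange(out, .data$run)
  }
  class(out) <- c("ensemble_result", setdiff(class(out), "translocation_event"))
  attr(out, "params") <- params
  out
}

ensemble_params <- function(ens) {
  p <- attr(ens, "params")
  if (is.null(p)) abort("ensemble has no parameter attribute",
                        class = "crowdpore_data_error")
  p
}

#' Sweep the driving force and collect translocation-time statistics
#'
#' For each force on the grid, runs attempts in batches until at least
#' `target_successes` successful translocations are collected (or
#' `max_attempts` is reached), then summarises mean translocation time,
#' standard error and success probability. The same master seed is used at
#' every force, so forces are compared on a common set of random streams.
#'
#' @param params Base [sim_params()]; its `F` is overridden by `forces`.
#' @param forces Force grid (default `c(10, 15, 20, 25, 30)`).
#' @param target_successes Successful events required per force.
#' @param max_attempts Attempt cap per force.
#' @param batch Batch size between success-count checks.
#' @param progress Print one line per completed force.
#' @return A tibble with one row per force: `F`, `n_attempts`,
#'   `n_success`, `p_success`, `mean_tau`, `sem`. Feed it to
#'   [fit_scaling_exponent()].
#' @export
run_force_sweep <- function(params, forces = c(10, 15, 20, 25, 30),
                            target_successes = 200, max_attempts = 5000,
                            batch = 50, progress = FALSE) {
  rows <- purrr::map(forces, function(f) {
    p <- params
    p$F <- f
    ens <- NULL
    start <- 1L
    repeat {
      n_new <- min(batch, max_attempts - (start - 1L))
      if (n_new <= 0) break
      chunk <- run_ensemble(p, n_runs = n_new, start_index = start)
      ens <- if (is.null(ens)) chunk else dplyr::bind_rows(ens, chunk)
      start <- start + n_new
      if (sum(ens$success) >= target_successes) break
    }
    attr(ens, "params") <- p
    class(ens) <- c("ensemble_result", class(tibble()))
    st <- tau_statistics(ens)
    pr <- translocation_probability(ens)
    if (progress) {
      cat(sprintf("F = %5.1f: %d/%d success, <tau> = %.3f +- %.3f\n",
                  f, pr$successes, pr$attempts, st$mean_tau, st$sem))
    }
    tibble(F = f, n_attempts = pr$attempts, n_success = pr$successes,
           p_success = pr$p, mean_tau = st$mean_tau, sem = st$sem)
  })
  dplyr::bind_rows(rows)
}

#' Sweep the crowding extent
#'
#' Runs an ensemble at each crowding extent and summarises mean
#' translocation time and mean per-segment translocation time, the
#' quantities that grow approximately exponentially with crowding.
#'
#' @inheritParams run_force_sweep
#' @param rhos Crowding grid.
#' @return A tibble with one row per `rho`: attempt/success counts, mean
#'   translocation time with standard error, and mean segment time.
#' @export
run_rho_sweep <- function(params, rhos = c(0, 0.2, 0.4, 0.6),
                          target_successes = 100, max_attempts = 5000,
                          batch = 50, progress = FALSE) {
  rows <- purrr::map(rhos, function(r) {
    p <- params
    p$rho <- r
    ens <- NULL
    start <- 1L
    repeat {
      n_new <- min(batch, max_attempts - (start - 1L))
      if (n_new <= 0) break
      chunk <- run_ensemble(p, n_runs = n_new, start_index = start)
      ens <- if (is.null(ens)) chunk else dplyr::bind_rows(ens, chunk)
      start <- start + n_new
      if (sum(ens$success) >= target_successes) break
    }
    attr(ens, "params") <- p
    class(ens) <- c("ensemble_result", class(tibble()))
    st <- tau_statistics(ens)
    pr <- translocation_probability(ens)
    if (progress) {
      cat(sprintf("rho = %4.2f: %d/%d success, <tau> = %.3f\n",
                  r, pr$successes, pr$attempts, st$mean_tau))
    }
    tibble(rho = r, n_attempts = pr$attempts, n_success = pr$successes,
           p_success = pr$p, mean_tau = st$mean_tau, sem = st$sem,
           mean_segment_time = mean_segment_time(ens))
  })
  dplyr::bind_rows(rows)
}
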