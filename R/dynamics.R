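#' Construct a system state
#'
#' One time point of the dynamical system: bead positions and velocities
#' plus the static environment (wall particles and obstacles) they interact
#' with.
#'
#' @param positions `N x 3` matrix of bead positions.
#' @param velocities `N x 3` matrix of bead velocities (default zero).
#' @param geometry A [build_channel()] geometry.
#' @param obstacles Obstacle set from [place_obstacles()] (or `NULL`).
#' @param time Current time in \eqn{t_{LJ}} units.
#' @param tether Index (1-based) of a bead held fixed, or `NA` for none.
#' @return An object of class `system_state`.
#' @export
system_state <- function(positions, velocities = NULL, geometry,
                         obstacles = NULL, time = 0, tether = NA_integer_) {
  positions <- unname(as.matrix(positions))
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  }
  stopifnot(ncol(positions) == 3, all(dim(velocities) == dim(positions)))
  structure(list(positions = positions,
                 velocities = unname(as.matrix(velocities)),
                 geometry = geometry,
                 obstacles = obstacle_matrix(obstacles),
                 time = time, tether = tether),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d beads at t = %g t_LJ%s\n",
              nrow(x$positions), x$time,
              if (!is.na(x$tether)) sprintf(", bead %d tethered", x$tether)
              else ""))
  invisible(x)
}

#' Advance the state by Langevin dynamics
#'
#' Integrates the Langevin equation of motion
#' \eqn{m\ddot r_i = -\nabla U_i - \xi \dot r_i + F\hat z + W_i(t)} with
#' Gaussian thermal noise obeying the fluctuation-dissipation relation
#' (discrete per-component impulse variance \eqn{2 k_B T \xi\, dt}), using
#' the GJF Langevin velocity-Verlet scheme, which reproduces
#' configurational statistics and free diffusion exactly at finite `dt`.
#' A tethered bead is held at its position with zero velocity.
#'
#' @param state A [system_state()].
#' @param params A [sim_params()] object (supplies `dt`, `friction`,
#'   `kBT`).
#' @param n_steps Number of steps to take.
#' @param seed,index,stream Seeding of the noise stream; identical values
#'   reproduce the trajectory bit for bit.
#' @param field_on Whether the driving force acts (off during
#'   equilibration).
#' @param record_every If positive, record the squared radius of gyration
#'   and instantaneous kinetic temperature every that many steps; returned
#'   as attributes `rg2_trace` and `temp_trace`.
#' @param dump_every If positive, capture a coordinate frame every that
#'   many steps; returned as attribute `frames` (a list of `N x 3`
#'   matrices with times in attribute `frame_times`), ready for
#'   [write_trajectory()].
#' @return The advanced `system_state`.
#' @export
langevin_run <- function(state, params, n_steps, seed = params$seed,
                         index = 0L, stream = 3L, field_on = TRUE,
                         record_every = 0L, dump_every = 0L) {
  stopifnot(inherits(state, "system_state"))
  if (n_steps == 0) return(state)
  teth <- if (is.na(state$tether)) -1L else as.integer(state$tether) - 1L
  rec <- if (dump_every > 0) as.integer(dump_every) else
    as.integer(record_every)
  res <- cpp_integrate(state$positions, state$velocities,
                       state$geometry$wall, state$obstacles,
                       pars_for_cpp(params, state$geometry),
                       as.integer(n_steps),
                       seed, as.integer(index), as.integer(stream),
                       teth, field_on, rec, dump_every > 0)
  check_integration_status(res)
  out <- state
  out$positions <- res$positions
  out$velocities <- res$velocities
  out$time <- state$time + res$steps_done * params$dt
  attr(out, "rg2_trace") <- res$rg2_trace
  attr(out, "temp_trace") <- res$temp_trace
  if (dump_every > 0) {
    attr(out, "frames") <- res$frames
    attr(out, "frame_times") <- state$time + res$frame_times
  }
  out
}

#' @rdname langevin_run
#' @export
langevin_step <- function(state, params, seed = params$seed, index = 0L,
                          stream = 3L, field_on = TRUE) {
  langevin_run(state, params, 1L, seed = seed, index = index,
               stream = stream, field_on = field_on)
}

check_integration_status <- function(res) {
  if (res$status == 0) return(invisible(res))
  steps <- res$steps_done %||% res$n_steps %||% NA_real_
  if (res$status == 1) {
    abort(sprintf("broken bond at bead %d after %g steps",
                  res$bad_index, steps),
          class = "crowdpore_bond_error")
  }
  abort(sprintf("particle overlap singularity at bead %d after %g steps",
                res$bad_index, steps),
        class = "crowdpore_overlap_error")
}

#' Instantaneous kinetic temperature
#'
#' \eqn{m \langle |v|^2 \rangle / 3} over free (untethered) beads; the
#' thermostat diagnostic whose long-time average should equal `kBT`.
#'
#' @param state A [system_state()].
#' @param params A [sim_params()] (supplies the bead mass).
#' @return Kinetic temperature in units of \eqn{\epsilon}.
#' @export
kinetic_temperature <- function(state, params = sim_params()) {
  v <- state$velocities
  if (!is.na(state$tether)) v <- v[-state$tether, , drop = FALSE]
  if (nrow(v) == 0) abort("no free beads", class = "crowdpore_data_error")
  params$mass * mean(rowSums(v^2)) / 3
}

#' Equilibrate a tethered chain
#'
#' Runs Langevin dynamics with bead 1 tethered at the channel entrance and
#' the driving force off, so the remaining beads relax to an equilibrium
#' coil on the cis side. The squared radius-of-gyration trace is recorded
#' for convergence diagnostics; a warning is raised when the means of its
#' first and second halves disagree by more than 10%.
#'
#' @param state A [system_state()] with a tether set.
#' @param params A [sim_params()] object.
#' @param n_steps Number of equilibration steps (default `params$n_equil`).
#' @param seed,index Stream seeding.
#' @param check_convergence Whether to compare the two halves of the Rg
#'   trace.
#' @return The equilibrated `system_state` with attribute `rg2_trace`.
#' @export
equilibrate <- function(state, params, n_steps = params$n_equil,
                        seed = params$seed, index = 0L,
                        check_convergence = TRUE) {
  if (n_steps == 0) return(state)
  rec <- max(1L, as.integer(n_steps / 200))
  out <- langevin_run(state, params, n_steps, seed = seed, index = index,
                      stream = 3L, field_on = FALSE, record_every = rec)
  tr <- attr(out, "rg2_trace")
  if (check_convergence && length(tr) >= 20) {
    h <- length(tr) %/% 2
    m1 <- mean(tr[seq_len(h)])
    m2 <- mean(tr[(h + 1):length(tr)])
    if (abs(m1 - m2) > 0.1 * max(m2, .Machine$double.eps)) {
      warn(sprintf(
        "equilibration Rg^2 trace halves differ by %.0f%%; consider more steps",
        100 * abs(m1 - m2) / m2))
    }
  }
  out
}
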