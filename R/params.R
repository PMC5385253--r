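#' Simulation parameters
#'
#' Bundles every constant of the model in reduced Lennard-Jones units
#' (lengths in bead diameters \eqn{\sigma}, energies in \eqn{\epsilon},
#' times in \eqn{t_{LJ} = (m\sigma^2/\epsilon)^{1/2}}). The defaults are the
#' study conditions of the crowded-channel translocation model: a
#' Kremer-Grest chain (FENE bonds with \eqn{k = 7\epsilon}, \eqn{R_0 =
#' 2\sigma}; WCA excluded volume) in a channel of length \eqn{L = 5} and
#' radius \eqn{R = 2}, thermostatted at \eqn{k_BT = 1.2\epsilon} with
#' friction \eqn{\xi = 0.7}, crowded by static spherical obstacles of
#' diameter \eqn{d = 1}.
#'
#' @param N Chain length (number of beads), at least 2.
#' @param F Driving force per bead along +z, applied inside the channel.
#' @param rho Crowding extent: nominal fraction of channel volume occupied
#'   by obstacles, \eqn{\rho = N_o V_o / V_c} with \eqn{V_o =
#'   (4/3)\pi(d/2)^3} and \eqn{V_c = \pi R^2 L}. Must lie in `[0, 1)`.
#' @param L,R,d Channel length, accessible channel radius, obstacle diameter.
#' @param sigma,epsilon Bead diameter and repulsion strength (the units).
#' @param k_spring,R0 FENE spring constant and maximum bond extension.
#' @param mass Bead mass (reduced units; sets \eqn{t_{LJ} = 1}).
#' @param friction Langevin friction coefficient \eqn{\xi}.
#' @param kBT Thermostat temperature in units of \eqn{\epsilon}.
#' @param dt Integration time step in \eqn{t_{LJ}} used while the chain
#'   equilibrates (thermal motion only).
#' @param dt_run Base time step of the driven phase (defaults to `dt`).
#'   Both phases subdivide the base step adaptively whenever a bond
#'   approaches the FENE divergence or a bead moves fast, so the base
#'   step only sets the sampling resolution of quiet stretches.
#' @param stall_time Jam detector: a run in which no bead newly enters or
#'   exits the channel for this long (in \eqn{t_{LJ}}) is abandoned as a
#'   timeout failure. Set to 0 to disable.
#' @param n_equil Equilibration steps with bead 1 tethered at the entrance.
#' @param max_steps Step cap per translocation attempt; hitting it marks the
#'   attempt a `timeout` failure.
#' @param n_runs Default ensemble size.
#' @param seed Master seed; per-run streams are split from it by run index.
#' @param field_everywhere If `TRUE` the driving force acts on every bead
#'   regardless of position; by default it acts only on beads inside the
#'   channel.
#' @param fixed_obstacles If `TRUE` one obstacle configuration is shared by
#'   all runs of an ensemble; by default obstacles are redrawn per run so
#'   ensemble averages include disorder averaging.
#' @param membrane_extent Radial extent of the repulsive membrane lattice on
#'   the planes z = 0 and z = L (default `3 * R`).
#'
#' @return An object of class `sim_params`: a validated named list.
#' @examples
#' p <- sim_params(N = 16, F = 20, rho = 0.4)
#' p$k_spring
#' @export
sim_params <- function(N = 128, F = 10, rho = 0,
                       L = 5, R = 2, d = 1,
                       sigma = 1, epsilon = 1, k_spring = 7 * epsilon,
                       R0 = 2 * sigma, mass = 1,
                       friction = 0.7, kBT = 1.2 * epsilon, dt = 0.005,
                       dt_run = dt, stall_time = 500,
                       n_equil = 5e4, max_steps = 1e8, n_runs = 2000,
                       seed = 1L,
                       field_everywhere = FALSE, fixed_obstacles = FALSE,
                       membrane_extent = 3 * R) {
  p <- list(
    N = as.integer(N), F = F, rho = rho, L = L, R = R, d = d,
    sigma = sigma, epsilon = epsilon, k_spring = k_spring, R0 = R0,
    mass = mass, friction = friction, kBT = kBT, dt = dt, dt_run = dt_run,
    stall_time = stall_time,
    n_equil = as.numeric(n_equil), max_steps = as.numeric(max_steps),
    n_runs = as.integer(n_runs), seed = as.numeric(seed),
    field_everywhere = isTRUE(field_everywhere),
    fixed_obstacles = isTRUE(fixed_obstacles),
    membrane_extent = membrane_extent
  )
  class(p) <- "sim_params"
  validate_params(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  chain N = %d, force F = %g, crowding rho = %g\n",
              x$N, x$F, x$rho))
  cat(sprintf("  channel L = %g, R = %g, obstacle d = %g (N_o = %d)\n",
              x$L, x$R, x$d, n_obstacles_for_rho(x$rho, x)))
  cat(sprintf("  FENE k = %g, R0 = %g; xi = %g, kBT = %g, dt = %g (run %g)\n",
              x$k_spring, x$R0, x$friction, x$kBT, x$dt, x$dt_run))
  cat(sprintf("  n_equil = %g, max_steps = %g, n_runs = %d, seed = %g\n",
              x$n_equil, x$max_steps, x$n_runs, x$seed))
  invisible(x)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) abort(msg, class = "crowdpore_config_error")
  chk(p$N >= 2, "N must be at least 2")
  chk(p$rho >= 0 && p$rho < 1, "rho must lie in [0, 1)")
  for (f in c("L", "R", "d", "sigma", "epsilon", "k_spring", "R0", "mass",
              "kBT", "dt", "dt_run", "membrane_extent")) {
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1 && p[[f]] > 0,
        paste0(f, " must be a positive scalar"))
  }
  chk(p$friction >= 0, "friction must be nonnegative")
  chk(p$R0 > p$sigma, "R0 must exceed sigma")
  chk(p$n_equil >= 0, "n_equil must be nonnegative")
  chk(p$stall_time >= 0, "stall_time must be nonnegative")
  chk(p$max_steps >= 1, "max_steps must be at least 1")
  chk(p$n_runs >= 1, "n_runs must be at least 1")
  chk(abs(p$seed) < 2^31, "seed must be a 32-bit integer")
  p
}

#' Load simulation parameters from a YAML configuration file
#'
#' Reads a flat YAML mapping whose keys are the arguments of
#' [sim_params()]. Omitted keys take the model defaults; unknown keys are an
#' error (they are almost always typos). Values passed through `overrides`
#' beat the file, mirroring command-line precedence.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list of values that take precedence over the file.
#' @return A validated `sim_params` object.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("N: 16\nF: 20", cfg)
#' load_config(cfg, overrides = list(F = 15))$F
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path),
            class = "crowdpore_config_error")
    }
    # keep YAML-1.1 boolean-looking scalars (the keys N and F!) as text
    keep <- function(x) x
    vals <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                                  "bool#no" = keep))
    if (is.null(vals)) vals <- list()
    for (flag in c("field_everywhere", "fixed_obstacles")) {
      if (is.character(vals[[flag]])) {
        vals[[flag]] <- tolower(vals[[flag]]) %in% c("true", "yes", "on")
      }
    }
  }
  nm <- names(vals)
  nm[nm == "force"] <- "F" # CLI-friendly alias
  names(vals) <- nm
  vals <- modifyList(vals, overrides)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")),
          class = "crowdpore_config_error")
  }
  do.call(sim_params, vals)
}

# flat list view used by the C++ layer; the analytic membrane closure is
# keyed to the geometry actually present (0 disables it, e.g. free space)
pars_for_cpp <- function(p, geom = NULL) {
  mem <- 0
  if (!is.null(geom) && nrow(geom$wall) > 0) mem <- geom$membrane_extent
  list(sigma = p$sigma, epsilon = p$epsilon, k_spring = p$k_spring,
       R0 = p$R0, mass = p$mass, friction = p$friction, kBT = p$kBT,
       dt = p$dt, F = p$F, L = p$L, R = p$R, d = p$d,
       mem_extent = mem, field_everywhere = p$field_everywhere)
}
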