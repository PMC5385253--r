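#' FENE bond potential
#'
#' Energy of the finitely extensible nonlinear elastic bond between
#' consecutive beads, \eqn{U(r) = -\frac{1}{2} k R_0^2 \ln(1 - r^2/R_0^2)}.
#' The divergence at \eqn{r \to R_0} keeps bonds from crossing.
#'
#' @param r Bond length(s); must satisfy `0 <= r < R0`.
#' @param params A [sim_params()] object supplying `k_spring` and `R0`.
#' @return Energy, vectorised over `r`.
#' @examples
#' p <- sim_params()
#' fene_energy(1, p) # -14 * log(0.75)
#' @export
fene_energy <- function(r, params = sim_params()) {
  stopifnot(is.numeric(r), all(r >= 0))
  if (any(r >= params$R0)) {
    abort(sprintf("broken bond: r >= R0 at index %d",
                  which(r >= params$R0)[1]),
          class = "crowdpore_bond_error")
  }
  -0.5 * params$k_spring * params$R0^2 * log(1 - r^2 / params$R0^2)
}

#' FENE bond force
#'
#' Force exerted on a bead by a FENE bond, directed so as to shorten the
#' bond, with magnitude \eqn{k r / (1 - r^2/R_0^2)}; the negative analytic
#' gradient of [fene_energy()].
#'
#' @param pair A list with `r` (scalar separation) and `unit_vector`
#'   (3-vector from the partner towards the bead), as built by
#'   [pair_distance()].
#' @inheritParams fene_energy
#' @return A 3-vector force on the bead.
#' @examples
#' pr <- pair_distance(c(1, 0, 0), c(0, 0, 0))
#' fene_force(pr, sim_params()) # magnitude 7 / 0.75 towards the partner
#' @export
fene_force <- function(pair, params = sim_params()) {
  r <- pair$r
  if (r >= params$R0) {
    abort("broken bond: r >= R0", class = "crowdpore_bond_error")
  }
  if (r == 0) return(c(0, 0, 0))
  mag <- params$k_spring * r / (1 - r^2 / params$R0^2)
  -mag * pair$unit_vector
}

#' Separation between two particles
#'
#' @param xi,xj Positions (3-vectors) of the bead and its partner.
#' @return A list with the scalar separation `r` and the `unit_vector`
#'   pointing from `xj` to `xi` (zero vector when coincident).
#' @export
pair_distance <- function(xi, xj) {
  dv <- as.numeric(xi) - as.numeric(xj)
  r <- sqrt(sum(dv^2))
  list(r = r, unit_vector = if (r > 0) dv / r else c(0, 0, 0))
}

#' WCA (truncated-shifted repulsive Lennard-Jones) potential
#'
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r \le 2^{1/6}\sigma}, exactly zero beyond the cutoff. Used for all
#' bead-bead, bead-wall and bead-obstacle pairs, so every excluded-volume
#' interaction is purely repulsive.
#'
#' @param r Separation(s), strictly positive.
#' @param params A [sim_params()] object supplying `epsilon`.
#' @param sigma_pair Pair diameter; defaults to the bead diameter. For
#'   bead-obstacle pairs use `(sigma + d) / 2`.
#' @return Energy, vectorised over `r`.
#' @examples
#' wca_energy(1, sim_params())       # epsilon
#' wca_energy(1.5, sim_params())     # 0 beyond the cutoff
#' @export
wca_energy <- function(r, params = sim_params(), sigma_pair = params$sigma) {
  stopifnot(is.numeric(r))
  if (any(r <= 0)) {
    abort("overlapping particles: r must be positive",
          class = "crowdpore_overlap_error")
  }
  s6 <- (sigma_pair / r)^6
  u <- 4 * params$epsilon * (s6^2 - s6) + params$epsilon
  u[r > 2^(1 / 6) * sigma_pair] <- 0
  u
}

#' WCA force
#'
#' Purely repulsive force of magnitude
#' \eqn{(24\epsilon/r)[2(\sigma/r)^{12} - (\sigma/r)^6]} inside the cutoff
#' and identically zero beyond it; the negative gradient of [wca_energy()].
#'
#' @inheritParams fene_force
#' @inheritParams wca_energy
#' @return A 3-vector force on the bead (pointing away from the partner).
#' @export
wca_force <- function(pair, params = sim_params(), sigma_pair = params$sigma) {
  r <- pair$r
  if (r <= 0) {
    abort("overlapping particles: r must be positive",
          class = "crowdpore_overlap_error")
  }
  if (r >= 2^(1 / 6) * sigma_pair) return(c(0, 0, 0))
  s6 <- (sigma_pair / r)^6
  mag <- (24 * params$epsilon / r) * (2 * s6^2 - s6)
  mag * pair$unit_vector
}

#' Total force on every bead
#'
#' Sums, for each bead: FENE forces from its bonds, WCA forces from all
#' other beads, WCA forces from the static wall particles and obstacles
#' carried by the state's geometry, and the driving force \eqn{F\hat z} on
#' beads currently inside the channel (or on all beads when
#' `field_everywhere` is set). Wall particles and obstacles are static and
#' receive no update. Uses a cell list over the static particles.
#'
#' @param state A [system_state()] object.
#' @param params A [sim_params()] object.
#' @param field_on Whether the driving force term is included.
#' @return An `N x 3` matrix of forces with the total potential energy in
#'   attribute `"energy"`.
#' @export
total_forces <- function(state, params, field_on = TRUE) {
  stopifnot(inherits(state, "system_state"))
  geom <- state$geometry
  res <- cpp_forces(state$positions, geom$wall, state$obstacles,
                    pars_for_cpp(params, geom), field_on)
  if (res$status == 1) {
    abort(sprintf("broken bond at bead %d", res$bad_index),
          class = "crowdpore_bond_error")
  }
  if (res$status == 2) {
    abort(sprintf("particle overlap singularity at bead %d", res$bad_index),
          class = "crowdpore_overlap_error")
  }
  f <- res$forces
  attr(f, "energy") <- res$energy
  f
}
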