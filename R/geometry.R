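#' Number of obstacles realising a crowding extent
#'
#' The crowding extent is defined through \eqn{\rho = N_o V_o / V_c} with
#' obstacle volume \eqn{V_o = (4/3)\pi(d/2)^3} and channel volume
#' \eqn{V_c = \pi R^2 L}, so the obstacle count is the nearest integer to
#' \eqn{\rho V_c / V_o}.
#'
#' @param rho Crowding extent in `[0, 1)`.
#' @param params A [sim_params()] object supplying `L`, `R`, `d`.
#' @return Integer obstacle count \eqn{N_o}.
#' @examples
#' n_obstacles_for_rho(0.4, sim_params()) # 48
#' @export
n_obstacles_for_rho <- function(rho, params = sim_params()) {
  if (any(rho < 0 | rho >= 1)) {
    abort("rho must lie in [0, 1)", class = "crowdpore_config_error")
  }
  v_c <- pi * params$R^2 * params$L
  v_o <- (4 / 3) * pi * (params$d / 2)^3
  as.integer(round(rho * v_c / v_o))
}

#' Build the static channel geometry
#'
#' Constructs the stationary wall particles: rings of radius
#' \eqn{R + \sigma/2} lining the cylinder over \eqn{z \in [0, L]}, and a
#' triangular lattice tiling the membrane planes \eqn{z = 0} and
#' \eqn{z = L} outside the pore, out to `membrane_extent`. Lattice and ring
#' spacings are at most \eqn{\sigma\sqrt{3}/2} so no gap can pass a bead of
#' diameter \eqn{\sigma} (leak-tightness): the only way from the cis side
#' (`z < 0`) to the trans side (`z > L`) is through the pore.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `channel_geometry`: a list with `L`, `R`,
#'   `d`, `sigma`, `membrane_extent` and the `wall` particle matrix.
#' @export
build_channel <- function(params = sim_params()) {
  sigma <- params$sigma
  L <- params$L
  R <- params$R
  s <- sigma * sqrt(3) / 2  # maximum allowed spacing
  r_line <- R + sigma / 2

  # cylinder lining: staggered rings
  nz <- ceiling(L / s)
  zs <- seq(0, L, length.out = nz + 1)
  n_ring <- ceiling(2 * pi * r_line / s)
  rings <- purrr::map(seq_along(zs), function(i) {
    offset <- if (i %% 2 == 0) pi / n_ring else 0
    th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring + offset
    cbind(r_line * cos(th), r_line * sin(th), zs[i])
  })

  # membrane planes: triangular lattice, spacing s, annulus outside the pore
  a <- s
  ext <- params$membrane_extent
  jmax <- ceiling(ext / (a * sqrt(3) / 2)) + 1
  imax <- ceiling(ext / a) + 1
  grid <- expand.grid(i = -imax:imax, j = -jmax:jmax)
  mx <- grid$i * a + (grid$j %% 2) * a / 2
  my <- grid$j * a * sqrt(3) / 2
  rad <- sqrt(mx^2 + my^2)
  keep <- rad >= r_line & rad <= ext
  plane <- cbind(mx[keep], my[keep])
  membrane <- rbind(cbind(plane, 0), cbind(plane, L))

  wall <- rbind(do.call(rbind, rings), membrane)
  colnames(wall) <- c("x", "y", "z")
  structure(list(L = L, R = R, d = params$d, sigma = sigma,
                 membrane_extent = ext, wall = wall),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> L = %g, R = %g, d = %g, %d wall particles\n",
              x$L, x$R, x$d, nrow(x$wall)))
  invisible(x)
}

#' Place crowding obstacles
#'
#' Draws `n_obstacles_for_rho(rho)` obstacle centres uniformly over the
#' accessible cylinder \eqn{\{0 \le z \le L,\ r_\perp \le R - d/2\}}, so
#' every obstacle lies fully inside the channel. Obstacle-obstacle overlap
#' is permitted: the crowding extents studied (up to \eqn{\rho = 0.8})
#' exceed hard-sphere random packing in this volume, so independent uniform
#' placement is the construction that realises every \eqn{\rho}.
#'
#' @inheritParams n_obstacles_for_rho
#' @param geom A [build_channel()] geometry (used for bounds).
#' @param seed Seed of the placement stream; the same seed always yields
#'   the same configuration.
#' @param index Stream index (used by ensembles to redraw obstacles per
#'   run).
#' @return A tibble with columns `x`, `y`, `z` of class `obstacle_set`,
#'   with `rho` and `count` attributes.
#' @export
place_obstacles <- function(rho, geom, params = sim_params(), seed = params$seed,
                            index = 0L) {
  n <- n_obstacles_for_rho(rho, params)
  m <- cpp_place_obstacles(n, geom$L, geom$R, geom$d, params$sigma, seed,
                           as.integer(index), 1L)
  out <- tibble(x = m[, 1], y = m[, 2], z = m[, 3])
  class(out) <- c("obstacle_set", class(out))
  attr(out, "rho") <- rho
  attr(out, "count") <- n
  out
}

obstacle_matrix <- function(obstacles) {
  if (is.null(obstacles) || nrow(obstacles) == 0) {
    return(matrix(numeric(0), ncol = 3))
  }
  unname(as.matrix(obstacles[, c("x", "y", "z")]))
}

#' Classify positions into cis / channel / trans regions
#'
#' A point is in the `channel` iff \eqn{0 \le z \le L} and its radial
#' distance from the axis is at most \eqn{R}; `cis` iff \eqn{z < 0}; `trans`
#' iff \eqn{z > L}. Points with \eqn{z \in [0, L]} but radial distance
#' beyond \eqn{R} (geometrically excluded for beads) are assigned by the
#' sign of \eqn{z - L/2}.
#'
#' @param positions An `n x 3` matrix (or 3-vector) of positions.
#' @param geom A [build_channel()] geometry.
#' @return Character vector in `c("cis", "channel", "trans")`.
#' @examples
#' g <- build_channel(sim_params())
#' region_classify(c(0, 0, -1), g)
#' @export
region_classify <- function(positions, geom) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  z <- positions[, 3]
  rad2 <- positions[, 1]^2 + positions[, 2]^2
  out <- ifelse(z < 0, "cis",
         ifelse(z > geom$L, "trans",
         ifelse(rad2 <= geom$R^2, "channel",
         ifelse(z < geom$L / 2, "cis", "trans"))))
  out
}

#' Export geometry (and optionally a chain) as an XYZ snapshot
#'
#' Writes a single-frame XYZ file with element tags `W` (wall), `O`
#' (obstacle) and `C` (chain bead) for visualisation.
#'
#' @param geom A [build_channel()] geometry.
#' @param path Output file path.
#' @param obstacles Optional obstacle set from [place_obstacles()].
#' @param beads Optional `N x 3` matrix of bead positions.
#' @return `path`, invisibly.
#' @export
write_geometry_xyz <- function(geom, path, obstacles = NULL, beads = NULL) {
  coords <- geom$wall
  tags <- rep("W", nrow(coords))
  om <- obstacle_matrix(obstacles)
  if (nrow(om) > 0) {
    coords <- rbind(coords, om)
    tags <- c(tags, rep("O", nrow(om)))
  }
  if (!is.null(beads)) {
    coords <- rbind(coords, beads)
    tags <- c(tags, rep("C", nrow(beads)))
  }
  write_xyz_frame(coords, tags, comment = "channel geometry", path = path,
                  append = FALSE)
  invisible(path)
}
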