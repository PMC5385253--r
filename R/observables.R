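#' Gyration-tensor shape metrics of a configuration
#'
#' Builds the gyration tensor about the centroid, takes its ordered
#' eigenvalues \eqn{L_1^2 \le L_2^2 \le L_3^2} (the orthogonal components
#' of the squared radius of gyration along the principal axes of inertia)
#' and returns the shape factor
#' \deqn{\delta = 1 - 3\,\frac{L_1^2 L_2^2 + L_2^2 L_3^2 + L_3^2 L_1^2}
#'   {(L_1^2 + L_2^2 + L_3^2)^2},}
#' which is 0 for a spherically symmetric mass distribution and 1 for a
#' rod.
#'
#' @param coordinates An `M x 3` matrix of positions, `M >= 2`, not all
#'   coincident.
#' @return An object of class `shape_metrics`: list with
#'   `principal_components` (ordered ascending), `S2` (their sum) and
#'   `delta`.
#' @examples
#' rod <- cbind(1:10, 0, 0)
#' shape_factor(rod)$delta # 1
#' @export
shape_factor <- function(coordinates) {
  x <- unname(as.matrix(coordinates))
  stopifnot(ncol(x) == 3)
  if (nrow(x) < 2) {
    abort("need at least two points", class = "crowdpore_data_error")
  }
  xc <- sweep(x, 2, colMeans(x))
  tensor <- crossprod(xc) / nrow(x)
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  s2 <- sum(ev)
  if (s2 <= 0) {
    abort("all points coincident: shape undefined",
          class = "crowdpore_data_error")
  }
  delta <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / s2^2
  structure(list(principal_components = ev, S2 = s2, delta = delta),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("<shape_metrics> delta = %.4f, S2 = %.4f (L2 = %s)\n",
              x$delta, x$S2,
              paste(signif(x$principal_components, 4), collapse = ", ")))
  invisible(x)
}

# delta from the 6 unique gyration-tensor entries (xx,yy,zz,xy,xz,yz),
# vectorised over rows, using the tensor invariants: the pairwise
# eigenvalue products sum to (tr^2 - tr(A^2)) / 2, so no eigen-solve is
# needed.
delta_from_gyr <- function(g) {
  tr <- g[, 1] + g[, 2] + g[, 3]
  tra2 <- g[, 1]^2 + g[, 2]^2 + g[, 3]^2 +
    2 * (g[, 4]^2 + g[, 5]^2 + g[, 6]^2)
  i2 <- (tr^2 - tra2) / 2
  1 - 3 * i2 / tr^2
}

successful_events <- function(ens, require_some = TRUE) {
  ok <- dplyr::filter(ens, .data$success)
  if (require_some && nrow(ok) == 0) {
    abort("no successful translocation events",
          class = "crowdpore_data_error")
  }
  ok
}

sem_of <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1) return(0)
  sd(x) / sqrt(length(x))
}

#' Translocation probability with Wilson interval
#'
#' Fraction of successful attempts in an ensemble, with the Wilson 95%
#' score interval (well behaved at 0 and 1).
#'
#' @param ens An `ensemble_result` (or any data frame with a logical
#'   `success` column).
#' @param conf Confidence level of the interval.
#' @return A one-row tibble: `successes`, `attempts`, `p`, `ci_lo`,
#'   `ci_hi`.
#' @export
translocation_probability <- function(ens, conf = 0.95) {
  n <- nrow(ens)
  if (n < 1) abort("empty ensemble", class = "crowdpore_data_error")
  k <- sum(ens$success)
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / den
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  tibble(successes = k, attempts = n, p = ph,
         ci_lo = max(0, centre - half), ci_hi = min(1, centre + half))
}

#' Translocation-time statistics
#'
#' Arithmetic mean and standard error of the translocation time over the
#' successful events of an ensemble (the translocation time is defined
#' only for completed translocations).
#'
#' @param ens An `ensemble_result`.
#' @return A one-row tibble: `n`, `mean_tau`, `sem`, `median_tau`.
#' @export
tau_statistics <- function(ens) {
  ok <- successful_events(ens)
  tibble(n = nrow(ok), mean_tau = mean(ok$tau), sem = sem_of(ok$tau),
         median_tau = stats::median(ok$tau))
}

#' Per-bead translocation-time profile
#'
#' For each bead index `s`, the channel residence time
#' \eqn{\tau(s) = t_{exit}(s) - t_{entry}(s)} averaged over successful
#' events. Two alternative readings of a per-segment time are exported
#' alongside: the waiting time between consecutive bead exits
#' (`tau_wait`, indexed by exit rank) and the cumulative time to the
#' `s`-th exit (`tau_cum`), so the three conventions can be compared on
#' the same ensemble.
#'
#' @param ens An `ensemble_result` with at least one success.
#' @return A tibble of class `crowdpore_profile` with columns `s`, `tau`,
#'   `sem`, `tau_wait`, `sem_wait`, `tau_cum`, `sem_cum`.
#' @export
tau_per_bead <- function(ens) {
  ok <- successful_events(ens)
  res <- do.call(rbind, purrr::map2(ok$exit_times, ok$entry_times, `-`))
  wait <- do.call(rbind, purrr::map(ok$exit_order_times,
                                    ~ diff(c(0, .x))))
  cum <- do.call(rbind, ok$exit_order_times)
  out <- tibble(
    s = seq_len(ncol(res)),
    tau = colMeans(res), sem = apply(res, 2, sem_of),
    tau_wait = colMeans(wait), sem_wait = apply(wait, 2, sem_of),
    tau_cum = colMeans(cum), sem_cum = apply(cum, 2, sem_of)
  )
  new_profile(out, "tau(s)", "mean channel residence time of bead s")
}

#' Mean translocation time over all segments
#'
#' The average of the per-bead residence times, \eqn{(1/N)\sum_s \tau(s)};
#' grows approximately exponentially with the crowding extent.
#'
#' @param ens An `ensemble_result` with at least one success.
#' @return A single number (time in \eqn{t_{LJ}}).
#' @export
mean_segment_time <- function(ens) {
  mean(tau_per_bead(ens)$tau)
}

#' Beads-in-channel profile
#'
#' Ensemble mean, over successful events, of the number of beads inside
#' the channel at the instant the `s`-th bead first exits.
#'
#' @param ens An `ensemble_result` with at least one success.
#' @return A tibble of class `crowdpore_profile`: `s`, `n_in`, `sem`.
#' @export
n_in_profile <- function(ens) {
  ok <- successful_events(ens)
  m <- do.call(rbind, ok$n_in_at_exit)
  out <- tibble(s = seq_len(ncol(m)), n_in = colMeans(m),
                sem = apply(m, 2, sem_of))
  new_profile(out, "N_in(s)", "beads inside channel at the s-th exit")
}

#' Shape-factor profile
#'
#' Ensemble mean of the shape factor \eqn{\langle\delta\rangle} computed
#' from the gyration tensor captured at each exit count `s`. By default
#' the whole chain's tensor is used; `scope = "translocated"` uses only
#' the beads already out of the channel.
#'
#' @param ens An `ensemble_result` with at least one success.
#' @param scope `"whole"` (default) or `"translocated"`.
#' @return A tibble of class `crowdpore_profile`: `s`, `delta`, `sem`.
#' @export
delta_profile <- function(ens, scope = c("whole", "translocated")) {
  scope <- match.arg(scope)
  ok <- successful_events(ens)
  col <- if (scope == "whole") "gyr_whole" else "gyr_out"
  if (!col %in% names(ok)) {
    abort("ensemble carries no gyration snapshots",
          class = "crowdpore_data_error")
  }
  d <- do.call(rbind, purrr::map(ok[[col]], delta_from_gyr))
  out <- tibble(s = seq_len(ncol(d)), delta = colMeans(d, na.rm = TRUE),
                sem = apply(d, 2, sem_of))
  # s = 1 sub-chain is a single bead: shape undefined there
  if (scope == "translocated") out$delta[1] <- NA_real_
  new_profile(out, "<delta>(s)", "mean shape factor at exit count s")
}

#' Fit the translocation-time force-scaling exponent
#'
#' Weighted linear least squares of \eqn{\ln\langle\tau\rangle} on
#' \eqn{\ln F}: the scaling relation \eqn{\tau \sim F^{-\alpha}} gives
#' \eqn{\alpha} as minus the slope. Weights follow from the standard
#' errors of the mean times by error propagation,
#' \eqn{w = (\langle\tau\rangle / \mathrm{sem})^2}; with no (or zero)
#' standard errors the fit is unweighted.
#'
#' @param points A data frame with columns `F`, `mean_tau` and optionally
#'   `sem` — e.g. the output of [run_force_sweep()]. At least 3 points
#'   with positive `F` and `mean_tau`.
#' @return An object of class `scaling_fit` with elements `alpha`,
#'   `alpha_stderr`, `prefactor`, `points` and the underlying `lm` fit.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' pts <- data.frame(F = c(10, 15, 20, 25, 30))
#' pts$mean_tau <- 100 * pts$F^-0.5
#' fit_scaling_exponent(pts)$alpha
#' @export
fit_scaling_exponent <- function(points) {
  points <- as_tibble(points)
  if (!all(c("F", "mean_tau") %in% names(points))) {
    abort("points must have columns F and mean_tau",
          class = "crowdpore_data_error")
  }
  if (nrow(points) < 3) {
    abort("need at least 3 (F, mean tau) points",
          class = "crowdpore_data_error")
  }
  if (any(points$F <= 0) || any(points$mean_tau <= 0)) {
    abort("F and mean_tau must be positive",
          class = "crowdpore_data_error")
  }
  w <- NULL
  if ("sem" %in% names(points) && all(is.finite(points$sem)) &&
      all(points$sem > 0)) {
    w <- (points$mean_tau / points$sem)^2
  }
  df <- data.frame(lt = log(points$mean_tau), lf = log(points$F))
  fit <- if (is.null(w)) lm(lt ~ lf, data = df) else
    lm(lt ~ lf, data = df, weights = w)
  alpha <- -unname(coef(fit)[2])
  # exact power laws have zero residuals; summary.lm warns harmlessly
  se <- suppressWarnings(sqrt(diag(vcov(fit)))[2])
  structure(list(alpha = alpha, alpha_stderr = unname(se),
                 prefactor = exp(unname(coef(fit)[1])),
                 points = points, fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> tau ~ F^-alpha: alpha = %.4f +- %.4f (%d points)\n",
    x$alpha, x$alpha_stderr, nrow(x$points)))
  invisible(x)
}

new_profile <- function(df, label, description) {
  class(df) <- c("crowdpore_profile", class(df))
  attr(df, "label") <- label
  attr(df, "description") <- description
  df
}
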