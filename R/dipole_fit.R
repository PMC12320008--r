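# Equivalent-current-dipole fitting on averaged topographies.

#' Nonlinear single-dipole fit
#'
#' Derivative-free Nelder-Mead search over the dipole position, starting
#' from `start_pos`, minimizing the residual fraction
#' `||d - L(p) m||^2 / ||d||^2` where `m` is the linear least-squares
#' moment at each candidate position (truncated SVD, so the externally
#' silent radial direction does not inflate the moment). Positions leaving
#' the head ellipsoid are penalized smoothly rather than rejected, keeping
#' the simplex well-defined.
#'
#' @param topography numeric vector, one value per channel (T)
#' @param array an `opm_array`
#' @param start_pos starting position (m); typically the true location in
#'   simulation studies
#' @param reltol relative convergence tolerance on the objective
#' @param maxit maximum function evaluations
#' @return object of class `opm_dipole_fit`: list with `position` (m),
#'   `moment` (A*m), `residual_fraction`, `n_evals`, `converged`
#' @export
fit_dipole <- function(topography, array, start_pos, reltol = 1e-4,
                       maxit = 2000) {
  topography <- as.numeric(topography)
  if (all(topography == 0) || any(!is.finite(topography))) {
    stopf("topography must be finite and not all zero")
  }
  sp <- sensor_positions(array); so <- sensor_orientations(array)
  cen <- array$head$center; semi <- array$head$semi_axes
  opt <- cpp_fit_dipole(matrix(as.numeric(start_pos), 1, 3), topography,
                        sp, so, cen, cen, semi, reltol, maxit)
  pos <- as.numeric(opt$par)
  L <- dipole_leadfield(array, pos)
  m <- as.numeric(pinv(L) %*% topography)
  res <- topography - as.numeric(L %*% m)
  structure(
    list(position = pos, moment = m,
         residual_fraction = sum(res^2) / sum(topography^2),
         n_evals = opt$fevals,
         converged = isTRUE(opt$converged)),
    class = "opm_dipole_fit"
  )
}

#' @export
print.opm_dipole_fit <- function(x, ...) {
  cat(sprintf(
    "<opm_dipole_fit> pos (%.1f, %.1f, %.1f) mm; |m| %.2f nAm; rv %.3g\n",
    1000 * x$position[1], 1000 * x$position[2], 1000 * x$position[3],
    moment_magnitude(x), x$residual_fraction))
  invisible(x)
}

#' Localization error of a dipole fit, in millimeters
#' @param fit an `opm_dipole_fit` (or a length-3 position in m)
#' @param truth_pos true position (m)
#' @export
localization_error <- function(fit, truth_pos) {
  pos <- if (inherits(fit, "opm_dipole_fit")) fit$position else as.numeric(fit)
  1000 * sqrt(sum((pos - as.numeric(truth_pos))^2))
}

#' Magnitude of the fitted dipole moment, in nAm
#' @param fit an `opm_dipole_fit` (or a length-3 moment in A*m)
#' @export
moment_magnitude <- function(fit) {
  m <- if (inherits(fit, "opm_dipole_fit")) fit$moment else as.numeric(fit)
  1e9 * sqrt(sum(m^2))
}
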