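# Source grids, dipole-signal simulation with interleaved baseline/active
# columns, and the sensor- and brain-noise generators.

#' Regular dipole grid inside an ellipsoidal region
#'
#' Axis-aligned lattice with the origin as a lattice point, restricted to
#' points strictly inside the region ellipsoid, in its upper half
#' (z >= 0, equatorial plane included) and with z >= z_min when a positive
#' z_min is given. With this convention the 2.5 mm lattice in the default
#' brain compartment has 46,870 points.
#'
#' @param spacing lattice spacing (m)
#' @param region an [ellipsoid()]; defaults to the brain compartment
#' @param z_min minimum z coordinate (m); points with z >= z_min are kept
#' @return object of class `opm_source_grid`: list with `positions`,
#'   `spacing`, `region`, `z_min`
#' @export
make_source_grid <- function(spacing, region = brain_ellipsoid(), z_min = 0) {
  if (spacing <= 0) stopf("spacing must be positive")
  semi <- region$semi_axes; cen <- region$center
  ax <- lapply(1:3, function(k) {
    K <- ceiling(semi[k] / spacing) + 1
    cen[k] + spacing * seq(-K, K)
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  keep <- ellipsoid_value(region, pts) < 0 & pts[, 3] >= -1e-12
  if (z_min > 0) keep <- keep & pts[, 3] >= z_min - 1e-9
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) stopf("no lattice point falls inside the region")
  rownames(pts) <- NULL
  structure(list(positions = pts, spacing = spacing, region = region,
                 z_min = z_min),
            class = "opm_source_grid")
}

#' @export
print.opm_source_grid <- function(x, ...) {
  cat(sprintf("<opm_source_grid> %d points, spacing %.4g m, z_min %.4g m\n",
              nrow(x$positions), x$spacing, x$z_min))
  invisible(x)
}

#' Spatially and temporally white Gaussian sensor noise
#'
#' @param n_channels,n_samples matrix dimensions
#' @param sigma per-sample standard deviation in tesla (default 2 pT)
#' @param seed optional integer seed (RNG state is restored afterwards)
#' @return n_channels x n_samples matrix (T)
#' @export
white_sensor_noise <- function(n_channels, n_samples, sigma = 2e-12,
                               seed = NULL) {
  if (sigma < 0) stopf("sigma must be >= 0")
  local_seed(seed,
    matrix(stats::rnorm(n_channels * n_samples, 0, sigma),
           n_channels, n_samples))
}

#' Equivalent amplitude spectral density of white noise
#'
#' A per-sample standard deviation `sigma` corresponds to
#' `sigma / sqrt(bandwidth)` of amplitude spectral density; e.g. 2 pT rms
#' in a 100 Hz bandwidth is 200 fT/sqrt(Hz).
#'
#' @param sigma per-sample standard deviation (T)
#' @param bandwidth assumed bandwidth (Hz)
#' @return amplitude spectral density (T/sqrt(Hz))
#' @export
noise_floor_asd <- function(sigma, bandwidth = 100) {
  sigma / sqrt(bandwidth)
}

#' Precompute the channel-space factor of distributed brain noise
#'
#' Brain noise is the superposition of dipoles on a dense grid with i.i.d.
#' Gaussian moments (SD `sigma_moment` per Cartesian component, white over
#' time). Its exact channel covariance is
#' `sigma_moment^2 L L^T`; this returns a Cholesky-style factor `F` with
#' `F F^T` equal to that covariance, so noise can be drawn as `F %*% W`
#' with `W` standard normal, without forming the full source time courses.
#'
#' @param array an `opm_array`
#' @param grid_spacing brain-noise grid spacing (m); default 6.3 mm
#' @param sigma_moment dipole-moment SD (A*m); default 1 nAm
#' @param region brain compartment
#' @return list with `factor` (n_channels x n_channels), `n_sources`,
#'   `covariance`
#' @export
brain_noise_factor <- function(array, grid_spacing = 6.3e-3,
                               sigma_moment = 1e-9,
                               region = brain_ellipsoid()) {
  grid <- make_source_grid(grid_spacing, region)
  L <- grid_leadfield(array, grid)$matrix
  C <- sigma_moment^2 * tcrossprod(L)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  fac <- e$vectors %*% diag(sqrt(vals))
  list(factor = fac, n_sources = nrow(grid$positions), covariance = C)
}

#' Spatially correlated brain noise
#'
#' Draws zero-mean Gaussian noise with channel covariance
#' `sigma_moment^2 L L^T` where L is the leadfield of a dense dipole grid
#' (white over time, correlated over channels). A precomputed
#' [brain_noise_factor()] can be supplied to amortize the leadfield work.
#'
#' @param array an `opm_array`
#' @param n_samples number of time samples
#' @param grid_spacing grid spacing (m)
#' @param sigma_moment per-dipole moment SD (A*m)
#' @param seed optional integer seed
#' @param factor optional precomputed [brain_noise_factor()]
#' @return n_channels x n_samples matrix (T)
#' @export
brain_noise <- function(array, n_samples, grid_spacing = 6.3e-3,
                        sigma_moment = 1e-9, seed = NULL, factor = NULL) {
  if (sigma_moment == 0) {
    return(matrix(0, nrow(array$channels), n_samples))
  }
  if (is.null(factor)) {
    factor <- brain_noise_factor(array, grid_spacing, sigma_moment)
  }
  n_chan <- nrow(factor$factor)
  W <- local_seed(seed,
    matrix(stats::rnorm(n_chan * n_samples), n_chan, n_samples))
  factor$factor %*% W
}

#' Simulate a dipolar recording with interleaved baseline/active columns
#'
#' Starts from a 192 x n noise matrix and adds the forward solution of a
#' 10 nAm dipole (oriented along one of the two tangential axes of its
#' silent frame) to every even-numbered column. Odd-numbered columns are
#' baseline observations, even-numbered columns are active observations.
#'
#' @param array an `opm_array`
#' @param source_pos dipole location (m)
#' @param tangential_axis 1 (x', strongest) or 2 (y')
#' @param noise n_channels x n_samples noise matrix (T); may be zero
#' @param amplitude dipole amplitude (A*m), default 10 nAm
#' @return object of class `opm_recording`: list with `data`, `truth`
#'   (position, orientation, amplitude, noise-free topography), `n_samples`
#' @export
simulate_dipole_recording <- function(array, source_pos, tangential_axis = 1,
                                      noise, amplitude = 10e-9) {
  if (nrow(noise) != nrow(array$channels)) {
    stopf("noise must have one row per channel")
  }
  frame <- silent_frame(array, source_pos)
  ori <- if (tangential_axis == 1) frame$x else frame$y
  topo <- as.numeric(dipole_leadfield(array, source_pos) %*% (amplitude * ori))
  data <- noise
  active <- seq(2, ncol(data), by = 2)
  data[, active] <- data[, active] + topo
  structure(
    list(data = data,
         truth = list(position = as.numeric(source_pos), orientation = ori,
                      amplitude = amplitude, topography = topo),
         n_samples = ncol(data)),
    class = "opm_recording"
  )
}

#' Cut a recording into overlapping segments
#'
#' Default: 6,000 samples -> 45 segments of 600 samples with 80% overlap
#' (step 120). Starts run 0, 120, ..., 5280 so the final partial window is
#' dropped; the last `step` columns of the recording are unused. The step
#' is even, so baseline/active column parity is preserved inside segments.
#'
#' @param rec an `opm_recording` (or a bare matrix)
#' @param window segment length in samples
#' @param overlap fractional overlap in [0, 1)
#' @param n_segments number of segments to keep (default 45 for the
#'   standard 6,000-sample recording; otherwise all full windows)
#' @return list of `opm_segment` objects (fields `data`, `start_index`)
#' @export
segment_recording <- function(rec, window = 600, overlap = 0.8,
                              n_segments = NULL) {
  data <- if (inherits(rec, "opm_recording")) rec$data else rec
  n <- ncol(data)
  if (window > n) stopf("window exceeds recording length")
  step <- window * (1 - overlap)
  if (abs(step - round(step)) > 1e-9) stopf("window * (1 - overlap) must be an integer")
  step <- as.integer(round(step))
  starts <- seq(1L, n - window + 1L, by = step)
  if (is.null(n_segments)) {
    n_segments <- if (n == 6000 && window == 600 && step == 120) 45L
                  else length(starts)
  }
  starts <- starts[seq_len(min(n_segments, length(starts)))]
  lapply(starts, function(s) {
    structure(list(data = data[, s:(s + window - 1), drop = FALSE],
                   start_index = s),
              class = "opm_segment")
  })
}

#' Active-minus-baseline average topography of a segment
#'
#' Subtracts the mean over baseline (odd-numbered) columns from the mean
#' over active (even-numbered) columns; parity refers to the column index
#' in the parent recording. Any static field component cancels exactly.
#'
#' @param seg an `opm_segment`, or a matrix (then assumed to start at
#'   column 1 of its recording)
#' @return numeric vector, one value per channel (T)
#' @export
average_topography <- function(seg) {
  if (inherits(seg, "opm_segment")) {
    data <- seg$data; start <- seg$start_index
  } else {
    data <- seg; start <- 1L
  }
  gcol <- start + seq_len(ncol(data)) - 1L
  active <- gcol %% 2 == 0
  if (sum(active) != sum(!active)) {
    stopf("segment must contain equal numbers of baseline and active columns")
  }
  rowMeans(data[, active, drop = FALSE]) -
    rowMeans(data[, !active, drop = FALSE])
}
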