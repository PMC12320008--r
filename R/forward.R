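# Current-dipole forward model (homogeneous spherical conductor, Sarvas
# closed form) and the Gram-matrix sensitivity analysis.

#' Leadfield of a single current dipole
#'
#' Magnetic pickup of unit dipoles along x, y and z at `source_pos`, for
#' every channel of the array, in a homogeneous spherical conductor
#' centered at the head-ellipsoid center. Units: tesla per A*m.
#'
#' @param array an `opm_array`
#' @param source_pos length-3 position (m), strictly inside the brain/head
#' @return n_channels x 3 matrix
#' @export
dipole_leadfield <- function(array, source_pos) {
  source_pos <- as.numeric(source_pos)
  center <- array$head$center
  if (sqrt(sum((source_pos - center)^2)) < 1e-9) {
    stopf("source at the conductor center has no external field")
  }
  if (ellipsoid_value(array$head, source_pos) >= 0) {
    stopf("source must lie strictly inside the head")
  }
  cpp_sarvas_leadfield(sensor_positions(array), sensor_orientations(array),
                       matrix(source_pos, 1, 3), center)
}

#' Leadfield for a grid of dipoles
#'
#' @param array an `opm_array`
#' @param grid n x 3 matrix of source positions (m) or an `opm_source_grid`
#' @return object of class `opm_leadfield`: list with `matrix`
#'   (n_channels x 3 n_sources; columns in consecutive x,y,z triplets per
#'   source) and `source_positions`
#' @export
grid_leadfield <- function(array, grid) {
  pos <- if (inherits(grid, "opm_source_grid")) grid$positions else rbind(grid)
  if (nrow(pos) == 0) stopf("empty source grid")
  L <- cpp_sarvas_leadfield(sensor_positions(array),
                            sensor_orientations(array),
                            pos, array$head$center)
  structure(list(matrix = L, source_positions = pos,
                 channel_names = array$channels$channel_name),
            class = "opm_leadfield")
}

#' Diagonal of the source-normalized Gram matrix of a leadfield
#'
#' `diag(L L^T) / n_sources`: the average signal power each channel picks up
#' from unit dipoles distributed over the sources.
#'
#' @param lf an `opm_leadfield`
#' @return numeric vector (one value per channel, T^2 per unit moment^2)
#' @export
gram_diagonal <- function(lf) {
  M <- if (inherits(lf, "opm_leadfield")) lf$matrix else lf
  if (is.null(dim(M)) || ncol(M) == 0) stopf("empty leadfield")
  n_sources <- ceiling(ncol(M) / 3)
  rowSums(M^2) / n_sources
}

#' Ratio of mean Gram-diagonal values, radial over tangential channels
#'
#' @param g Gram diagonal (vector, one value per channel)
#' @param array the `opm_array` the leadfield was computed for
#' @export
radial_tangential_ratio <- function(g, array) {
  cls <- array$channels$axis_class
  rad <- cls == "radial"
  if (all(rad) || !any(rad)) {
    stopf("array must contain both radial and tangential channels")
  }
  mean(g[rad]) / mean(g[!rad])
}

#' Radial/tangential sensitivity ratio as a function of source depth
#'
#' Sorts sources by distance to the nearest channel, forms consecutive bins
#' of `bin_size` sources and reports the radial/tangential Gram ratio per
#' bin together with the bin's mean source-to-nearest-channel distance.
#'
#' @param array multi-axis `opm_array`
#' @param grid source positions (n x 3) or `opm_source_grid`
#' @param bin_size sources per bin
#' @return data frame with columns `distance` (m) and `ratio`
#' @export
distance_resolved_ratio <- function(array, grid, bin_size = 1000) {
  pos <- if (inherits(grid, "opm_source_grid")) grid$positions else rbind(grid)
  if (bin_size > nrow(pos)) stopf("bin_size exceeds number of sources")
  cls <- array$channels$axis_class
  if (all(cls == "radial")) stopf("monoaxial array has no tangential channels")
  sp <- sensor_positions(array)
  d <- apply(pos, 1, function(p) {
    sqrt(min(colSums((t(sp) - p)^2)))
  })
  ord <- order(d)
  n <- nrow(pos)
  starts <- seq(1, n, by = bin_size)
  res <- lapply(starts, function(s) {
    idx <- ord[s:min(s + bin_size - 1, n)]
    lf <- grid_leadfield(array, pos[idx, , drop = FALSE])
    data.frame(distance = mean(d[idx]),
               ratio = radial_tangential_ratio(gram_diagonal(lf), array))
  })
  do.call(rbind, res)
}

#' Local source frame with the silent direction as z'
#'
#' Right-singular vectors of the 3-column local leadfield: z' is the
#' direction of weakest external field (the most radial direction in a
#' spherical conductor), sign-aligned with the outward radial direction;
#' x' and y' span the tangential plane, ordered by decreasing singular
#' value, with handedness enforced.
#'
#' @param array an `opm_array`
#' @param source_pos length-3 position (m)
#' @return list with unit vectors `x`, `y`, `z` and singular values `d`
#' @export
silent_frame <- function(array, source_pos) {
  L <- dipole_leadfield(array, source_pos)
  s <- svd(L)
  if (max(s$d) <= 0) stopf("degenerate leadfield")
  xp <- s$v[, 1]; yp <- s$v[, 2]; zp <- s$v[, 3]
  outward <- as.numeric(source_pos) - array$head$center
  if (sum(zp * outward) < 0) zp <- -zp
  # right-handed: x' x y' = z'
  cr <- c(xp[2] * yp[3] - xp[3] * yp[2],
          xp[3] * yp[1] - xp[1] * yp[3],
          xp[1] * yp[2] - xp[2] * yp[1])
  if (sum(cr * zp) < 0) yp <- -yp
  list(x = xp, y = yp, z = zp, d = s$d)
}
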