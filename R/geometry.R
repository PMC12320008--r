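# Head/brain geometry and construction of the three 192-channel OPM arrays.

#' Ellipsoid region
#'
#' Axis-aligned ellipsoid given by its center and full cardinal axis lengths
#' (x: left-right, y: posterior-anterior, z: inferior-superior), in meters.
#'
#' @param full_axes numeric length-3, full axis lengths in m
#' @param center numeric length-3 center, in m
#' @return an object of class `ellipsoid` with fields `center`, `full_axes`
#'   and `semi_axes`
#' @export
ellipsoid <- function(full_axes, center = c(0, 0, 0)) {
  full_axes <- as.numeric(full_axes)
  center <- as.numeric(center)
  if (length(full_axes) != 3 || any(!is.finite(full_axes)) ||
      any(full_axes <= 0)) {
    stopf("`full_axes` must be 3 positive lengths (m)")
  }
  structure(
    list(center = center, full_axes = full_axes, semi_axes = full_axes / 2),
    class = "ellipsoid"
  )
}

#' Default head surface: ellipsoid with 15/18/16 cm cardinal axes
#' @export
head_ellipsoid <- function() ellipsoid(c(0.15, 0.18, 0.16))

#' Default brain compartment: ellipsoid with 12.9/15.4/13.7 cm cardinal axes
#' @export
brain_ellipsoid <- function() ellipsoid(c(0.129, 0.154, 0.137))

#' Implicit ellipsoid function ((x-c)/a)^2 + ... - 1, vectorized over rows
#' @noRd
ellipsoid_value <- function(ell, pos) {
  pos <- rbind(pos)
  q <- sweep(sweep(pos, 2, ell$center, "-"), 2, ell$semi_axes, "/")
  rowSums(q^2) - 1
}

#' Test whether points are strictly inside an ellipsoid
#' @param ell an [ellipsoid()]
#' @param pos n x 3 matrix of positions (m)
#' @export
inside_ellipsoid <- function(ell, pos) ellipsoid_value(ell, pos) < 0

#' Quasi-uniform sensor locations on the upper half of an ellipsoid
#'
#' Places `n` points on the z > 0 half of the ellipsoid surface using a
#' Fibonacci (golden-angle) lattice on the upper unit hemisphere, mapped to
#' the ellipsoid by anisotropic scaling with the semi-axes. The lattice is
#' offset by half a step in z so no point sits exactly at the pole, and the
#' construction is deterministic.
#'
#' @param n number of locations (>= 1)
#' @param head an [ellipsoid()] describing the head surface
#' @return n x 3 matrix of surface positions (m)
#' @export
distribute_locations <- function(n, head = head_ellipsoid()) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stopf("`n` must be a positive integer")
  }
  n <- as.integer(n)
  i <- seq_len(n) - 1L
  z <- 1 - (i + 0.5) / n                 # in (0, 1): upper hemisphere only
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(phi), s * sin(phi), z)
  sweep(sweep(u, 2, head$semi_axes, "*"), 2, head$center, "+")
}

#' Local surface frame (radial, azimuthal, polar) at a point on an ellipsoid
#'
#' The radial direction is the outward surface normal (normalized gradient
#' of the implicit ellipsoid function); azimuthal is `normalize(z x radial)`
#' (pointing "around" the vertical axis); polar is `radial x azimuthal`.
#' At the pole, where the azimuth is undefined, the azimuthal vector falls
#' back to the x-axis direction.
#'
#' @param head an [ellipsoid()]
#' @param p position on the surface (length-3, m)
#' @return list with unit vectors `radial`, `azimuthal`, `polar`
#' @export
surface_frame <- function(head, p) {
  rel <- (as.numeric(p) - head$center) / head$semi_axes^2
  radial <- rel / sqrt(sum(rel^2))
  az <- c(-radial[2], radial[1], 0)      # z-hat cross radial
  nrm <- sqrt(sum(az^2))
  if (nrm < 1e-12) {
    az <- c(1, 0, 0)                     # pole: documented tie-break
  } else {
    az <- az / nrm
  }
  pol <- c(radial[2] * az[3] - radial[3] * az[2],
           radial[3] * az[1] - radial[1] * az[3],
           radial[1] * az[2] - radial[2] * az[1])
  list(radial = radial, azimuthal = az, polar = pol)
}

#' Build a 192-channel OPM sensor array
#'
#' Constructs one of the three array designs sharing 192 channels:
#' \describe{
#'   \item{monoaxial}{192 locations, one radial channel each}
#'   \item{biaxial}{96 locations, radial plus one tangential channel whose
#'     axis alternates between azimuthal and polar across locations}
#'   \item{triaxial}{64 locations, radial + azimuthal + polar channels}
#' }
#' Locations follow [distribute_locations()] applied at the design's own
#' location count (not subsampled from a denser set).
#'
#' @param kind one of "monoaxial", "biaxial", "triaxial"
#' @param head head surface [ellipsoid()]
#' @return an object of class `opm_array`: list with `kind`, `head`,
#'   `n_locations` and a `channels` data frame (name, position, orientation,
#'   axis_class, location_id)
#' @export
build_array <- function(kind = c("monoaxial", "biaxial", "triaxial"),
                        head = head_ellipsoid()) {
  kind <- match.arg(kind)
  n_loc <- switch(kind, monoaxial = 192L, biaxial = 96L, triaxial = 64L)
  pos <- distribute_locations(n_loc, head)
  rows <- vector("list", n_loc)
  for (i in seq_len(n_loc)) {
    fr <- surface_frame(head, pos[i, ])
    axes <- switch(kind,
      monoaxial = list(radial = fr$radial),
      biaxial = if (i %% 2 == 1) {
        list(radial = fr$radial, azimuthal = fr$azimuthal)
      } else {
        list(radial = fr$radial, polar = fr$polar)
      },
      triaxial = list(radial = fr$radial, azimuthal = fr$azimuthal,
                      polar = fr$polar)
    )
    rows[[i]] <- do.call(rbind, lapply(names(axes), function(ax) {
      o <- axes[[ax]]
      data.frame(
        channel_name = sprintf("L%03d_%s", i, substr(ax, 1, 3)),
        x = pos[i, 1], y = pos[i, 2], z = pos[i, 3],
        ox = o[1], oy = o[2], oz = o[3],
        axis_class = ax, location_id = i,
        stringsAsFactors = FALSE
      )
    }))
  }
  channels <- do.call(rbind, rows)
  rownames(channels) <- NULL
  structure(
    list(kind = kind, head = head, n_locations = n_loc, channels = channels),
    class = "opm_array"
  )
}

#' Channel positions of an array as an n x 3 matrix (m)
#' @param array an `opm_array`
#' @export
sensor_positions <- function(array) {
  as.matrix(array$channels[, c("x", "y", "z")])
}

#' Channel sensing orientations of an array as an n x 3 matrix (unit vectors)
#' @param array an `opm_array`
#' @export
sensor_orientations <- function(array) {
  as.matrix(array$channels[, c("ox", "oy", "oz")])
}

#' @export
print.opm_array <- function(x, ...) {
  cat(sprintf("<opm_array> %s: %d channels at %d locations\n",
              x$kind, nrow(x$channels), x$n_locations))
  cat(sprintf("  axis classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$channels$axis_class)),
                            table(x$channels$axis_class)), collapse = ", ")))
  invisible(x)
}

#' Write an array to TSV plus a JSON sidecar with kind and head geometry
#'
#' @param array an `opm_array`
#' @param path TSV file path; the sidecar is written to `<path>.json`
#' @export
write_array <- function(array, path) {
  utils::write.table(array$channels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(kind = array$kind,
               head_center = array$head$center,
               head_full_axes = array$head$full_axes,
               n_locations = array$n_locations)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an array written by [write_array()]
#' @param path TSV file path (expects `<path>.json` sidecar)
#' @export
read_array <- function(path) {
  channels <- utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(kind = side$kind,
         head = ellipsoid(side$head_full_axes, side$head_center),
         n_locations = as.integer(side$n_locations),
         channels = channels),
    class = "opm_array"
  )
}
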