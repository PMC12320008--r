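# Rigid-body head/sensor motion: synthetic traces, recovery from head
# localization coils, and projection of a static ambient field onto the
# moving array.

#' Motion trace container
#'
#' A sequence of rigid-body transforms p -> R p + t sampled at a fixed
#' rate (default 10 Hz).
#'
#' @param rotations 3 x 3 x n array of rotation matrices
#' @param translations n x 3 matrix (m)
#' @param rate sampling rate (Hz)
#' @return object of class `opm_motion`
#' @export
motion_trace <- function(rotations, translations, rate = 10) {
  n <- dim(rotations)[3]
  translations <- rbind(translations)
  stopifnot(nrow(translations) == n)
  for (k in c(1L, n)) {
    R <- rotations[, , k]
    if (max(abs(crossprod(R) - diag(3))) > 1e-10 || abs(det(R) - 1) > 1e-10) {
      stopf("rotations must be proper orthogonal matrices")
    }
  }
  structure(list(rotations = rotations, translations = translations,
                 rate = rate, n_samples = n),
            class = "opm_motion")
}

#' @export
print.opm_motion <- function(x, ...) {
  disp <- sqrt(rowSums(x$translations^2))
  cat(sprintf("<opm_motion> %d samples at %g Hz; peak displacement %.2f mm\n",
              x$n_samples, x$rate, 1000 * max(disp)))
  invisible(x)
}

# Smoothed, zero-at-start random process with exact requested SD.
#' @noRd
smooth_walk <- function(n, rate, sd_target, smoothness) {
  w <- cumsum(stats::rnorm(n))
  # moving-average low-pass with window ~ smoothness seconds
  win <- max(1L, as.integer(round(smoothness * rate)))
  kernel <- rep(1 / win, win)
  sm <- stats::filter(w, kernel, sides = 2)
  sm[is.na(sm)] <- w[is.na(sm)]
  sm <- as.numeric(sm) - sm[1]
  s <- stats::sd(sm)
  if (s == 0 || sd_target == 0) return(rep(0, n))
  sm * (sd_target / s)
}

rot_xyz <- function(a, b, g) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Synthesize a rigid-body head-motion trace
#'
#' Translations and per-axis rotation angles are independent smoothed
#' Gaussian random walks, zero at t = 0 and rescaled so each component's
#' realized SD equals the request. Rotations are composed about the head
#' origin as Rz Ry Rx.
#'
#' @param n_samples number of samples (default 6000, ~10 min at 10 Hz)
#' @param rate sampling rate (Hz)
#' @param translation_sd per-axis displacement SD (m); default 5 mm
#' @param rotation_sd per-axis rotation-angle SD (degrees); default 1,
#'   which places the per-channel ambient signal SD of a head-mounted
#'   array in a calibrated 50 nT residual field near 0.7 nT
#' @param smoothness smoothing time constant (s); default 2
#' @param seed integer seed
#' @return an `opm_motion`
#' @export
synth_motion <- function(n_samples = 6000, rate = 10,
                         translation_sd = 5e-3, rotation_sd = 1,
                         smoothness = 2, seed = 1) {
  stopifnot(translation_sd >= 0, rotation_sd >= 0)
  local_seed(seed, {
    tr <- sapply(1:3, function(k) {
      smooth_walk(n_samples, rate, translation_sd, smoothness)
    })
    ang <- sapply(1:3, function(k) {
      smooth_walk(n_samples, rate, rotation_sd * pi / 180, smoothness)
    })
    R <- array(0, dim = c(3, 3, n_samples))
    for (i in seq_len(n_samples)) {
      R[, , i] <- rot_xyz(ang[i, 1], ang[i, 2], ang[i, 3])
    }
    motion_trace(R, tr, rate)
  })
}

#' Recover a rigid motion trace from head-localization coil positions
#'
#' Each sample's rigid transform maps the frame-0 coil triangle onto the
#' frame-t triangle (orthogonal Procrustes / Kabsch, no scaling). The
#' reported translation is the displacement of the circumcenter of the
#' coil triangle.
#'
#' @param coils 3 x 3 x n array: per sample, rows = the three coils
#'   (e.g. nasion, left ear, right ear), columns = x, y, z (m)
#' @param rate sampling rate (Hz)
#' @return an `opm_motion`; the transform maps rest positions p to
#'   `R (p - c0) + c0 + t` with `c0` the frame-0 circumcenter (stored in
#'   attribute `origin`)
#' @export
motion_from_coils <- function(coils, rate = 10) {
  n <- dim(coils)[3]
  ref <- coils[, , 1]
  c0 <- triangle_circumcenter(ref)
  R <- array(0, dim = c(3, 3, n))
  tr <- matrix(0, n, 3)
  P0 <- sweep(ref, 2, colMeans(ref))
  for (i in seq_len(n)) {
    Q <- coils[, , i]
    Pq <- sweep(Q, 2, colMeans(Q))
    H <- crossprod(P0, Pq)
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    Ri <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    R[, , i] <- Ri
    ci <- triangle_circumcenter(Q)
    tr[i, ] <- ci - c0
  }
  out <- motion_trace(R, tr, rate)
  attr(out, "origin") <- c0
  out
}

#' @noRd
triangle_circumcenter <- function(tri) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  ab <- b - a; ac <- c - a
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  n2 <- sum(n^2)
  if (n2 < 1e-18) stopf("collinear coils: circumcenter undefined")
  # circumcenter = a + (|ac|^2 (n x ab) + |ab|^2 (ac x n)) / (2 |n|^2)
  cr1 <- c(n[2] * ab[3] - n[3] * ab[2], n[3] * ab[1] - n[1] * ab[3],
           n[1] * ab[2] - n[2] * ab[1])
  cr2 <- c(ac[2] * n[3] - ac[3] * n[2], ac[3] * n[1] - ac[1] * n[3],
           ac[1] * n[2] - ac[2] * n[1])
  a + (sum(ac^2) * cr1 + sum(ab^2) * cr2) / (2 * n2)
}

#' Apply a motion sample to positions/orientations
#' @noRd
apply_motion <- function(motion, k, pos, ori, origin = c(0, 0, 0)) {
  R <- motion$rotations[, , k]
  t <- motion$translations[k, ]
  list(pos = sweep(sweep(pos, 2, origin) %*% t(R), 2, origin + t, "+"),
       ori = ori %*% t(R))
}

#' Ambient signal picked up by a moving sensor array
#'
#' For each time sample, the channels are rigidly moved (positions rotated
#' about `origin` and translated; orientations rotated) and the static
#' ambient field is evaluated at the moved positions via the field map's
#' B-spline interpolator; the channel signal is the projection of the local
#' field on the moved orientation.
#'
#' @param array an `opm_array`
#' @param motion an `opm_motion`
#' @param map an `opm_field_map` (the array should stay inside its box)
#' @param origin rotation origin (m); default the head center
#' @return n_channels x n_samples matrix (T)
#' @export
project_ambient <- function(array, motion, map, origin = NULL) {
  origin <- origin %||% array$head$center
  interp <- field_interpolator(map)
  pos <- sensor_positions(array)
  ori <- sensor_orientations(array)
  n <- motion$n_samples
  out <- matrix(0, nrow(pos), n)
  total_clamped <- 0
  for (k in seq_len(n)) {
    mk <- apply_motion(motion, k, pos, ori, origin)
    B <- suppressWarnings(interp(mk$pos))
    total_clamped <- total_clamped + attr(B, "n_clamped")
    out[, k] <- rowSums(B * mk$ori)
  }
  if (total_clamped > 0) {
    warning(sprintf(
      "%d sensor-sample(s) left the field-map box; field clamped",
      total_clamped))
  }
  out
}

#' Write a motion trace as TSV (t plus the 12 affine entries per sample)
#' @param motion an `opm_motion`
#' @param path output file
#' @export
write_motion <- function(motion, path) {
  n <- motion$n_samples
  aff <- t(sapply(seq_len(n), function(i) {
    c(as.numeric(motion$rotations[, , i]), motion$translations[i, ])
  }))
  colnames(aff) <- c(paste0("r", rep(1:3, 3), rep(1:3, each = 3)),
                     "tx", "ty", "tz")
  df <- data.frame(t = (seq_len(n) - 1) / motion$rate, aff)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motion trace written by [write_motion()], or a TSV with columns
#' t plus 9 coil coordinates (c1x..c3z), which is converted via
#' [motion_from_coils()]
#' @param path TSV file
#' @export
read_motion <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  n <- nrow(df)
  rate <- if (n > 1) 1 / (df$t[2] - df$t[1]) else 10
  if (all(c("r11", "tx") %in% names(df))) {
    R <- array(0, dim = c(3, 3, n))
    for (i in seq_len(n)) {
      R[, , i] <- matrix(as.numeric(df[i, paste0("r", rep(1:3, 3),
                                                 rep(1:3, each = 3))]), 3, 3)
    }
    motion_trace(R, as.matrix(df[, c("tx", "ty", "tz")]), rate)
  } else {
    cols <- as.vector(outer(c("x", "y", "z"), 1:3,
                            function(a, b) paste0("c", b, a)))
    coils <- array(0, dim = c(3, 3, n))
    for (i in seq_len(n)) {
      coils[, , i] <- matrix(as.numeric(df[i, cols]), 3, 3, byrow = TRUE)
    }
    motion_from_coils(coils, rate)
  }
}
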