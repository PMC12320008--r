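# Shared fixtures and an independent reference implementation of the
# spherical-conductor dipole field, used as an oracle for the compiled
# forward model. Heavy objects are memoized across test files.

.fixtures <- new.env(parent = emptyenv())

# implicit ellipsoid function, duplicated here so tests do not rely on
# package internals
ell_val <- function(ell, pos) {
  pos <- rbind(pos)
  q <- sweep(sweep(pos, 2, ell$center, "-"), 2, ell$semi_axes, "/")
  rowSums(q^2) - 1
}

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fix_array <- function(kind) {
  fixture(paste0("array_", kind), build_array(kind))
}

fix_signal_grid <- function() {
  fixture("signal_grid", make_source_grid(0.010, z_min = 0.020))
}

# Independent coding of the closed-form current-dipole field outside a
# homogeneous conducting sphere (potential-theory form, written differently
# from the compiled implementation).
ref_dipole_field <- function(r, q, r0) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  rn <- sqrt(sum(r^2))
  F <- a * (rn * a + rn^2 - sum(r0 * r))
  dF <- numeric(3)
  c1 <- a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + sum(a_vec * r) / a
  dF <- c1 * r - c2 * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  (1e-7 / F^2) * (F * qxr0 - sum(qxr0 * r) * dF)
}

ref_leadfield <- function(array, source_pos) {
  pos <- sensor_positions(array)
  ori <- sensor_orientations(array)
  cen <- array$head$center
  L <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (k in 1:3) {
      q <- c(0, 0, 0); q[k] <- 1
      L[i, k] <- sum(ref_dipole_field(pos[i, ] - cen, q,
                                      source_pos - cen) * ori[i, ])
    }
  }
  L
}

# noise-free segment carrying a given topography in its active columns
make_signal_segment <- function(topo, n = 600, start = 1L) {
  data <- matrix(0, length(topo), n)
  active <- (start + seq_len(n) - 1L) %% 2 == 0
  data[, active] <- topo
  structure(list(data = data, start_index = start), class = "opm_segment")
}
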