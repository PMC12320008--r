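# Interference suppression: baseline subtraction, harmonic field correction
# (HFC), SSS-type multipole methods (tSSS, AMM) and dual signal subspace
# projection (DSSP). Each `clean_*` function takes a segment and returns a
# cleaned active-minus-baseline topography, with diagnostics in attributes.

#' Baseline-subtraction topography of a segment
#'
#' Channel-by-channel subtraction of the mean baseline field from the mean
#' active field; identical to [average_topography()].
#' @param seg an `opm_segment`
#' @export
clean_baseline <- function(seg) average_topography(seg)

#' Harmonic field correction basis
#'
#' Pickup, by each channel, of the external-source (regular solid harmonic)
#' field models up to degree `L` about the head center. For `L = 1` the
#' columns are exactly the three Cartesian components of the channel
#' orientations (uniform fields).
#'
#' @param array an `opm_array`
#' @param L maximum degree (1 or 3 in the evaluation, any `L >= 1` works)
#' @return list with `matrix` (n_channels x L(L+2)), `kind`, `L` and the
#'   basis `condition` number
#' @export
hfc_basis <- function(array, L) {
  S <- solid_harmonic_basis(sensor_positions(array),
                            sensor_orientations(array),
                            L, "regular", array$head$center)
  S <- scale_columns(S)
  d <- svd(S, nu = 0, nv = 0)$d
  structure(list(matrix = S, kind = "external", L = L,
                 condition = d[1] / d[length(d)]),
            class = "opm_harmonic_basis")
}

#' @noRd
scale_columns <- function(S) {
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  sweep(S, 2, nrm, "/")
}

#' Orthogonal projector onto the complement of an HFC basis
#'
#' `I - S pinv(S)`: symmetric and idempotent; applied to data it removes
#' the low-order external field components.
#'
#' @param array an `opm_array`
#' @param L maximum harmonic degree
#' @export
hfc_projector <- function(array, L) {
  S <- hfc_basis(array, L)$matrix
  diag(nrow(S)) - S %*% pinv(S)
}

#' Harmonic-field-corrected topography
#'
#' Projects the segment onto the orthogonal complement of the external
#' harmonic basis (spatial regression), then averages active minus
#' baseline. Projection and averaging commute, so the projector is applied
#' to the averaged topography.
#'
#' @param seg an `opm_segment`
#' @param array an `opm_array`
#' @param L harmonic degree (1 or 3)
#' @param projector optional precomputed [hfc_projector()]
#' @export
clean_hfc <- function(seg, array, L = 1, projector = NULL) {
  P <- projector %||% hfc_projector(array, L)
  as.numeric(P %*% average_topography(seg))
}

#' SSS basis pair (internal + external multipole models)
#'
#' Internal field model: irregular solid harmonics to degree `L_in`;
#' external interference model: regular solid harmonics to degree `L_out`;
#' both about the head-ellipsoid center.
#'
#' @param array an `opm_array`
#' @param L_in internal expansion order (default 8)
#' @param L_out external expansion order (1 or 3)
#' @return list with `S_in`, `S_out`, `S` (column-bound), `condition`
#' @export
sss_basis <- function(array, L_in = 8, L_out = 1) {
  pos <- sensor_positions(array); ori <- sensor_orientations(array)
  cen <- array$head$center
  S_in <- scale_columns(solid_harmonic_basis(pos, ori, L_in, "irregular", cen))
  S_out <- scale_columns(solid_harmonic_basis(pos, ori, L_out, "regular", cen))
  S <- cbind(S_in, S_out)
  d <- svd(S, nu = 0, nv = 0)$d
  list(S_in = S_in, S_out = S_out, S = S,
       S_pinv = pinv(S, rtol = 1e-8), S_in_pinv = pinv(S_in, rtol = 1e-8),
       n_in = ncol(S_in), condition = d[1] / d[length(d)])
}

# Shared temporal-projection step: remove from `target` the temporal
# directions that `x_keep` (internal part) shares with `x_leak` (external
# part) at principal-angle correlation above `corr_limit`. A candidate
# course is only treated as interference if the external part carries at
# least `leak_ratio` of the internal part's energy along it: a brain
# signal that merely leaks into the external model fails this test and is
# protected from self-cancellation.
#' @noRd
temporal_intersection_clean <- function(x_keep, x_leak, corr_limit,
                                        target = x_keep, leak_ratio = 0.01) {
  s1 <- svd(x_keep, nu = 0)
  s2 <- svd(x_leak, nu = 0)
  scale_ref <- max(s1$d[1], s2$d[1])
  V1 <- s1$v[, s1$d > s1$d[1] * 1e-8, drop = FALSE]
  V2 <- s2$v[, s2$d > s2$d[1] * 1e-8, drop = FALSE]
  if (ncol(V1) == 0 || ncol(V2) == 0 || s2$d[1] < scale_ref * 1e-12) {
    attr(target, "removed_rank") <- 0L
    return(target)
  }
  cs <- svd(crossprod(V1, V2))
  sel <- which(cs$d > corr_limit)
  if (length(sel) > 0) {
    Tt <- V1 %*% cs$u[, sel, drop = FALSE]   # orthonormal temporal dirs
    e_in <- colSums((x_keep %*% Tt)^2)
    e_out <- colSums((x_leak %*% Tt)^2)
    sel <- sel[e_out > leak_ratio * e_in]
  }
  if (length(sel) == 0) {
    attr(target, "removed_rank") <- 0L
    return(target)
  }
  Tt <- V1 %*% cs$u[, sel, drop = FALSE]
  out <- target - (target %*% Tt) %*% t(Tt)
  attr(out, "removed_rank") <- length(sel)
  out
}

#' Temporal signal space separation (tSSS) cleaned topography
#'
#' Decomposes the segment into internal (irregular multipoles to `L_in`)
#' and external (regular multipoles to `L_out`) components about the head
#' center, keeps the internal reconstruction, removes the temporal
#' subspace it shares with the external reconstruction (principal-angle
#' correlation above `corr_limit`), then averages active minus baseline.
#'
#' @param seg an `opm_segment`
#' @param array an `opm_array`
#' @param L_in internal order (default 8)
#' @param L_out external order (1 or 3)
#' @param corr_limit temporal correlation limit (default 0.98)
#' @param basis optional precomputed [sss_basis()]
#' @return topography vector with attributes `removed_rank` and `condition`
#' @export
clean_tsss <- function(seg, array, L_in = 8, L_out = 1, corr_limit = 0.98,
                       basis = NULL) {
  b <- basis %||% sss_basis(array, L_in, L_out)
  x <- seg$data
  a <- b$S_pinv %*% x
  x_in <- b$S_in %*% a[seq_len(b$n_in), , drop = FALSE]
  x_out <- b$S_out %*% a[-seq_len(b$n_in), , drop = FALSE]
  xc <- temporal_intersection_clean(x_in, x_out, corr_limit)
  out <- average_topography(
    structure(list(data = xc, start_index = seg$start_index),
              class = "opm_segment"))
  attr(out, "removed_rank") <- attr(xc, "removed_rank")
  attr(out, "condition") <- b$condition
  out
}

#' Spatial pseudo-signal subspace for DSSP
#'
#' Leading left-singular vectors of the brain-grid leadfield, keeping the
#' smallest set capturing at least `energy` of the total squared singular
#' values.
#'
#' @param array an `opm_array`
#' @param grid source grid (n x 3 matrix or `opm_source_grid`)
#' @param energy energy fraction (default 0.99)
#' @return n_channels x k orthonormal matrix
#' @export
dssp_subspace <- function(array, grid, energy = 0.99) {
  L <- grid_leadfield(array, grid)$matrix
  s <- svd(L, nv = 0)
  k <- which(cumsum(s$d^2) / sum(s$d^2) >= energy)[1]
  s$u[, seq_len(k), drop = FALSE]
}

#' Dual signal subspace projection (DSSP) cleaned topography
#'
#' Splits the segment into components inside and outside the spatial
#' pseudo-signal subspace, finds the temporal subspace common to the two
#' parts (principal-angle correlation above `t_threshold`) and projects it
#' out of the full data, then averages active minus baseline.
#'
#' @param seg an `opm_segment`
#' @param array an `opm_array`
#' @param subspace precomputed [dssp_subspace()] (or a source grid from
#'   which to build it)
#' @param t_threshold temporal correlation threshold (default 0.95)
#' @return topography vector with attribute `removed_rank`
#' @export
clean_dssp <- function(seg, array, subspace, t_threshold = 0.95) {
  if (!is.matrix(subspace)) subspace <- dssp_subspace(array, subspace)
  x <- seg$data
  x_in <- subspace %*% crossprod(subspace, x)
  x_out <- x - x_in
  xc <- temporal_intersection_clean(x_in, x_out, t_threshold, target = x)
  out <- average_topography(
    structure(list(data = xc, start_index = seg$start_index),
              class = "opm_segment"))
  attr(out, "removed_rank") <- attr(xc, "removed_rank")
  out
}

#' Adaptive multipole modeling (AMM) cleaned topography
#'
#' Models the internal field with irregular multipoles to `L_in`, builds a
#' data-driven external subspace from the leading principal components of
#' the residual (which is orthogonal to the internal model by
#' construction), removes from the internal reconstruction the temporal
#' subspace it shares with the external component, then averages active
#' minus baseline. The spheroidal-basis refinements of the original method
#' are not implemented.
#'
#' @param seg an `opm_segment`
#' @param array an `opm_array`
#' @param L_in internal order (default 8)
#' @param n_ext_max maximum number of adaptive external components
#' @param energy residual-energy fraction for choosing the component count
#' @param corr_limit temporal correlation limit (default 0.98)
#' @param basis optional precomputed [sss_basis()] (only `S_in` is used)
#' @return topography vector with attribute `removed_rank`
#' @export
clean_amm <- function(seg, array, L_in = 8, n_ext_max = 10, energy = 0.99,
                      corr_limit = 0.98, basis = NULL) {
  b <- basis %||% sss_basis(array, L_in, 1)
  x <- seg$data
  coef_in <- b$S_in_pinv %*% x
  x_in <- b$S_in %*% coef_in
  resid <- x - x_in
  s <- svd(resid)
  if (max(s$d) > 0) {
    k <- which(cumsum(s$d^2) / sum(s$d^2) >= energy)[1]
    k <- min(k, n_ext_max)
    E <- s$u[, seq_len(k), drop = FALSE]
    x_ext <- E %*% crossprod(E, resid)
  } else {
    x_ext <- resid
  }
  xc <- temporal_intersection_clean(x_in, x_ext, corr_limit)
  out <- average_topography(
    structure(list(data = xc, start_index = seg$start_index),
              class = "opm_segment"))
  attr(out, "removed_rank") <- attr(xc, "removed_rank")
  out
}
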