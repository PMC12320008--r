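# Real spherical-harmonic field models.
#
# A magnetically quiet region admits a scalar potential; expanding it in
# regular solid harmonics r^l Y_lm (sources outside the region) or irregular
# solid harmonics r^-(l+1) Y_lm (sources inside) gives the field bases used
# by harmonic field correction (HFC), SSS-type methods and multipole
# modeling. Schmidt semi-normalized real harmonics, no Condon-Shortley
# phase; for each degree l the order runs m = 0, then (cos, sin) pairs for
# m = 1..l, giving L(L+2) terms for degrees 1..L.

#' Pickup of solid-harmonic field models by a set of magnetometers
#'
#' Column j holds, for every channel, the projection on the channel
#' orientation of the field \eqn{-\nabla \Phi_j} evaluated at the channel
#' position, where \eqn{\Phi_j} is the j-th real solid harmonic about
#' `origin`. (The overall sign is irrelevant for the subspaces built from
#' the basis.)
#'
#' @param pos n x 3 channel positions (m)
#' @param ori n x 3 unit channel orientations
#' @param L maximum harmonic degree (>= 1)
#' @param kind "regular" (r^l, external-source model) or "irregular"
#'   (r^-(l+1), internal-source model)
#' @param origin expansion origin (length-3, m)
#' @return n x L(L+2) matrix
#' @export
solid_harmonic_basis <- function(pos, ori, L,
                                 kind = c("regular", "irregular"),
                                 origin = c(0, 0, 0)) {
  kind <- match.arg(kind)
  pos <- rbind(pos); ori <- rbind(ori)
  stopifnot(L >= 1, nrow(pos) == nrow(ori))
  rel <- sweep(pos, 2, origin, "-")
  n <- nrow(rel)
  nterm <- L * (L + 2)
  out <- matrix(0, n, nterm)
  for (i in seq_len(n)) {
    g <- solid_harmonic_gradients(rel[i, ], L, kind)  # 3 x nterm
    out[i, ] <- as.numeric(ori[i, ] %*% g)
  }
  colnames(out) <- solid_harmonic_labels(L)
  out
}

solid_harmonic_labels <- function(L) {
  unlist(lapply(seq_len(L), function(l) {
    c(sprintf("l%dm0", l),
      as.vector(rbind(sprintf("l%dm%dc", l, seq_len(l)),
                      sprintf("l%dm%ds", l, seq_len(l)))))
  }))
}

# Gradient of every solid harmonic (degrees 1..L) at a single point.
# Returns a 3 x L(L+2) matrix of d(Phi)/d(x,y,z).
#' @noRd
solid_harmonic_gradients <- function(p, L, kind) {
  x <- p[1]; y <- p[2]; z <- p[3]
  r <- sqrt(x^2 + y^2 + z^2)
  if (r < 1e-12) {
    if (kind == "irregular") stopf("irregular harmonics undefined at origin")
    # regular: only l = 1 gradients are nonzero at the origin
    g <- matrix(0, 3, L * (L + 2))
    g[3, 1] <- 1; g[1, 2] <- 1; g[2, 3] <- 1  # z, x, y potentials
    return(g)
  }
  u <- z / r                       # cos(theta)
  s <- sqrt(max(0, 1 - u^2))       # sin(theta)
  phi <- atan2(y, x)
  # Associated Legendre tables (no Condon-Shortley):
  #   P[l, m]   = P_l^m(u)
  #   Tq[l, m]  = P_l^m(u) / s          (m >= 1; pole-safe by construction)
  #   dP[l, m]  = dP_l^m/dtheta
  P <- matrix(0, L + 1, L + 1)     # index [l+1, m+1]
  Tq <- matrix(0, L + 1, L + 1)
  dP <- matrix(0, L + 1, L + 1)
  P[1, 1] <- 1
  for (m in 0:L) {
    mi <- m + 1
    if (m > 0) {
      dfact <- prod(seq(1, 2 * m - 1, by = 2))
      P[mi, mi] <- dfact * s^m
      Tq[mi, mi] <- dfact * s^(m - 1)
    }
    if (m + 1 <= L) {
      P[mi + 1, mi] <- (2 * m + 1) * u * P[mi, mi]
      if (m > 0) Tq[mi + 1, mi] <- (2 * m + 1) * u * Tq[mi, mi]
    }
    if (m + 2 <= L) {
      for (l in (m + 2):L) {
        li <- l + 1
        P[li, mi] <- ((2 * l - 1) * u * P[li - 1, mi] -
                        (l - 1 + m) * P[li - 2, mi]) / (l - m)
        if (m > 0) {
          Tq[li, mi] <- ((2 * l - 1) * u * Tq[li - 1, mi] -
                           (l - 1 + m) * Tq[li - 2, mi]) / (l - m)
        }
      }
    }
  }
  for (l in 1:L) {
    li <- l + 1
    dP[li, 1] <- -P[li, 2]                          # m = 0
    if (l >= 1) {
      for (m in 1:l) {
        mi <- m + 1
        Tprev <- if (l - 1 >= m) Tq[li - 1, mi] else 0
        dP[li, mi] <- l * u * Tq[li, mi] - (l + m) * Tprev
      }
    }
  }
  # spherical unit vectors
  cp <- cos(phi); sp <- sin(phi)
  rhat <- c(s * cp, s * sp, u)
  that <- c(u * cp, u * sp, -s)
  phat <- c(-sp, cp, 0)
  nterm <- L * (L + 2)
  g <- matrix(0, 3, nterm)
  col <- 1L
  for (l in 1:L) {
    li <- l + 1
    rad <- if (kind == "regular") {
      list(f = r^l, df = l * r^(l - 1), fr = r^(l - 1))
    } else {
      list(f = r^(-(l + 1)), df = -(l + 1) * r^(-(l + 2)), fr = r^(-(l + 2)))
    }
    for (m in 0:l) {
      mi <- m + 1
      norm <- if (m == 0) 1 else {
        sqrt(2 * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
      }
      cm <- cos(m * phi); sm <- sin(m * phi)
      trig <- if (m == 0) list(1) else list(cm, sm)
      dtrig <- if (m == 0) list(0) else list(-m * sm, m * cm)
      for (k in seq_along(trig)) {
        Br <- rad$df * norm * P[li, mi] * trig[[k]]
        Bt <- rad$fr * norm * dP[li, mi] * trig[[k]]
        Bp <- if (m == 0) 0 else rad$fr * norm * Tq[li, mi] * dtrig[[k]]
        g[, col] <- Br * rhat + Bt * that + Bp * phat
        col <- col + 1L
      }
    }
  }
  g
}

#' Values of the real solid harmonic potentials at given positions
#'
#' Companion to [solid_harmonic_basis()]: returns the scalar potentials
#' whose gradients define the basis fields (same term ordering).
#'
#' @param pos n x 3 positions (m)
#' @param L maximum degree
#' @param kind "regular" or "irregular"
#' @param origin expansion origin
#' @return n x L(L+2) matrix of potential values
#' @export
solid_harmonic_potentials <- function(pos, L,
                                      kind = c("regular", "irregular"),
                                      origin = c(0, 0, 0)) {
  kind <- match.arg(kind)
  pos <- rbind(pos)
  rel <- sweep(pos, 2, origin, "-")
  out <- matrix(0, nrow(rel), L * (L + 2))
  for (i in seq_len(nrow(rel))) {
    p <- rel[i, ]
    r <- sqrt(sum(p^2))
    u <- p[3] / r; s <- sqrt(max(0, 1 - u^2)); phi <- atan2(p[2], p[1])
    col <- 1L
    for (l in 1:L) {
      rad <- if (kind == "regular") r^l else r^(-(l + 1))
      for (m in 0:l) {
        Pl <- legendre_plm(l, m, u, s)
        norm <- if (m == 0) 1 else {
          sqrt(2 * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        }
        if (m == 0) {
          out[i, col] <- rad * norm * Pl
          col <- col + 1L
        } else {
          out[i, col] <- rad * norm * Pl * cos(m * phi)
          out[i, col + 1L] <- rad * norm * Pl * sin(m * phi)
          col <- col + 2L
        }
      }
    }
  }
  colnames(out) <- solid_harmonic_labels(L)
  out
}

# P_l^m(u) without Condon-Shortley phase, by upward recursion
#' @noRd
legendre_plm <- function(l, m, u, s) {
  if (m > l) return(0)
  pmm <- if (m == 0) 1 else prod(seq(1, 2 * m - 1, by = 2)) * s^m
  if (l == m) return(pmm)
  pm1 <- (2 * m + 1) * u * pmm
  if (l == m + 1) return(pm1)
  for (ll in (m + 2):l) {
    pnew <- ((2 * ll - 1) * u * pm1 - (ll - 1 + m) * pmm) / (ll - m)
    pmm <- pm1; pm1 <- pnew
  }
  pm1
}

# --- low-degree harmonic polynomial fields in Cartesian closed form ---------
# Used by the synthetic ambient-field generator: fields are gradients of
# real harmonic polynomials of degree 1..3, so they are divergence- and
# curl-free by construction. Returns the field of each basis potential.

#' Fields of the real harmonic polynomial potentials of a given degree
#'
#' @param pos n x 3 positions (m)
#' @param degree 1 (3 uniform fields), 2 (5 constant-gradient fields) or
#'   3 (7 constant-curvature fields)
#' @return list of n x 3 field matrices, one per basis potential
#' @export
harmonic_poly_fields <- function(pos, degree) {
  pos <- rbind(pos)
  x <- pos[, 1]; y <- pos[, 2]; z <- pos[, 3]
  zero <- numeric(length(x)); one <- rep(1, length(x))
  grads <- switch(as.character(degree),
    "1" = list(cbind(one, zero, zero),
               cbind(zero, one, zero),
               cbind(zero, zero, one)),
    "2" = list(cbind(y, x, zero),                    # xy
               cbind(zero, z, y),                    # yz
               cbind(z, zero, x),                    # zx
               cbind(2 * x, -2 * y, zero),           # x^2 - y^2
               cbind(-2 * x, -2 * y, 4 * z)),        # 2z^2 - x^2 - y^2
    "3" = list(cbind(-6 * x * z, -6 * y * z, 6 * z^2 - 3 * x^2 - 3 * y^2),
               cbind(4 * z^2 - 3 * x^2 - y^2, -2 * x * y, 8 * x * z),
               cbind(-2 * x * y, 4 * z^2 - x^2 - 3 * y^2, 8 * y * z),
               cbind(2 * x * z, -2 * y * z, x^2 - y^2),
               cbind(y * z, x * z, x * y),
               cbind(3 * x^2 - 3 * y^2, -6 * x * y, zero),
               cbind(6 * x * y, 3 * x^2 - 3 * y^2, zero)),
    stopf("degree must be 1, 2 or 3")
  )
  grads
}
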