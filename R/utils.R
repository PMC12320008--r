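# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' disturb the global random stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Derive a stream seed from a master seed and small integer indices
#'
#' Deterministic, collision-poor within the index ranges used here, and kept
#' below 2^31 so it is a valid R integer seed.
#' @param master master seed (any integer)
#' @param ... small non-negative integer indices (location, orientation, ...)
#' @return an integer seed
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 99991
  for (i in idx) s <- (s * 131 + as.double(i)) %% 2147483629
  as.integer(s)
}

#' Moore-Penrose pseudoinverse via truncated SVD
#' @noRd
pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > max(s$d) * rtol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Orthonormal basis of a matrix row space (right singular vectors)
#' @noRd
row_space_basis <- function(X, rtol = 1e-8) {
  s <- svd(X, nu = 0)
  keep <- s$d > max(s$d, 0) * rtol
  s$v[, keep, drop = FALSE]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
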