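test_that("field summaries recover analytic uniform and gradient fields", {
  g <- list(x = seq(-0.1, 0.1, 0.05), y = seq(-0.1, 0.1, 0.05),
            z = seq(-0.1, 0.1, 0.05))
  pos <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  u <- field_map(g, matrix(rep(c(50e-9, 0, 0), each = nrow(pos)),
                           ncol = 3))
  su <- summarize_field(u)
  expect_equal(su$mean_abs_field, 50e-9)
  expect_equal(su$mean_grad1, 0)
  expect_equal(su$mean_grad2, 0)

  gr <- field_map(g, cbind(3e-9 * pos[, 3], 0, 0))
  expect_equal(summarize_field(gr)$mean_grad1, 3e-9, tolerance = 1e-10)

  # brute-force recomputation on a 3x3x3 toy map
  g3 <- list(x = c(-1, 0, 1) * 0.1, y = c(-1, 0, 1) * 0.1,
             z = c(-1, 0, 1) * 0.1)
  set.seed(8)
  f3 <- matrix(rnorm(27 * 3, sd = 1e-9), 27, 3)
  m3 <- field_map(g3, f3)
  s3 <- summarize_field(m3)
  A <- array(f3, dim = c(3, 3, 3, 3))
  J <- sapply(1:3, function(comp) {
    c((A[3, 2, 2, comp] - A[1, 2, 2, comp]) / 0.2,
      (A[2, 3, 2, comp] - A[2, 1, 2, comp]) / 0.2,
      (A[2, 2, 3, comp] - A[2, 2, 1, comp]) / 0.2)
  })
  expect_equal(s3$mean_grad1, sqrt(sum(J^2)), tolerance = 1e-12)
  expect_equal(s3$mean_abs_field, mean(sqrt(rowSums(f3^2))))
})

test_that("synthetic maps hit the published summary targets", {
  fm <- fixture("field_map_default", synth_field_map(seed = 1))
  s <- summarize_field(fm)
  expect_equal(s$mean_abs_field, 50.1e-9, tolerance = 0.05)
  expect_equal(s$mean_grad1, 6.7e-9, tolerance = 0.05)
  expect_equal(s$mean_grad2, 35.6e-9, tolerance = 0.05)
  expect_error(synth_field_map(mean_abs_field = 0), "positive")

  # gradient-free targets give a uniform field (each component constant)
  fu <- synth_field_map(50e-9, 0, 0, seed = 2)
  spread <- apply(fu$field, 2, function(col) diff(range(col)))
  expect_lt(max(spread), max(abs(fu$field)) * 1e-9 + 1e-20)
})

test_that("uniform variant takes componentwise medians", {
  fm <- fixture("field_map_default", synth_field_map(seed = 1))
  uv <- uniform_variant(fm)
  expect_equal(unique(uv$field), rbind(apply(fm$field, 2, median)),
               ignore_attr = TRUE)
  expect_equal(summarize_field(uv)$mean_grad1, 0)
  # robust to a single outlier sample
  fm2 <- fm
  fm2$field[5, ] <- 1e-3
  expect_equal(uniform_variant(fm2)$field[1, 1],
               median(fm2$field[, 1]))
  # an already-uniform map is unchanged
  expect_equal(uniform_variant(uv)$field, uv$field)
})

test_that("B-spline interpolation is exact on nodes and linear fields", {
  g <- list(x = seq(-0.2, 0.2, 0.05), y = seq(-0.2, 0.2, 0.05),
            z = seq(-0.2, 0.2, 0.05))
  pos <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  set.seed(10)
  fm <- field_map(g, matrix(rnorm(nrow(pos) * 3, sd = 1e-9), ncol = 3))
  vals <- interpolate_field(fm, pos[c(1, 100, 400), ])
  expect_equal(vals, fm$field[c(1, 100, 400), ], tolerance = 1e-10,
               ignore_attr = TRUE)

  lin <- field_map(g, cbind(1e-9 + 2e-9 * pos[, 1] - 1e-9 * pos[, 3],
                            3e-9 * pos[, 2], 1e-9 * pos[, 1]))
  q <- matrix(runif(60, -0.17, 0.17), 20, 3)
  got <- interpolate_field(lin, q)
  want <- cbind(1e-9 + 2e-9 * q[, 1] - 1e-9 * q[, 3],
                3e-9 * q[, 2], 1e-9 * q[, 1])
  expect_lt(max(abs(got - want)), 1e-10 * max(abs(want)))

  # quadratic field at mid-cells: below 1% of the field scale
  quad <- field_map(g, cbind(pos[, 1]^2 - pos[, 3]^2, pos[, 1] * pos[, 2],
                             2 * pos[, 1] * pos[, 3]) * 1e-7)
  qm <- q + 0.025
  gotq <- interpolate_field(quad, qm)
  wantq <- cbind(qm[, 1]^2 - qm[, 3]^2, qm[, 1] * qm[, 2],
                 2 * qm[, 1] * qm[, 3]) * 1e-7
  expect_lt(max(abs(gotq - wantq)), 0.01 * max(abs(wantq)))

  # out-of-box queries are clamped with a warning
  expect_warning(interpolate_field(lin, rbind(c(1, 0, 0))), "clamp")
})

test_that("synthetic motion respects its amplitude and smoothness contract", {
  m0 <- synth_motion(100, translation_sd = 0, rotation_sd = 0, seed = 1)
  expect_equal(m0$translations, matrix(0, 100, 3))
  for (k in c(1, 50)) expect_equal(m0$rotations[, , k], diag(3))

  m <- synth_motion(2000, translation_sd = 4e-3, rotation_sd = 1.5, seed = 3)
  expect_equal(m$translations[1, ], c(0, 0, 0))
  expect_equal(m$rotations[, , 1], diag(3), tolerance = 1e-12)
  sds <- apply(m$translations, 2, sd)
  expect_true(all(abs(sds - 4e-3) / 4e-3 < 0.2))
  for (k in c(7, 1999)) {
    R <- m$rotations[, , k]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  expect_identical(synth_motion(50, seed = 4)$translations,
                   synth_motion(50, seed = 4)$translations)
})

test_that("rigid motion is recovered from localization coils", {
  coils0 <- rbind(c(0.09, 0, -0.02), c(-0.05, 0.06, -0.03),
                  c(-0.05, -0.07, -0.02))
  n <- 40
  coils <- array(0, dim = c(3, 3, n))
  coils[, , 1] <- coils0
  ang <- 10 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  for (k in 2:n) coils[, , k] <- coils0 %*% t(Rz)
  mt <- motion_from_coils(coils)
  expect_equal(mt$rotations[, , 1], diag(3), tolerance = 1e-12)
  expect_equal(mt$rotations[, , 2], Rz, tolerance = 1e-9)
  ang_rec <- acos((sum(diag(mt$rotations[, , 2])) - 1) / 2)
  expect_equal(ang_rec, ang, tolerance = 1e-9)

  # noisy coils: translation RMSE below 0.2 mm at 0.1 mm coil noise
  set.seed(12)
  tr_true <- cbind(cumsum(rnorm(n, 0, 2e-4)), cumsum(rnorm(n, 0, 2e-4)),
                   cumsum(rnorm(n, 0, 2e-4)))
  tr_true[1, ] <- 0
  for (k in 1:n) {
    coils[, , k] <- sweep(coils0, 2, tr_true[k, ], "+") +
      matrix(rnorm(9, 0, 1e-4), 3, 3)
  }
  mtn <- motion_from_coils(coils)
  resid <- mtn$translations - sweep(tr_true, 2, tr_true[1, ])
  expect_lt(sqrt(mean(resid^2)), 2e-4)
  # collinear coils are rejected
  bad <- array(rep(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), n),
               dim = c(3, 3, n))
  expect_error(motion_from_coils(bad), "collinear")
})

test_that("ambient projection matches closed forms for simple motions", {
  arr <- fix_array("triaxial")
  fm <- fixture("field_map_default", synth_field_map(seed = 1))
  interp <- field_interpolator(fm)
  pos <- sensor_positions(arr); ori <- sensor_orientations(arr)

  ident <- motion_trace(array(diag(3), dim = c(3, 3, 4)), matrix(0, 4, 3))
  sig <- project_ambient(arr, ident, fm)
  expect_equal(sig[, 1], rowSums(interp(pos) * ori), tolerance = 1e-12)
  expect_equal(sig, sig[, c(1, 1, 1, 1)], tolerance = 1e-12,
               ignore_attr = TRUE)

  # uniform field: translation-invariant; rotation matches B . (R o)
  B0 <- c(30e-9, -10e-9, 25e-9)
  gu <- fm$grid
  posg <- as.matrix(expand.grid(x = gu$x, y = gu$y, z = gu$z))
  uni <- field_map(gu, matrix(B0, nrow(posg), 3, byrow = TRUE))
  trans <- motion_trace(array(diag(3), dim = c(3, 3, 3)),
                        rbind(c(0, 0, 0), c(0.01, -0.01, 0.02),
                              c(-0.02, 0, 0.01)))
  sigt <- project_ambient(arr, trans, uni)
  expect_lt(max(abs(sigt - sigt[, 1])), 1e-20)

  ang <- 5 * pi / 180
  Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
              c(0, 0, 1))
  rot <- motion_trace(array(c(diag(3), Rz), dim = c(3, 3, 2)),
                      matrix(0, 2, 3))
  sigr <- project_ambient(arr, rot, uni)
  expect_equal(sigr[, 2], as.numeric((ori %*% t(Rz)) %*% B0),
               tolerance = 1e-9)
  # Cauchy-Schwarz bound in a uniform field
  expect_lt(max(abs(sigr)), sqrt(sum(B0^2)) * (1 + 1e-12))
})

test_that("field maps and motion traces round-trip through TSV", {
  fm <- fixture("field_map_default", synth_field_map(seed = 1))
  p <- tempfile(fileext = ".tsv")
  write_field_map(fm, p)
  back <- read_field_map(p)
  expect_equal(back$grid, fm$grid, tolerance = 1e-12)
  expect_equal(back$field, fm$field, tolerance = 1e-12, ignore_attr = TRUE)

  m <- synth_motion(20, seed = 5)
  pm <- tempfile(fileext = ".tsv")
  write_motion(m, pm)
  mb <- read_motion(pm)
  expect_equal(mb$rotations, m$rotations, tolerance = 1e-10)
  expect_equal(mb$translations, m$translations, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mb$rate, 10, tolerance = 1e-9)
})
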