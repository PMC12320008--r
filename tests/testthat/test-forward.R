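test_that("radial dipoles are externally silent and the field is linear", {
  arr <- fix_array("monoaxial")
  src <- c(0.02, -0.01, 0.045)
  L <- dipole_leadfield(arr, src)
  # a 10 nAm moment along the radius from the sphere center (= origin)
  b_rad <- L %*% (10e-9 * src / sqrt(sum(src^2)))
  expect_lt(max(abs(b_rad)), 1e-25)
  # linearity: doubling the moment doubles every entry
  m <- c(1e-9, -2e-9, 0.5e-9)
  expect_equal(as.numeric(L %*% (2 * m)), 2 * as.numeric(L %*% m),
               tolerance = 1e-14)
  expect_error(dipole_leadfield(arr, arr$head$center), "center")
  expect_error(dipole_leadfield(arr, c(0, 0, 0.2)), "inside")
})

test_that("compiled forward model matches an independent closed-form coding", {
  arr <- fix_array("triaxial")
  set.seed(11)
  for (i in 1:5) {
    src <- c(runif(1, -0.03, 0.03), runif(1, -0.03, 0.03), runif(1, 0.01, 0.05))
    L <- dipole_leadfield(arr, src)
    Lr <- ref_leadfield(arr, src)
    expect_lt(max(abs(L - Lr)) / max(abs(Lr)), 1e-10)
  }
})

test_that("grid leadfields stack per-source blocks in order", {
  arr <- fix_array("biaxial")
  set.seed(2)
  grid <- cbind(runif(10, -0.02, 0.02), runif(10, -0.02, 0.02),
                runif(10, 0.01, 0.05))
  lf <- grid_leadfield(arr, grid)
  expect_equal(ncol(lf$matrix), 30)
  for (s in c(1, 4, 10)) {
    expect_equal(lf$matrix[, (3 * s - 2):(3 * s)],
                 dipole_leadfield(arr, grid[s, ]), tolerance = 1e-14)
  }
  expect_equal(grid_leadfield(arr, grid[3, , drop = FALSE])$matrix,
               dipole_leadfield(arr, grid[3, ]), tolerance = 1e-14)
  # total squared norm accumulates per source
  tot <- sum(lf$matrix^2)
  per <- sum(sapply(1:10, function(s) sum(dipole_leadfield(arr, grid[s, ])^2)))
  expect_equal(tot, per, tolerance = 1e-12)
  expect_error(grid_leadfield(arr, matrix(0, 0, 3)), "empty")
})

test_that("gram diagonal equals diag(L L^T)/N and behaves arithmetically", {
  expect_equal(gram_diagonal(matrix(1, 5, 1)), rep(1, 5))
  expect_equal(gram_diagonal(rbind(c(1, 0, 0, 2, 0, 0)))[1], 2.5)
  arr <- fix_array("triaxial")
  set.seed(3)
  grid <- cbind(runif(10, -0.02, 0.02), runif(10, -0.02, 0.02),
                runif(10, 0.01, 0.05))
  lf <- grid_leadfield(arr, grid)
  expect_equal(gram_diagonal(lf), diag(lf$matrix %*% t(lf$matrix)) / 10,
               tolerance = 1e-12)
  # invariance to source ordering
  lf2 <- grid_leadfield(arr, grid[10:1, ])
  expect_equal(gram_diagonal(lf), gram_diagonal(lf2), tolerance = 1e-12)
})

test_that("radial channels pick up more source power than tangential ones", {
  g <- fixture("gram_small", {
    arr <- fix_array("triaxial")
    grid <- make_source_grid(0.02)     # coarse grid for speed
    gram_diagonal(grid_leadfield(arr, grid))
  })
  arr <- fix_array("triaxial")
  ratio <- radial_tangential_ratio(g, arr)
  expect_gt(ratio, 1)
  # brute-force means
  rad <- arr$channels$axis_class == "radial"
  expect_equal(ratio, mean(g[rad]) / mean(g[!rad]), tolerance = 1e-12)
  expect_equal(radial_tangential_ratio(rep(2, 192), arr), 1)
  expect_error(radial_tangential_ratio(g, fix_array("monoaxial")), "radial")

  bi <- fix_array("biaxial")
  gb <- gram_diagonal(grid_leadfield(bi, make_source_grid(0.02)))
  expect_gt(radial_tangential_ratio(gb, bi), 1)
})

test_that("distance-resolved ratio bins sources by proximity to sensors", {
  arr <- fix_array("triaxial")
  grid <- make_source_grid(0.025)
  n <- nrow(grid$positions)
  bin <- 40
  curve <- distance_resolved_ratio(arr, grid, bin)
  expect_equal(nrow(curve), ceiling(n / bin))
  expect_true(all(diff(curve$distance) > 0))
  # per-bin values match an independent recomputation on the sorted subsets
  sp <- sensor_positions(arr)
  d <- apply(grid$positions, 1, function(p) sqrt(min(colSums((t(sp) - p)^2))))
  ord <- order(d)
  idx1 <- ord[1:bin]
  g1 <- gram_diagonal(grid_leadfield(arr, grid$positions[idx1, ]))
  expect_equal(curve$ratio[1], radial_tangential_ratio(g1, arr),
               tolerance = 1e-10)
  # a single bin covering everything equals the global ratio
  all_curve <- distance_resolved_ratio(arr, grid, n)
  gall <- gram_diagonal(grid_leadfield(arr, grid))
  expect_equal(all_curve$ratio[1], radial_tangential_ratio(gall, arr),
               tolerance = 1e-10)
  expect_error(distance_resolved_ratio(fix_array("monoaxial"), grid, 10))
})

test_that("silent frame isolates the weakest-gain source direction", {
  arr <- fix_array("triaxial")
  # on the +z axis of a spherical head the silent direction is z
  sph_head <- ellipsoid(c(0.16, 0.16, 0.16))
  arr_s <- build_array("triaxial", sph_head)
  fr <- silent_frame(arr_s, c(0, 0, 0.05))
  expect_equal(abs(fr$z), c(0, 0, 1), tolerance = 1e-6)

  set.seed(4)
  dirs <- matrix(rnorm(3 * 500), 500, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in 1:20) {
    src <- c(runif(1, -0.04, 0.04), runif(1, -0.04, 0.04),
             runif(1, 0.01, 0.06))
    fr <- silent_frame(arr, src)
    M <- rbind(fr$x, fr$y, fr$z)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
    L <- dipole_leadfield(arr, src)
    gz <- sqrt(sum((L %*% fr$z)^2))
    gains <- sqrt(colSums((L %*% t(dirs))^2))
    expect_lte(gz, min(gains) * (1 + 1e-9))
    expect_lte(gz, min(sqrt(sum((L %*% fr$x)^2)), sqrt(sum((L %*% fr$y)^2))))
    # sign convention: z' points outward
    expect_gt(sum(fr$z * src), 0)
  }
})
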