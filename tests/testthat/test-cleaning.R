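# A moderately deep test dipole: the multipole-based methods (tSSS, AMM)
# represent such sources accurately, whereas sources millimetres below the
# sensors carry harmonic content above any tractable internal order.
test_source <- function() c(0.01, -0.02, 0.04)

test_that("baseline subtraction equals the averaged topography", {
  arr <- fix_array("triaxial")
  topo <- as.numeric(dipole_leadfield(arr, test_source()) %*%
                       c(0, 1e-8, 0))
  seg <- make_signal_segment(topo)
  expect_identical(clean_baseline(seg), average_topography(seg))
  expect_equal(clean_baseline(seg), topo, tolerance = 1e-12)
})

test_that("HFC removes low-order external fields exactly", {
  arr <- fix_array("triaxial")
  b <- hfc_basis(arr, 1)
  expect_equal(qr(b$matrix)$rank, 3)
  P <- hfc_projector(arr, 1)
  # idempotent and symmetric
  expect_lt(max(abs(P %*% P - P)), 1e-9)
  expect_lt(max(abs(P - t(P))), 1e-12)

  topo <- as.numeric(dipole_leadfield(arr, test_source()) %*% c(0, 1e-8, 0))
  seg_clean <- make_signal_segment(topo)
  # time-varying uniform-field interference on every column
  set.seed(14)
  U <- sensor_orientations(arr) %*% (matrix(rnorm(3 * 600), 3, 600) * 1e-9)
  seg_dirty <- seg_clean
  seg_dirty$data <- seg_dirty$data + U
  ref <- clean_hfc(seg_clean, arr, 1)
  got <- clean_hfc(seg_dirty, arr, 1)
  expect_lt(max(abs(got - ref)), 1e-12 * max(abs(ref)))
  # applying the projector twice changes nothing
  expect_equal(as.numeric(P %*% got), got, tolerance = 1e-12)

  # on white noise the mean variance shrinks by (1 - rank/192)
  rank3 <- qr(hfc_basis(arr, 3)$matrix)$rank
  set.seed(15)
  W <- matrix(rnorm(192 * 2000), 192, 2000)
  P3 <- hfc_projector(arr, 3)
  shrink <- mean(colSums((P3 %*% W)^2)) / mean(colSums(W^2))
  expect_equal(shrink, 1 - rank3 / 192, tolerance = 0.01)
})

test_that("tSSS separates internal signal from external interference", {
  arr <- fix_array("triaxial")
  b <- fixture("sss_triaxial", sss_basis(arr, 8, 1))
  topo <- as.numeric(dipole_leadfield(arr, test_source()) %*% c(0, 1e-8, 0))
  seg <- make_signal_segment(topo)
  # no interference: dipole topography preserved
  out0 <- clean_tsss(seg, arr, basis = b)
  expect_lt(sqrt(sum((out0 - topo)^2) / sum(topo^2)), 0.05)

  # time-varying uniform interference lies exactly in the external model
  set.seed(16)
  U <- sensor_orientations(arr) %*% (matrix(rnorm(3 * 600), 3, 600) * 1e-9)
  segd <- seg
  segd$data <- segd$data + U
  outd <- clean_tsss(segd, arr, basis = b)
  expect_lt(sqrt(sum((outd - topo)^2) / sum(topo^2)), 0.05)

  # spatial reconstruction is idempotent (oblique projector)
  x <- segd$data
  recon <- function(y) {
    a <- b$S_pinv %*% y
    b$S_in %*% a[seq_len(b$n_in), , drop = FALSE]
  }
  x1 <- recon(x)
  expect_lt(max(abs(recon(x1) - x1)), 1e-9 * max(abs(x1)))

  # the SSS matrix is better conditioned for triaxial than monoaxial arrays
  cond_tri <- sss_basis(arr, 8, 3)$condition
  cond_mono <- sss_basis(fix_array("monoaxial"), 8, 3)$condition
  expect_gt(cond_mono, cond_tri)
})

test_that("DSSP removes interference sharing a temporal subspace", {
  arr <- fix_array("triaxial")
  Us <- fixture("dssp_triaxial", dssp_subspace(arr, fix_signal_grid()))
  k <- ncol(Us)
  expect_lt(max(abs(crossprod(Us) - diag(k))), 1e-10)

  topo <- as.numeric(dipole_leadfield(arr, test_source()) %*% c(0, 1e-8, 0))
  seg <- make_signal_segment(topo)
  set.seed(17)
  noise <- matrix(rnorm(192 * 600, 0, 2e-13), 192, 600)
  seg$data <- seg$data + noise
  # no interference: output equals plain baseline subtraction
  expect_equal(clean_dssp(seg, arr, subspace = Us),
               clean_baseline(seg), tolerance = 1e-9, ignore_attr = TRUE)

  # constructed toy: interference with a generic spatial pattern (energy on
  # both sides of the subspace split, as any physical interferer has) and
  # its own temporal course, orthogonal to the signal's on/off course
  iv <- rnorm(192)
  iv <- iv / sqrt(sum(iv^2))
  course <- sin(seq_len(600) / 3)
  # orthogonalize against the signal's on/off course so interference
  # removal cannot take signal energy with it
  sq <- rep(c(0, 1), 300)
  course <- course - sq * sum(course * sq) / sum(sq * sq)
  amp_grid <- c(0, 1e-11, 1e-10, 1e-9)
  removed <- sapply(amp_grid, function(a) {
    segd <- seg
    segd$data <- segd$data + a * iv %*% t(course)
    out <- clean_dssp(segd, arr, subspace = Us)
    attr(out, "removed_rank")
  })
  expect_true(all(diff(removed) >= 0))      # monotone in amplitude
  segd <- seg
  segd$data <- segd$data + 1e-9 * iv %*% t(course)
  out <- clean_dssp(segd, arr, subspace = Us)
  expect_gt(attr(out, "removed_rank"), 0)
  # interference (3 orders of magnitude above the signal) is cleaned down
  # to the interference-free result
  ref <- clean_baseline(seg)
  expect_lt(sqrt(sum((out - ref)^2) / sum(topo^2)), 0.05)
  expect_gt(sqrt(sum((clean_baseline(segd) - ref)^2) / sum(topo^2)), 1)
})

test_that("AMM models internal fields and suppresses uniform interference", {
  arr <- fix_array("triaxial")
  b <- fixture("sss_triaxial", sss_basis(arr, 8, 1))
  # deep source: the orthogonal internal projection AMM uses leaks more for
  # shallow sources than the joint tSSS fit does
  topo <- as.numeric(dipole_leadfield(arr, c(0.005, -0.015, 0.03)) %*%
                       c(0, 1e-8, 0))
  seg <- make_signal_segment(topo)
  set.seed(18)
  # jitter well below the (deep, hence weak) topography
  seg$data <- seg$data + matrix(rnorm(192 * 600, 0, 1e-15), 192, 600)
  out0 <- clean_amm(seg, arr, basis = b)
  expect_lt(sqrt(sum((out0 - topo)^2) / sum(topo^2)), 0.05)

  # internal projector is idempotent
  Pin <- b$S_in %*% b$S_in_pinv
  expect_lt(max(abs(Pin %*% Pin - Pin)), 1e-8)

  # strong time-varying uniform interference, no signal: suppressed by
  # >= 40 dB relative to baseline subtraction alone
  U <- sensor_orientations(arr) %*% (matrix(rnorm(3 * 600), 3, 600) * 1e-9)
  segU <- structure(list(data = U, start_index = 1L), class = "opm_segment")
  base <- clean_baseline(segU)
  outU <- clean_amm(segU, arr, basis = b)
  expect_gt(20 * log10(sqrt(sum(base^2) / sum(outU^2))), 40)
})

test_that("LCMV peaks at the true source and is calibrated under the null", {
  arr <- fix_array("biaxial")
  grid <- make_source_grid(0.02, z_min = 0.02)
  lf <- grid_leadfield(arr, grid)
  src <- grid$positions[17, ]
  fr <- silent_frame(arr, src)
  topo <- as.numeric(dipole_leadfield(arr, src) %*% (1e-8 * fr$x))
  set.seed(19)
  noise <- matrix(rnorm(192 * 600, 0, 2e-13), 192, 600)
  seg <- make_signal_segment(topo)
  seg$data <- seg$data + noise
  res <- lcmv_localize(seg, arr, grid, leadfield = lf)
  expect_equal(as.numeric(res$peaks[1, ]), as.numeric(src))

  # pure white noise: the active/baseline power ratio is near 1; taking
  # the best orientation biases it slightly upward, never below 1
  seg0 <- structure(list(data = matrix(rnorm(192 * 600, 0, 2e-12), 192, 600),
                         start_index = 1L), class = "opm_segment")
  res0 <- lcmv_localize(seg0, arr, grid, leadfield = lf)
  expect_gt(median(log(res0$maps[, 1])), -0.05)
  expect_lt(median(log(res0$maps[, 1])), 0.3)
})
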