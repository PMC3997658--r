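test_that("discard_initial trims the study frame counts coherently", {
  expect_equal(nrow(discard_initial(matrix(0, 250, 5), 4)), 246)
  expect_equal(nrow(discard_initial(matrix(0, 156, 5), 4)), 152)
  x <- matrix(rnorm(50), 10, 5)
  expect_identical(discard_initial(x, 0), x)
  arr <- array(rnorm(2 * 2 * 2 * 10), c(2, 2, 2, 10))
  expect_equal(dim(discard_initial(arr, 4))[4], 6)
  expect_error(discard_initial(matrix(0, 3, 1), 4), "cannot discard")
})

test_that("gaussian smoothing conserves mass, fixes constants, commutes with shifts", {
  vol <- array(0, c(15, 15, 15))
  vol[8, 8, 8] <- 1
  sm <- smooth_gaussian(vol, fwhm = 5, voxel_size = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6) # interior impulse keeps unit mass
  expect_identical(smooth_gaussian(vol, 0, 3), vol)

  const <- array(7, c(15, 15, 15))
  smc <- smooth_gaussian(const, 5, 3)
  expect_equal(smc[5:11, 5:11, 5:11], const[5:11, 5:11, 5:11], tolerance = 1e-9)

  set.seed(1)
  a <- array(0, c(16, 12, 12))
  a[5:8, 5:8, 5:8] <- rnorm(64)
  sa <- smooth_gaussian(a, 5, 3)
  b <- array(0, c(16, 12, 12))
  b[8:11, 5:8, 5:8] <- a[5:8, 5:8, 5:8] # translated by 3 voxels along x
  sb <- smooth_gaussian(b, 5, 3)
  expect_equal(sb[7:13, 3:10, 3:10], sa[4:10, 3:10, 3:10], tolerance = 1e-10)
})

test_that("restricted smoothing weights reproduce full smoothing exactly", {
  g <- small_grid(13)
  set.seed(2)
  arr <- array(rnorm(prod(g$shape) * 4), c(g$shape, 4))
  full <- smooth_gaussian(arr, 5, 3)
  vox <- sphere_voxels(voi("X", peak_mni = c(0, 0, 0)), g)
  W <- rsfcnet:::sphere_smooth_weights(g, vox, 5, 3)
  flat <- matrix(arr, prod(g$shape), 4)
  fullflat <- matrix(full, prod(g$shape), 4)
  expect_equal(as.matrix(W %*% flat), fullflat[vox, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("nuisance design has the documented column structure", {
  set.seed(3)
  motion <- matrix(rnorm(200 * 6, 0, 0.1), 200, 6)
  tissue <- matrix(rnorm(200 * 3), 200, 3)
  X2 <- build_nuisance(motion, tissue, order = 2)
  expect_equal(dim(X2), c(200L, 31L)) # 15 + 15 squares + intercept
  X1 <- build_nuisance(motion, tissue, order = 1)
  expect_equal(dim(X1), c(200L, 16L))
  expect_equal(colnames(X2)[31], "intercept")
  # backward difference, first frame zero, then mean-centered
  d1 <- c(0, diff(motion[, 1]))
  expect_equal(unname(X2[, "dmot1"]), d1 - mean(d1))
  expect_true(all(abs(colMeans(X2[, 1:30])) < 1e-12))
  expect_error(build_nuisance(motion[, 1:5], tissue), "6 columns")
  expect_error(build_nuisance(motion[1:100, ], tissue), "mismatch")
})

test_that("degenerate nuisance columns are pruned down to demeaning", {
  motion <- matrix(0, 50, 6)
  tissue <- matrix(1, 50, 3)
  expect_warning(X <- build_nuisance(motion, tissue, order = 2), "pruned")
  expect_equal(colnames(X), "intercept")
  y <- rnorm(50)
  expect_equal(regress_out(y, X), y - mean(y))
})

test_that("regress_out produces orthogonal residuals and is idempotent", {
  set.seed(4)
  motion <- matrix(rnorm(120 * 6, 0, 0.1), 120, 6)
  tissue <- matrix(rnorm(120 * 3), 120, 3)
  X <- build_nuisance(motion, tissue, 2)
  y <- matrix(rnorm(120 * 7), 120, 7)
  r <- regress_out(y, X)
  expect_lt(max(abs(crossprod(X, r))) / max(abs(y)), 1e-8)
  expect_equal(regress_out(r, X), r, tolerance = 1e-10)
  # a series inside the design space is annihilated
  expect_lt(max(abs(regress_out(X[, 3], X))), 1e-8)
  # recovery: signal orthogonal to design survives contamination by a column
  sig <- regress_out(rnorm(120), X)
  contaminated <- sig + 0.7 * X[, 1]
  expect_gt(cor(regress_out(contaminated, X), sig), 0.99)
})

test_that("band-pass filter has the specified frequency response and zero phase", {
  tt <- seq_len(500) * 2.0
  inb <- sin(2 * pi * 0.04 * tt)
  out <- bandpass(inb, tr = 2.0)
  expect_gt(sd(out) / sd(inb), 0.90)
  # zero phase: cross-correlation peaks at lag 0
  cc <- ccf(out, inb, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)

  stopb <- sin(2 * pi * 0.2 * tt)
  expect_lt(sd(bandpass(stopb, 2.0)) / sd(stopb), 0.10)
  expect_lt(max(abs(bandpass(rep(3, 300), 2.0))), 1e-10)
  expect_error(bandpass(rnorm(100), tr = 2.0, band = c(0.01, 0.3)), "Nyquist")
})

test_that("preprocessing improves recovery of clean signal under artifacts", {
  set.seed(5)
  nt <- 200; tr <- 2
  clean <- bandpass(rnorm(nt), tr)
  motion <- rsfcnet:::motion_trace(nt, 0.06, 0.0012)
  tissue <- matrix(rnorm(nt * 3), nt, 3)
  drift <- 3 * seq_len(nt) / nt
  artifact <- 0.8 * scale(c(0, framewise_displacement(motion)$frame))[, 1]
  dirty <- clean + drift + artifact + 0.3 * tissue[, 1] + rnorm(nt, 0, 0.3)
  proc <- rsfcnet:::preprocess_node_series(cbind(a = dirty, b = rnorm(nt)),
                                           motion, tissue, tr,
                                           preproc_config(n_discard = 0))
  expect_gt(cor(proc[, "a"], clean), cor(dirty, clean))
})
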