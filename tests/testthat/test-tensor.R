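test_that("OLS log-linear fit is exact on noise-free signal", {
  gt <- fixture_gtab()
  # the anisotropic reference case
  D <- c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)
  fit <- fit_tensor_loglinear(single_voxel_dwi(D, gt), gt)
  expect_lt(max(abs(drop(fit$coef) - D)), 1e-9)
  expect_equal(drop(fit$S0), 1000, tolerance = 1e-6)
  # property: exact for arbitrary SPD tensors
  set.seed(42)
  for (i in 1:25) {
    D <- random_spd_tensor()
    fit <- fit_tensor_loglinear(single_voxel_dwi(D, gt), gt)
    expect_lt(max(abs(drop(fit$coef) - D)), 1e-12)
  }
})

test_that("isotropic tensors fit with vanishing off-diagonals", {
  gt <- fixture_gtab()
  fit <- fit_tensor_loglinear(single_voxel_dwi(c(rep(0.8e-3, 3), 0, 0, 0), gt),
                              gt)
  expect_equal(drop(fit$coef)[1:3], rep(0.8e-3, 3), tolerance = 1e-12)
  expect_lt(max(abs(drop(fit$coef)[4:6])), 1e-12)
})

test_that("masked-out and non-positive voxels are flagged, not fatal", {
  gt <- fixture_gtab(n_dir = 12)
  D <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  dwi <- single_voxel_dwi(D, gt)
  arr <- array(0, c(2, 1, 1, length(gt$bvals)))
  arr[1, 1, 1, ] <- dwi$data
  arr[2, 1, 1, ] <- 0                      # dead voxel
  fit <- fit_tensor_loglinear(dwi_volume(arr, 2), gt)
  expect_true(fit$mask[1, 1, 1])
  expect_false(fit$mask[2, 1, 1])
  expect_equal(fit$coef[2, 1, 1, ], rep(0, 6))
})

test_that("eigenvalues match a characteristic-polynomial root oracle", {
  set.seed(7)
  for (i in 1:40) {
    D6 <- random_spd_tensor()
    M <- tensor6_to_mat(D6)
    sc <- mean(diag(M))                    # work at O(1) scale for polyroot
    Ms <- M / sc
    cp <- c(-det(Ms),
            Ms[1, 1] * Ms[2, 2] + Ms[1, 1] * Ms[3, 3] + Ms[2, 2] * Ms[3, 3] -
              Ms[1, 2]^2 - Ms[1, 3]^2 - Ms[2, 3]^2,
            -sum(diag(Ms)), 1)
    oracle <- sort(Re(polyroot(cp)), decreasing = TRUE) * sc
    lam <- dtialps:::sym3_eigenvalues(matrix(D6, 1))
    expect_lt(max(abs(drop(lam) - oracle)), 1e-12)
  }
})

test_that("FA hits its closed-form limits and handles zeros", {
  shape <- c(1, 1, 3)
  cf <- array(0, c(shape, 6))
  cf[1, 1, 1, ] <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)   # isotropic -> FA 0
  cf[1, 1, 2, ] <- c(1e-3, 0, 0, 0, 0, 0)         # stick -> FA 1
  # voxel 3 stays all-zero -> FA defined as 0
  maps <- derive_maps(tensor_field(cf, array(1, shape), array(TRUE, shape), 2))
  expect_equal(maps$FA[1, 1, 1], 0, tolerance = 1e-12)
  # stick limit: eigen-solving a doubly degenerate spectrum is accurate to
  # about sqrt(machine eps), not machine eps
  expect_equal(maps$FA[1, 1, 2], 1, tolerance = 1e-6)
  expect_identical(maps$FA[1, 1, 3], 0)
  expect_equal(maps$MD[1, 1, 1], 1e-3, tolerance = 1e-15)
  # principal direction of the stick tensor is the x axis
  expect_equal(abs(maps$dir1[1, 1, 2, ]), c(1, 0, 0), tolerance = 1e-9)
})

test_that("FA is invariant under rotations of the tensor", {
  set.seed(13)
  fa_of <- function(D6) {
    shape <- c(1, 1, 1)
    maps <- derive_maps(tensor_field(array(D6, c(shape, 6)),
                                     array(1, shape), array(TRUE, shape), 2))
    maps$FA[1, 1, 1]
  }
  for (i in 1:15) {
    D6 <- random_spd_tensor()
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D6r <- mat_to_tensor6(Q %*% tensor6_to_mat(D6) %*% t(Q))
    expect_equal(fa_of(D6), fa_of(D6r), tolerance = 1e-9)
  }
})

test_that("tensor recovery stays accurate at SNR 50", {
  gt <- fixture_gtab()
  spec <- phantom_spec(grid_shape = c(16L, 16L, 9L), g = 0.5,
                       noise_sigma = 1000 / 50, seed = 3L)
  ph <- generate_phantom_dwi(spec, gt)
  fit <- fit_tensor_loglinear(ph$dwi, gt)
  err <- abs(fit$coef - ph$truth$coef)
  md <- mean(spec$d_perp * 2 + spec$d_axial) / 3
  # median per-element error relative to the mean diffusivity scale
  expect_lt(median(err) / md, 0.05)
})

test_that("Gaussian smoothing preserves constants and matches the kernel", {
  m <- constant_maps(1e-3, 2e-3, 3e-3, shape = c(12, 12, 10))
  expect_identical(smooth_maps(m, 0), m)              # fwhm 0 = identity
  sm <- smooth_maps(m, 6)
  expect_equal(max(abs(sm$Dxx - 1e-3)), 0, tolerance = 1e-15)  # DC preserved
  expect_error(smooth_maps(m, -2), "fwhm")

  # impulse response equals the separable normalized sampled Gaussian
  shape <- c(21, 21, 21)
  imp <- constant_maps(0, 0, 0, shape = shape)
  imp$Dxx[11, 11, 11] <- 1
  fwhm <- 6; vs <- 2
  out <- smooth_maps(imp, fwhm)$Dxx
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vs
  rad <- max(1, ceiling(4 * sigma))
  k <- dnorm(seq(-rad, rad), sd = sigma); k <- k / sum(k)
  k_at <- function(d) ifelse(abs(d) <= rad, k[d + rad + 1], 0)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 1),
                   c(0, 0, 2), c(1, 2, 2))) {
    expected <- k_at(off[1]) * k_at(off[2]) * k_at(off[3])
    got <- out[11 + off[1], 11 + off[2], 11 + off[3]]
    expect_equal(got, expected, tolerance = 1e-6 * expected)
  }
})
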