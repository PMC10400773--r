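test_that("sphere masks match brute-force voxel enumeration", {
  shape <- c(20L, 20L, 12L); vs <- 2; aff <- grid_affine(vs)
  # sub-voxel radius centered on a voxel center -> exactly that voxel
  ctr <- (c(10, 10, 6) - 1) * vs
  m1 <- sphere_mask(list(x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3],
                         radius_mm = 0.9), shape, aff)
  expect_equal(sum(m1), 1L)
  expect_true(m1[10, 10, 6])
  # 5 mm radius: count equals exhaustive distance check
  m5 <- sphere_mask(list(x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3],
                         radius_mm = 5), shape, aff)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  d2 <- rowSums((sweep(idx, 2, c(10, 10, 6)) * vs)^2)
  expect_equal(sum(m5), sum(d2 <= 25))
  expect_equal(as.vector(m5), d2 <= 25)
  # off-center ROI too
  off <- c(7.3, 12.1, 9.9)
  mo <- sphere_mask(list(x_mm = off[1], y_mm = off[2], z_mm = off[3],
                         radius_mm = 5), shape, aff)
  d2o <- rowSums(sweep(sweep(idx, 2, c(1, 1, 1)) * vs, 2, off)^2)
  expect_equal(as.vector(mo), d2o <= 25)
  # center far outside the grid errors
  expect_error(sphere_mask(list(x_mm = 140, y_mm = 0, z_mm = 0,
                                radius_mm = 5), shape, aff), "outside")
})

test_that("ROI center averaging is the arithmetic mean with guards", {
  one <- data.frame(label = "projection", hemisphere = "L",
                    x_mm = 3, y_mm = 4, z_mm = 5)
  expect_equal(average_roi_centers(one)[, c("x_mm", "y_mm", "z_mm")],
               one[, c("x_mm", "y_mm", "z_mm")])
  two <- data.frame(label = "projection", hemisphere = "L",
                    x_mm = c(0, 2), y_mm = c(0, 4), z_mm = c(0, 6))
  expect_equal(unlist(average_roi_centers(two)[, c("x_mm", "y_mm", "z_mm")]),
               c(x_mm = 1, y_mm = 2, z_mm = 3))
  set.seed(1)
  many <- data.frame(label = "association", hemisphere = "R",
                     x_mm = rnorm(20), y_mm = rnorm(20), z_mm = rnorm(20))
  avg <- average_roi_centers(many)
  # independent summation oracle
  expect_equal(avg$x_mm, sum(many$x_mm) / 20, tolerance = 1e-12)
  expect_equal(avg$z_mm, sum(many$z_mm) / 20, tolerance = 1e-12)
  mixed <- many; mixed$label[3] <- "projection"
  expect_error(average_roi_centers(mixed), "mixed")
  expect_error(average_roi_centers(many[0, ]), "at least one")
})

test_that("ALPS input extraction averages the right maps over the right ROIs", {
  maps <- constant_maps(2e-3, 1.1e-3, 0.9e-3, shape = c(20, 20, 12))
  rois <- roi_table(data.frame(
    label = c("projection", "association"), hemisphere = "L",
    x_mm = c(6, 6), y_mm = c(6, 26), z_mm = 7, radius_mm = 5))
  inp <- extract_alps_inputs(maps, rois, "L")
  # constant fields: placement is irrelevant
  expect_equal(inp$Dxx_proj, 2e-3)
  expect_equal(inp$Dxx_assoc, 2e-3)
  expect_equal(inp$Dyy_proj, 1.1e-3)
  expect_equal(inp$Dzz_assoc, 0.9e-3)
  expect_error(extract_alps_inputs(maps, rois, "R"), "hemisphere R")

  # ROI straddling two half-spaces: voxel-count-weighted average
  maps2 <- constant_maps(1e-3, 1e-3, 1e-3, shape = c(20, 20, 12))
  maps2$Dxx[1:10, , ] <- 4e-3          # left half of the grid differs
  roi <- list(x_mm = 9 * 2 + 1, y_mm = 10, z_mm = 8, radius_mm = 6)
  m <- sphere_mask(roi, dim(maps2$mask), maps2$affine)
  oracle <- sum(maps2$Dxx[m]) / sum(m)
  rois2 <- roi_table(data.frame(
    label = c("projection", "association"), hemisphere = "L",
    x_mm = roi$x_mm, y_mm = roi$y_mm, z_mm = roi$z_mm, radius_mm = 6))
  expect_equal(extract_alps_inputs(maps2, rois2, "L")$Dxx_proj, oracle,
               tolerance = 1e-12)
})

test_that("the ALPS formula and its invariances hold", {
  eq <- list(Dxx_proj = 1e-3, Dxx_assoc = 1e-3,
             Dyy_proj = 1e-3, Dzz_assoc = 1e-3)
  expect_equal(alps_index(eq), 1)
  expect_equal(alps_index(list(Dxx_proj = 2e-3, Dxx_assoc = 2e-3,
                               Dyy_proj = 1e-3, Dzz_assoc = 1e-3)), 2)
  expect_error(alps_index(list(Dxx_proj = -1e-3, Dxx_assoc = 1e-3,
                               Dyy_proj = 1e-3, Dzz_assoc = 1e-3)),
               "positive")
  set.seed(3)
  for (i in 1:20) {
    v <- as.list(setNames(runif(4, 0.3e-3, 2e-3),
                          c("Dxx_proj", "Dxx_assoc", "Dyy_proj",
                            "Dzz_assoc")))
    a <- alps_index(v)
    # scale invariance under k > 0
    k <- runif(1, 0.1, 10)
    expect_equal(alps_index(lapply(v, `*`, k)), a, tolerance = 1e-12)
    # strictly increasing in the numerator terms, decreasing in denominator
    up <- v; up$Dxx_proj <- up$Dxx_proj * 1.01
    expect_gt(alps_index(up), a)
    up <- v; up$Dxx_assoc <- up$Dxx_assoc * 1.01
    expect_gt(alps_index(up), a)
    dn <- v; dn$Dyy_proj <- dn$Dyy_proj * 1.01
    expect_lt(alps_index(dn), a)
    dn <- v; dn$Dzz_assoc <- dn$Dzz_assoc * 1.01
    expect_lt(alps_index(dn), a)
  }
})

test_that("bilateral index is the unweighted hemisphere mean", {
  expect_equal(bilateral_alps(1.3, 1.3), 1.3)
  expect_equal(bilateral_alps(1.0, 2.0), 1.5)
  expect_error(bilateral_alps(1.0, NA), "hemispheres")
  # phantoms are left-right symmetric by construction
  gt <- fixture_gtab()
  ph <- generate_phantom_dwi(phantom_spec(g = 0.25, noise_sigma = 0), gt)
  res <- alps_from_dwi(ph$dwi, gt, ph$rois)
  expect_lt(abs(res$L_ALPS - res$R_ALPS), 1e-6)
  expect_equal(res$Bi_ALPS, res$L_ALPS, tolerance = 1e-6)
})

test_that("roi tables validate their vocabularies", {
  good <- data.frame(label = "projection", hemisphere = "L",
                     x_mm = 1, y_mm = 2, z_mm = 3, radius_mm = 5)
  expect_s3_class(roi_table(good), "roi_table")
  bad <- good; bad$label <- "commissural"
  expect_error(roi_table(bad), "label")
  bad <- good; bad$hemisphere <- "left"
  expect_error(roi_table(bad), "hemisphere")
  bad <- good; bad$radius_mm <- 0
  expect_error(roi_table(bad), "radius")
  expect_error(roi_table(good[, -3]), "missing columns")
})
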