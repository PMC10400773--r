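#' 4-D diffusion-weighted volume
#'
#' @param data 4-D non-negative array, X x Y x Z x N (N = number of gradient
#'   entries).
#' @param voxel_size Isotropic voxel edge in mm.
#' @param affine 4 x 4 invertible voxel-to-world map (mm).
#' @param mask Optional 3-D logical brain mask; default all TRUE.
#' @return A `dwi_volume` list.
#' @export
dwi_volume <- function(data, voxel_size, affine = grid_affine(voxel_size),
                       mask = NULL) {
  stopifnot(length(dim(data)) == 4L)
  if (any(data < 0)) stop("DWI data must be non-negative")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(mask), dim(data)[1:3]))
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 mask = mask), class = "dwi_volume")
}

#' Per-voxel diffusion tensor field
#'
#' Six coefficients per voxel in the order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
#' (mm^2/s), plus the estimated S0 and a validity mask (voxels where the fit
#' succeeded).
#'
#' @param coef 4-D array X x Y x Z x 6.
#' @param S0 3-D array of estimated b = 0 signal.
#' @param mask 3-D logical array of fitted voxels.
#' @param voxel_size,affine Grid geometry.
#' @return A `tensor_field` list.
#' @export
tensor_field <- function(coef, S0, mask, voxel_size,
                         affine = grid_affine(voxel_size)) {
  stopifnot(length(dim(coef)) == 4L, dim(coef)[4] == 6L)
  structure(list(coef = coef, S0 = S0, mask = mask,
                 voxel_size = voxel_size, affine = affine),
            class = "tensor_field")
}

#' Log-linear (OLS) diffusion tensor fit
#'
#' Per voxel, solves `ln S_i = ln S0 - b_i g_i' D g_i` by ordinary least
#' squares with design row
#' `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`.
#' Multiple b = 0 volumes are averaged into a single row before fitting.
#' Voxels outside the mask, or with a non-positive signal in any retained
#' measurement, are left as zeros and excluded from the output mask.
#'
#' @param dwi A [dwi_volume()].
#' @param gtab A [gradient_table()] matching the 4th dimension of `dwi`.
#' @return A [tensor_field()].
#' @export
fit_tensor_loglinear <- function(dwi, gtab) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(gtab, "gradient_table"))
  shape <- dim(dwi$data)[1:3]
  N <- dim(dwi$data)[4]
  if (N != length(gtab$bvals))
    stop("DWI has ", N, " volumes but gradient table has ",
         length(gtab$bvals), " entries")
  sig <- matrix(dwi$data, nrow = prod(shape), ncol = N)   # voxels x N
  b0 <- gtab$bvals == 0
  if (sum(b0) > 1) {                 # average repeated b0 measurements
    s0mean <- rowMeans(sig[, b0, drop = FALSE])
    sig <- cbind(s0mean, sig[, !b0, drop = FALSE])
    gt2 <- list(bvals = c(0, gtab$bvals[!b0]),
                bvecs = cbind(0, gtab$bvecs[, !b0, drop = FALSE]))
    class(gt2) <- "gradient_table"
  } else gt2 <- gtab
  X <- tensor_design(gt2)
  if (nrow(X) < 7L) stop("fewer than 7 usable measurements per voxel")
  qrX <- qr(X)
  if (qrX$rank < 7L) stop("rank-deficient design: collinear directions")
  fit_mask <- as.vector(dwi$mask) & rowSums(sig <= 0) == 0
  coef <- matrix(0, prod(shape), 7)
  if (any(fit_mask))
    coef[fit_mask, ] <- t(qr.coef(qrX, t(log(sig[fit_mask, , drop = FALSE]))))
  tensor_field(array(coef[, 2:7], dim = c(shape, 6)),
               S0 = array(exp(coef[, 1]) * fit_mask, shape),
               mask = array(fit_mask, shape),
               voxel_size = dwi$voxel_size, affine = dwi$affine)
}

# Analytic eigenvalues of symmetric 3x3 matrices, vectorized over rows of a
# 6-column coefficient matrix (xx, yy, zz, xy, xz, yz). Trigonometric
# closed form with one Newton polish step on the characteristic polynomial
# per root. Returns a matrix with columns sorted l1 >= l2 >= l3.
sym3_eigenvalues <- function(cf) {
  xx <- cf[, 1]; yy <- cf[, 2]; zz <- cf[, 3]
  xy <- cf[, 4]; xz <- cf[, 5]; yz <- cf[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < .Machine$double.xmin^0.25
  ps <- ifelse(iso, 1, p)
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; bxz <- xz / ps; byz <- yz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  lam <- cbind(l1, l2, l3)
  lam[iso, ] <- q[iso]
  # Newton polish: p(l) = det(D - l I); one step per root
  c2 <- -(xx + yy + zz)
  c1 <- xx * yy + xx * zz + yy * zz - xy^2 - xz^2 - yz^2
  c0 <- -(xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) +
            xz * (xy * yz - yy * xz))
  for (k in 1:3) {
    l <- lam[, k]
    f <- ((l + c2) * l + c1) * l + c0
    fp <- (3 * l + 2 * c2) * l + c1
    step <- ifelse(abs(fp) > 0, f / fp, 0)
    ok <- abs(step) < ifelse(iso, 1, p)    # guard spurious large steps
    lam[, k] <- l - ifelse(ok, step, 0)
  }
  cbind(pmax(lam[, 1], lam[, 2], lam[, 3]),
        lam[, 1] + lam[, 2] + lam[, 3] -
          pmax(lam[, 1], lam[, 2], lam[, 3]) -
          pmin(lam[, 1], lam[, 2], lam[, 3]),
        pmin(lam[, 1], lam[, 2], lam[, 3]))
}

# Principal eigenvector (of the largest eigenvalue) per row, via the
# column-space of (D - l2 I)(D - l3 I); the column of largest norm is a
# robust representative. Rows with a degenerate leading pair get c(0,0,1)
# by convention (direction is undefined there).
sym3_principal_dir <- function(cf, lam) {
  xx <- cf[, 1]; yy <- cf[, 2]; zz <- cf[, 3]
  xy <- cf[, 4]; xz <- cf[, 5]; yz <- cf[, 6]
  l2 <- lam[, 2]; l3 <- lam[, 3]
  # M = (D - l2 I) %*% (D - l3 I), written out componentwise
  a11 <- xx - l2; a22 <- yy - l2; a33 <- zz - l2
  b11 <- xx - l3; b22 <- yy - l3; b33 <- zz - l3
  m11 <- a11 * b11 + xy * xy + xz * xz
  m21 <- xy * b11 + a22 * xy + yz * xz
  m31 <- xz * b11 + yz * xy + a33 * xz
  m12 <- a11 * xy + xy * b22 + xz * yz
  m22 <- xy * xy + a22 * b22 + yz * yz
  m32 <- xz * xy + yz * b22 + a33 * yz
  m13 <- a11 * xz + xy * yz + xz * b33
  m23 <- xy * xz + a22 * yz + yz * b33
  m33 <- xz * xz + yz * yz + a33 * b33
  n1 <- m11^2 + m21^2 + m31^2
  n2 <- m12^2 + m22^2 + m32^2
  n3 <- m13^2 + m23^2 + m33^2
  pick <- max.col(cbind(n1, n2, n3), ties.method = "first")
  v <- cbind(ifelse(pick == 1, m11, ifelse(pick == 2, m12, m13)),
             ifelse(pick == 1, m21, ifelse(pick == 2, m22, m23)),
             ifelse(pick == 1, m31, ifelse(pick == 2, m32, m33)))
  nrm <- sqrt(rowSums(v^2))
  deg <- nrm < .Machine$double.eps * 1e3
  v <- v / ifelse(deg, 1, nrm)
  v[deg, ] <- rep(c(0, 0, 1), each = sum(deg))
  v
}

#' Derive scalar maps from a tensor field
#'
#' Eigen-decomposes every voxel's tensor and returns the maps the ALPS
#' analysis consumes: the diagonal diffusivities Dxx/Dyy/Dzz, fractional
#' anisotropy `FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||`, mean
#' diffusivity, sorted eigenvalues and the principal direction. Negative
#' eigenvalues (a noise artifact) are clamped to zero for FA/MD only; the
#' raw tensor diagonals are passed through unclamped. An all-zero tensor
#' yields FA = 0.
#'
#' @param field A [tensor_field()].
#' @return A `tensor_maps` list of 3-D arrays (`Dxx`, `Dyy`, `Dzz`, `FA`,
#'   `MD`, `L1`, `L2`, `L3`, and `dir1`, a 4-D X x Y x Z x 3 array), plus
#'   grid geometry.
#' @export
derive_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  shape <- dim(field$coef)[1:3]
  cf <- matrix(field$coef, ncol = 6)
  lam <- sym3_eigenvalues(cf)
  dir1 <- sym3_principal_dir(cf, lam)
  lamc <- pmax(lam, 0)               # clamp for FA/MD only
  md <- rowMeans(lamc)
  num <- sqrt(rowSums((lamc - md)^2))
  den <- sqrt(rowSums(lamc^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  structure(list(
    Dxx = array(cf[, 1], shape), Dyy = array(cf[, 2], shape),
    Dzz = array(cf[, 3], shape),
    FA = array(fa, shape), MD = array(md, shape),
    L1 = array(lamc[, 1], shape), L2 = array(lamc[, 2], shape),
    L3 = array(lamc[, 3], shape),
    dir1 = array(dir1, c(shape, 3)),
    mask = field$mask, voxel_size = field$voxel_size, affine = field$affine
  ), class = "tensor_maps")
}

# 1-D truncated Gaussian kernel as a banded convolution matrix with zero
# padding; kernel normalized to unit sum (edge renormalization is handled
# by the mask-normalized convolution in smooth_maps).
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  rad <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-rad, rad), sd = sigma_vox)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (o in seq(-rad, rad)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[o + rad + 1]
  }
  K
}

conv_axis <- function(vol, K, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- K %*% matrix(v, nrow = dv[1])
  v <- array(v, dv)
  aperm(v, order(perm))
}

#' Gaussian smoothing of scalar maps
#'
#' Convolves each scalar map with an isotropic Gaussian of the given FWHM
#' (`sigma = FWHM / 2.3548` converted to voxels), using mask-normalized
#' convolution: values outside the mask carry zero weight, and the result is
#' renormalized by the smoothed mask, so a constant field stays constant
#' inside the mask. `fwhm_mm = 0` is the identity.
#'
#' @param maps A `tensor_maps` object from [derive_maps()].
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @param which Character vector of map names to smooth.
#' @return A `tensor_maps` object with the selected maps smoothed.
#' @export
smooth_maps <- function(maps, fwhm_mm,
                        which = c("Dxx", "Dyy", "Dzz", "FA", "MD")) {
  stopifnot(inherits(maps, "tensor_maps"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(maps)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / maps$voxel_size
  shape <- dim(maps$mask)
  Ks <- lapply(shape, gauss_conv_matrix, sigma_vox = sigma_vox)
  sm <- function(vol) {
    for (ax in 1:3) vol <- conv_axis(vol, Ks[[ax]], ax)
    vol
  }
  w <- sm(array(as.numeric(maps$mask), shape))
  for (nm in which) {
    v <- sm(maps[[nm]] * maps$mask)
    out <- array(0, shape)
    inside <- maps$mask & w > 0
    out[inside] <- v[inside] / w[inside]
    maps[[nm]] <- out
  }
  maps
}
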