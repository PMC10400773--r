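# Shared fixtures, all generated in code.

fixture_gtab <- function(n_dir = 32, b = 1000) default_gradient_table(n_dir, b)

# Single-voxel DWI volume with a prescribed tensor (6 coefficients:
# xx, yy, zz, xy, xz, yz) -- the smallest possible fit problem.
single_voxel_dwi <- function(D6, gtab, S0 = 1000) {
  X <- dtialps:::tensor_design(gtab)
  sig <- S0 * exp(drop(X[, -1, drop = FALSE] %*% D6))
  dwi_volume(array(sig, c(1, 1, 1, length(sig))), voxel_size = 2)
}

# Random symmetric positive-definite tensor on the diffusivity scale.
random_spd_tensor <- function() {
  A <- matrix(rnorm(9), 3)
  S <- crossprod(A) + diag(3) * 0.1
  S <- S / max(abs(S)) * 1.5e-3
  c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
}

tensor6_to_mat <- function(D6) {
  matrix(c(D6[1], D6[4], D6[5],
           D6[4], D6[2], D6[6],
           D6[5], D6[6], D6[3]), 3, 3)
}

mat_to_tensor6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3],
                                M[1, 2], M[1, 3], M[2, 3])

# Constant-valued tensor_maps object on a small grid.
constant_maps <- function(dxx, dyy, dzz, shape = c(10, 10, 8),
                          voxel_size = 2, fa = 0.5) {
  structure(list(
    Dxx = array(dxx, shape), Dyy = array(dyy, shape), Dzz = array(dzz, shape),
    FA = array(fa, shape), MD = array((dxx + dyy + dzz) / 3, shape),
    L1 = array(dxx, shape), L2 = array(dyy, shape), L3 = array(dzz, shape),
    dir1 = array(0, c(shape, 3)),
    mask = array(TRUE, shape), voxel_size = voxel_size,
    affine = grid_affine(voxel_size)), class = "tensor_maps")
}
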