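#' Diffusion gradient table
#'
#' Bundles b-values and unit gradient directions in the FSL bval/bvec dialect
#' and validates the geometry required for a tensor fit: at least one b = 0
#' measurement and at least six non-collinear diffusion-weighted directions
#' (the rank condition of the 6-parameter tensor design).
#'
#' @param bvals Numeric vector of b-values (s/mm^2), length N.
#' @param bvecs Numeric 3 x N matrix of gradient directions (FSL row order:
#'   x, y, z components). Vectors with bval > 0 must have unit norm to within
#'   1e-3; they are renormalized exactly on construction.
#' @return An object of class `gradient_table` with elements `bvals`
#'   (length N) and `bvecs` (3 x N, unit columns where bval > 0).
#' @examples
#' gt <- default_gradient_table(n_dir = 32, b = 1000)
#' gt$bvals[1:3]
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (x, y, z components); got ", nrow(bvecs))
  if (ncol(bvecs) != length(bvals))
    stop("bvals length (", length(bvals), ") does not match number of bvecs (",
         ncol(bvecs), ")")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("all bvals must be finite and >= 0")
  if (!any(bvals == 0))
    stop("gradient table must contain at least one b = 0 measurement")
  dw <- bvals > 0
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("diffusion-weighted bvecs must be unit vectors (norm within 1e-3 of 1)")
  bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm, "/")
  dimnames(bvecs) <- NULL
  gt <- structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
  if (n_distinct_directions(gt) < 6L)
    stop("insufficient directions: at least 6 distinct non-collinear ",
         "diffusion-weighted directions are required")
  if (qr(tensor_design(gt)[bvals > 0, -1, drop = FALSE])$rank < 6L)
    stop("insufficient directions: gradient scheme is rank-deficient for a ",
         "tensor fit")
  gt
}

# Count directions distinct up to antipodal symmetry (g and -g sample the
# same tensor projection).
n_distinct_directions <- function(gtab, tol = 1e-6) {
  v <- gtab$bvecs[, gtab$bvals > 0, drop = FALSE]
  if (ncol(v) == 0L) return(0L)
  # canonical sign: first nonzero component positive
  for (j in seq_len(ncol(v))) {
    nz <- which(abs(v[, j]) > tol)[1]
    if (!is.na(nz) && v[nz, j] < 0) v[, j] <- -v[, j]
  }
  nrow(unique(round(t(v) / tol) * tol))
}

#' Design matrix of the log-linear tensor model
#'
#' Row i is `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`
#' so that `ln S = X %*% c(ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param gtab A [gradient_table()].
#' @return N x 7 numeric matrix.
#' @keywords internal
tensor_design <- function(gtab) {
  b <- gtab$bvals
  g <- gtab$bvecs
  cbind(1,
        -b * g[1, ]^2,
        -b * g[2, ]^2,
        -b * g[3, ]^2,
        -2 * b * g[1, ] * g[2, ],
        -2 * b * g[1, ] * g[3, ],
        -2 * b * g[2, ] * g[3, ])
}

#' Near-uniform gradient directions on the hemisphere
#'
#' Deterministic Fibonacci-spiral point set on the upper hemisphere, a
#' standard construction for evenly spread diffusion-sampling schemes. The
#' set is antipodally symmetric in effect (only one of g / -g is kept).
#'
#' @param n Number of directions (>= 6).
#' @return 3 x n matrix of unit vectors.
#' @export
spread_directions <- function(n) {
  stopifnot(n >= 6)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i     # golden-angle azimuth
  z <- i / n                        # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Default acquisition scheme
#'
#' One b = 0 volume plus `n_dir` evenly spread directions at a single shell,
#' emulating a routine single-shell DTI protocol (b = 1000 s/mm^2, 32
#' directions by default).
#'
#' @param n_dir Number of diffusion-weighted directions.
#' @param b Shell b-value (s/mm^2).
#' @param n_b0 Number of b = 0 volumes.
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(n_dir = 32, b = 1000, n_b0 = 1) {
  dirs <- spread_directions(n_dir)
  gradient_table(bvals = c(rep(0, n_b0), rep(b, n_dir)),
                 bvecs = cbind(matrix(0, 3, n_b0), dirs))
}
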