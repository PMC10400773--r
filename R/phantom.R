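#' Synthetic DWI phantom specification
#'
#' Describes a piecewise-constant tensor phantom that emulates the
#' periventricular geometry the ALPS index relies on: projection fibers
#' (corona radiata) run head-foot (z), association fibers (superior
#' longitudinal fasciculus) run anterior-posterior (y), and perivascular
#' flow adds diffusivity along the left-right axis (x). A single unitless
#' parameter `g` in `[0, 1]` scales the perivascular x-axis diffusivity in
#' both fiber regions:
#' `Dxx = d_perp + g * (d_axial - d_perp)`,
#' so `g = 0` gives ordinary fibers (ALPS = 1) and `g = 1` drives the
#' x diffusivity up to the along-fiber value.
#'
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param voxel_size Isotropic voxel edge in mm (default 2).
#' @param regions Named list with entries `projection_L`, `projection_R`,
#'   `association_L`, `association_R`, each created by [region_box()] or
#'   [region_sphere()]; anything else is background. Regions must not
#'   overlap. `NULL` uses a default four-quadrant layout.
#' @param d_axial Along-fiber diffusivity (mm^2/s).
#' @param d_perp Cross-fiber diffusivity (mm^2/s); `d_axial >= d_perp > 0`.
#' @param g Glymphatic-activity parameter in `[0, 1]`.
#' @param S0 Non-diffusion-weighted signal (arbitrary units).
#' @param noise_sigma Rician noise SD in signal units (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 16L), voxel_size = 2,
                         regions = NULL,
                         d_axial = 1.4e-3, d_perp = 0.4e-3, g = 0.5,
                         S0 = 1000, noise_sigma = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L),
            length(voxel_size) == 1L, voxel_size > 0)
  if (!(d_axial >= d_perp && d_perp > 0))
    stop("require d_axial >= d_perp > 0")
  if (g < 0 || g > 1) stop("g must lie in [0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(regions)) regions <- default_phantom_regions(grid_shape)
  needed <- c("projection_L", "projection_R", "association_L", "association_R")
  if (!all(needed %in% names(regions)))
    stop("regions must include: ", paste(needed, collapse = ", "))
  spec <- structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                         regions = regions, d_axial = d_axial, d_perp = d_perp,
                         g = g, S0 = S0, noise_sigma = noise_sigma,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  check_regions(spec)
  spec
}

#' @rdname phantom_spec
#' @param min,max Inclusive 1-based voxel-index corners of a box.
#' @export
region_box <- function(min, max) {
  stopifnot(length(min) == 3L, length(max) == 3L, all(max >= min))
  list(shape = "box", min = as.integer(min), max = as.integer(max))
}

#' @rdname phantom_spec
#' @param center Voxel-index center of a sphere.
#' @param radius_vox Radius in voxels.
#' @export
region_sphere <- function(center, radius_vox) {
  stopifnot(length(center) == 3L, radius_vox > 0)
  list(shape = "sphere", center = as.numeric(center),
       radius_vox = as.numeric(radius_vox))
}

# Four non-overlapping boxes, one per fiber region/hemisphere, centered in
# the grid quadrants. Each box must be large enough to contain the 5 mm
# analysis sphere with margin.
default_phantom_regions <- function(grid_shape) {
  n <- grid_shape
  if (any(n < c(16L, 16L, 9L)))
    stop("default regions need a grid of at least 16 x 16 x 9 voxels")
  xl <- c(2L, floor(n[1] / 2) - 2L); xr <- c(ceiling(n[1] / 2) + 2L, n[1] - 1L)
  ya <- c(2L, floor(n[2] / 2) - 2L); yp <- c(ceiling(n[2] / 2) + 2L, n[2] - 1L)
  zz <- c(2L, n[3] - 1L)
  list(
    projection_L  = region_box(c(xl[1], ya[1], zz[1]), c(xl[2], ya[2], zz[2])),
    projection_R  = region_box(c(xr[1], ya[1], zz[1]), c(xr[2], ya[2], zz[2])),
    association_L = region_box(c(xl[1], yp[1], zz[1]), c(xl[2], yp[2], zz[2])),
    association_R = region_box(c(xr[1], yp[1], zz[1]), c(xr[2], yp[2], zz[2]))
  )
}

region_mask <- function(region, grid_shape) {
  m <- array(FALSE, grid_shape)
  if (region$shape == "box") {
    lo <- pmax(region$min, 1L); hi <- pmin(region$max, grid_shape)
    if (any(lo > hi)) stop("region box lies outside the grid")
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else {
    idx <- arrayInd(seq_along(m), grid_shape)
    d2 <- (idx[, 1] - region$center[1])^2 + (idx[, 2] - region$center[2])^2 +
      (idx[, 3] - region$center[3])^2
    m[d2 <= region$radius_vox^2] <- TRUE
  }
  m
}

region_center_vox <- function(region) {
  if (region$shape == "box") (region$min + region$max) / 2 else region$center
}

check_regions <- function(spec) {
  masks <- lapply(spec$regions, region_mask, grid_shape = spec$grid_shape)
  total <- Reduce(`+`, lapply(masks, as.integer))
  if (any(total > 1L)) stop("phantom regions overlap")
  invisible(TRUE)
}

#' Grid affine for phantoms
#'
#' Axis-aligned voxel-to-world map: voxel (1,1,1) sits at the world origin
#' and axes scale by the voxel size (world = mm).
#'
#' @param voxel_size Voxel edge in mm.
#' @return 4 x 4 affine matrix.
#' @export
grid_affine <- function(voxel_size) {
  a <- diag(c(rep(voxel_size, 3), 1))
  a[1:3, 4] <- 0
  a
}

voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE] + 1
}

#' Add Rician noise to a magnitude MR signal
#'
#' Magnitude MR data are Rician distributed: the noisy signal is
#' `sqrt((S + n1)^2 + n2^2)` with `n1, n2` independent zero-mean Gaussians
#' of SD `sigma`. At `sigma = 0` the input is returned unchanged.
#'
#' @param signal Non-negative numeric array.
#' @param sigma Noise SD in signal units (>= 0).
#' @param seed Optional integer seed.
#' @return Array of the same shape, non-negative.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (any(signal < 0)) stop("signal must be non-negative")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Generate a synthetic DWI phantom with known tensor ground truth
#'
#' Builds the per-voxel tensor field implied by `spec` (projection fibers
#' `diag(Dxx, d_perp, d_axial)`, association fibers `diag(Dxx, d_axial,
#' d_perp)`, isotropic background at `d_perp`), synthesizes the DWI signal
#' `S = S0 * exp(-b g' D g)` for every gradient, applies Rician noise, and
#' returns analysis-ready ROI centers (5 mm spheres at each fiber-region
#' center).
#'
#' @param spec A [phantom_spec()].
#' @param gtab A [gradient_table()].
#' @return List with `dwi` (a `dwi_volume`), `truth` (ground-truth
#'   `tensor_field`), and `rois` (ROI table; see [roi_table()]).
#' @export
generate_phantom_dwi <- function(spec, gtab) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(gtab, "gradient_table"))
  check_regions(spec)
  shape <- spec$grid_shape
  nvox <- prod(shape)
  # 6 tensor coefficients per voxel: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
  D <- matrix(0, nvox, 6)
  D[, 1:3] <- spec$d_perp            # isotropic background
  dxx <- spec$d_perp + spec$g * (spec$d_axial - spec$d_perp)
  for (nm in names(spec$regions)) {
    m <- as.vector(region_mask(spec$regions[[nm]], shape))
    if (grepl("^projection", nm)) {
      D[m, 1] <- dxx; D[m, 2] <- spec$d_perp; D[m, 3] <- spec$d_axial
    } else if (grepl("^association", nm)) {
      D[m, 1] <- dxx; D[m, 2] <- spec$d_axial; D[m, 3] <- spec$d_perp
    }
  }
  X <- tensor_design(gtab)           # N x 7
  # ln S = ln S0 + [design without intercept] %*% D  => S = S0 * exp(...)
  lnS <- X[, -1, drop = FALSE] %*% t(D)        # N x nvox
  sig <- spec$S0 * exp(lnS)
  sig <- add_rician_noise(sig, spec$noise_sigma, seed = spec$seed)
  data4d <- array(t(sig), dim = c(shape, length(gtab$bvals)))
  affine <- grid_affine(spec$voxel_size)
  dwi <- dwi_volume(data4d, voxel_size = spec$voxel_size, affine = affine)
  truth <- tensor_field(array(D, dim = c(shape, 6)),
                        S0 = array(spec$S0, shape),
                        mask = array(TRUE, shape),
                        voxel_size = spec$voxel_size, affine = affine)
  rois <- phantom_rois(spec)
  list(dwi = dwi, truth = truth, rois = rois)
}

#' Default analysis ROIs of a phantom
#'
#' One 5 mm sphere per fiber region, centered at the region center, in world
#' (mm) coordinates.
#'
#' @param spec A [phantom_spec()].
#' @param radius_mm Sphere radius in mm.
#' @return ROI table (see [roi_table()]).
#' @export
phantom_rois <- function(spec, radius_mm = 5) {
  affine <- grid_affine(spec$voxel_size)
  rows <- lapply(names(spec$regions), function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    ctr <- voxel_to_world(affine, region_center_vox(spec$regions[[nm]]))
    data.frame(label = parts[1], hemisphere = parts[2],
               x_mm = ctr[1], y_mm = ctr[2], z_mm = ctr[3],
               radius_mm = radius_mm, stringsAsFactors = FALSE)
  })
  roi_table(do.call(rbind, rows))
}
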