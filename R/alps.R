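#' ROI specification table
#'
#' Validates a table of spherical ROI definitions in world (mm) coordinates.
#' The ALPS analysis needs one `projection` and one `association` ROI per
#' hemisphere, each a 5 mm sphere at the lateral-ventricle level by
#' convention.
#'
#' @param df Data frame with columns `label` (one of `projection`,
#'   `association`), `hemisphere` (`L` or `R`), `x_mm`, `y_mm`, `z_mm`,
#'   `radius_mm` (> 0).
#' @return The validated data frame with class `roi_table`.
#' @export
roi_table <- function(df) {
  req <- c("label", "hemisphere", "x_mm", "y_mm", "z_mm", "radius_mm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("ROI table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$label %in% c("projection", "association")))
    stop("ROI label must be 'projection' or 'association'")
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("ROI hemisphere must be 'L' or 'R'")
  if (any(df$radius_mm <= 0)) stop("ROI radius must be > 0")
  class(df) <- unique(c("roi_table", class(df)))
  df
}

#' Read an ROI configuration file (CSV or JSON)
#'
#' @param path File with columns/fields `label`, `hemisphere`, `x_mm`,
#'   `y_mm`, `z_mm`, `radius_mm`.
#' @return A [roi_table()].
#' @export
read_roi_config <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  roi_table(df)
}

#' Spherical ROI voxel mask
#'
#' A voxel belongs to the sphere iff the Euclidean distance from its center
#' (in world mm, through the affine) to the ROI center is at most the
#' radius. Errors if the ROI center falls outside the grid or the mask
#' comes out empty.
#'
#' @param roi One-row ROI spec (list or data frame row with `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm`).
#' @param shape Integer grid dimensions (3).
#' @param affine 4 x 4 voxel-to-world map.
#' @return 3-D logical array.
#' @export
sphere_mask <- function(roi, shape, affine) {
  ctr <- c(roi$x_mm, roi$y_mm, roi$z_mm)
  vox <- world_to_voxel(affine, ctr)
  if (any(vox < 0.5) || any(vox > shape + 0.5))
    stop("ROI center (", paste(signif(ctr, 4), collapse = ", "),
         ") mm lies outside the volume")
  idx <- arrayInd(seq_len(prod(shape)), shape)
  w <- voxel_to_world(affine, idx)
  d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
  m <- array(d2 <= roi$radius_mm^2, shape)
  if (!any(m)) stop("empty ROI mask: radius ", roi$radius_mm,
                    " mm contains no voxel center")
  m
}

#' Average ROI centers across subjects
#'
#' Reproduces the group-template step in which per-subject manually placed
#' ROI coordinates are averaged (e.g. over 20 subjects per scanner batch)
#' to build one shared mask. Plain per-coordinate arithmetic mean; all
#' centers must share one label and hemisphere.
#'
#' @param centers Data frame with columns `label`, `hemisphere`, `x_mm`,
#'   `y_mm`, `z_mm` (one row per subject).
#' @return One-row data frame with the mean center.
#' @export
average_roi_centers <- function(centers) {
  if (nrow(centers) < 1L) stop("need at least one center")
  if (length(unique(centers$label)) != 1L ||
      length(unique(centers$hemisphere)) != 1L)
    stop("mixed labels/hemispheres: average centers per ROI only")
  data.frame(label = centers$label[1], hemisphere = centers$hemisphere[1],
             x_mm = mean(centers$x_mm), y_mm = mean(centers$y_mm),
             z_mm = mean(centers$z_mm), stringsAsFactors = FALSE)
}

#' Extract the four ALPS diffusivity inputs for one hemisphere
#'
#' Means over the projection- and association-fiber spheres of the
#' directional diffusivity maps: `Dxx` in both ROIs (the perivascular
#' direction), `Dyy` in the projection ROI and `Dzz` in the association ROI
#' (the perpendicular directions entering the denominator).
#'
#' @param maps A `tensor_maps` object.
#' @param rois A [roi_table()] containing both labels for the hemisphere.
#' @param hemisphere `"L"` or `"R"`.
#' @return List with `Dxx_proj`, `Dxx_assoc`, `Dyy_proj`, `Dzz_assoc`
#'   (mm^2/s) and voxel counts `n_proj`, `n_assoc`.
#' @export
extract_alps_inputs <- function(maps, rois, hemisphere) {
  stopifnot(inherits(maps, "tensor_maps"))
  h <- rois[rois$hemisphere == hemisphere, , drop = FALSE]
  proj <- h[h$label == "projection", , drop = FALSE]
  asso <- h[h$label == "association", , drop = FALSE]
  if (nrow(proj) != 1L || nrow(asso) != 1L)
    stop("need exactly one projection and one association ROI for hemisphere ",
         hemisphere)
  shape <- dim(maps$mask)
  mp <- sphere_mask(as.list(proj), shape, maps$affine) & maps$mask
  ma <- sphere_mask(as.list(asso), shape, maps$affine) & maps$mask
  if (!any(mp) || !any(ma)) stop("ROI mask empty after applying brain mask")
  out <- list(Dxx_proj = mean(maps$Dxx[mp]), Dxx_assoc = mean(maps$Dxx[ma]),
              Dyy_proj = mean(maps$Dyy[mp]), Dzz_assoc = mean(maps$Dzz[ma]),
              n_proj = sum(mp), n_assoc = sum(ma))
  if (any(unlist(out[1:4]) <= 0))
    stop("non-positive ROI-mean diffusivity: degenerate fit in hemisphere ",
         hemisphere)
  out
}

#' ALPS index from the four directional diffusivities
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`:
#' diffusivity along the perivascular (x) direction relative to the
#' diffusivity perpendicular to both fiber tracts. Equals 1 in isotropic
#' tissue; values above 1 indicate preferential diffusion along the
#' perivascular axis.
#'
#' @param inputs List with positive `Dxx_proj`, `Dxx_assoc`, `Dyy_proj`,
#'   `Dzz_assoc` (as from [extract_alps_inputs()]).
#' @return Unitless index (> 0).
#' @export
alps_index <- function(inputs) {
  v <- unlist(inputs[c("Dxx_proj", "Dxx_assoc", "Dyy_proj", "Dzz_assoc")])
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all four ALPS inputs must be positive")
  ((v[["Dxx_proj"]] + v[["Dxx_assoc"]]) / 2) /
    ((v[["Dyy_proj"]] + v[["Dzz_assoc"]]) / 2)
}

#' Bilateral ALPS index
#'
#' Unweighted mean of the left- and right-hemisphere indices.
#'
#' @param L,R Per-hemisphere ALPS indices (> 0).
#' @return `(L + R) / 2`.
#' @export
bilateral_alps <- function(L, R) {
  if (missing(L) || missing(R) || is.null(L) || is.null(R) ||
      is.na(L) || is.na(R))
    stop("both hemispheres are required for the bilateral index")
  stopifnot(L > 0, R > 0)
  (L + R) / 2
}

#' Per-subject ALPS computation from tensor maps
#'
#' Runs [extract_alps_inputs()] and [alps_index()] for both hemispheres and
#' assembles the audit row: L/R/Bi indices, the four ROI-mean diffusivities
#' per hemisphere, ROI voxel counts, and the mean FA over the four ROIs
#' (the FA summary used as the comparison feature in classification).
#'
#' @param maps A `tensor_maps` object.
#' @param rois A [roi_table()] with all four ROIs.
#' @param subject_id Identifier copied into the output row.
#' @return One-row data frame.
#' @export
compute_alps <- function(maps, rois, subject_id = "subject") {
  res <- list()
  fa_vals <- numeric(0)
  for (h in c("L", "R")) {
    inp <- extract_alps_inputs(maps, rois, h)
    res[[h]] <- inp
    hrois <- rois[rois$hemisphere == h, , drop = FALSE]
    for (i in seq_len(nrow(hrois))) {
      m <- sphere_mask(as.list(hrois[i, ]), dim(maps$mask), maps$affine) &
        maps$mask
      fa_vals <- c(fa_vals, maps$FA[m])
    }
  }
  L <- alps_index(res$L); R <- alps_index(res$R)
  data.frame(
    subject_id = subject_id, L_ALPS = L, R_ALPS = R,
    Bi_ALPS = bilateral_alps(L, R), FA_mean = mean(fa_vals),
    L_Dxx_proj = res$L$Dxx_proj, L_Dxx_assoc = res$L$Dxx_assoc,
    L_Dyy_proj = res$L$Dyy_proj, L_Dzz_assoc = res$L$Dzz_assoc,
    R_Dxx_proj = res$R$Dxx_proj, R_Dxx_assoc = res$R$Dxx_assoc,
    R_Dyy_proj = res$R$Dyy_proj, R_Dzz_assoc = res$R$Dzz_assoc,
    L_n_proj = res$L$n_proj, L_n_assoc = res$L$n_assoc,
    R_n_proj = res$R$n_proj, R_n_assoc = res$R$n_assoc,
    stringsAsFactors = FALSE
  )
}

#' Full DWI-to-ALPS pipeline for one subject
#'
#' Tensor fit, map derivation, optional Gaussian smoothing, ROI extraction
#' and the ALPS index in one call. Smoothing defaults to 0 mm: the
#' piecewise-constant phantoms this package validates against make any
#' smoothing across region boundaries a boundary artifact; pass
#' `fwhm_mm = 6` to mirror a conventional real-data preprocessing chain.
#'
#' @param dwi A [dwi_volume()].
#' @param gtab A [gradient_table()].
#' @param rois A [roi_table()].
#' @param subject_id Identifier for the output row.
#' @param fwhm_mm Smoothing FWHM in mm applied to the diffusivity maps.
#' @return One-row data frame as from [compute_alps()].
#' @export
alps_from_dwi <- function(dwi, gtab, rois, subject_id = "subject",
                          fwhm_mm = 0) {
  maps <- derive_maps(fit_tensor_loglinear(dwi, gtab))
  if (fwhm_mm > 0) maps <- smooth_maps(maps, fwhm_mm)
  compute_alps(maps, rois, subject_id)
}
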