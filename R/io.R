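#' Read FSL-style bval/bvec files
#'
#' bval: one whitespace-separated row of b-values. bvec: three rows (x, y,
#' z components), one column per volume.
#'
#' @param bval_path,bvec_path Text file paths.
#' @return A [gradient_table()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("gradient file not found: ", p)
  bvals <- scan(bval_path, quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    stop("malformed bvec file: expected 3 rows, got ", length(lines))
  rows <- lapply(lines, function(l) scan(text = l, quiet = TRUE))
  if (length(unique(lengths(rows))) != 1L)
    stop("malformed bvec file: rows have unequal lengths")
  bvecs <- do.call(rbind, rows)
  if (ncol(bvecs) != length(bvals))
    stop("bval count (", length(bvals), ") does not match bvec columns (",
         ncol(bvecs), ")")
  gradient_table(bvals, bvecs)
}

#' Write FSL-style bval/bvec files
#'
#' @param gtab A [gradient_table()].
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(formatC(gtab$bvals, format = "g", digits = 10),
                   collapse = " "), bval_path)
  writeLines(apply(gtab$bvecs, 1, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read a DWI dataset (NIfTI + bval/bvec)
#'
#' @param nifti_path 4-D NIfTI-1 volume (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL gradient files.
#' @return List with `dwi` (a [dwi_volume()]) and `gtab`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  if (!file.exists(nifti_path)) stop("NIfTI file not found: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D volume, got ", length(d), "-D")
  gtab <- read_bvals_bvecs(bval_path, bvec_path)
  if (d[4] != length(gtab$bvals))
    stop("volume has ", d[4], " measurements but gradient table has ",
         length(gtab$bvals))
  aff <- structure(RNifti::xform(img), class = NULL)
  vs <- RNifti::pixdim(img)[1]
  list(dwi = dwi_volume(array(as.numeric(img), d), voxel_size = vs,
                        affine = aff),
       gtab = gtab)
}

#' Write a DWI dataset (NIfTI + bval/bvec)
#'
#' @param dwi A [dwi_volume()].
#' @param gtab A [gradient_table()].
#' @param nifti_path,bval_path,bvec_path Output paths.
#' @return Invisibly, `nifti_path`.
#' @export
write_dwi <- function(dwi, gtab, nifti_path, bval_path, bvec_path) {
  arr <- dwi$data
  attr(arr, "pixdim") <- c(rep(dwi$voxel_size, 3), 1)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  RNifti::writeNifti(img, nifti_path)
  write_bvals_bvecs(gtab, bval_path, bvec_path)
  invisible(nifti_path)
}

#' Write a scalar map as NIfTI-1 float32
#'
#' @param map 3-D array.
#' @param affine 4 x 4 affine.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scalar_map <- function(map, affine, path) {
  arr <- map
  attr(arr, "pixdim") <- rep(abs(affine[1, 1]), 3)
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
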