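#' Write a diffusion-weighted volume as NIfTI-1 with FSL bval/bvec files
#'
#' Writes `<prefix>.nii` (or `.nii.gz` if `gzip = TRUE`), `<prefix>.bval`
#' (one whitespace-separated row of b-values) and `<prefix>.bvec` (three rows
#' of direction components, columns = volumes).
#'
#' @param dwi An `alps_dwi`.
#' @param prefix Output path prefix.
#' @param gzip Compress the NIfTI file (default FALSE; uncompressed output
#'   has stable checksums, which the pipeline manifest relies on).
#' @return Invisibly, the three file paths written.
#' @export
write_dwi <- function(dwi, prefix, gzip = FALSE) {
  nii <- paste0(prefix, if (gzip) ".nii.gz" else ".nii")
  img <- RNifti::asNifti(dwi$data, reference = NULL)
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  RNifti::pixdim(img) <- c(dwi$voxdim, 1)
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(apply(dwi$scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec)
  invisible(c(nii = nii, bval = bval, bvec = bvec))
}

#' Read a diffusion-weighted volume with FSL bval/bvec files
#'
#' @param nii Path to the 4-D NIfTI file.
#' @param bval,bvec Paths to the FSL-dialect gradient table: one row of
#'   b-values and three rows of direction components, whitespace-separated,
#'   columns = volumes.
#' @return An `alps_dwi`.
#' @export
read_dwi <- function(nii, bval, bvec) {
  img <- RNifti::readNifti(nii)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4) stop("expected a 4-D diffusion volume")
  bvals <- scan(bval, quiet = TRUE)
  bv <- as.matrix(read.table(bvec))
  if (nrow(bv) != 3 || ncol(bv) != length(bvals))
    stop("bvec must have 3 rows and one column per volume")
  if (length(bvals) != dim(data)[4])
    stop("gradient table does not match the number of volumes")
  nrm <- sqrt(colSums(bv^2))
  if (any(bvals > 0 & abs(nrm - 1) > 1e-4))
    stop("weighted directions must be unit vectors")
  scheme <- structure(list(bvals = bvals, bvecs = unname(bv),
                           n_b0 = sum(bvals == 0)),
                      class = "alps_scheme")
  aff <- RNifti::xform(img)
  vox <- RNifti::pixdim(img)[1:3]
  structure(list(data = data, affine = unclass(aff), voxdim = vox,
                 scheme = scheme),
            class = "alps_dwi")
}

#' Write / read a 3-D map or binary mask as NIfTI-1
#'
#' @param map 3-D array (or 4-D for color maps).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxdim Voxel size in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; default axis-aligned RAS
#'   centered on the volume.
#' @return `write_map`: invisibly, the path. `read_map`: a list with `data`,
#'   `voxdim`, `affine`.
#' @export
write_map <- function(map, path, voxdim = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- phantom_affine(dim(map)[1:3], voxdim)
  img <- RNifti::asNifti(map)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::pixdim(img) <- c(voxdim, rep(1, length(dim(map)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxdim = RNifti::pixdim(img)[1:3],
       affine = unclass(RNifti::xform(img)))
}

#' Read / write ALPS ROI definitions as JSON
#'
#' The interchange format is a JSON array with one object per ROI:
#' `{"hemisphere": "left", "fiber_class": "projection",
#'   "center_voxel": [i, j, k], "diameter_mm": 5}` with 0-based voxel
#' indices (the convention of most neuroimaging tools). In R the ROIs are
#' held as [roi_spec()] objects with 1-based indices; conversion happens
#' here.
#'
#' @param path JSON file path.
#' @return `read_rois`: a list of `alps_roi` objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    roi_spec(hemisphere = r$hemisphere, fiber_class = r$fiber_class,
             center = unlist(r$center_voxel) + 1L,
             diameter_mm = if (is.null(r$diameter_mm)) 5 else r$diameter_mm)
  })
}

#' @rdname read_rois
#' @param rois List of `alps_roi` objects.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r)
    list(hemisphere = r$hemisphere, fiber_class = r$fiber_class,
         center_voxel = as.integer(r$center - 1L), diameter_mm = r$diameter_mm))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
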