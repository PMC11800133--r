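#' Volume of a binary mask in millilitres
#'
#' Count of nonzero voxels times the voxel volume (product of the voxel
#' dimensions, mm^3), divided by 1000. Any nonzero value counts as inside,
#' so relabelled masks give identical volumes; a mask with values other than
#' two levels (0 and one nonzero value) is rejected.
#'
#' @param mask 3-D array, binary (0 / one nonzero level).
#' @param voxdim Voxel dimensions in mm.
#' @return Volume in mL.
#' @export
mask_volume <- function(mask, voxdim) {
  v <- unique(as.vector(mask))
  if (length(setdiff(v, 0)) > 1)
    stop("mask is not binary")
  sum(mask != 0) * prod(voxdim) / 1000
}

#' Perihematomal edema volume by subtraction
#'
#' Edema = total lesion volume (T2) minus hematoma volume (SWI). The two
#' masks may live on different native grids, so the subtraction is scalar.
#' A negative difference (possible across modalities) is floored at zero
#' with a warning.
#'
#' @param total_ml Total lesion volume in mL.
#' @param hematoma_ml Hematoma volume in mL.
#' @return Edema volume in mL (>= 0).
#' @export
edema_volume <- function(total_ml, hematoma_ml) {
  if (total_ml < 0 || hematoma_ml < 0) stop("volumes must be >= 0")
  d <- total_ml - hematoma_ml
  if (d < 0) {
    warning("hematoma volume exceeds total lesion volume; edema floored at 0")
    d <- 0
  }
  d
}

#' Relative edema ratio
#'
#' The quotient of the edema volume to the hemorrhage volume, a
#' size-normalised measure of edema severity.
#'
#' @param edema_ml Edema volume in mL.
#' @param hemorrhage_ml Hemorrhage volume in mL (> 0).
#' @return Dimensionless ratio.
#' @export
relative_edema_ratio <- function(edema_ml, hemorrhage_ml) {
  if (hemorrhage_ml <= 0) stop("ratio undefined: hemorrhage volume must be > 0")
  if (edema_ml < 0) stop("edema volume must be >= 0")
  edema_ml / hemorrhage_ml
}

#' Full volume report from lesion masks
#'
#' Computes hemorrhage volume, edema volume (total minus hematoma, floored
#' at zero) and the relative edema ratio from a hematoma mask and a
#' total-lesion mask, each on its own native grid.
#'
#' @param hematoma 3-D binary array (hematoma on SWI).
#' @param total_lesion 3-D binary array (hematoma plus edema on T2).
#' @param voxdim_hematoma,voxdim_total Voxel dimensions (mm) of each grid;
#'   `voxdim_total` defaults to the hematoma grid.
#' @return An object of class `volume_report` with `hemorrhage_ml`,
#'   `edema_ml`, `relative_edema_ratio`.
#' @export
volume_report <- function(hematoma, total_lesion, voxdim_hematoma,
                          voxdim_total = voxdim_hematoma) {
  hem <- mask_volume(hematoma, voxdim_hematoma)
  tot <- mask_volume(total_lesion, voxdim_total)
  ede <- edema_volume(tot, hem)
  ratio <- if (hem > 0) relative_edema_ratio(ede, hem) else NA_real_
  structure(list(hemorrhage_ml = hem, edema_ml = ede,
                 relative_edema_ratio = ratio),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("Lesion volumetry: hemorrhage %.2f mL, edema %.2f mL, relative edema ratio %s\n",
              x$hemorrhage_ml, x$edema_ml,
              if (is.na(x$relative_edema_ratio)) "NA"
              else sprintf("%.3f", x$relative_edema_ratio)))
  invisible(x)
}
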