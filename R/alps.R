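#' Define an ALPS region of interest
#'
#' A circular ROI on one axial slice of the diffusivity maps, identified by
#' hemisphere and fiber class. The ALPS protocol uses one projection-fiber
#' and one association-fiber ROI per hemisphere, 5 mm in diameter, on the
#' slice where the deep medullary veins run perpendicular to the body of the
#' lateral ventricle.
#'
#' @param hemisphere `"left"` or `"right"`.
#' @param fiber_class `"projection"` or `"association"`.
#' @param center Voxel coordinates `c(i, j, k)` (1-based; `k` is the axial
#'   slice).
#' @param diameter_mm In-plane ROI diameter in mm (default 5).
#' @return An object of class `alps_roi`.
#' @export
roi_spec <- function(hemisphere, fiber_class, center, diameter_mm = 5) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  fiber_class <- match.arg(fiber_class, c("projection", "association"))
  if (diameter_mm <= 0) stop("diameter must be positive")
  if (length(center) != 3 || any(center < 1))
    stop("center must be 1-based voxel coordinates c(i, j, k)")
  structure(list(hemisphere = hemisphere, fiber_class = fiber_class,
                 center = as.numeric(center), diameter_mm = diameter_mm),
            class = "alps_roi")
}

#' Mean axis diffusivities over an ROI disc
#'
#' Averages each of the Dxx/Dyy/Dzz maps over the voxels of one axial slice
#' whose in-plane center distance from the ROI center is at most
#' `diameter_mm / 2` (voxel-center-in-disc membership, native grid, no
#' partial-volume weighting).
#'
#' @param maps Named list of 3-D arrays `Dxx`, `Dyy`, `Dzz` as returned by
#'   [axis_diffusivities()].
#' @param roi An `alps_roi`.
#' @param voxdim Voxel size in mm (in-plane sizes are used for the distance).
#' @return List with `Dx`, `Dy`, `Dz` (mm^2/s) and `n_voxels`.
#' @export
extract_roi_means <- function(maps, roi, voxdim) {
  stopifnot(inherits(roi, "alps_roi"))
  dims <- dim(maps$Dxx)
  k <- round(roi$center[3])
  if (k < 1 || k > dims[3] ||
      roi$center[1] < 1 || roi$center[1] > dims[1] ||
      roi$center[2] < 1 || roi$center[2] > dims[2])
    stop(sprintf("ROI %s/%s lies outside the volume",
                 roi$hemisphere, roi$fiber_class))
  r <- roi$diameter_mm / 2
  # candidate voxel window around the center, then exact disc membership
  di <- ceiling(r / voxdim[1]); dj <- ceiling(r / voxdim[2])
  ii <- max(1, round(roi$center[1]) - di):min(dims[1], round(roi$center[1]) + di)
  jj <- max(1, round(roi$center[2]) - dj):min(dims[2], round(roi$center[2]) + dj)
  grid <- expand.grid(i = ii, j = jj)
  d2 <- ((grid$i - roi$center[1]) * voxdim[1])^2 +
        ((grid$j - roi$center[2]) * voxdim[2])^2
  sel <- grid[d2 <= r^2, ]
  if (nrow(sel) == 0)
    stop(sprintf("ROI %s/%s contains no voxel centers",
                 roi$hemisphere, roi$fiber_class))
  pick <- function(m) mean(m[cbind(sel$i, sel$j, k)])
  list(Dx = pick(maps$Dxx), Dy = pick(maps$Dyy), Dz = pick(maps$Dzz),
       n_voxels = nrow(sel))
}

#' The ALPS index from ROI mean diffusivities
#'
#' ALPS = (Dx_proj + Dx_assoc) / (Dy_proj + Dz_assoc): diffusivity along the
#' perivascular (x) direction in both fiber tracts, relative to the tracts'
#' non-dominant in-plane axes. Values near 1 indicate no preferential
#' perivascular diffusion; healthy adults typically measure well above 1.
#'
#' @param means Named list with `Dx_proj`, `Dy_proj`, `Dz_proj`, `Dx_assoc`,
#'   `Dy_assoc`, `Dz_assoc` (mm^2/s).
#' @return The scalar ALPS index.
#' @export
compute_alps <- function(means) {
  need <- c("Dx_proj", "Dy_proj", "Dz_proj", "Dx_assoc", "Dy_assoc", "Dz_assoc")
  miss <- setdiff(need, names(means))
  if (length(miss)) stop("missing ROI means: ", paste(miss, collapse = ", "))
  den <- means$Dy_proj + means$Dz_assoc
  if (!is.finite(den) || den <= 0)
    stop("ALPS denominator (Dy_proj + Dz_assoc) must be positive")
  (means$Dx_proj + means$Dx_assoc) / den
}

#' Lateralize hemispheric ALPS indices against the lesion side
#'
#' For a left- or right-sided lesion the hemispheric indices are relabelled
#' ipsilateral/contralateral; for subtentorial lesions or controls (no
#' lateralized lesion) only the per-subject average of the two sides is
#' defined.
#'
#' @param left,right Hemispheric ALPS indices (may be `NA` only when the
#'   lesion side does not require them).
#' @param lesion_side One of `"left"`, `"right"`, `"subtentorial"`, `"none"`.
#' @return An object of class `alps_result` with `left`, `right`,
#'   `ipsilateral`, `contralateral`, `average`, `lesion_side`.
#' @export
lateralize <- function(left, right, lesion_side) {
  lesion_side <- match.arg(lesion_side,
                           c("left", "right", "subtentorial", "none"))
  if (lesion_side %in% c("left", "right")) {
    if (is.na(left) || is.na(right))
      stop("both hemispheric indices are required for a lateralized lesion")
    ipsi <- if (lesion_side == "left") left else right
    contra <- if (lesion_side == "left") right else left
    avg <- (ipsi + contra) / 2
  } else {
    if (is.na(left) || is.na(right))
      stop("both hemispheric indices are required to form the average")
    ipsi <- NA_real_; contra <- NA_real_
    avg <- (left + right) / 2
  }
  structure(list(left = left, right = right, ipsilateral = ipsi,
                 contralateral = contra, average = avg,
                 lesion_side = lesion_side),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat("DTI-ALPS index\n")
  cat(sprintf("  left  %.4f   right %.4f\n", x$left, x$right))
  if (!is.na(x$ipsilateral))
    cat(sprintf("  ipsilateral %.4f   contralateral %.4f   (lesion: %s)\n",
                x$ipsilateral, x$contralateral, x$lesion_side))
  cat(sprintf("  average %.4f\n", x$average))
  invisible(x)
}

#' Bilateral ALPS indices from axis-diffusivity maps and ROI definitions
#'
#' Convenience wrapper: extracts ROI means for the four ROIs (projection and
#' association, both hemispheres), computes the hemispheric ALPS indices, and
#' lateralizes them against the lesion side.
#'
#' @param maps Output of [axis_diffusivities()].
#' @param rois List of four `alps_roi` objects covering both fiber classes
#'   in both hemispheres.
#' @param voxdim Voxel size in mm.
#' @param lesion_side Passed to [lateralize()] (default `"none"`).
#' @return List with `result` (an `alps_result`) and `roi_means` (data frame
#'   of per-ROI mean diffusivities and voxel counts).
#' @export
alps_from_maps <- function(maps, rois, voxdim, lesion_side = "none") {
  tab <- do.call(rbind, lapply(rois, function(r) {
    m <- extract_roi_means(maps, r, voxdim)
    data.frame(hemisphere = r$hemisphere, fiber_class = r$fiber_class,
               Dx = m$Dx, Dy = m$Dy, Dz = m$Dz, n_voxels = m$n_voxels,
               stringsAsFactors = FALSE)
  }))
  hemi_index <- function(h) {
    p <- tab[tab$hemisphere == h & tab$fiber_class == "projection", ]
    a <- tab[tab$hemisphere == h & tab$fiber_class == "association", ]
    if (nrow(p) != 1 || nrow(a) != 1)
      stop("need exactly one projection and one association ROI for the ",
           h, " hemisphere")
    compute_alps(list(Dx_proj = p$Dx, Dy_proj = p$Dy, Dz_proj = p$Dz,
                      Dx_assoc = a$Dx, Dy_assoc = a$Dy, Dz_assoc = a$Dz))
  }
  res <- lateralize(hemi_index("left"), hemi_index("right"), lesion_side)
  list(result = res, roi_means = tab)
}

#' Suggest ALPS ROI centers from a color-FA map (advisory)
#'
#' Scans a periventricular search band on the given axial slice for the most
#' z-dominant (projection) and y-dominant (association) anisotropic voxel in
#' each hemisphere, mimicking how an operator picks ROI sites on the
#' direction-encoded FA image. The output is advisory: placement remains an
#' input to the analysis and should be reviewed.
#'
#' @param features A `tensor_features`.
#' @param slice Axial slice index (1-based).
#' @param diameter_mm Diameter recorded in the suggested ROIs.
#' @return List of four `alps_roi` objects.
#' @export
suggest_alps_rois <- function(features, slice, diameter_mm = 5) {
  cfa <- color_fa(features)
  dims <- dim(cfa)[1:3]
  if (slice < 1 || slice > dims[3]) stop("slice outside volume")
  mid <- (dims[1] + 1) / 2
  blue <- cfa[, , slice, 3]; green <- cfa[, , slice, 2]
  best <- function(score, side) {
    s <- score
    if (side == "left") s[seq_len(dims[1]) >= mid, ] <- -Inf
    else s[seq_len(dims[1]) <= mid, ] <- -Inf
    w <- which(s == max(s), arr.ind = TRUE)[1, ]
    c(w[1], w[2], slice)
  }
  list(
    roi_spec("left", "projection", best(blue, "left"), diameter_mm),
    roi_spec("right", "projection", best(blue, "right"), diameter_mm),
    roi_spec("left", "association", best(green, "left"), diameter_mm),
    roi_spec("right", "association", best(green, "right"), diameter_mm)
  )
}
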