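#' Specify a synthetic ALPS phantom
#'
#' Describes a digital diffusion-MRI phantom with the periventricular geometry
#' that the ALPS protocol reads: a CSF-filled ventricle body at the volume
#' center, projection-fiber tracts (principal diffusion axis
#' inferior-superior, z) immediately lateral to it on both sides, and
#' association-fiber tracts (principal axis anterior-posterior, y) lateral to
#' those, with deep medullary veins implied along x on a designated axial
#' slice. Optionally a nested hematoma/edema lesion pair is embedded in one
#' hemisphere.
#'
#' Coordinates are 1-based voxel indices on the phantom grid. The affine is
#' axis-aligned RAS with the origin at the volume center, so +x is
#' left-to-right, +y posterior-to-anterior, +z inferior-to-superior.
#'
#' @param grid Integer grid shape (nx, ny, nz).
#' @param voxdim Voxel size in mm; the default matches a 1.7 x 1.7 x 2 mm
#'   DTI protocol.
#' @param S0 Unweighted signal amplitude (arbitrary units).
#' @param scheme An `alps_scheme`; default 30 directions at b = 1000 with one
#'   b = 0 volume.
#' @param tensors Named list of 3x3 tensors or 6-vectors (mm^2/s) per region
#'   label. Recognised labels: `background`, `ventricle_CSF`,
#'   `projection_fiber` (or `_L`/`_R` variants), `association_fiber` (ditto),
#'   `hematoma`, `edema`. Omitted labels take the defaults below.
#' @param noise_sigma Rician noise level in signal units (0 = noiseless).
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @param lesion `NULL` for a healthy phantom, or a list with elements
#'   `hematoma` and `edema`, each `list(center = c(i,j,k), semiaxes =
#'   c(a,b,c))` in voxel units; the hematoma ellipsoid must be nested inside
#'   the edema (total lesion) ellipsoid.
#'
#' @details Default tissue tensors (phantom parameters, in mm^2/s):
#' isotropic 0.7e-3 background, isotropic 3.0e-3 CSF, projection fibers
#' diag(1.1, 0.6, 1.6)e-3, association fibers diag(1.0, 1.6, 0.84)e-3 --
#' chosen so the analytic ALPS index of the healthy phantom,
#' (1.1 + 1.0) / (0.6 + 0.84) = 1.458, sits near values reported for healthy
#' adults; isotropic 0.45e-3 hematoma (restricted diffusion) and 1.1e-3
#' vasogenic edema.
#'
#' @return An object of class `alps_phantom_spec`.
#' @export
phantom_spec <- function(grid = c(96, 96, 40),
                         voxdim = c(1.7, 1.7, 2),
                         S0 = 1000,
                         scheme = make_scheme(30, 1000, 1),
                         tensors = list(),
                         noise_sigma = 0,
                         seed = 1L,
                         lesion = NULL) {
  stopifnot(length(grid) == 3, all(grid >= 8), length(voxdim) == 3,
            all(voxdim > 0), S0 > 0)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  defaults <- default_phantom_tensors()
  known <- c(names(defaults), "projection_fiber", "association_fiber")
  bad <- setdiff(names(tensors), known)
  if (length(bad))
    stop("unknown region label in tensors: ", paste(bad, collapse = ", "))
  # a side-free fiber entry applies to both hemispheres
  for (fib in c("projection_fiber", "association_fiber")) {
    if (!is.null(tensors[[fib]])) {
      for (s in c("_L", "_R"))
        if (is.null(tensors[[paste0(fib, s)]]))
          tensors[[paste0(fib, s)]] <- tensors[[fib]]
      tensors[[fib]] <- NULL
    }
  }
  tens <- utils::modifyList(defaults, tensors)
  tens <- lapply(tens, as_tensor_matrix)
  for (nm in names(tens)) {
    ev <- eigen(tens[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stop("tensor for region '", nm, "' is not positive definite")
  }
  if (!is.null(lesion)) validate_lesion(lesion, grid)
  structure(list(grid = as.integer(grid), voxdim = voxdim, S0 = S0,
                 scheme = scheme, tensors = tens, noise_sigma = noise_sigma,
                 seed = as.integer(seed), lesion = lesion),
            class = "alps_phantom_spec")
}

default_phantom_tensors <- function() {
  iso <- function(d) diag(rep(d, 3))
  list(
    background          = iso(0.7e-3),
    ventricle_CSF       = iso(3.0e-3),
    projection_fiber_L  = diag(c(1.1e-3, 0.6e-3, 1.6e-3)),
    projection_fiber_R  = diag(c(1.1e-3, 0.6e-3, 1.6e-3)),
    association_fiber_L = diag(c(1.0e-3, 1.6e-3, 0.84e-3)),
    association_fiber_R = diag(c(1.0e-3, 1.6e-3, 0.84e-3)),
    hematoma            = iso(0.45e-3),
    edema               = iso(1.1e-3)
  )
}

validate_lesion <- function(lesion, grid) {
  if (!all(c("hematoma", "edema") %in% names(lesion)))
    stop("lesion must contain 'hematoma' and 'edema' ellipsoids")
  for (nm in c("hematoma", "edema")) {
    el <- lesion[[nm]]
    if (length(el$center) != 3 || length(el$semiaxes) != 3 ||
        any(el$semiaxes < 0))
      stop("lesion ellipsoid '", nm, "' needs center and nonnegative semiaxes")
  }
  invisible(TRUE)
}

phantom_labels <- function() {
  c("background", "ventricle_CSF",
    "projection_fiber_L", "projection_fiber_R",
    "association_fiber_L", "association_fiber_R",
    "hematoma", "edema")
}

# Integer label volume for the periventricular geometry. Left hemisphere is
# the low-x half (RAS: -x is the subject's left).
phantom_region_map <- function(spec) {
  g <- spec$grid
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2
  labs <- phantom_labels()
  lab <- array(1L, dim = g)  # background

  ix <- slice.index(lab, 1); iy <- slice.index(lab, 2); iz <- slice.index(lab, 3)
  # proportions of the grid; ventricle body spans a central z band,
  # fiber tracts span all slices so the DMV slice is unambiguous
  vw <- 0.07 * g[1]; vl <- 0.20 * g[2]
  gap1 <- 0.02 * g[1]; pw <- 0.06 * g[1]
  gap2 <- 0.03 * g[1]; aw <- 0.06 * g[1]
  fy <- 0.15 * g[2]
  zlo <- round(0.25 * g[3]); zhi <- round(0.85 * g[3])

  vent <- abs(ix - cx) <= vw & abs(iy - cy) <= vl & iz >= zlo & iz <= zhi
  lab[vent] <- 2L

  proj_off <- vw + gap1 + pw / 2
  asso_off <- vw + gap1 + pw + gap2 + aw / 2
  inb <- abs(iy - cy) <= fy
  lab[inb & abs(ix - (cx - proj_off)) <= pw / 2] <- 3L   # projection L
  lab[inb & abs(ix - (cx + proj_off)) <= pw / 2] <- 4L   # projection R
  lab[inb & abs(ix - (cx - asso_off)) <= aw / 2] <- 5L   # association L
  lab[inb & abs(ix - (cx + asso_off)) <= aw / 2] <- 6L   # association R

  if (!is.null(spec$lesion)) {
    hem <- ellipsoid_mask(g, spec$lesion$hematoma$center,
                          spec$lesion$hematoma$semiaxes)
    tot <- ellipsoid_mask(g, spec$lesion$edema$center,
                          spec$lesion$edema$semiaxes)
    if (any(hem & !tot))
      stop("hematoma not contained in total lesion")
    lab[tot] <- 8L  # edema
    lab[hem] <- 7L  # hematoma
  }

  dmv_slice <- round(0.55 * g[3])
  roi_centers <- data.frame(
    hemisphere  = c("left", "right", "left", "right"),
    fiber_class = c("projection", "projection", "association", "association"),
    i = round(c(cx - proj_off, cx + proj_off, cx - asso_off, cx + asso_off)),
    j = rep(round(cy), 4),
    k = rep(dmv_slice, 4),
    stringsAsFactors = FALSE
  )
  list(labels = lab, level_names = labs, roi_centers = roi_centers,
       dmv_slice = dmv_slice)
}

ellipsoid_mask <- function(grid, center, semiaxes) {
  m <- array(FALSE, dim = grid)
  if (any(semiaxes <= 0)) return(m)  # degenerate ellipsoid is empty
  ix <- slice.index(m, 1); iy <- slice.index(m, 2); iz <- slice.index(m, 3)
  ((ix - center[1]) / semiaxes[1])^2 +
    ((iy - center[2]) / semiaxes[2])^2 +
    ((iz - center[3]) / semiaxes[3])^2 <= 1
}

phantom_affine <- function(grid, voxdim) {
  a <- diag(c(voxdim, 1))
  a[1:3, 4] <- -voxdim * (grid - 1) / 2
  a
}

#' Build the synthetic diffusion-weighted phantom
#'
#' Renders the phantom described by a [phantom_spec()] into a 4-D
#' diffusion-weighted volume using the single-tensor signal model, and
#' returns the ground truth the tests need: the assigned per-voxel tensor
#' field, the ROI centers for both hemispheres, the analytic per-hemisphere
#' ALPS index implied by the assigned fiber tensors, and (when a lesion is
#' present) the binary hematoma / total-lesion masks.
#'
#' With `noise_sigma = 0` the signals are exactly the model prediction;
#' otherwise Rician noise is added under the spec's seed, so identical specs
#' produce bit-identical volumes.
#'
#' @param spec An `alps_phantom_spec`.
#' @return A list with elements `dwi` (class `alps_dwi`: 4-D `data`, `affine`,
#'   `voxdim`, `scheme`) and `truth` (class `alps_phantom_truth`).
#' @export
build_alps_phantom <- function(spec) {
  stopifnot(inherits(spec, "alps_phantom_spec"))
  rm_ <- phantom_region_map(spec)
  lab <- rm_$labels
  if (any(lab < 1L | lab > length(rm_$level_names)))
    stop("region map contains unknown label")
  nvol <- length(spec$scheme$bvals)
  # one signal profile per label, then index-map into the volume
  sig_by_label <- vapply(seq_along(rm_$level_names), function(l) {
    tensor_signal(spec$tensors[[rm_$level_names[l]]], spec$scheme, spec$S0)
  }, numeric(nvol))
  data <- array(0, dim = c(spec$grid, nvol))
  for (v in seq_len(nvol))
    data[, , , v] <- sig_by_label[v, ][lab]

  dwi <- structure(list(data = data,
                        affine = phantom_affine(spec$grid, spec$voxdim),
                        voxdim = spec$voxdim, scheme = spec$scheme),
                   class = "alps_dwi")
  if (spec$noise_sigma > 0)
    dwi <- add_rician_noise(dwi, spec$noise_sigma, seed = spec$seed)

  # ground-truth tensor field (6 unique components per voxel)
  vec6 <- vapply(rm_$level_names, function(nm) tensor_to_vec6(spec$tensors[[nm]]),
                 numeric(6))
  tfield <- array(0, dim = c(spec$grid, 6))
  for (c6 in 1:6)
    tfield[, , , c6] <- vec6[c6, ][lab]

  alps_true <- c(
    left  = analytic_alps(spec$tensors$projection_fiber_L,
                          spec$tensors$association_fiber_L),
    right = analytic_alps(spec$tensors$projection_fiber_R,
                          spec$tensors$association_fiber_R)
  )
  masks <- NULL
  if (!is.null(spec$lesion)) masks <- simulate_lesion_masks(spec)

  truth <- structure(list(tensor_field = tfield, region_labels = lab,
                          level_names = rm_$level_names,
                          roi_centers = rm_$roi_centers,
                          dmv_slice = rm_$dmv_slice,
                          alps_analytic = alps_true, lesion_masks = masks),
                     class = "alps_phantom_truth")
  list(dwi = dwi, truth = truth)
}

# ALPS index implied by assigned diagonal entries of the two fiber tensors.
analytic_alps <- function(D_proj, D_assoc) {
  (D_proj[1, 1] + D_assoc[1, 1]) / (D_proj[2, 2] + D_assoc[3, 3])
}

#' Add Rician noise to a diffusion-weighted volume
#'
#' Magnitude-MRI noise: each signal S is replaced by
#' sqrt((S + n1)^2 + n2^2) with n1, n2 ~ Normal(0, sigma), the distribution
#' of the magnitude of a complex Gaussian-corrupted signal.
#'
#' @param dwi An `alps_dwi`.
#' @param sigma Noise standard deviation in signal units (>= 0; 0 returns the
#'   input unchanged).
#' @param seed Optional integer seed for reproducibility.
#' @return The noisy `alps_dwi`.
#' @export
add_rician_noise <- function(dwi, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(dwi)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dwi$data)
  n1 <- stats::rnorm(n, 0, sigma)
  n2 <- stats::rnorm(n, 0, sigma)
  dwi$data <- array(sqrt((as.vector(dwi$data) + n1)^2 + n2^2),
                    dim = dim(dwi$data))
  dwi
}

#' Binary lesion masks from a phantom specification
#'
#' Rasterises the nested hematoma / total-lesion ellipsoids of a
#' [phantom_spec()] onto the phantom grid. The hematoma must be contained in
#' the total lesion; a zero-semiaxis hematoma yields an empty mask (pure
#' edema lesion).
#'
#' @param spec An `alps_phantom_spec` with a non-NULL `lesion`.
#' @return An object of class `alps_lesion_masks`: binary arrays `hematoma`
#'   and `total_lesion`, plus `voxdim` and `affine`.
#' @export
simulate_lesion_masks <- function(spec) {
  stopifnot(inherits(spec, "alps_phantom_spec"))
  if (is.null(spec$lesion)) stop("spec has no lesion block")
  hem <- ellipsoid_mask(spec$grid, spec$lesion$hematoma$center,
                        spec$lesion$hematoma$semiaxes)
  tot <- ellipsoid_mask(spec$grid, spec$lesion$edema$center,
                        spec$lesion$edema$semiaxes)
  if (any(hem & !tot)) stop("hematoma not contained in total lesion")
  structure(list(hematoma = hem * 1L, total_lesion = tot * 1L,
                 voxdim = spec$voxdim,
                 affine = phantom_affine(spec$grid, spec$voxdim)),
            class = "alps_lesion_masks")
}
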