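#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, estimates the seven parameters (ln S0 and the six unique tensor
#' components) that minimise the squared error of
#' ln S_i = ln S0 - b_i g_i' D g_i over the acquisition. The default is
#' ordinary least squares on the log-signals, solved for all voxels in one
#' matrix operation; `method = "wls"` adds one reweighting pass with weights
#' equal to the squared predicted signals, the standard variance-stabilising
#' correction for log-transformed Rician-corrupted magnitudes.
#'
#' Signals at or below zero are clamped to `clamp_frac` times the voxel's
#' mean b = 0 signal before the log; voxels whose signals are all zero are
#' dropped from the fit mask with a warning count.
#'
#' @param dwi An `alps_dwi` with >= 6 weighted directions and >= 1 b = 0
#'   volume.
#' @param mask Optional logical/0-1 array selecting voxels to fit (default:
#'   all).
#' @param method `"ols"` (default) or `"wls"`.
#' @param clamp_frac Signal floor as a fraction of the voxel's estimated S0.
#' @return An object of class `tensor_field`: `components` (4-D array, last
#'   dimension the 6 unique components in the order Dxx, Dyy, Dzz, Dxy, Dxz,
#'   Dyz, in mm^2/s), `S0`, logical `mask`, `voxdim`, `affine`,
#'   `n_clamped` (voxels needing the signal floor), and `method`.
#' @export
fit_tensor <- function(dwi, mask = NULL, method = c("ols", "wls"),
                       clamp_frac = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(dwi, "alps_dwi"))
  sch <- dwi$scheme
  if (sum(sch$bvals > 0) < 6 || sch$n_b0 < 1)
    stop("need >= 6 weighted directions and >= 1 b = 0 volume")
  X <- tensor_design_matrix(sch)
  if (qr(X)$rank < 7) stop("rank-deficient design matrix")

  g3 <- dim(dwi$data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = g3)
  mask <- array(as.logical(mask), dim = g3)

  nvol <- dim(dwi$data)[4]
  sig <- matrix(dwi$data, ncol = nvol)      # voxels x volumes
  idx <- which(mask)
  S <- sig[idx, , drop = FALSE]

  dead <- rowSums(S > 0) == 0
  if (any(dead)) {
    warning(sum(dead), " all-zero voxel(s) excluded from fit mask")
    mask[idx[dead]] <- FALSE
    idx <- idx[!dead]
    S <- S[!dead, , drop = FALSE]
  }

  s0hat <- rowMeans(S[, sch$bvals == 0, drop = FALSE])
  floorv <- pmax(clamp_frac * s0hat, .Machine$double.xmin)
  need_clamp <- S <= 0
  n_clamped <- sum(rowSums(need_clamp) > 0)
  if (n_clamped > 0)
    S[need_clamp] <- floorv[row(need_clamp)[need_clamp]]

  beta <- qr.coef(qr(X), t(log(S)))         # 7 x voxels
  if (method == "wls") {
    for (v in seq_along(idx)) {
      w <- as.vector(exp(X %*% beta[, v]))^2
      XtW <- t(X * w)
      beta[, v] <- solve(XtW %*% X, XtW %*% log(S[v, ]))
    }
  }

  comp <- array(0, dim = c(g3, 6))
  cm <- matrix(comp, ncol = 6)
  cm[idx, ] <- t(beta[2:7, , drop = FALSE])
  comp <- array(cm, dim = c(g3, 6))
  S0 <- array(0, dim = g3)
  S0[idx] <- exp(beta[1, ])

  structure(list(components = comp, S0 = S0, mask = mask,
                 voxdim = dwi$voxdim, affine = dwi$affine,
                 n_clamped = n_clamped, method = method),
            class = "tensor_field")
}

# Rows of the log-linear design: [1, -b gx^2, -b gy^2, -b gz^2,
#                                 -2b gx gy, -2b gx gz, -2b gy gz]
tensor_design_matrix <- function(scheme) {
  b <- scheme$bvals
  g <- t(scheme$bvecs)
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("Diffusion tensor field: %s grid, %d fitted voxels (%s fit, %d clamped)\n",
              paste(dim(x$components)[1:3], collapse = " x "),
              sum(x$mask), x$method, x$n_clamped))
  invisible(x)
}

#' Eigendecompose a tensor field
#'
#' Per masked voxel, returns the eigenvalues sorted in descending order and
#' the principal eigenvector with a deterministic sign convention (first
#' nonzero component positive; ties between eigenvalues are broken by index
#' order as returned by the symmetric solver).
#'
#' @param field A `tensor_field`.
#' @return An object of class `tensor_features` with `eigenvalues` (4-D, last
#'   dim 3, descending), `v1` (4-D, last dim 3, unit), `mask`, `voxdim`.
#' @export
eigendecompose <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  g3 <- dim(field$components)[1:3]
  idx <- which(field$mask)
  cm <- matrix(field$components, ncol = 6)
  ev <- matrix(0, length(idx), 3)
  v1 <- matrix(0, length(idx), 3)
  for (n in seq_along(idx)) {
    e <- eigen(as_tensor_matrix(cm[idx[n], ]), symmetric = TRUE)
    ev[n, ] <- e$values                 # eigen() sorts descending
    v <- e$vectors[, 1]
    nz <- which(abs(v) > 1e-12)
    if (length(nz) && v[nz[1]] < 0) v <- -v
    v1[n, ] <- v
  }
  evals <- array(0, dim = c(g3, 3)); v1a <- array(0, dim = c(g3, 3))
  em <- matrix(evals, ncol = 3); vm <- matrix(v1a, ncol = 3)
  em[idx, ] <- ev; vm[idx, ] <- v1
  structure(list(eigenvalues = array(em, c(g3, 3)),
                 v1 = array(vm, c(g3, 3)),
                 mask = field$mask, voxdim = field$voxdim),
            class = "tensor_features")
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2)),
#' the normalised eigenvalue dispersion: 0 for isotropic diffusion, 1 for a
#' stick. Vectorised over voxels; an all-zero triple returns 0.
#'
#' @param l1,l2,l3 Eigenvalue arrays/vectors (mm^2/s).
#' @return FA values in `[0, 1]` (same shape as the inputs).
#' @export
fractional_anisotropy <- function(l1, l2, l3) {
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  pmin(fa, 1)
}

#' Direction-encoded color FA map
#'
#' The conventional red-green-blue encoding of the principal diffusion
#' direction, modulated by anisotropy:
#' (r, g, b) = FA * (|v1x|, |v1y|, |v1z|), clipped to `[0, 1]`. Negative
#' estimated eigenvalues are clamped to zero for the FA modulation only.
#'
#' @param features A `tensor_features`.
#' @return 4-D array, last dimension 3 (r, g, b).
#' @export
color_fa <- function(features) {
  stopifnot(inherits(features, "tensor_features"))
  ev <- features$eigenvalues
  g3 <- dim(ev)[1:3]
  l <- lapply(1:3, function(k) pmax(array(ev[, , , k], g3), 0))
  fa <- fractional_anisotropy(l[[1]], l[[2]], l[[3]])
  out <- array(0, dim = c(g3, 3))
  for (k in 1:3)
    out[, , , k] <- pmin(pmax(fa * abs(array(features$v1[, , , k], g3)), 0), 1)
  out
}

#' Axis diffusivity maps (Dxx, Dyy, Dzz)
#'
#' The tensor diagonal in image axes: with the volume in canonical RAS
#' orientation these are the diffusivities along left-right (x),
#' anterior-posterior (y) and inferior-superior (z) that the ALPS index
#' reads. Their voxelwise sum equals the eigenvalue sum (trace invariance).
#'
#' @param field A `tensor_field`.
#' @return Named list of three 3-D arrays: `Dxx`, `Dyy`, `Dzz` (mm^2/s).
#' @export
axis_diffusivities <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  g3 <- dim(field$components)[1:3]
  list(Dxx = array(field$components[, , , 1], g3),
       Dyy = array(field$components[, , , 2], g3),
       Dzz = array(field$components[, , , 3], g3))
}
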