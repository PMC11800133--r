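# Shared fixtures and independent oracles, built in code at test time.

# A phantom small enough for fast fits but wide enough that a 5 mm ROI disc
# stays inside its fiber tract.
small_phantom_spec <- function(...) {
  phantom_spec(grid = c(48, 48, 16), voxdim = c(1.7, 1.7, 2), S0 = 500, ...)
}

# ROI list at the phantom's ground-truth centers.
truth_rois <- function(truth, diameter_mm = 5) {
  tr <- truth$roi_centers
  mapply(function(h, f, i, j, k) roi_spec(h, f, c(i, j, k), diameter_mm),
         tr$hemisphere, tr$fiber_class, tr$i, tr$j, tr$k, SIMPLIFY = FALSE)
}

# Full phantom -> fit -> ALPS pipeline, returning the alps_result.
pipeline_alps <- function(spec, lesion_side = "none") {
  ph <- build_alps_phantom(spec)
  field <- fit_tensor(ph$dwi)
  maps <- axis_diffusivities(field)
  res <- alps_from_maps(maps, truth_rois(ph$truth), spec$voxdim, lesion_side)
  list(result = res$result, truth = ph$truth)
}

# Exhaustive two-sided Fisher oracle: sum of hypergeometric probabilities not
# exceeding the observed table's, over all tables with the observed margins.
fisher_exact_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  pr <- dhyper(x, r1, r2, c1)
  sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)])
}

# Newton-Raphson logistic solver, independent of stats::glm.
logistic_newton_oracle <- function(X, y, tol = 1e-12, maxit = 100) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-as.vector(X1 %*% beta)))
    W <- p * (1 - p)
    step <- solve(t(X1) %*% (X1 * W), t(X1) %*% (y - p))
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Per-voxel log-linear solve through lm.fit, independent of the vectorised
# batch path in fit_tensor.
tensor_ols_oracle <- function(signals, scheme) {
  X <- glymphalps:::tensor_design_matrix(scheme)
  stats::lm.fit(X, log(signals))$coefficients
}
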