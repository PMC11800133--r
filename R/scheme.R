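#' Build a diffusion acquisition scheme
#'
#' Constructs a single-shell diffusion-weighted acquisition: `n_b0` unweighted
#' (b = 0) volumes followed by `n_directions` weighted volumes at b-value `b`.
#' Gradient directions are a deterministic spherical Fibonacci point set, which
#' is near-uniform on the sphere and reproducible for any direction count.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6; six is
#'   the identifiability limit of the symmetric tensor plus S0).
#' @param b b-value of the weighted volumes in s/mm^2 (default 1000).
#' @param n_b0 Number of unweighted volumes (>= 1, default 1).
#' @return An object of class `alps_scheme`: a list with `bvals` (length
#'   `n_b0 + n_directions`), `bvecs` (3 x n volumes matrix; zero columns for
#'   b = 0), and `n_b0`.
#' @examples
#' sch <- make_scheme(30, b = 1000, n_b0 = 1)
#' length(sch$bvals)  # 31
#' @export
make_scheme <- function(n_directions, b = 1000, n_b0 = 1) {
  if (n_directions < 6)
    stop("tensor not identifiable: need at least 6 diffusion directions")
  if (b <= 0) stop("b must be positive")
  if (n_b0 < 1) stop("need at least one b = 0 volume")
  dirs <- fibonacci_sphere(n_directions)
  bvals <- c(rep(0, n_b0), rep(b, n_directions))
  mk <- function(d) {
    bv <- cbind(matrix(0, 3, n_b0), t(d))
    dimnames(bv) <- NULL
    structure(list(bvals = bvals, bvecs = bv, n_b0 = n_b0),
              class = "alps_scheme")
  }
  sch <- mk(dirs)
  # small direction counts can hit symmetry accidents of the lattice that
  # leave the tensor design rank-deficient; break them with a tiny
  # deterministic index-dependent jitter
  if (qr(tensor_design_matrix(sch))$rank < 7) {
    i <- seq_len(n_directions)
    dirs <- dirs + 0.02 * cbind(sin(i), cos(2 * i), sin(3 * i + 1))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sch <- mk(dirs)
  }
  sch
}

#' @export
print.alps_scheme <- function(x, ...) {
  nw <- sum(x$bvals > 0)
  cat(sprintf("Diffusion acquisition scheme: %d volumes (%d b=0, %d weighted at b=%g s/mm^2)\n",
              length(x$bvals), x$n_b0, nw, max(x$bvals)))
  invisible(x)
}

# Spherical Fibonacci lattice: n unit vectors, deterministic, near-uniform.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i        # golden-angle longitude
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Predict single-tensor diffusion-weighted signals
#'
#' Evaluates the monoexponential single-tensor signal model
#' S_i = S0 * exp(-b_i * g_i' D g_i) for every volume of a scheme.
#'
#' @param D Symmetric 3x3 diffusion tensor (mm^2/s), or a length-6 vector
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#' @param scheme An `alps_scheme`.
#' @param S0 Unweighted signal amplitude (default 1).
#' @return Numeric vector of signals, one per scheme volume; b = 0 entries
#'   equal `S0` exactly.
#' @export
tensor_signal <- function(D, scheme, S0 = 1) {
  D <- as_tensor_matrix(D)
  g <- scheme$bvecs
  # quadratic form g'Dg per volume, vectorised over columns of g
  q <- colSums(g * (D %*% g))
  S0 * exp(-scheme$bvals * q)
}

# Accept a 3x3 symmetric matrix or the 6-vector (xx, yy, zz, xy, xz, yz).
as_tensor_matrix <- function(D) {
  if (is.matrix(D)) {
    if (!all(dim(D) == c(3, 3))) stop("tensor must be 3x3")
    if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D))))
      stop("tensor must be symmetric")
    return(D)
  }
  if (length(D) != 6) stop("tensor must be 3x3 or a length-6 vector")
  matrix(c(D[1], D[4], D[5],
           D[4], D[2], D[6],
           D[5], D[6], D[3]), 3, 3)
}

# Inverse of as_tensor_matrix: unique components in (xx, yy, zz, xy, xz, yz).
tensor_to_vec6 <- function(D) {
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}
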