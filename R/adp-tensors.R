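#' Anisotropic displacement tensors
#'
#' An ADP is a symmetric 3x3 mean-square displacement tensor in Angstrom^2,
#' stored as its six independent components in the order
#' u11, u22, u33, u23, u13, u12 together with a basis tag:
#' `"cif_star"` for components referred to the reciprocal-axis basis used by
#' CIF and SHELX (the dimensionless U^ij convention), `"cartesian"` for
#' components on an orthonormal frame.
#'
#' @param u11,u22,u33,u23,u13,u12 tensor components in Angstrom^2
#' @param basis `"cif_star"` or `"cartesian"`
#' @return an object of class `adp_tensor`: numeric length-6 with a basis
#'   attribute
#' @export
adp_tensor <- function(u11, u22, u33, u23 = 0, u13 = 0, u12 = 0,
                       basis = c("cartesian", "cif_star")) {
  basis <- match.arg(basis)
  u <- c(u11, u22, u33, u23, u13, u12)
  if (length(u) != 6 || !all(is.finite(u))) stop("ADP needs six finite components")
  structure(u, basis = basis, class = "adp_tensor",
            names = c("u11", "u22", "u33", "u23", "u13", "u12"))
}

adp_basis <- function(u) {
  b <- attr(u, "basis")
  if (is.null(b)) stop("object carries no ADP basis tag")
  b
}

#' @export
print.adp_tensor <- function(x, ...) {
  cat(sprintf("ADP [%s]: ", adp_basis(x)))
  cat(sprintf("%8.5f", unclass(x)), "\n")
  invisible(x)
}

# six components <-> symmetric 3x3
u6_to_mat <- function(u) {
  matrix(c(u[1], u[6], u[5],
           u[6], u[2], u[4],
           u[5], u[4], u[3]), nrow = 3)
}

mat_to_u6 <- function(M) {
  c(M[1, 1], M[2, 2], M[3, 3], M[2, 3], M[1, 3], M[1, 2])
}

#' Equivalent isotropic displacement, trace(U)/3
#' @param u an `adp_tensor` (Cartesian) or length-6 vector
#' @return U_iso in Angstrom^2
#' @export
u_iso <- function(u) sum(u[1:3]) / 3

is_psd <- function(M, tol = 1e-8) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol
}

#' Convert an ADP from the CIF reciprocal basis to Cartesian
#'
#' Applies `U_cart = A D U_cif D A^T` with `D = diag(a*, b*, c*)` and `A` the
#' orthogonalization matrix of the cell. The quadratic form (and hence
#' positive definiteness) is preserved.
#'
#' @param u an `adp_tensor` with basis `"cif_star"`
#' @param cell a `unit_cell`
#' @return an `adp_tensor` with basis `"cartesian"`
#' @export
cif_to_cartesian <- function(u, cell) {
  if (adp_basis(u) != "cif_star") stop("input ADP is not on the cif_star basis")
  A <- cell_matrix(cell)
  D <- diag(reciprocal_lengths(cell))
  M <- A %*% D %*% u6_to_mat(u) %*% D %*% t(A)
  v <- mat_to_u6((M + t(M)) / 2)
  adp_tensor(v[1], v[2], v[3], v[4], v[5], v[6], basis = "cartesian")
}

#' Convert an ADP from Cartesian to the CIF reciprocal basis
#'
#' Exact inverse of [cif_to_cartesian()].
#'
#' @inheritParams cif_to_cartesian
#' @param u an `adp_tensor` with basis `"cartesian"`
#' @return an `adp_tensor` with basis `"cif_star"`
#' @export
cartesian_to_cif <- function(u, cell) {
  if (adp_basis(u) != "cartesian") stop("input ADP is not on the cartesian basis")
  A <- cell_matrix(cell)
  if (abs(det(A)) < 1e-12) stop("singular cell matrix")
  Dinv <- diag(1 / reciprocal_lengths(cell))
  Ainv <- solve(A)
  M <- Dinv %*% Ainv %*% u6_to_mat(u) %*% t(Ainv) %*% Dinv
  v <- mat_to_u6((M + t(M)) / 2)
  adp_tensor(v[1], v[2], v[3], v[4], v[5], v[6], basis = "cif_star")
}

#' Hirshfeld rigid-bond projection difference
#'
#' For two atoms A and B with Cartesian ADPs, computes
#' `abs(n' U_A n - n' U_B n)` with `n` the unit vector along the interatomic
#' direction. For a rigid pair the two projections are equal and the
#' difference vanishes.
#'
#' @param uA,uB Cartesian `adp_tensor`s (or length-6 vectors)
#' @param rA,rB Cartesian positions in Angstrom
#' @return the projection difference Delta in Angstrom^2 (>= 0)
#' @export
bond_projection_delta <- function(uA, uB, rA, rB) {
  d <- as.numeric(rB) - as.numeric(rA)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-10) stop("coincident atomic positions")
  n <- d / nd
  pa <- drop(t(n) %*% u6_to_mat(uA) %*% n)
  pb <- drop(t(n) %*% u6_to_mat(uB) %*% n)
  abs(pa - pb)
}

#' Gaussian-overlap similarity statistic S for two ADPs
#'
#' Treats each ADP as the covariance of a trivariate Gaussian probability
#' density and measures their spatial overlap
#' `R12 = integral sqrt(p1 p2) dr`, which has the closed form
#' `2^(3/2) (det U1 det U2)^(1/4) / det(U1 + U2)^(1/2)`.
#' The statistic `S = 100 (1 - R12)` is 0 for identical tensors and
#' approaches 100 when the two densities do not overlap at all.
#'
#' @param u1,u2 positive-definite Cartesian `adp_tensor`s
#' @return S, dimensionless in \[0, 100\]
#' @export
overlap_similarity_s <- function(u1, u2) {
  M1 <- u6_to_mat(u1)
  M2 <- u6_to_mat(u2)
  for (nm in c("first", "second")) {
    M <- if (nm == "first") M1 else M2
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("the ", nm, " ADP is not positive definite")
  }
  r12 <- 2^1.5 * (det(M1) * det(M2))^0.25 / sqrt(det(M1 + M2))
  # clamp rounding spill just outside the theoretical range [0, 100]
  min(100, max(0, 100 * (1 - r12)))
}

#' Fit a scaling model between two matched sets of ADPs
#'
#' Fits `U_target ~ kappa * U_source + offset` by least squares over all
#' matched pairs, where `kappa` is a single multiplicative scale and `offset`
#' a symmetric additive tensor (6 components). The objective is the summed
#' squared Frobenius norm of the per-atom residual tensors. This is the
#' standard device for bringing displacement parameters from two refinements
#' (e.g. X-ray derived estimates and a neutron model) onto a common scale.
#'
#' @param source,target lists of Cartesian `adp_tensor`s (or length-6
#'   vectors), matched elementwise; at least 7 pairs
#' @param scale_only if `TRUE`, fit kappa with the offset fixed at zero
#' @return a list of class `adp_scaling` with `kappa`, `offset` (length-6),
#'   `rms` (root-mean-square residual over all 6N components, Angstrom^2)
#' @export
fit_adp_scaling <- function(source, target, scale_only = FALSE) {
  if (length(source) != length(target)) stop("source/target length mismatch")
  n <- length(source)
  if (scale_only && n < 1) stop("need at least one pair")
  if (!scale_only && n < 7) stop("need at least 7 matched pairs for kappa + offset")
  # rows: 6 components per pair; off-diagonal rows weighted sqrt(2) so the
  # objective is the Frobenius norm of the 3x3 residual
  w <- sqrt(c(1, 1, 1, 2, 2, 2))
  src <- t(vapply(source, as.numeric, numeric(6)))
  tgt <- t(vapply(target, as.numeric, numeric(6)))
  W <- matrix(w, nrow = n, ncol = 6, byrow = TRUE)
  y <- as.vector(t(tgt * W))
  Xk <- as.vector(t(src * W))
  if (scale_only) {
    X <- matrix(Xk, ncol = 1)
  } else {
    Xoff <- do.call(rbind, replicate(n, diag(w), simplify = FALSE))
    X <- cbind(Xk, Xoff)
  }
  sv <- svd(X)
  keep <- sv$d > 1e-10 * sv$d[1]
  if (sum(keep) < ncol(X)) {
    warning("degenerate design in ADP scaling fit; minimum-norm solution returned")
  }
  coefs <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  kappa <- coefs[1]
  offset <- if (scale_only) numeric(6) else coefs[2:7]
  if (kappa <= 0) warning("fitted kappa is non-positive")
  resid <- tgt - (kappa * src + matrix(offset, n, 6, byrow = TRUE))
  structure(list(kappa = kappa, offset = offset,
                 rms = sqrt(mean(resid^2)), n = n),
            class = "adp_scaling")
}

#' @export
print.adp_scaling <- function(x, ...) {
  cat(sprintf("ADP scaling: kappa = %.6f, rms residual = %.3e A^2 (%d pairs)\n",
              x$kappa, x$rms, x$n))
  cat("offset:", sprintf("%9.2e", x$offset), "\n")
  invisible(x)
}

#' Apply a fitted ADP scaling to a tensor
#'
#' @param u a Cartesian `adp_tensor`
#' @param scaling an `adp_scaling` from [fit_adp_scaling()]
#' @return the scaled Cartesian `adp_tensor` `kappa * U + offset`; a warning
#'   is raised if the result is not positive semidefinite
#' @export
apply_adp_scaling <- function(u, scaling) {
  if (scaling$kappa <= 0) stop("kappa must be positive")
  v <- scaling$kappa * as.numeric(u) + scaling$offset
  out <- adp_tensor(v[1], v[2], v[3], v[4], v[5], v[6], basis = "cartesian")
  if (!is_psd(u6_to_mat(out))) {
    warning("scaled ADP is not positive semidefinite")
  }
  out
}
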