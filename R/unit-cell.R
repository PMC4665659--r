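#' Crystallographic unit cell
#'
#' Constructs a unit-cell object from the six cell parameters. Lengths are in
#' Angstrom, angles in degrees. The orthogonalization convention used
#' throughout the package places the crystal a axis along Cartesian x and the
#' b axis in the xy plane (right-handed); this is the common PDB convention
#' and is recorded here because file round trips depend on it even though the
#' tensor algebra does not.
#'
#' @param a,b,c cell edge lengths in Angstrom (> 0)
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @return an object of class `unit_cell`
#' @examples
#' cell <- unit_cell(7.1, 8.2, 9.3, 95, 101, 112)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
    class = "unit_cell"
  )
  if (cell_volume(cell) <= 0) stop("cell parameters give non-positive volume")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param cell a `unit_cell`
#' @return volume in Angstrom^3
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(-1)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Orthogonalization matrix (fractional -> Cartesian)
#'
#' Returns the 3x3 matrix `A` such that `r_cart = A %*% r_frac`, under the
#' a-along-x, b-in-xy convention.
#'
#' @param cell a `unit_cell`
#' @return 3x3 numeric matrix (Angstrom)
#' @export
cell_matrix <- function(cell) {
  al <- cell$alpha * pi / 180
  be <- cell$beta * pi / 180
  ga <- cell$gamma * pi / 180
  v <- cell_volume(cell) / (cell$a * cell$b * cell$c)
  matrix(c(
    cell$a, cell$b * cos(ga), cell$c * cos(be),
    0,      cell$b * sin(ga), cell$c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0,      0,                cell$c * v / sin(ga)
  ), nrow = 3, byrow = TRUE)
}

#' Reciprocal cell edge lengths (a*, b*, c*) in 1/Angstrom
#' @param cell a `unit_cell`
#' @return numeric length-3 vector
#' @export
reciprocal_lengths <- function(cell) {
  A <- cell_matrix(cell)
  G <- crossprod(A)           # direct metric tensor
  Gs <- solve(G)              # reciprocal metric tensor
  sqrt(diag(Gs))
}

frac_to_cart <- function(frac, cell) {
  A <- cell_matrix(cell)
  t(A %*% t(as.matrix(frac)))
}

cart_to_frac <- function(cart, cell) {
  Ainv <- solve(cell_matrix(cell))
  t(Ainv %*% t(as.matrix(cart)))
}
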