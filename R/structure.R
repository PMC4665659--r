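#' Crystal structure container
#'
#' Holds a unit cell, an ordered atom table, symmetry operator strings and
#' optional measurement temperature. Anisotropic displacement components are
#' stored on the CIF reciprocal-axis basis (u11, u22, u33, u23, u13, u12)
#' regardless of the dialect they were read from; readers convert on input
#' and writers convert back on output.
#'
#' @param cell a `unit_cell`
#' @param atoms a data.frame with columns `label`, `element`, `fx`, `fy`,
#'   `fz` (fractional coordinates), and optionally `occ`, `uiso`,
#'   `u11`...`u12` (cif_star basis; `NA` where absent)
#' @param symmetry character vector of symmetry operator strings
#'   (e.g. `"x,y,z"`)
#' @param temperature measurement temperature in kelvin, or `NA`
#' @param dialect source-format tag
#' @return an object of class `crystal_structure`
#' @export
crystal_structure <- function(cell, atoms, symmetry = "x,y,z",
                              temperature = NA_real_, dialect = "r") {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  if (nrow(atoms) < 1) stop("structure must contain at least one atom")
  need <- c("label", "element", "fx", "fy", "fz")
  if (!all(need %in% names(atoms))) {
    stop("atom table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(atoms$label)) stop("duplicate atom labels")
  if (any(!nzchar(atoms$label))) stop("empty atom label")
  if (!all(is.finite(as.matrix(atoms[, c("fx", "fy", "fz")])))) {
    stop("non-finite fractional coordinates")
  }
  atoms$element <- normalize_element(atoms$element)
  atomic_number(atoms$element)  # validates symbols
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$uiso)) atoms$uiso <- NA_real_
  for (cmp in c("u11", "u22", "u33", "u23", "u13", "u12")) {
    if (is.null(atoms[[cmp]])) atoms[[cmp]] <- NA_real_
  }
  atoms$is_h <- atoms$element == "H"
  if (!is.na(temperature) && temperature <= 0) stop("temperature must be positive")
  rownames(atoms) <- NULL
  structure(list(cell = cell, atoms = atoms, symmetry = symmetry,
                 temperature = temperature, dialect = dialect),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  n <- nrow(x$atoms)
  cat(sprintf("crystal structure: %d atoms (%d H), dialect '%s'\n",
              n, sum(x$atoms$is_h), x$dialect))
  print(x$cell)
  if (!is.na(x$temperature)) cat(sprintf("temperature: %.1f K\n", x$temperature))
  cat(sprintf("anisotropic ADPs on %d atoms\n", sum(!is.na(x$atoms$u11))))
  invisible(x)
}

#' Cartesian atomic positions of a structure
#' @param s a `crystal_structure`
#' @return n x 3 matrix of Cartesian coordinates in Angstrom
#' @export
atom_positions <- function(s) {
  pos <- frac_to_cart(as.matrix(s$atoms[, c("fx", "fy", "fz")]), s$cell)
  rownames(pos) <- s$atoms$label
  pos
}

has_aniso <- function(s) !is.na(s$atoms$u11)

#' Cartesian ADP of one atom
#'
#' Returns atom `i`'s anisotropic displacement tensor converted to the
#' Cartesian basis as a length-6 vector (u11, u22, u33, u23, u13, u12), or
#' `NULL` when the atom carries no anisotropic record.
#'
#' @param s a `crystal_structure`
#' @param i atom index
#' @return numeric length-6 vector in Angstrom^2, or `NULL`
#' @export
atom_adp_cart <- function(s, i) {
  a <- s$atoms[i, ]
  if (!is.na(a$u11)) {
    u <- adp_tensor(a$u11, a$u22, a$u33, a$u23, a$u13, a$u12, basis = "cif_star")
    return(as.numeric(cif_to_cartesian(u, s$cell)))
  }
  NULL
}

# Set atom i's ADP from Cartesian components (stored as cif_star).
set_atom_adp_cart <- function(s, i, u_cart) {
  u <- adp_tensor(u_cart[1], u_cart[2], u_cart[3], u_cart[4], u_cart[5],
                  u_cart[6], basis = "cartesian")
  v <- as.numeric(cartesian_to_cif(u, s$cell))
  s$atoms[i, c("u11", "u22", "u33", "u23", "u13", "u12")] <- as.list(v)
  s
}

# TRUE when any atom shares a site through partial occupancy (disorder guard).
detect_disorder <- function(s) {
  any(s$atoms$occ < 1 - 1e-6)
}

# Special-position / polymer guard: any symmetry image (non-identity op, with
# lattice translations in -1..1) within bonding distance of an atom.
detect_special_positions <- function(s, tolerance = 0.4) {
  ops <- setdiff(trimws(tolower(gsub(" ", "", s$symmetry))), "x,y,z")
  if (length(ops) == 0) return(FALSE)
  frac <- as.matrix(s$atoms[, c("fx", "fy", "fz")])
  A <- cell_matrix(s$cell)
  rmax <- max(covalent_radius(s$atoms$element))
  cutoff <- 2 * rmax + tolerance
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (op in ops) {
    img <- apply_symop(op, frac)
    for (k in seq_len(nrow(shifts))) {
      d <- frac - (img + matrix(shifts[k, ], nrow(frac), 3, byrow = TRUE))
      dc <- d %*% t(A)
      dist <- sqrt(rowSums(dc^2))
      if (any(dist < cutoff)) return(TRUE)
    }
  }
  FALSE
}

# Evaluate a symmetry-operator string like "-x,y+1/2,-z" on fractional coords.
apply_symop <- function(op, frac) {
  parts <- strsplit(op, ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", op)
  out <- matrix(0, nrow(frac), 3)
  env0 <- list()
  for (j in 1:3) {
    expr <- parse(text = parts[j])[[1]]
    for (i in seq_len(nrow(frac))) {
      out[i, j] <- eval(expr, list(x = frac[i, 1], y = frac[i, 2], z = frac[i, 3]))
    }
  }
  out
}
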