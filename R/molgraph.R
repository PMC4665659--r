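#' Build the molecular bond graph of a structure
#'
#' Two atoms are bonded when their Cartesian distance does not exceed the sum
#' of their covalent radii plus `tolerance`. Hydrogen atoms are constrained
#' to a single bond: when an H atom has several in-range neighbours only the
#' shortest contact is kept.
#'
#' @param s a [crystal_structure()]
#' @param tolerance bonding tolerance in Angstrom added to the
#'   covalent-radius sum (default 0.40, standard crystallographic practice)
#' @return an object of class `mol_graph` with elements `edges` (data.frame
#'   `i`, `j`, `length`, `ring`), `molecule` (component index per atom),
#'   `structure`, and the underlying igraph object
#' @export
detect_bonds <- function(s, tolerance = 0.40) {
  pos <- atom_positions(s)
  n <- nrow(pos)
  rc <- covalent_radius(s$atoms$element)
  d <- as.matrix(stats::dist(pos))
  cut <- outer(rc, rc, "+") + tolerance
  adj <- d <= cut & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      length = d[idx])
  # enforce degree 1 for hydrogen: keep the shortest candidate only
  for (h in which(s$atoms$is_h)) {
    mine <- which(edges$i == h | edges$j == h)
    if (length(mine) > 1) {
      keep <- mine[which.min(edges$length[mine])]
      edges <- edges[-setdiff(mine, keep), , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  # deterministic component numbering by lowest atom index
  first <- vapply(split(seq_len(n), comp), min, numeric(1))
  relabel <- match(comp, names(sort(first)))
  molecule <- rank(first)[as.character(comp)]
  names(molecule) <- NULL
  iso <- which(tabulate(molecule) == 1)
  if (n > 1 && length(iso) > 0) {
    warning("isolated atom(s) with no bonds: ",
            paste(s$atoms$label[molecule %in% iso], collapse = ", "))
  }
  # ring membership: an edge is in a ring iff it is not a bridge
  br <- igraph::bridges(g)
  bridge_edge <- rep(FALSE, nrow(edges))
  if (length(br) > 0) {
    ends <- igraph::ends(g, br)
    key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    bkey <- paste(pmin(as.numeric(ends[, 1]), as.numeric(ends[, 2])),
                  pmax(as.numeric(ends[, 1]), as.numeric(ends[, 2])))
    bridge_edge <- key %in% bkey
  }
  edges$ring <- !bridge_edge
  structure(list(edges = edges, molecule = molecule, structure = s,
                 graph = g, tolerance = tolerance),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("molecular graph: %d atoms, %d bonds, %d molecule(s)\n",
              length(x$molecule), nrow(x$edges), max(x$molecule)))
  invisible(x)
}

#' Connected components (molecules) of a bond graph
#'
#' @param g a `mol_graph`
#' @return list of integer vectors of atom indices, ordered by lowest atom
#'   index
#' @export
molecules <- function(g) {
  unname(lapply(split(seq_along(g$molecule), g$molecule), unname))
}

# neighbours of atom i
graph_neighbors <- function(g, i) {
  c(g$edges$j[g$edges$i == i], g$edges$i[g$edges$j == i])
}

#' Candidate torsion axes of a molecule
#'
#' Returns the bonds of the non-hydrogen skeleton whose removal disconnects
#' the molecule (bridges). These approximate the single bonds about which a
#' torsional libration of an attached rigid group is physically possible;
#' ring bonds are excluded automatically because they are not bridges.
#'
#' @param g a `mol_graph`
#' @param molecule integer vector of atom indices (one component of
#'   [molecules()])
#' @return data.frame with columns `i`, `j` (atom indices of each axis bond)
#' @export
candidate_torsion_axes <- function(g, molecule) {
  s <- g$structure
  heavy <- molecule[!s$atoms$is_h[molecule]]
  if (length(heavy) < 2) return(data.frame(i = integer(0), j = integer(0)))
  e <- g$edges
  keep <- e$i %in% heavy & e$j %in% heavy
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) return(data.frame(i = integer(0), j = integer(0)))
  sub <- igraph::graph_from_data_frame(
    data.frame(from = match(e$i, heavy), to = match(e$j, heavy)),
    directed = FALSE, vertices = data.frame(name = seq_along(heavy)))
  br <- igraph::bridges(sub)
  if (length(br) == 0) return(data.frame(i = integer(0), j = integer(0)))
  ends <- igraph::ends(sub, br)
  out <- data.frame(i = heavy[as.numeric(ends[, 1])],
                    j = heavy[as.numeric(ends[, 2])])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Split a molecule into attached rigid group and body at a bridge bond
#'
#' Removes the bond and returns the two resulting atom sets. The smaller set
#' (total atom count, hydrogens included) is the attached rigid group (ARG);
#' on a tie the set containing the lower-indexed bond endpoint is taken as
#' the body.
#'
#' @param g a `mol_graph`
#' @param molecule atom indices of the molecule
#' @param bond length-2 vector (i, j) of atom indices of a bridge bond
#' @return list with `arg` and `body` integer vectors
#' @export
split_by_bond <- function(g, molecule, bond) {
  i <- bond[1]; j <- bond[2]
  e <- g$edges
  inmol <- e$i %in% molecule & e$j %in% molecule
  drop <- (e$i == i & e$j == j) | (e$i == j & e$j == i)
  if (!any(drop & inmol)) stop("bond is not part of the molecule")
  e2 <- e[inmol & !drop, , drop = FALSE]
  sub <- igraph::graph_from_data_frame(
    data.frame(from = match(e2$i, molecule), to = match(e2$j, molecule)),
    directed = FALSE, vertices = data.frame(name = seq_along(molecule)))
  comp <- igraph::components(sub)$membership
  ci <- comp[match(i, molecule)]
  cj <- comp[match(j, molecule)]
  if (ci == cj) stop("bond is not a bridge of the molecule")
  set_i <- molecule[comp == ci]
  set_j <- molecule[comp == cj]
  if (length(set_i) < length(set_j)) {
    list(arg = set_i, body = set_j)
  } else if (length(set_j) < length(set_i)) {
    list(arg = set_j, body = set_i)
  } else {
    # tie: body is the side holding the lower-indexed endpoint
    lo <- min(i, j)
    if (lo %in% set_i) list(arg = set_j, body = set_i)
    else list(arg = set_i, body = set_j)
  }
}

#' Chemical-environment (invariom-style) name of an atom
#'
#' For a hydrogen atom bonded to parent X with other neighbours N1, N2, ...
#' the name is `H1x[1n1 1n2 ...]` without spaces, all element symbols after
#' the leading H in lower case, neighbours sorted by descending atomic
#' number; the digit 1 is the (assumed single) bond order. A methyl H whose
#' parent carbon also binds C, H, H is thus `H1c[1c1h1h]` and a hydroxyl H
#' whose oxygen binds one further C is `H1o[1c]`. For non-H atoms an
#' analogous two-shell descriptor is produced, used only as a cache key.
#'
#' @param g a `mol_graph`
#' @param atom atom index
#' @return the environment name string
#' @export
environment_name <- function(g, atom) {
  s <- g$structure
  nb <- graph_neighbors(g, atom)
  tok <- function(els) {
    if (length(els) == 0) return("")
    z <- atomic_number(els)
    paste0("1", tolower(els[order(-z, tolower(els))]), collapse = "")
  }
  if (s$atoms$is_h[atom]) {
    if (length(nb) != 1) {
      stop("hydrogen atom ", s$atoms$label[atom], " has degree ", length(nb))
    }
    parent <- nb[1]
    others <- setdiff(graph_neighbors(g, parent), atom)
    paste0("H1", tolower(s$atoms$element[parent]),
           "[", tok(s$atoms$element[others]), "]")
  } else {
    # non-H: element + sorted first shell + per-neighbour second shell
    z <- atomic_number(s$atoms$element[nb])
    sub <- vapply(nb, function(k) {
      second <- setdiff(graph_neighbors(g, k), atom)
      paste0("1", tolower(s$atoms$element[k]),
             "(", tok(s$atoms$element[second]), ")")
    }, character(1))
    ord <- order(-z, sub)
    paste0(s$atoms$element[atom], "[", paste(sub[ord], collapse = ""), "]")
  }
}

#' Deterministic local atomic frame
#'
#' Builds a proper orthonormal frame attached to an atom, used to transfer
#' internal ADP tensors between chemically equivalent atoms in different
#' orientations. The local z axis points from the atom to its
#' highest-priority neighbour (priority: atomic number descending, then
#' label ascending); the local x axis points toward the highest-priority
#' second-shell neighbour, orthogonalized against z; y completes a
#' right-handed frame. When no second-shell neighbour exists the global x
#' axis (projected perpendicular to z) is used.
#'
#' @param g a `mol_graph`
#' @param atom atom index
#' @return list of class `local_frame` with `origin` (atom index) and
#'   `rotation` (3x3 matrix mapping local to global Cartesian)
#' @export
local_frame <- function(g, atom) {
  s <- g$structure
  pos <- atom_positions(s)
  nb <- graph_neighbors(g, atom)
  if (length(nb) == 0) stop("atom ", s$atoms$label[atom], " has no bonds")
  prio <- order(-atomic_number(s$atoms$element[nb]), s$atoms$label[nb])
  parent <- nb[prio[1]]
  z <- pos[parent, ] - pos[atom, ]
  z <- z / sqrt(sum(z^2))
  second <- setdiff(graph_neighbors(g, parent), atom)
  xref <- NULL
  if (length(second) > 0) {
    p2 <- order(-atomic_number(s$atoms$element[second]), s$atoms$label[second])
    cand <- pos[second[p2[1]], ] - pos[atom, ]
    proj <- cand - sum(cand * z) * z
    if (sqrt(sum(proj^2)) > 1e-6) xref <- proj
  }
  if (is.null(xref)) {
    # fall back to the global x axis projected perpendicular to z
    gx <- c(1, 0, 0)
    proj <- gx - sum(gx * z) * z
    if (sqrt(sum(proj^2)) < 1e-6) {
      gy <- c(0, 1, 0)
      proj <- gy - sum(gy * z) * z
    }
    xref <- proj
  }
  x <- xref / sqrt(sum(xref^2))
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- cbind(x, y, z)
  dimnames(R) <- NULL
  structure(list(origin = atom, rotation = R), class = "local_frame")
}
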