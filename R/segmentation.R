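#' Rigidity index of a candidate attached rigid group
#'
#' Evaluates the empirical rigidity index for one candidate torsion axis.
#' `delta_intra` collects the Hirshfeld rigid-bond projection differences
#' over bonded non-H pairs inside the candidate group; `delta_inter`
#' collects the projection differences over all non-H cross pairs (one atom
#' in the group, one in the body, projected along the pair vector). The
#' index is
#' `Omega = epsilon * mean(delta_intra) - mean(delta_inter)`,
#' with `mean(delta_intra) = 0` when the group contains no bonded non-H
#' pair. A negative Omega accepts the group: the ADP differences across the
#' attachment bond are then more than `epsilon` times those within the
#' group, i.e. the group is internally rigid but flexibly attached.
#'
#' @param u_eff named list of Cartesian length-6 ADPs (internal-subtracted),
#'   indexed by atom index as character
#' @param arg_atoms,body_atoms integer atom-index vectors
#' @param g a `mol_graph`
#' @param epsilon weighting factor (> 0, default 2: the group is accepted
#'   when the cross differences are at least twice the internal ones)
#' @return list of class `rigidity_report`: `delta_intra`, `delta_inter`,
#'   `omega` (Angstrom^2), `accepted`
#' @export
rigidity_index <- function(u_eff, arg_atoms, body_atoms, g, epsilon = 2) {
  if (epsilon <= 0) stop("epsilon must be positive")
  s <- g$structure
  pos <- atom_positions(s)
  heavy_arg <- arg_atoms[!s$atoms$is_h[arg_atoms]]
  heavy_body <- body_atoms[!s$atoms$is_h[body_atoms]]
  uget <- function(i) {
    u <- u_eff[[as.character(i)]]
    if (is.null(u)) stop("missing effective ADP for atom ", s$atoms$label[i])
    u
  }
  d_intra <- numeric(0)
  e <- g$edges
  for (k in seq_len(nrow(e))) {
    if (e$i[k] %in% heavy_arg && e$j[k] %in% heavy_arg) {
      d_intra <- c(d_intra, bond_projection_delta(
        uget(e$i[k]), uget(e$j[k]), pos[e$i[k], ], pos[e$j[k], ]))
    }
  }
  d_inter <- numeric(0)
  for (i in heavy_arg) {
    for (j in heavy_body) {
      d_inter <- c(d_inter, bond_projection_delta(
        uget(i), uget(j), pos[i, ], pos[j, ]))
    }
  }
  if (length(d_inter) == 0) {
    stop("no non-H cross pairs: rigidity of the group cannot be judged")
  }
  m_intra <- if (length(d_intra) == 0) 0 else mean(d_intra)
  omega <- epsilon * m_intra - mean(d_inter)
  # strict acceptance omega < 0, with a floor of 1e-12 A^2 so that exact
  # rigidity is not accepted through floating-point rounding of zero deltas
  structure(list(delta_intra = d_intra, delta_inter = d_inter,
                 omega = omega, accepted = omega < -1e-12),
            class = "rigidity_report")
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat(sprintf("rigidity index: Omega = %+.3e A^2 (%s); %d intra / %d inter pairs\n",
              x$omega, if (x$accepted) "accepted" else "rejected",
              length(x$delta_intra), length(x$delta_inter)))
  invisible(x)
}

#' Automatic rigid-body segmentation of a molecule
#'
#' Evaluates the rigidity index for every candidate torsion axis of the
#' molecule and assembles the accepted attached rigid groups. Accepted
#' groups with fewer than `min_group_size` atoms (hydrogens included) are
#' discarded in a cross-referencing pass, since such small groups do not
#' allow a stable least-squares optimization. Overlapping accepted groups
#' are resolved greedily by Omega rank (most negative kept); the body must
#' retain at least 8 non-H atoms, otherwise the most weakly accepted groups
#' are released back into the body.
#'
#' @param g a `mol_graph`
#' @param molecule atom indices of one molecule
#' @param u_eff named list of Cartesian length-6 ADPs (internal-subtracted)
#'   for the non-H atoms
#' @param epsilon rigidity-index weight (default 2)
#' @param min_group_size minimum atom count of an accepted group (default 8)
#' @return list of class `segmentation_model`: `molecule`, `body_atoms`,
#'   `args` (list of `list(axis, atoms, omega)`), `reports` (one
#'   `rigidity_report` per candidate axis), `epsilon`, `min_group_size`
#' @export
segment_molecule <- function(g, molecule, u_eff, epsilon = 2,
                             min_group_size = 8) {
  s <- g$structure
  heavy <- molecule[!s$atoms$is_h[molecule]]
  if (length(heavy) < 2) stop("molecule needs at least 2 non-H atoms")
  axes <- candidate_torsion_axes(g, molecule)
  cand <- list()
  reports <- list()
  if (nrow(axes) > 0) {
    for (k in seq_len(nrow(axes))) {
      bond <- c(axes$i[k], axes$j[k])
      sp <- split_by_bond(g, molecule, bond)
      rep_k <- rigidity_index(u_eff, sp$arg, sp$body, g, epsilon)
      key <- paste(sort(bond), collapse = "-")
      reports[[key]] <- rep_k
      if (rep_k$accepted) {
        cand[[length(cand) + 1]] <- list(axis = bond, atoms = sp$arg,
                                         omega = rep_k$omega)
      }
    }
  }
  # size filter (atom count includes H)
  cand <- Filter(function(a) length(a$atoms) >= min_group_size, cand)
  # overlap resolution: greedy by Omega (most negative first)
  if (length(cand) > 1) {
    cand <- cand[order(vapply(cand, function(a) a$omega, numeric(1)))]
    kept <- list()
    taken <- integer(0)
    for (a in cand) {
      if (!any(a$atoms %in% taken) && !any(a$axis %in% taken)) {
        kept[[length(kept) + 1]] <- a
        taken <- c(taken, a$atoms)
      }
    }
    cand <- kept
  }
  # body stability floor: keep at least 8 non-H atoms in the body
  repeat {
    arg_atoms <- unlist(lapply(cand, function(a) a$atoms))
    body <- setdiff(molecule, arg_atoms)
    if (sum(!s$atoms$is_h[body]) >= 8 || length(cand) == 0) break
    worst <- which.max(vapply(cand, function(a) a$omega, numeric(1)))
    cand <- cand[-worst]
  }
  arg_atoms <- unlist(lapply(cand, function(a) a$atoms))
  structure(list(molecule = molecule,
                 body_atoms = setdiff(molecule, arg_atoms),
                 args = cand, reports = reports, epsilon = epsilon,
                 min_group_size = min_group_size),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  s_labels <- NULL
  cat(sprintf("segmentation: %d-atom molecule, %d attached rigid group(s)\n",
              length(x$molecule), length(x$args)))
  for (a in x$args) {
    cat(sprintf("  axis %d-%d: %d atoms, Omega = %+.3e A^2\n",
                a$axis[1], a$axis[2], length(a$atoms), a$omega))
  }
  cat(sprintf("  body: %d atoms\n", length(x$body_atoms)))
  invisible(x)
}
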