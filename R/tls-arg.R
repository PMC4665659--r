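#' Subtract internal ADPs from the observed non-H ADPs
#'
#' Computes the fit targets of the rigid-body analysis: for every non-H atom
#' the observed Cartesian ADP minus the internal (intramolecular) ADP
#' transferred from the database. Removing the internal contribution before
#' the TLS fit prevents contamination of the lattice-motion parameters with
#' intramolecular vibrations. Results may legitimately fail positive
#' semidefiniteness — they are fit targets, not physical ADPs.
#'
#' @param s a [crystal_structure()]
#' @param db an `internal_adp_db`
#' @param g the structure's `mol_graph`
#' @param temperature kelvin
#' @param missing_internal `"error"` (default) or `"zero"`: what to do when
#'   an atom's environment name has no database entry
#' @return named list (atom index as character) of Cartesian length-6 ADPs
#' @export
subtract_internal <- function(s, db, g, temperature,
                              missing_internal = c("error", "zero")) {
  missing_internal <- match.arg(missing_internal)
  out <- list()
  for (i in which(!s$atoms$is_h)) {
    uobs <- atom_adp_cart(s, i)
    if (is.null(uobs)) {
      if (!is.na(s$atoms$uiso[i])) {
        message("atom ", s$atoms$label[i],
                ": isotropic U only; using U_iso * I as observed ADP")
        uobs <- c(rep(s$atoms$uiso[i], 3), 0, 0, 0)
      } else {
        next
      }
    }
    name <- environment_name(g, i)
    uint <- tryCatch({
      fr <- local_frame(g, i)
      as.numeric(transfer_internal_adp(db, name, fr, temperature))
    }, error = function(e) {
      if (missing_internal == "zero") {
        warning("no internal ADP for ", s$atoms$label[i], " ('", name,
                "'); assuming zero internal motion")
        rep(0, 6)
      } else {
        stop(e)
      }
    })
    out[[as.character(i)]] <- uobs - uint
  }
  out
}

# antisymmetric matrix A with A %*% omega == omega x d  (d = r - origin)
skew_arm <- function(d) {
  matrix(c(0, -d[3], d[2],
           d[3], 0, -d[1],
           -d[2], d[1], 0), nrow = 3, byrow = TRUE)
}

#' External (rigid-body) ADP at a position
#'
#' Evaluates the TLS + attached-rigid-group displacement model at a point:
#' `U = T + A L A' + A S + S' A'` with `A` the antisymmetric matrix of the
#' lever arm `r - origin`, plus `amp * v v'` with `v = n x (r - p)` for each
#' attached rigid group the atom belongs to (`n` unit axis, `p` a point on
#' the axis, `amp` the mean-square libration angle). Body-group correlation
#' is neglected: each group contributes one independent libration.
#'
#' @param tls list with 3x3 matrices `T` (Angstrom^2), `L` (rad^2), `S`
#'   (Angstrom rad, trace 0) and `origin` (Cartesian Angstrom)
#' @param args list of attached rigid groups, each
#'   `list(axis_point, axis_dir, amplitude, atoms)`; may be empty
#' @param position Cartesian position (length-3, Angstrom)
#' @param membership indices into `args` of the groups the atom belongs to
#' @return symmetric 3x3 matrix in Angstrom^2
#' @export
external_adp <- function(tls, args = list(), position, membership = integer(0)) {
  d <- as.numeric(position) - as.numeric(tls$origin)
  A <- -skew_arm(d)
  U <- tls$T + A %*% tls$L %*% t(A) + A %*% tls$S + t(tls$S) %*% t(A)
  for (k in membership) {
    g <- args[[k]]
    n <- g$axis_dir / sqrt(sum(g$axis_dir^2))
    rel <- as.numeric(position) - as.numeric(g$axis_point)
    v <- c(n[2] * rel[3] - n[3] * rel[2],
           n[3] * rel[1] - n[1] * rel[3],
           n[1] * rel[2] - n[2] * rel[1])
    U <- U + g$amplitude * tcrossprod(v)
  }
  (U + t(U)) / 2
}

# basis matrices for the 20 TLS unknowns:
# T: 6 symmetric; L: 6 symmetric; S: 8 (3x3 traceless, s33 = -s11-s22)
tls_basis <- function() {
  sym6 <- lapply(1:6, function(k) u6_to_mat(replace(numeric(6), k, 1)))
  Sb <- list()
  E <- function(i, j) { M <- matrix(0, 3, 3); M[i, j] <- 1; M }
  Sb[[1]] <- E(1, 1) - E(3, 3)   # s11 free, balanced by s33
  Sb[[2]] <- E(2, 2) - E(3, 3)   # s22 free, balanced by s33
  Sb <- c(Sb, list(E(1, 2), E(1, 3), E(2, 1), E(2, 3), E(3, 1), E(3, 2)))
  list(T = sym6, L = sym6, S = Sb)
}

# design row-block (6 x npar) for one atom
tls_design_block <- function(position, origin, arg_geoms, membership) {
  d <- as.numeric(position) - as.numeric(origin)
  A <- -skew_arm(d)
  basis <- tls_basis()
  cols <- list()
  for (M in basis$T) cols[[length(cols) + 1]] <- mat_to_u6(M)
  for (M in basis$L) {
    W <- A %*% M %*% t(A)
    cols[[length(cols) + 1]] <- mat_to_u6((W + t(W)) / 2)
  }
  for (M in basis$S) {
    W <- A %*% M + t(M) %*% t(A)
    cols[[length(cols) + 1]] <- mat_to_u6((W + t(W)) / 2)
  }
  for (k in seq_along(arg_geoms)) {
    g <- arg_geoms[[k]]
    if (k %in% membership) {
      n <- g$axis_dir / sqrt(sum(g$axis_dir^2))
      rel <- as.numeric(position) - as.numeric(g$axis_point)
      v <- c(n[2] * rel[3] - n[3] * rel[2],
             n[3] * rel[1] - n[1] * rel[3],
             n[1] * rel[2] - n[2] * rel[1])
      W <- tcrossprod(v)
      cols[[length(cols) + 1]] <- mat_to_u6(W)
    } else {
      cols[[length(cols) + 1]] <- numeric(6)
    }
  }
  do.call(cbind, cols)
}

params_to_tls <- function(theta, origin) {
  basis <- tls_basis()
  Tm <- matrix(0, 3, 3); Lm <- matrix(0, 3, 3); Sm <- matrix(0, 3, 3)
  for (k in 1:6) Tm <- Tm + theta[k] * basis$T[[k]]
  for (k in 1:6) Lm <- Lm + theta[6 + k] * basis$L[[k]]
  for (k in 1:8) Sm <- Sm + theta[12 + k] * basis$S[[k]]
  list(T = Tm, L = Lm, S = Sm, origin = origin)
}

#' Fit the TLS + attached-rigid-group model
#'
#' Linear least-squares fit of the segmented rigid-body displacement model
#' to internal-subtracted non-H ADPs. Unknowns are the 6 components of T,
#' the 6 of L, the 8 of the traceless S, and one mean-square libration
#' amplitude per attached rigid group; unit weights on all 6N tensor
#' components. The TLS origin is the unweighted centroid of the body non-H
#' atoms (fitted ADPs are origin-invariant, so no center-of-reaction shift
#' is applied). Negative group amplitudes are clipped to zero and the
#' remaining parameters refitted.
#'
#' @param u_targets named list (atom index as character) of Cartesian
#'   length-6 target ADPs, typically from [subtract_internal()]
#' @param positions n x 3 matrix of Cartesian atomic positions for the whole
#'   structure (rows indexed by atom index)
#' @param seg a `segmentation_model`
#' @param origin optional Cartesian TLS origin; defaults to the centroid of
#'   the body non-H atoms. Fitted ADPs are invariant under this choice (T
#'   and S absorb the shift), so it is exposed mainly for diagnostics.
#' @return an object of class `tls_arg_fit` with components `tls`
#'   (T, L, S, origin), `args` (per-group axis, amplitude, member atoms),
#'   `residuals` (per-atom length-6 residual tensors), `rms` (Angstrom^2),
#'   `condition` (design condition number), `fitted`, `targets`
#' @seealso [predict.tls_arg_fit()], [assemble_hydrogen_adps()]
#' @export
fit_tls_arg <- function(u_targets, positions, seg, origin = NULL) {
  s_atoms <- as.integer(names(u_targets))
  body_t <- intersect(seg$body_atoms, s_atoms)
  if (length(body_t) < 4) stop("need at least 4 body atoms with target ADPs")
  if (is.null(origin)) origin <- colMeans(positions[body_t, , drop = FALSE])

  arg_geoms <- lapply(seg$args, function(a) {
    p1 <- positions[a$axis[1], ]
    p2 <- positions[a$axis[2], ]
    dirv <- p2 - p1
    list(axis_point = p1, axis_dir = dirv / sqrt(sum(dirv^2)),
         atoms = a$atoms, axis = a$axis)
  })
  membership <- lapply(s_atoms, function(i) {
    which(vapply(arg_geoms, function(g) i %in% g$atoms, logical(1)))
  })
  # groups need at least one off-axis target atom, else amplitude pinned to 0
  fixed_zero <- logical(length(arg_geoms))
  for (k in seq_along(arg_geoms)) {
    g <- arg_geoms[[k]]
    offaxis <- vapply(seq_along(s_atoms), function(ii) {
      i <- s_atoms[ii]
      if (!(k %in% membership[[ii]])) return(FALSE)
      rel <- positions[i, ] - g$axis_point
      n <- g$axis_dir
      v <- rel - sum(rel * n) * n
      sqrt(sum(v^2)) > 1e-6
    }, logical(1))
    if (!any(offaxis)) {
      warning("attached group ", k, " has no off-axis target atom; ",
              "amplitude fixed to 0")
      fixed_zero[k] <- TRUE
    }
  }

  build_system <- function(active) {
    X <- do.call(rbind, lapply(seq_along(s_atoms), function(ii) {
      blk <- tls_design_block(positions[s_atoms[ii], ], origin, arg_geoms,
                              membership[[ii]])
      blk[, c(rep(TRUE, 20), active), drop = FALSE]
    }))
    y <- unlist(u_targets, use.names = FALSE)
    list(X = X, y = y)
  }

  solve_ls <- function(X, y) {
    sv <- svd(X)
    keep <- sv$d > 1e-10 * sv$d[1]
    theta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    cond <- sv$d[1] / min(sv$d[keep])
    rank_def <- sum(!keep)
    list(theta = drop(theta), condition = cond, rank_deficiency = rank_def)
  }

  active <- !fixed_zero
  repeat {
    sys <- build_system(active)
    sol <- solve_ls(sys$X, sys$y)
    amps <- sol$theta[-(1:20)]
    neg <- amps < 0
    if (!any(neg)) break
    # clip-to-zero-and-refit for non-negativity
    idx_active <- which(active)
    active[idx_active[neg]] <- FALSE
  }
  if (sol$rank_deficiency > 0) {
    message("rank-deficient TLS design (deficiency ", sol$rank_deficiency,
            ", condition ", format(sol$condition, digits = 3),
            "); minimum-norm solution used")
  }

  amplitudes <- numeric(length(arg_geoms))
  if (any(active)) amplitudes[which(active)] <- sol$theta[-(1:20)]
  tls <- params_to_tls(sol$theta[1:20], origin)
  args_out <- lapply(seq_along(arg_geoms), function(k) {
    g <- arg_geoms[[k]]
    list(axis = g$axis, axis_point = g$axis_point, axis_dir = g$axis_dir,
         amplitude = amplitudes[k], atoms = g$atoms)
  })

  fitted <- lapply(seq_along(s_atoms), function(ii) {
    mat_to_u6(external_adp(tls, args_out, positions[s_atoms[ii], ],
                           membership[[ii]]))
  })
  names(fitted) <- names(u_targets)
  residuals <- Map(function(t, f) t - f, u_targets, fitted)
  rms <- sqrt(mean(unlist(residuals)^2))

  structure(list(tls = tls, args = args_out, residuals = residuals,
                 rms = rms, condition = sol$condition,
                 rank_deficiency = sol$rank_deficiency,
                 fitted = fitted, targets = u_targets,
                 positions = positions, segmentation = seg),
            class = "tls_arg_fit")
}

#' @export
print.tls_arg_fit <- function(x, ...) {
  cat("segmented rigid-body (TLS+ARG) fit\n")
  cat(sprintf("  atoms fitted: %d   rms residual: %.3e A^2   condition: %.3g\n",
              length(x$targets), x$rms, x$condition))
  cat(sprintf("  T_iso = %.5f A^2   L_iso = %.5f rad^2\n",
              mean(diag(x$tls$T)), mean(diag(x$tls$L))))
  for (k in seq_along(x$args)) {
    a <- x$args[[k]]
    cat(sprintf("  group %d (axis %d-%d): <phi^2> = %.5f rad^2, %d atoms\n",
                k, a$axis[1], a$axis[2], a$amplitude, length(a$atoms)))
  }
  invisible(x)
}

#' @export
summary.tls_arg_fit <- function(object, ...) {
  per_atom <- vapply(object$residuals, function(r) sqrt(mean(r^2)), numeric(1))
  out <- list(fit = object, per_atom_rms = per_atom,
              T = object$tls$T, L = object$tls$L, S = object$tls$S)
  class(out) <- "summary.tls_arg_fit"
  out
}

#' @export
print.summary.tls_arg_fit <- function(x, ...) {
  print(x$fit)
  cat("\nT (A^2):\n"); print(round(x$T, 6))
  cat("L (rad^2):\n"); print(round(x$L, 6))
  cat("S (A rad):\n"); print(round(x$S, 6))
  cat("\nper-atom rms residual (A^2):\n")
  print(round(x$per_atom_rms, 8))
  invisible(x)
}

#' @export
coef.tls_arg_fit <- function(object, ...) {
  c(stats::setNames(mat_to_u6(object$tls$T),
                    paste0("T.", c("11", "22", "33", "23", "13", "12"))),
    stats::setNames(mat_to_u6(object$tls$L),
                    paste0("L.", c("11", "22", "33", "23", "13", "12"))),
    stats::setNames(as.vector(t(object$tls$S)),
                    paste0("S.", c("11", "12", "13", "21", "22", "23",
                                   "31", "32", "33"))),
    stats::setNames(vapply(object$args, function(a) a$amplitude, numeric(1)),
                    if (length(object$args))
                      paste0("phi2.", seq_along(object$args)) else character(0)))
}

#' @export
residuals.tls_arg_fit <- function(object, ...) object$residuals

#' @export
fitted.tls_arg_fit <- function(object, ...) object$fitted

#' Predict external ADPs at new positions
#'
#' Evaluates the fitted rigid-body model at arbitrary Cartesian positions —
#' this is how hydrogen atoms (absent from the fit) receive their external
#' displacement contribution.
#'
#' @param object a `tls_arg_fit`
#' @param positions m x 3 matrix of Cartesian positions (Angstrom)
#' @param membership list (length m) of group-index vectors, or `NULL` for
#'   body atoms only
#' @param ... unused
#' @return list of symmetric 3x3 matrices in Angstrom^2
#' @export
predict.tls_arg_fit <- function(object, positions, membership = NULL, ...) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  m <- nrow(positions)
  if (is.null(membership)) membership <- rep(list(integer(0)), m)
  lapply(seq_len(m), function(i) {
    external_adp(object$tls, object$args, positions[i, ], membership[[i]])
  })
}

#' Simulate rigid-body displacements from a fitted model
#'
#' Draws random rigid-body displacement vectors for one position from the
#' fitted Gaussian motion model (translation + libration + screw coupling +
#' group libration). Mainly a diagnostic device.
#'
#' @param object a `tls_arg_fit`
#' @param nsim number of draws
#' @param seed optional seed
#' @param position Cartesian position (length-3)
#' @param membership group indices the position belongs to
#' @param ... unused
#' @return nsim x 3 matrix of displacement vectors (Angstrom)
#' @export
simulate.tls_arg_fit <- function(object, nsim = 1000, seed = NULL,
                                 position, membership = integer(0), ...) {
  if (!is.null(seed)) set.seed(seed)
  Sig <- rbind(cbind(object$tls$T, t(object$tls$S)),
               cbind(object$tls$S, object$tls$L))
  ev <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  Z <- matrix(stats::rnorm(nsim * 6), nsim, 6)
  tw <- Z %*% t(ev$vectors %*% diag(sqrt(lam)))
  d <- as.numeric(position) - object$tls$origin
  A <- -skew_arm(d)
  disp <- tw[, 1:3] + tw[, 4:6] %*% t(A)
  for (k in membership) {
    g <- object$args[[k]]
    n <- g$axis_dir
    rel <- as.numeric(position) - g$axis_point
    v <- c(n[2] * rel[3] - n[3] * rel[2],
           n[3] * rel[1] - n[1] * rel[3],
           n[1] * rel[2] - n[2] * rel[1])
    phi <- stats::rnorm(nsim, 0, sqrt(max(g$amplitude, 0)))
    disp <- disp + outer(phi, v)
  }
  disp
}

#' Assemble hydrogen ADPs from the fit and the internal database
#'
#' For every hydrogen atom the estimated ADP is the external contribution
#' evaluated at its position (including the libration of any attached rigid
#' group it belongs to) plus the internal contribution transferred from the
#' database in the atom's local frame. The result is written back into the
#' structure on its native (cif_star) basis. Hydrogen tensors that fail
#' positive semidefiniteness are flagged with a warning, not clipped.
#'
#' @param s a [crystal_structure()]
#' @param g the structure's `mol_graph`
#' @param seg a `segmentation_model` (or list of them, one per molecule)
#' @param fit a `tls_arg_fit` (or list of fits matching `seg`)
#' @param db an `internal_adp_db`
#' @param temperature kelvin
#' @param missing_internal `"error"` or `"zero"`
#' @return the structure with hydrogen ADPs filled in; attribute
#'   `"nonpsd_h"` lists flagged hydrogen labels
#' @export
assemble_hydrogen_adps <- function(s, g, seg, fit, db, temperature,
                                   missing_internal = c("error", "zero")) {
  missing_internal <- match.arg(missing_internal)
  segs <- if (inherits(seg, "segmentation_model")) list(seg) else seg
  fits <- if (inherits(fit, "tls_arg_fit")) list(fit) else fit
  pos <- atom_positions(s)
  flagged <- character(0)
  for (i in which(s$atoms$is_h)) {
    mol_idx <- which(vapply(segs, function(sg) i %in% sg$molecule, logical(1)))
    if (length(mol_idx) == 0) next
    f <- fits[[mol_idx[1]]]
    memb <- which(vapply(f$args, function(a) i %in% a$atoms, logical(1)))
    Ue <- external_adp(f$tls, f$args, pos[i, ], memb)
    name <- environment_name(g, i)
    Ui <- tryCatch({
      fr <- local_frame(g, i)
      u6_to_mat(as.numeric(transfer_internal_adp(db, name, fr, temperature)))
    }, error = function(e) {
      if (missing_internal == "zero") {
        warning("no internal ADP for H ", s$atoms$label[i], " ('", name,
                "'); external contribution only")
        matrix(0, 3, 3)
      } else {
        stop(e)
      }
    })
    U <- Ue + Ui
    if (!is_psd(U)) flagged <- c(flagged, s$atoms$label[i])
    s <- set_atom_adp_cart(s, i, mat_to_u6(U))
  }
  if (length(flagged)) {
    warning("non-positive-semidefinite H ADP(s): ",
            paste(flagged, collapse = ", "))
  }
  attr(s, "nonpsd_h") <- flagged
  s
}
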