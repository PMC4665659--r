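# Shared fixtures and independent oracles for the test suite.
# Every oracle here re-derives the quantity from first principles (sampling,
# grid integration, explicit matrix arithmetic) without touching the code
# path it is used to check.

# six components (u11,u22,u33,u23,u13,u12) -> symmetric 3x3
mat6 <- function(u) {
  matrix(c(u[1], u[6], u[5],
           u[6], u[2], u[4],
           u[5], u[4], u[3]), nrow = 3)
}

vec6 <- function(M) c(M[1, 1], M[2, 2], M[3, 3], M[2, 3], M[1, 3], M[1, 2])

adp_from_mat <- function(M, basis = "cartesian") {
  adp_tensor(M[1, 1], M[2, 2], M[3, 3], M[2, 3], M[1, 3], M[1, 2],
             basis = basis)
}

# random positive-definite tensor with eigenvalues in [lo, hi] Angstrom^2
rand_pd <- function(lo = 0.005, hi = 0.1) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  Q %*% diag(runif(3, lo, hi)) %*% t(Q)
}

rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Numerical-integration oracle for the Gaussian overlap statistic:
# evaluates integral sqrt(p1(r) p2(r)) dr on a grid aligned with the
# principal axes of the integrand (itself a Gaussian), trapezoid-free plain
# Riemann sum -- spectrally accurate for Gaussians at this spacing.
numeric_overlap_s <- function(U1, U2, npts = 61, extent = 8) {
  M1 <- solve(U1); M2 <- solve(U2)
  C <- 2 * solve(M1 + M2)
  ev <- eigen(C, symmetric = TRUE)
  gs <- lapply(1:3, function(k) {
    seq(-extent, extent, length.out = npts) * sqrt(ev$values[k])
  })
  st <- vapply(gs, function(g) g[2] - g[1], numeric(1))
  gr <- as.matrix(expand.grid(gs[[1]], gs[[2]], gs[[3]])) %*% t(ev$vectors)
  c1 <- 1 / sqrt((2 * pi)^3 * det(U1))
  c2 <- 1 / sqrt((2 * pi)^3 * det(U2))
  q1 <- rowSums((gr %*% M1) * gr)
  q2 <- rowSums((gr %*% M2) * gr)
  r12 <- sum(sqrt(c1 * c2) * exp(-(q1 + q2) / 4)) * prod(st)
  100 * (1 - r12)
}

# Monte-Carlo oracle for the rigid-motion covariance: samples correlated
# translations t and rotations w from the joint 6x6 covariance
# [[T, S'], [S, L]], adds an independent torsion phi about (axis n, point p),
# and returns the empirical covariance of
#   u = t + w x (r - origin) + phi * n x (r - p).
mc_external_adp <- function(Tm, Lm, Sm, origin, r, nsamp = 1e6,
                            arg = NULL) {
  Sig <- rbind(cbind(Tm, t(Sm)), cbind(Sm, Lm))
  ev <- eigen((Sig + t(Sig)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  Z <- matrix(rnorm(nsamp * 6), nsamp, 6)
  tw <- Z %*% t(ev$vectors %*% diag(sqrt(lam)))
  d <- r - origin
  u <- tw[, 1:3] + cbind(tw[, 5] * d[3] - tw[, 6] * d[2],
                         tw[, 6] * d[1] - tw[, 4] * d[3],
                         tw[, 4] * d[2] - tw[, 5] * d[1])
  if (!is.null(arg)) {
    n <- arg$axis_dir / sqrt(sum(arg$axis_dir^2))
    rel <- r - arg$axis_point
    v <- c(n[2] * rel[3] - n[3] * rel[2],
           n[3] * rel[1] - n[1] * rel[3],
           n[1] * rel[2] - n[2] * rel[1])
    phi <- rnorm(nsamp, 0, sqrt(arg$amplitude))
    u <- u + outer(phi, v)
  }
  crossprod(u) / nsamp
}

# random joint-PSD TLS parameter set at physically plausible magnitudes
rand_tls_params <- function() {
  B <- diag(c(rep(sqrt(0.02), 3), rep(sqrt(0.004), 3)))
  G <- matrix(rnorm(36), 6, 6)
  Sig <- B %*% tcrossprod(G) %*% B / 6
  list(T = Sig[1:3, 1:3], L = Sig[4:6, 4:6], S = Sig[4:6, 1:3])
}

make_traceless <- function(S) S - diag(rep(sum(diag(S)) / 3, 3))

# --- tiny molecular fixtures (built in code) --------------------------------

big_cell <- function(edge = 20) unit_cell(edge, edge, edge)

structure_from_cart <- function(labels, elements, pos, cell = big_cell(),
                                temperature = NA_real_) {
  A <- solve(cell_matrix(cell))
  frac <- t(A %*% t(pos))
  crystal_structure(cell, data.frame(
    label = labels, element = elements,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    stringsAsFactors = FALSE), temperature = temperature)
}

# water: O with two H
water_structure <- function() {
  structure_from_cart(
    c("O1", "H1", "H2"), c("O", "H", "H"),
    rbind(c(5, 5, 5),
          c(5 + 0.96, 5, 5),
          c(5 - 0.24, 5 + 0.93, 5)))
}

# methane: C with four tetrahedral H
methane_structure <- function() {
  t <- 1.09 / sqrt(3)
  structure_from_cart(
    c("C1", "H1", "H2", "H3", "H4"), c("C", "H", "H", "H", "H"),
    rbind(c(5, 5, 5),
          c(5 + t, 5 + t, 5 + t),
          c(5 + t, 5 - t, 5 - t),
          c(5 - t, 5 + t, 5 - t),
          c(5 - t, 5 - t, 5 + t)))
}

# methanol-like CH3-OH (gives a methyl H and a hydroxyl H)
methanol_structure <- function() {
  t <- 1.09 / sqrt(3)
  structure_from_cart(
    c("C1", "O1", "H1", "H2", "H3", "H4"),
    c("C", "O", "H", "H", "H", "H"),
    rbind(c(5, 5, 5),
          c(5 + 1.42, 5, 5),                     # O
          c(5 - t, 5 + t, 5 + t),                # methyl H
          c(5 - t, 5 - t, 5 + t),
          c(5 - t, 5, 5 - 1.02),
          c(5 + 1.42 + 0.63, 5 + 0.76, 5)))      # hydroxyl H on O
}

# planar hexagon of carbons (benzene skeleton, no H)
hexagon_structure <- function() {
  th <- (0:5) * pi / 3
  structure_from_cart(paste0("C", 1:6), rep("C", 6),
                      cbind(5 + 1.39 * cos(th), 5 + 1.39 * sin(th), 5))
}

# two hexagons joined by one single bond (biphenyl skeleton)
biphenyl_structure <- function() {
  th <- (0:5) * pi / 3
  ring1 <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
  shift <- 2 * 1.39 + 1.48
  ring2 <- cbind(shift - 1.39 * cos(th), 1.39 * sin(th), 0)
  pos <- rbind(ring1, ring2) + 6
  structure_from_cart(paste0("C", 1:12), rep("C", 12), pos)
}

# ethane-like C2H6 (exact tie under the split rule)
ethane_structure <- function() {
  t <- 1.09 / sqrt(3)
  structure_from_cart(
    c("C1", "C2", "H1", "H2", "H3", "H4", "H5", "H6"),
    c("C", "C", rep("H", 6)),
    rbind(c(5, 5, 5), c(6.54, 5, 5),
          c(5 - t, 5 + t, 5 + t), c(5 - t, 5 - t, 5 + t),
          c(5 - t, 5, 5 - 1.02),
          c(6.54 + t, 5 + t, 5 - t), c(6.54 + t, 5 - t, 5 - t),
          c(6.54 + t, 5, 5 + 1.02)))
}

# default model-compound pairing for a synthetic structure
synth_model_compounds <- function(ss) {
  list(list(structure = ss$model_compound, modes = ss$modes))
}

# segmentation model built from the generator's planted ground truth,
# bypassing the Omega detector (used to study the least-squares estimator
# in isolation, e.g. under noise levels where detection breaks down)
true_segmentation <- function(ss, mol_index = 1) {
  g <- ss$graph
  mol <- molecules(g)[[mol_index]]
  lab <- ss$structure$atoms$label
  suffix <- if (mol_index == 2) "B" else ""
  group <- match(paste0(ss$truth$group_labels, suffix), lab)
  axis <- match(paste0(ss$truth$axis_labels, suffix), lab)
  args <- if (length(group) && !anyNA(axis)) {
    list(list(axis = axis, atoms = group, omega = NA_real_))
  } else list()
  structure(list(molecule = mol, body_atoms = setdiff(mol, group),
                 args = args, reports = list(), epsilon = 2,
                 min_group_size = 8),
            class = "segmentation_model")
}

# largest absolute difference between an estimated structure's H ADPs and
# the generator's planted values
h_adp_error <- function(est_structure, truth) {
  max(vapply(names(truth$h_adps), function(nm) {
    i <- match(nm, est_structure$atoms$label)
    max(abs(atom_adp_cart(est_structure, i) - truth$h_adps[[nm]]))
  }, numeric(1)))
}
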