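#' Specification for a synthetic test structure
#'
#' Collects the ground-truth parameters from which [make_structure()] builds
#' a crystal structure with known external (TLS + attached-rigid-group) and
#' internal (mock normal-mode) displacement contributions. Defaults emulate
#' a small organic molecule measured around 100 K: translational amplitudes
#' of about 0.02 Angstrom^2, librations of a few (degrees)^2, a torsional
#' group libration of 0.01 rad^2, and intramolecular modes spanning
#' 80-3200 cm^-1 (two of them deliberately below the 200 cm^-1 cutoff).
#'
#' @param topology one of `"rigid_ring"` (puckered 8-carbon ring, rigid),
#'   `"ring_tail"` (ring plus rigid 2-carbon tail), `"methyl"` (ring plus
#'   methyl group), `"arg9"` (ring + methyl + librating 9-atom cyclopentyl
#'   group), `"arg_chain"` (ring + librating chain group whose atom count is
#'   set by `group_h`), `"two_molecule"` (two copies of `arg9` in one cell)
#' @param cell a `unit_cell` (default triclinic 17 x 15 x 14, 84/95/102)
#' @param tls ground-truth list `T`, `L`, `S` (3x3 each) or `NULL` for the
#'   documented defaults; the origin is always the centroid of the body
#'   non-H atoms
#' @param amplitude mean-square libration of the planted group in rad^2
#' @param group_h hydrogens on the first chain atom for `arg_chain` (1 gives
#'   a 7-atom group, 2 an 8-atom group)
#' @param frequencies mode wavenumbers in cm^-1, or `NULL` for the default
#'   ladder (two below-cutoff modes at 80 and 150, the rest spread to 3200)
#' @param noise_sd i.i.d. Gaussian noise added to each Cartesian component
#'   of the observed non-H ADPs, in Angstrom^2
#' @param temperature measurement temperature in kelvin
#' @param seed integer seed controlling the mock modes, random TLS values
#'   (when `tls = "random"`) and the noise
#' @return a list of class `synth_spec`
#' @export
synth_spec <- function(topology = c("arg9", "rigid_ring", "ring_tail",
                                    "methyl", "arg_chain", "two_molecule"),
                       cell = NULL, tls = NULL, amplitude = 0.01,
                       group_h = 1, frequencies = NULL, noise_sd = 0,
                       temperature = 100, seed = 1) {
  topology <- match.arg(topology)
  if (amplitude < 0 || noise_sd < 0) stop("variances must be non-negative")
  if (group_h < 0) stop("group size parameter must be >= 1 atom")
  if (is.null(cell)) cell <- unit_cell(17.0, 15.0, 14.0, 84, 95, 102)
  structure(list(topology = topology, cell = cell, tls = tls,
                 amplitude = amplitude, group_h = group_h,
                 frequencies = frequencies, noise_sd = noise_sd,
                 temperature = temperature, seed = seed),
            class = "synth_spec")
}

# ---- geometry builders ------------------------------------------------------

# puckered ("crown") 8-carbon ring, C-C 1.54 A, +- h pucker
geom_crown <- function(h = 0.40, bond = 1.54) {
  chord <- sqrt(bond^2 - (2 * h)^2)
  R <- chord / (2 * sin(pi / 8))
  th <- (0:7) * pi / 4
  pos <- cbind(R * cos(th), R * sin(th), h * (-1)^(0:7))
  labels <- paste0("C", 1:8)
  hs <- list()
  for (i in c(2, 4, 6, 8)) {
    u <- c(cos(th[i]), sin(th[i]), 0) * 0.8 + c(0, 0, (-1)^(i - 1) * 0.6)
    u <- u / sqrt(sum(u^2))
    hs[[length(hs) + 1]] <- list(label = paste0("HC", i), parent = i,
                                 pos = pos[i, ] + 1.09 * u)
  }
  list(pos = pos, labels = labels, elements = rep("C", 8), hydrogens = hs)
}

# unit vector orthogonal basis for a direction
perp_basis <- function(e) {
  e <- e / sqrt(sum(e^2))
  ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- ref - sum(ref * e) * e
  p <- p / sqrt(sum(p^2))
  q <- c(e[2] * p[3] - e[3] * p[2],
         e[3] * p[1] - e[1] * p[3],
         e[1] * p[2] - e[2] * p[1])
  list(e = e, p = p, q = q)
}

# cyclopentyl ring (5 C, 4 H) attached at `anchor` along direction e
geom_cyclopentyl <- function(anchor, e, bond_attach = 1.50, side = 1.50) {
  b <- perp_basis(e)
  rho <- side / (2 * sin(pi / 5))
  A1 <- anchor + bond_attach * b$e
  Cc <- A1 + rho * b$e
  phis <- 2 * pi * (0:4) / 5
  pos <- t(vapply(phis, function(phi) {
    Cc + rho * (cos(phi) * (-b$e) + sin(phi) * b$p)
  }, numeric(3)))
  labels <- paste0("D", 1:5)
  hs <- list()
  for (k in 2:5) {
    u <- pos[k, ] - Cc
    u <- u / sqrt(sum(u^2))
    hs[[length(hs) + 1]] <- list(label = paste0("HD", k), parent = k,
                                 pos = pos[k, ] + 1.09 * u)
  }
  list(pos = pos, labels = labels, elements = rep("C", 5), hydrogens = hs)
}

# methyl group attached at `anchor` along e
geom_methyl <- function(anchor, e, label = "M1", hprefix = "HM") {
  b <- perp_basis(e)
  M <- anchor + 1.52 * b$e
  hs <- list()
  for (j in 1:3) {
    u <- b$e / 3 + sqrt(8) / 3 * (cos(2 * pi * j / 3) * b$p +
                                    sin(2 * pi * j / 3) * b$q)
    hs[[j]] <- list(label = paste0(hprefix, j), parent = 1,
                    pos = M + 1.09 * u)
  }
  list(pos = matrix(M, 1, 3), labels = label, elements = "C", hydrogens = hs)
}

# zig-zag chain group of 3 carbons with group_h hydrogens on the first atom
geom_chain <- function(anchor, e, group_h = 1) {
  b <- perp_basis(e)
  # tetrahedral-like zig-zag so that 1-3 carbons stay out of bonding range
  e2 <- (b$e * 0.6 + b$p * 0.8); e2 <- e2 / sqrt(sum(e2^2))
  e3 <- (b$e * 0.951 - b$p * 0.309); e3 <- e3 / sqrt(sum(e3^2))
  G1 <- anchor + 1.52 * b$e
  G2 <- G1 + 1.52 * e2
  G3 <- G2 + 1.52 * e3
  pos <- rbind(G1, G2, G3)
  hs <- list()
  addh <- function(parent, u, lab) {
    u <- u / sqrt(sum(u^2))
    hs[[length(hs) + 1]] <<- list(label = lab, parent = parent,
                                  pos = pos[parent, ] + 1.09 * u)
  }
  if (group_h >= 1) addh(1, -b$p - 0.3 * b$e + 0.7 * b$q, "HG1")
  if (group_h >= 2) addh(1, -b$p - 0.3 * b$e - 0.7 * b$q, "HG4")
  addh(2, b$q + 0.3 * b$p, "HG2")
  addh(3, e3 + b$q, "HG3")
  addh(3, e3 - b$q, "HG5")
  list(pos = pos, labels = paste0("G", 1:3), elements = rep("C", 3),
       hydrogens = hs)
}

# assemble one molecule from fragments; returns atom table (Cartesian),
# intended axis (label pair) and intended group labels
build_molecule_geometry <- function(topology, group_h) {
  crown <- geom_crown()
  th1 <- 0
  e_out1 <- c(cos(th1), sin(th1), 0.5); e_out1 <- e_out1 / sqrt(sum(e_out1^2))
  th5 <- pi
  e_out5 <- c(cos(th5), sin(th5), 0.5); e_out5 <- e_out5 / sqrt(sum(e_out5^2))
  frags <- list()
  axis <- NULL
  group_labels <- character(0)
  add_frag <- function(fr, attach_label) {
    frags[[length(frags) + 1]] <<- c(fr, list(attach = attach_label))
  }
  if (topology %in% c("arg9", "two_molecule")) {
    cp <- geom_cyclopentyl(crown$pos[1, ], e_out1)
    add_frag(cp, "C1")
    me <- geom_methyl(crown$pos[5, ], e_out5)
    add_frag(me, "C5")
    axis <- c("C1", "D1")
    group_labels <- c(paste0("D", 1:5), paste0("HD", 2:5))
  } else if (topology == "arg_chain") {
    ch <- geom_chain(crown$pos[1, ], e_out1, group_h)
    add_frag(ch, "C1")
    axis <- c("C1", "G1")
    group_labels <- c(ch$labels, vapply(ch$hydrogens, `[[`, "", "label"))
  } else if (topology == "methyl") {
    me <- geom_methyl(crown$pos[5, ], e_out5)
    add_frag(me, "C5")
  } else if (topology == "ring_tail") {
    # rigid two-carbon tail
    b <- perp_basis(e_out1)
    T1 <- crown$pos[1, ] + 1.52 * b$e
    e2 <- (b$e * 0.6 + b$p * 0.8); e2 <- e2 / sqrt(sum(e2^2))
    T2 <- T1 + 1.52 * e2
    hs <- list(list(label = "HT2", parent = 2,
                    pos = T2 + 1.09 * (e2 + b$q) / sqrt(sum((e2 + b$q)^2))))
    add_frag(list(pos = rbind(T1, T2), labels = c("T1", "T2"),
                  elements = c("C", "C"), hydrogens = hs), "C1")
  }
  lab <- crown$labels
  el <- crown$elements
  pos <- crown$pos
  parent_of <- character(0)
  for (h in crown$hydrogens) {
    lab <- c(lab, h$label); el <- c(el, "H"); pos <- rbind(pos, h$pos)
  }
  edges <- cbind(paste0("C", 1:8), paste0("C", c(2:8, 1)))
  for (h in crown$hydrogens) {
    edges <- rbind(edges, c(crown$labels[h$parent], h$label))
  }
  for (fr in frags) {
    base <- length(lab)
    lab <- c(lab, fr$labels); el <- c(el, fr$elements)
    pos <- rbind(pos, fr$pos)
    edges <- rbind(edges, c(fr$attach, fr$labels[1]))
    if (length(fr$labels) > 1) {
      for (k in 2:length(fr$labels)) {
        edges <- rbind(edges, c(fr$labels[k - 1], fr$labels[k]))
      }
      if (length(fr$labels) == 5) {  # close the cyclopentyl ring
        edges <- rbind(edges, c(fr$labels[5], fr$labels[1]))
      }
    }
    for (h in fr$hydrogens) {
      lab <- c(lab, h$label); el <- c(el, "H"); pos <- rbind(pos, h$pos)
      edges <- rbind(edges, c(fr$labels[h$parent], h$label))
    }
  }
  rownames(pos) <- NULL
  list(labels = lab, elements = el, pos = pos, edges = edges,
       axis = axis, group_labels = group_labels)
}

# random physically plausible TLS set from the current RNG stream
random_tls <- function() {
  rnd_spd <- function(scale, aniso = 0.3) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    lam <- scale * (1 + stats::runif(3, -aniso, aniso))
    Q %*% diag(lam) %*% t(Q)
  }
  Tm <- rnd_spd(0.02)
  Lm <- rnd_spd(0.003)
  Sm <- matrix(stats::rnorm(9, 0, 8e-4), 3, 3)
  Sm <- Sm - diag(rep(sum(diag(Sm)) / 3, 3))
  list(T = Tm, L = Lm, S = Sm)
}

default_tls <- function() {
  list(T = diag(c(0.020, 0.016, 0.024)) +
         matrix(c(0, 2e-3, -1e-3, 2e-3, 0, 1.5e-3, -1e-3, 1.5e-3, 0), 3, 3),
       L = diag(c(0.0030, 0.0042, 0.0024)) +
         matrix(c(0, 4e-4, -3e-4, 4e-4, 0, 2e-4, -3e-4, 2e-4, 0), 3, 3),
       S = matrix(c(6e-4, -4e-4, 3e-4,
                    5e-4, -2e-4, -3e-4,
                    2e-4, 4e-4, -4e-4), 3, 3, byrow = TRUE))
}

#' Mock normal modes with known mass-weighted orthonormal eigenvectors
#'
#' Builds a `normal_modes` object for a given geometry by orthonormal
#' completion of a seeded random matrix. The vectors are exactly
#' mass-weighted orthonormal by construction; the supplied wavenumbers are
#' attached in order.
#'
#' @param geometry n x 3 Cartesian coordinates (Angstrom)
#' @param elements element symbols (length n)
#' @param frequencies wavenumbers in cm^-1 (at most 3n values)
#' @param seed integer seed
#' @param labels optional atom labels carried into the neutral file
#' @return a `normal_modes` object
#' @export
make_mock_modes <- function(geometry, elements, frequencies, seed = 1,
                            labels = NULL) {
  n <- nrow(geometry)
  k <- length(frequencies)
  if (k < 1 || k > 3 * n) stop("mode count must be in 1..3N")
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(3 * n * k), 3 * n, k)))
  normal_modes(frequencies, t(Q), atomic_mass(elements), geometry, elements,
               labels)
}

default_mode_frequencies <- function(n_modes) {
  if (n_modes <= 2) return(seq(300, 3000, length.out = n_modes))
  c(80, 150, seq(250, 3200, length.out = n_modes - 2))
}

#' Generate a synthetic crystal structure with known ground truth
#'
#' Builds the geometry of the chosen topology with bond lengths drawn from
#' the covalent-radius table (so [detect_bonds()] recovers the intended
#' graph), assigns to every non-H atom the observed ADP
#' `U_obs = U_ext(TLS + group libration) + U_int(mock modes) + noise`, and
#' records the hydrogen ground-truth ADPs only in the sidecar record —
#' mimicking X-ray input, where H displacements are not observed. Internal
#' ADPs are assigned through the same environment-name database transfer
#' the estimation pipeline uses, so the planted values are exactly
#' representable by the model.
#'
#' @param spec a [synth_spec()]
#' @return list of class `synth_structure` with `structure` (observed, ADPs
#'   on non-H only), `truth` (ground-truth record: per-atom external,
#'   internal and total Cartesian ADPs, hydrogen ADPs, TLS parameters per
#'   molecule, planted axis and group, intended bond list), `modes`,
#'   `db` (the internal-ADP database), `model_compound`
#' @export
make_structure <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  mol <- build_molecule_geometry(spec$topology, spec$group_h)
  n_mol <- if (spec$topology == "two_molecule") 2 else 1
  labels <- mol$labels
  elements <- mol$elements
  pos <- mol$pos
  mol_id <- rep(1L, length(labels))
  edges <- mol$edges
  if (n_mol == 2) {
    ang <- c(0.9, 0.4, 1.7)
    Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0,
                   sin(ang[1]), cos(ang[1]), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[2]), -sin(ang[2]),
                   0, sin(ang[2]), cos(ang[2])), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(ang[3]), 0, sin(ang[3]), 0, 1, 0,
                   -sin(ang[3]), 0, cos(ang[3])), 3, 3, byrow = TRUE)
    Rg <- Rz %*% Rx %*% Ry
    shift <- c(7.5, 6.5, 6.0)
    pos2 <- t(Rg %*% t(mol$pos)) + matrix(shift, nrow(mol$pos), 3, byrow = TRUE)
    lab2 <- paste0(mol$labels, "B")
    labels <- c(labels, lab2)
    elements <- c(elements, mol$elements)
    pos <- rbind(pos, pos2)
    mol_id <- c(mol_id, rep(2L, length(lab2)))
    edges <- rbind(edges, cbind(paste0(mol$edges[, 1], "B"),
                                paste0(mol$edges[, 2], "B")))
  }
  # place in the cell, centred around fractional (0.3, 0.3, 0.3)
  A <- cell_matrix(spec$cell)
  centre <- A %*% c(0.3, 0.3, 0.3) - colMeans(pos)
  pos <- pos + matrix(centre, nrow(pos), 3, byrow = TRUE)
  frac <- cart_to_frac(pos, spec$cell)
  atoms <- data.frame(label = labels, element = elements,
                      fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                      occ = 1, stringsAsFactors = FALSE)
  s <- crystal_structure(spec$cell, atoms, temperature = spec$temperature,
                         dialect = "synthetic")
  g <- detect_bonds(s)
  # verify the generator geometry produced exactly the intended bond graph
  got <- paste(pmin(s$atoms$label[g$edges$i], s$atoms$label[g$edges$j]),
               pmax(s$atoms$label[g$edges$i], s$atoms$label[g$edges$j]))
  want <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (!setequal(got, want)) {
    stop("generator geometry inconsistent with intended bond graph; ",
         "unexpected: ", paste(setdiff(got, want), collapse = ", "),
         " missing: ", paste(setdiff(want, got), collapse = ", "))
  }

  # mock internal modes for the model compound (= first molecule, gas phase)
  mc_atoms <- data.frame(label = mol$labels, element = mol$elements,
                         fx = 0, fy = 0, fz = 0, stringsAsFactors = FALSE)
  mc_pos <- mol$pos
  big <- unit_cell(50, 50, 50)
  mc_frac <- cart_to_frac(mc_pos, big)
  mc_atoms$fx <- mc_frac[, 1]; mc_atoms$fy <- mc_frac[, 2]
  mc_atoms$fz <- mc_frac[, 3]
  mc <- crystal_structure(big, mc_atoms, dialect = "synthetic")
  freqs <- spec$frequencies
  if (is.null(freqs)) freqs <- default_mode_frequencies(3 * nrow(mc_pos) - 6)
  modes <- make_mock_modes(mc_pos, mol$elements, freqs, seed = spec$seed,
                           labels = mol$labels)
  db <- suppressWarnings(build_internal_db(list(list(structure = mc, modes = modes)),
                                           spec$temperature))

  # internal ADPs for every structure atom via the database transfer path
  u_int <- list()
  for (i in seq_len(nrow(s$atoms))) {
    name <- environment_name(g, i)
    fr <- local_frame(g, i)
    u_int[[i]] <- as.numeric(transfer_internal_adp(db, name, fr,
                                                   spec$temperature))
  }

  # ground-truth external motion per molecule
  tls_in <- spec$tls
  mols <- molecules(g)
  set.seed(spec$seed + 1)
  truth_tls <- list()
  args_truth <- list()
  u_ext <- vector("list", nrow(s$atoms))
  for (m in seq_along(mols)) {
    midx <- mols[[m]]
    tl <- if (is.null(tls_in)) default_tls()
          else if (identical(tls_in, "random")) random_tls() else tls_in
    group_lab <- if (length(mol$group_labels))
      paste0(mol$group_labels, if (m == 2) "B" else "") else character(0)
    group_idx <- match(group_lab, s$atoms$label)
    axis_idx <- if (!is.null(mol$axis))
      match(paste0(mol$axis, if (m == 2) "B" else ""), s$atoms$label)
    else NULL
    body_idx <- setdiff(midx, group_idx)
    heavy_body <- body_idx[!s$atoms$is_h[body_idx]]
    pos_all <- atom_positions(s)
    tl$origin <- colMeans(pos_all[heavy_body, , drop = FALSE])
    args <- list()
    if (!is.null(axis_idx) && spec$amplitude > 0) {
      p1 <- pos_all[axis_idx[1], ]; p2 <- pos_all[axis_idx[2], ]
      dirv <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
      args <- list(list(axis = axis_idx, axis_point = p1, axis_dir = dirv,
                        amplitude = spec$amplitude, atoms = group_idx))
    }
    for (i in midx) {
      memb <- if (length(args) && i %in% group_idx) 1L else integer(0)
      u_ext[[i]] <- mat_to_u6(external_adp(tl, args, pos_all[i, ], memb))
    }
    truth_tls[[m]] <- tl
    args_truth[[m]] <- args
  }

  # observed ADPs: non-H atoms only, with optional noise
  set.seed(spec$seed + 2)
  u_obs <- vector("list", nrow(s$atoms))
  h_truth <- list()
  for (i in seq_len(nrow(s$atoms))) {
    u_tot <- u_ext[[i]] + u_int[[i]]
    if (s$atoms$is_h[i]) {
      h_truth[[s$atoms$label[i]]] <- u_tot
    } else {
      u <- u_tot + stats::rnorm(6, 0, spec$noise_sd)
      u_obs[[i]] <- u
      s <- set_atom_adp_cart(s, i, u)
    }
  }

  truth <- list(edges = edges, molecule = mol_id, tls = truth_tls,
                args = args_truth, axis_labels = mol$axis,
                group_labels = mol$group_labels,
                u_ext = u_ext, u_int = u_int, u_obs = u_obs,
                h_adps = h_truth, spec = spec)
  structure(list(structure = s, truth = truth, modes = modes, db = db,
                 model_compound = mc, graph = g),
            class = "synth_structure")
}

#' @export
print.synth_structure <- function(x, ...) {
  cat("synthetic structure (topology '", x$truth$spec$topology, "')\n", sep = "")
  print(x$structure)
  invisible(x)
}

#' Write a synthetic structure plus its ground-truth sidecar
#'
#' Writes the observed structure in the requested dialect, the mock mode
#' file in the neutral format and a plain-text sidecar with the planted
#' hydrogen ADPs (`label u11 u22 u33 u23 u13 u12`, Cartesian).
#'
#' @param ss a `synth_structure`
#' @param basename path prefix; files `<basename>.cif` (or `.res`/`.pdb`),
#'   `<basename>_modes.txt` and `<basename>_truth.txt` are produced
#' @param dialect structure dialect to write
#' @return named character vector of the written paths
#' @export
write_synth <- function(ss, basename, dialect = "cif") {
  ext <- switch(dialect, cif = ".cif", shelx_res = ".res", pdb = ".pdb")
  spath <- paste0(basename, ext)
  write_structure(ss$structure, spath, dialect)
  mpath <- paste0(basename, "_modes.txt")
  write_modes(ss$modes, mpath)
  tpath <- paste0(basename, "_truth.txt")
  out <- c("# planted hydrogen ADPs (Cartesian): label u11 u22 u33 u23 u13 u12")
  for (nm in names(ss$truth$h_adps)) {
    out <- c(out, paste(nm, paste(sprintf("%.12e", ss$truth$h_adps[[nm]]),
                                  collapse = " ")))
  }
  writeLines(out, tpath)
  c(structure = spath, modes = mpath, truth = tpath)
}
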