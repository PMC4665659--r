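#' Parse harmonic normal-mode data
#'
#' Two dialects are supported. The `neutral` dialect is this package's
#' structured mode file (see Details). The `qm_log` dialect extracts
#' frequency blocks with Cartesian displacement columns, the molecular
#' geometry and atomic masses from a quantum-chemistry text log in the
#' widespread Gaussian layout. In both cases displacement vectors are
#' re-normalized to mass-weighted orthonormality
#' (`sum_atoms |l_Ak|^2 = 1` per mode); imaginary frequencies are retained
#' as negative wavenumbers.
#'
#' @details The neutral format is line-oriented plain text:
#' \preformatted{
#' natoms N
#' nmodes K
#' elements  <N symbols>
#' masses    <N values, unified amu>
#' geometry           # N lines: x y z in Angstrom
#' ...
#' frequencies_cm-1 <K values>
#' modes              # K lines, 3N values each (atom-major x y z),
#' ...                # mass-weighted displacement components
#' }
#'
#' @param path file path
#' @param dialect `"neutral"` or `"qm_log"`
#' @return an object of class `normal_modes` with `frequencies` (cm^-1),
#'   `modes` (K x 3N matrix, mass-weighted, unit norm per row), `masses`
#'   (amu), `geometry` (N x 3, Angstrom), `elements`
#' @export
parse_modes <- function(path, dialect = c("neutral", "qm_log")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nm <- switch(dialect,
    neutral = parse_modes_neutral(lines, path),
    qm_log = parse_modes_qmlog(lines, path)
  )
  validate_modes(nm, path)
}

normal_modes <- function(frequencies, modes, masses, geometry, elements,
                         labels = NULL) {
  structure(list(frequencies = frequencies, modes = modes, masses = masses,
                 geometry = geometry, elements = elements, labels = labels),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("normal modes: %d atoms, %d modes, %.1f..%.1f cm^-1\n",
              length(x$masses), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

validate_modes <- function(nm, path) {
  n <- length(nm$masses)
  k <- length(nm$frequencies)
  if (nrow(nm$geometry) != n) {
    stop("mode file ", path, ": geometry/mass atom-count mismatch")
  }
  if (k > 3 * n) stop("mode file ", path, ": more than 3N modes")
  if (!all(is.finite(nm$frequencies))) {
    stop("mode file ", path, ": non-finite frequency")
  }
  if (ncol(nm$modes) != 3 * n || nrow(nm$modes) != k) {
    stop("mode file ", path, ": mode matrix is not K x 3N")
  }
  norms <- sqrt(rowSums(nm$modes^2))
  if (any(norms < 1e-12)) stop("mode file ", path, ": zero displacement vector")
  nm$modes <- nm$modes / norms
  nm
}

parse_modes_neutral <- function(lines, path) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  grab <- function(key) {
    i <- grep(paste0("^", key, "\\b"), lines)
    if (length(i) == 0) stop("neutral mode file ", path, ": missing '", key, "'")
    i[1]
  }
  val <- function(key) {
    strsplit(lines[grab(key)], "\\s+")[[1]][-1]
  }
  n <- as.integer(val("natoms")[1])
  k <- as.integer(val("nmodes")[1])
  elements <- val("elements")
  if (length(elements) != n) stop("neutral mode file ", path, ": element count mismatch")
  labels <- if (any(grepl("^labels\\b", lines))) val("labels") else NULL
  if (!is.null(labels) && length(labels) != n) {
    stop("neutral mode file ", path, ": label count mismatch")
  }
  masses <- as.numeric(val("masses"))
  if (length(masses) != n || anyNA(masses)) {
    stop("neutral mode file ", path, ": bad masses block")
  }
  ig <- grab("geometry")
  if (ig + n > length(lines)) stop("neutral mode file ", path, ": truncated geometry")
  geom <- t(vapply(lines[(ig + 1):(ig + n)], function(l) {
    as.numeric(strsplit(l, "\\s+")[[1]])
  }, numeric(3), USE.NAMES = FALSE))
  freqs <- as.numeric(val("frequencies_cm-1"))
  if (length(freqs) != k || anyNA(freqs)) {
    stop("neutral mode file ", path, ": bad frequencies block")
  }
  im <- grab("modes")
  if (im + k > length(lines)) stop("neutral mode file ", path, ": truncated modes")
  modes <- t(vapply(lines[(im + 1):(im + k)], function(l) {
    v <- as.numeric(strsplit(l, "\\s+")[[1]])
    if (length(v) != 3 * n || anyNA(v)) {
      stop("neutral mode file ", path, ": bad mode row")
    }
    v
  }, numeric(3 * n), USE.NAMES = FALSE))
  normal_modes(freqs, modes, masses, geom, elements, labels)
}

parse_modes_qmlog <- function(lines, path) {
  # geometry: last "Standard orientation" (or "Input orientation") table
  ori <- grep("(Standard|Input) orientation", lines)
  if (length(ori) == 0) stop("QM log ", path, ": no orientation table")
  start <- ori[length(ori)] + 5
  geom <- list(); zs <- integer(0)
  i <- start
  while (i <= length(lines) && !grepl("^\\s*-{5,}", lines[i])) {
    v <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]])
    zs <- c(zs, as.integer(v[2]))
    geom[[length(geom) + 1]] <- v[4:6]
    i <- i + 1
  }
  n <- length(geom)
  if (n == 0) stop("QM log ", path, ": empty orientation table")
  geometry <- do.call(rbind, geom)
  elements <- .elements$symbol[match(zs, .elements$z)]
  if (anyNA(elements)) stop("QM log ", path, ": unknown atomic number")
  # masses from thermochemistry block; fall back to standard weights
  masses <- atomic_mass(elements)
  ml <- grep("has atomic number\\s+\\d+ and mass", lines, value = TRUE)
  if (length(ml) >= n) {
    mm <- as.numeric(sub(".*mass\\s+([0-9.]+).*", "\\1", ml[seq_len(n)]))
    if (!anyNA(mm)) masses <- mm
  }
  fl <- grep("Frequencies --", lines)
  if (length(fl) == 0) stop("QM log ", path, ": no frequency block")
  freqs <- numeric(0)
  modes <- list()
  for (f in fl) {
    fv <- as.numeric(strsplit(trimws(sub(".*Frequencies --", "", lines[f])),
                              "\\s+")[[1]])
    nblock <- length(fv)
    # displacement table starts after the "Atom  AN  X Y Z ..." header
    hdr <- f
    while (hdr <= length(lines) &&
           !grepl("^\\s*Atom\\s+AN\\s+X\\s+Y\\s+Z", lines[hdr])) hdr <- hdr + 1
    if (hdr + n > length(lines)) stop("QM log ", path, ": truncated mode block")
    block <- matrix(0, nblock, 3 * n)
    for (a in seq_len(n)) {
      v <- as.numeric(strsplit(trimws(lines[hdr + a]), "\\s+")[[1]])
      if (length(v) < 2 + 3 * nblock) stop("QM log ", path, ": short mode row")
      for (b in seq_len(nblock)) {
        block[b, (3 * (a - 1) + 1):(3 * a)] <- v[(3 * b):(3 * b + 2)]
      }
    }
    freqs <- c(freqs, fv)
    for (b in seq_len(nblock)) modes[[length(modes) + 1]] <- block[b, ]
  }
  modes <- do.call(rbind, modes)
  # Cartesian displacement columns -> mass-weighted rows
  wt <- rep(sqrt(masses), each = 3)
  modes <- modes * matrix(wt, nrow(modes), 3 * n, byrow = TRUE)
  normal_modes(freqs, modes, masses, geometry, elements)
}

#' Write a normal-mode set in the neutral format
#' @param nm a `normal_modes` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_modes <- function(nm, path) {
  n <- length(nm$masses)
  out <- c("# hadp neutral mode file v1",
           paste("natoms", n),
           paste("nmodes", length(nm$frequencies)),
           paste("elements", paste(nm$elements, collapse = " ")),
           if (!is.null(nm$labels)) paste("labels", paste(nm$labels, collapse = " ")),
           paste("masses", paste(sprintf("%.8f", nm$masses), collapse = " ")),
           "geometry",
           apply(nm$geometry, 1, function(r) paste(sprintf("%.10f", r), collapse = " ")),
           paste("frequencies_cm-1",
                 paste(sprintf("%.6f", nm$frequencies), collapse = " ")),
           "modes",
           apply(nm$modes, 1, function(r) paste(sprintf("%.12e", r), collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

# per-mode mean-square amplitude <q^2> in kg m^2 units / omega factors:
# (hbar / 2 omega) coth(hbar omega / 2 kB T), returned in kg * m^2? No --
# returns hbar/(2 omega) * coth(...) in J s = kg m^2 / s * ... ; divided by
# atom mass (kg) it yields m^2.
mode_msd_factor <- function(nu_cm, T_K) {
  omega <- 2 * pi * .const$c_cm * nu_cm        # rad / s
  x <- .const$hbar * omega / (2 * .const$k_B * T_K)
  # coth(x) stable for large x
  cothx <- ifelse(x > 20, 1, 1 / tanh(x))
  .const$hbar / (2 * omega) * cothx            # kg m^2 (per unit mass division)
}

#' Internal ADP of one atom from its normal modes
#'
#' Computes the temperature-dependent mean-square displacement tensor of an
#' atom from the harmonic modes,
#' `U = sum_k (hbar / (2 m omega_k)) coth(hbar omega_k / (2 kB T)) l_k l_k'`,
#' summing over modes whose (scaled) wavenumber is at or above the
#' low-frequency cutoff. Modes below the cutoff — including imaginary modes
#' carried as negative wavenumbers and the near-zero rigid-body modes — are
#' excluded: their displacement content belongs to the external (lattice)
#' motion that the TLS fit models.
#'
#' @param nm a `normal_modes` object
#' @param atom atom index within the mode set
#' @param temperature temperature in kelvin (> 0)
#' @param cutoff low-frequency cutoff in cm^-1 (default 200)
#' @param freq_scale multiplicative frequency scaling factor (default 1)
#' @return symmetric positive-semidefinite 3x3 matrix in Angstrom^2
#' @export
internal_adp <- function(nm, atom, temperature, cutoff = 200, freq_scale = 1) {
  if (temperature <= 0) stop("temperature must be positive")
  if (cutoff < 0) stop("cutoff must be non-negative")
  if (freq_scale <= 0) stop("freq_scale must be positive")
  nu <- nm$frequencies * freq_scale
  keep <- which(nu >= cutoff)
  U <- matrix(0, 3, 3)
  m_kg <- nm$masses[atom] * .const$amu
  cols <- (3 * (atom - 1) + 1):(3 * atom)
  for (k in keep) {
    l <- nm$modes[k, cols]
    U <- U + mode_msd_factor(nu[k], temperature) / m_kg * tcrossprod(l)
  }
  U * .const$m2_to_A2
}

#' Build the internal-ADP database from model compounds
#'
#' For every atom of every model compound the internal ADP is computed at
#' the requested temperature, rotated into the atom's local frame and stored
#' under its chemical-environment name. When two atoms map to the same name
#' the first entry wins and a warning reports the collision.
#'
#' @param model_compounds list of `list(structure = , modes = )` pairs; each
#'   structure must allow a bond graph (the mode-set atom order must match
#'   the structure's atom order)
#' @param temperature kelvin
#' @param cutoff,freq_scale passed to [internal_adp()]
#' @param bond_tolerance bonding tolerance for the model-compound graph
#' @return an object of class `internal_adp_db`: named list of entries
#'   `list(name, temperature, u_local)` keyed `name@T`
#' @export
build_internal_db <- function(model_compounds, temperature, cutoff = 200,
                              freq_scale = 1, bond_tolerance = 0.40) {
  db <- structure(list(), class = "internal_adp_db")
  tkey <- sprintf("%.1f", round(temperature, 1))
  for (mc in model_compounds) {
    s <- mc$structure
    nm <- mc$modes
    if (nrow(s$atoms) != length(nm$masses)) {
      warning("model compound atom count does not match its mode set; skipped")
      next
    }
    g <- detect_bonds(s, tolerance = bond_tolerance)
    for (i in seq_len(nrow(s$atoms))) {
      name <- tryCatch(environment_name(g, i), error = function(e) NULL)
      if (is.null(name)) {
        warning("atom ", s$atoms$label[i], " could not be named; skipped")
        next
      }
      key <- paste0(name, "@", tkey)
      if (!is.null(db[[key]])) {
        warning("duplicate environment name '", name, "'; first entry kept")
        next
      }
      Ug <- internal_adp(nm, i, temperature, cutoff, freq_scale)
      fr <- local_frame(g, i)
      Ul <- t(fr$rotation) %*% Ug %*% fr$rotation
      entry <- list(name = name, temperature = round(temperature, 1),
                    u_local = mat_to_u6((Ul + t(Ul)) / 2))
      db[[key]] <- entry
    }
  }
  db
}

#' @export
print.internal_adp_db <- function(x, ...) {
  cat(sprintf("internal ADP database: %d entries\n", length(x)))
  for (e in x) {
    cat(sprintf("  %-20s @ %6.1f K  U_iso = %.5f A^2\n",
                e$name, e$temperature, sum(e$u_local[1:3]) / 3))
  }
  invisible(x)
}

# find a db entry by name within 1 K of the requested temperature
db_lookup <- function(db, name, temperature) {
  hits <- Filter(function(e) e$name == name &&
                   abs(e$temperature - temperature) <= 1.0, db)
  if (length(hits) == 0) return(NULL)
  dt <- vapply(hits, function(e) abs(e$temperature - temperature), numeric(1))
  hits[[which.min(dt)]]
}

#' Transfer an internal ADP from the database into a target frame
#'
#' Looks up the entry for `name` at the requested temperature (nearest entry
#' within 1 K) and rotates the stored local-frame tensor into the target
#' atom's frame: `U = R U_local R'`.
#'
#' @param db an `internal_adp_db`
#' @param name environment name to look up
#' @param frame_target a `local_frame` for the receiving atom
#' @param temperature kelvin
#' @return Cartesian `adp_tensor`
#' @export
transfer_internal_adp <- function(db, name, frame_target, temperature) {
  e <- db_lookup(db, name, temperature)
  if (is.null(e)) {
    avail <- unique(vapply(db, function(x) x$name, character(1)))
    stop("no internal ADP entry for '", name, "' at ", temperature,
         " K; available names: ",
         paste(utils::head(sort(avail), 10), collapse = ", "))
  }
  R <- frame_target$rotation
  U <- R %*% u6_to_mat(e$u_local) %*% t(R)
  v <- mat_to_u6((U + t(U)) / 2)
  adp_tensor(v[1], v[2], v[3], v[4], v[5], v[6], basis = "cartesian")
}

#' Model-compound structure from a mode set
#'
#' Wraps the gas-phase geometry carried by a `normal_modes` object in a
#' large dummy cell so it can serve directly as the structure half of a
#' model compound for [build_internal_db()].
#'
#' @param nm a `normal_modes` object
#' @param cell_edge edge of the dummy cubic cell in Angstrom
#' @return a [crystal_structure()]
#' @export
model_compound_from_modes <- function(nm, cell_edge = 50) {
  cell <- unit_cell(cell_edge, cell_edge, cell_edge)
  frac <- cart_to_frac(nm$geometry, cell)
  n <- length(nm$masses)
  labels <- if (!is.null(nm$labels)) nm$labels else paste0(nm$elements, seq_len(n))
  atoms <- data.frame(
    label = labels,
    element = nm$elements,
    fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
    stringsAsFactors = FALSE)
  crystal_structure(cell, atoms, dialect = "model_compound")
}

#' Write / read the internal-ADP cache file
#'
#' Plain-text cache: one line per entry,
#' `name temperature u11 u22 u33 u23 u13 u12` (local-frame components in
#' Angstrom^2).
#'
#' @param db an `internal_adp_db`
#' @param path file path
#' @return `path` (write) or an `internal_adp_db` (read)
#' @export
write_internal_db <- function(db, path) {
  out <- c("# hadp internal ADP cache v1: name T u11 u22 u33 u23 u13 u12")
  for (e in db) {
    out <- c(out, paste(e$name, sprintf("%.1f", e$temperature),
                        paste(sprintf("%.12e", e$u_local), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_internal_db
#' @export
read_internal_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  db <- structure(list(), class = "internal_adp_db")
  for (ln in lines) {
    v <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(v) != 8) stop("malformed cache line: ", ln)
    e <- list(name = v[1], temperature = as.numeric(v[2]),
              u_local = as.numeric(v[3:8]))
    db[[paste0(e$name, "@", sprintf("%.1f", e$temperature))]] <- e
  }
  db
}
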