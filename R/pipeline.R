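#' Estimate hydrogen ADPs for a structure
#'
#' Runs the full estimation workflow: environment naming, internal-ADP
#' database construction (or loading), subtraction of internal ADPs from
#' the observed non-H ADPs, automatic rigid-body segmentation, the TLS +
#' attached-rigid-group least-squares fit per molecule, evaluation of the
#' external contribution at every hydrogen position, and assembly of the
#' hydrogen ADPs as external + internal. Structures containing disorder
#' (partial occupancies) or atoms in bonding contact with their own
#' symmetry images are refused.
#'
#' @param structure a [crystal_structure()] or a file path readable by
#'   [read_structure()]
#' @param model_compounds list of `list(structure=, modes=)` pairs used to
#'   build the internal-ADP database; ignored when `db` is given
#' @param db an `internal_adp_db` (e.g. from [read_internal_db()])
#' @param temperature kelvin; defaults to the structure's own temperature
#'   record, and is required from one of the two sources
#' @param cutoff low-frequency cutoff in cm^-1 (default 200)
#' @param freq_scale frequency scaling factor (default 1)
#' @param epsilon rigidity-index weight (default 2)
#' @param min_group_size minimum attached-group size in atoms (default 8)
#' @param bond_tolerance bonding tolerance in Angstrom (default 0.40)
#' @param missing_internal `"error"` or `"zero"`
#' @param output optional path to write the estimated structure to
#' @param output_dialect dialect for `output`
#' @param verbose print per-step summaries
#' @return list of class `hadp_estimate`: `structure` (with hydrogen ADPs
#'   filled in), `fits` (one `tls_arg_fit` per molecule), `segmentations`,
#'   `db`, `graph`, `temperature`, `log` (character vector of step records)
#' @export
estimate_hadps <- function(structure, model_compounds = NULL, db = NULL,
                           temperature = NULL, cutoff = 200, freq_scale = 1,
                           epsilon = 2, min_group_size = 8,
                           bond_tolerance = 0.40,
                           missing_internal = c("error", "zero"),
                           output = NULL, output_dialect = "cif",
                           verbose = FALSE) {
  missing_internal <- match.arg(missing_internal)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  s <- if (is.character(structure)) read_structure(structure) else structure
  stopifnot(inherits(s, "crystal_structure"))
  if (is.null(temperature)) temperature <- s$temperature
  if (is.null(temperature) || is.na(temperature)) {
    stop("temperature unknown: give `temperature=` or a structure file ",
         "carrying _diffrn_ambient_temperature / TEMP")
  }
  if (detect_disorder(s)) {
    stop("structure contains disordered atoms (partial occupancy); ",
         "disorder handling is not supported")
  }
  if (detect_special_positions(s, bond_tolerance)) {
    stop("atoms are in bonding contact with their own symmetry images ",
         "(special position or polymeric structure); not supported")
  }
  say("structure: %d atoms (%d H), T = %.1f K", nrow(s$atoms),
      sum(s$atoms$is_h), temperature)

  if (is.null(db)) {
    if (is.null(model_compounds)) {
      stop("either `db` or `model_compounds` must be supplied")
    }
    db <- suppressWarnings(
      build_internal_db(model_compounds, temperature, cutoff, freq_scale,
                        bond_tolerance))
  }
  say("internal ADP database: %d entries", length(db))

  g <- detect_bonds(s, bond_tolerance)
  u_eff <- subtract_internal(s, db, g, temperature, missing_internal)
  mols <- molecules(g)
  say("bond graph: %d bonds, %d molecule(s)", nrow(g$edges), length(mols))

  segs <- list()
  fits <- list()
  pos <- atom_positions(s)
  for (m in seq_along(mols)) {
    seg <- segment_molecule(g, mols[[m]], u_eff, epsilon, min_group_size)
    for (key in names(seg$reports)) {
      say("molecule %d axis %s: Omega = %+.3e A^2 (%s)", m, key,
          seg$reports[[key]]$omega,
          if (seg$reports[[key]]$accepted) "accepted" else "rejected")
    }
    say("molecule %d: %d attached rigid group(s)", m, length(seg$args))
    tgt <- u_eff[names(u_eff) %in% as.character(mols[[m]])]
    fit <- fit_tls_arg(tgt, pos, seg)
    say("molecule %d fit: rms residual %.3e A^2, condition %.3g", m,
        fit$rms, fit$condition)
    segs[[m]] <- seg
    fits[[m]] <- fit
  }

  n_h <- sum(s$atoms$is_h)
  if (n_h == 0) {
    say("no hydrogen atoms: structure returned with ADPs unchanged")
    out_s <- s
  } else {
    out_s <- assemble_hydrogen_adps(s, g, segs, fits, db, temperature,
                                    missing_internal)
    say("estimated ADPs for %d hydrogen atoms (%d flagged non-PSD)",
        n_h, length(attr(out_s, "nonpsd_h")))
  }
  if (!is.null(output)) {
    write_structure(out_s, output, output_dialect)
    say("wrote %s (%s)", output, output_dialect)
  }
  structure(list(structure = out_s, fits = fits, segmentations = segs,
                 db = db, graph = g, temperature = temperature, log = log),
            class = "hadp_estimate")
}

#' @export
print.hadp_estimate <- function(x, ...) {
  cat("hydrogen ADP estimation\n")
  for (ln in x$log) cat(" ", ln, "\n")
  invisible(x)
}

#' Compare the ADPs of two structures with the overlap statistic S
#'
#' Atoms are matched by label. With `with_scaling = TRUE` a scaling model
#' (kappa + symmetric offset) is first fitted on the matched non-H pairs
#' and applied to structure A, removing overall-scale differences between
#' refinements before comparison. The table reports S per hydrogen atom
#' plus the arithmetic mean; non-positive-definite tensors are skipped with
#' a warning.
#'
#' @param a,b `crystal_structure`s or file paths
#' @param with_scaling fit and apply the ADP scaling model first
#' @param hydrogen_only restrict the S table to hydrogen atoms (default);
#'   otherwise all matched atoms with ADPs are tabulated
#' @return list of class `adp_comparison`: `table` (data.frame `label`,
#'   `S`), `mean_S`, `scaling` (or `NULL`)
#' @export
compare_adps <- function(a, b, with_scaling = FALSE, hydrogen_only = TRUE) {
  sa <- if (is.character(a)) read_structure(a) else a
  sb <- if (is.character(b)) read_structure(b) else b
  common <- intersect(sa$atoms$label, sb$atoms$label)
  if (length(common) == 0) stop("structures share no atom labels")
  ua <- list(); ub <- list()
  for (lab in common) {
    ia <- match(lab, sa$atoms$label); ib <- match(lab, sb$atoms$label)
    va <- atom_adp_cart(sa, ia); vb <- atom_adp_cart(sb, ib)
    if (is.null(va) || is.null(vb)) next
    ua[[lab]] <- va; ub[[lab]] <- vb
  }
  if (length(ua) == 0) stop("no matched atoms carry anisotropic ADPs")
  scaling <- NULL
  if (with_scaling) {
    ish <- sa$atoms$is_h[match(names(ua), sa$atoms$label)]
    if (sum(!ish) < 7) stop("scaling fit needs at least 7 matched non-H pairs")
    scaling <- fit_adp_scaling(ua[!ish], ub[!ish])
    ua <- lapply(ua, function(u) as.numeric(apply_adp_scaling(
      adp_tensor(u[1], u[2], u[3], u[4], u[5], u[6]), scaling)))
  }
  keep <- names(ua)
  if (hydrogen_only) {
    keep <- keep[sa$atoms$is_h[match(keep, sa$atoms$label)]]
    if (length(keep) == 0) {
      warning("no hydrogen atoms with ADPs in both structures; ",
              "tabulating all matched atoms")
      keep <- names(ua)
    }
  }
  svals <- vapply(keep, function(lab) {
    tryCatch(overlap_similarity_s(
      adp_tensor(ua[[lab]][1], ua[[lab]][2], ua[[lab]][3], ua[[lab]][4],
                 ua[[lab]][5], ua[[lab]][6]),
      adp_tensor(ub[[lab]][1], ub[[lab]][2], ub[[lab]][3], ub[[lab]][4],
                 ub[[lab]][5], ub[[lab]][6])),
      error = function(e) {
        warning("atom ", lab, " skipped: ", conditionMessage(e))
        NA_real_
      })
  }, numeric(1))
  tab <- data.frame(label = keep, S = round(svals, 2),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, mean_S = mean(svals, na.rm = TRUE),
                 scaling = scaling),
            class = "adp_comparison")
}

#' @export
print.adp_comparison <- function(x, ...) {
  cat("ADP comparison (overlap statistic S, 0 = identical, 100 = disjoint)\n")
  if (!is.null(x$scaling)) print(x$scaling)
  print(x$table, row.names = FALSE)
  cat(sprintf("mean    %.2f\n", x$mean_S))
  invisible(x)
}

#' Segmentation report for a structure
#'
#' Runs the workflow up to and including segmentation and returns the
#' candidate axes with their rigidity indices and the accepted attached
#' rigid groups. Deterministic: re-running on the same inputs gives the
#' identical report.
#'
#' @inheritParams estimate_hadps
#' @return list of class `segment_report`: per molecule, a data.frame of
#'   candidate axes (`axis`, `omega`, `accepted`) and the accepted groups
#' @export
segment_report <- function(structure, model_compounds = NULL, db = NULL,
                           temperature = NULL, cutoff = 200, freq_scale = 1,
                           epsilon = 2, min_group_size = 8,
                           bond_tolerance = 0.40,
                           missing_internal = c("error", "zero")) {
  missing_internal <- match.arg(missing_internal)
  s <- if (is.character(structure)) read_structure(structure) else structure
  if (is.null(temperature)) temperature <- s$temperature
  if (is.null(temperature) || is.na(temperature)) stop("temperature unknown")
  if (is.null(db)) {
    if (is.null(model_compounds)) stop("either `db` or `model_compounds` needed")
    db <- suppressWarnings(
      build_internal_db(model_compounds, temperature, cutoff, freq_scale,
                        bond_tolerance))
  }
  g <- detect_bonds(s, bond_tolerance)
  u_eff <- subtract_internal(s, db, g, temperature, missing_internal)
  mols <- molecules(g)
  out <- list()
  for (m in seq_along(mols)) {
    seg <- segment_molecule(g, mols[[m]], u_eff, epsilon, min_group_size)
    axes <- data.frame(axis = names(seg$reports),
                       omega = vapply(seg$reports, function(r) r$omega,
                                      numeric(1)),
                       accepted = vapply(seg$reports, function(r) r$accepted,
                                         logical(1)),
                       stringsAsFactors = FALSE)
    rownames(axes) <- NULL
    out[[m]] <- list(molecule = m, candidates = axes,
                     groups = lapply(seg$args, function(a) {
                       list(axis = paste(sort(a$axis), collapse = "-"),
                            n_atoms = length(a$atoms), omega = a$omega,
                            atoms = s$atoms$label[a$atoms])
                     }))
  }
  structure(out, class = "segment_report")
}

#' @export
print.segment_report <- function(x, ...) {
  for (m in x) {
    cat(sprintf("molecule %d: %d candidate axis/axes\n", m$molecule,
                nrow(m$candidates)))
    if (nrow(m$candidates)) print(m$candidates, row.names = FALSE)
    if (length(m$groups)) {
      for (gp in m$groups) {
        cat(sprintf("  accepted group at axis %s: %d atoms, Omega = %+.3e\n",
                    gp$axis, gp$n_atoms, gp$omega))
      }
    } else {
      cat("  no accepted groups: molecule treated as one rigid body\n")
    }
  }
  invisible(x)
}
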