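#' Read a crystal structure with ADPs
#'
#' Reads CIF (core dictionary cell / symmetry / atom_site / atom_site_aniso
#' items), SHELX `.res`/`.ins`, or PDB (CRYST1/ATOM/ANISOU) files. CIF and
#' SHELX anisotropic components are interpreted on the reciprocal-axis
#' (cif_star) basis; PDB ANISOU records on the Cartesian basis and converted.
#' Hydrogen atoms are identified by element. The measurement temperature is
#' taken from `_diffrn_ambient_temperature` (CIF), the `TEMP` card in Celsius
#' (SHELX), or a `REMARK 200 TEMPERATURE` line (PDB) when present.
#'
#' @param path file path
#' @param dialect one of `"auto"`, `"cif"`, `"shelx_res"`, `"pdb"`
#' @return a [crystal_structure()]
#' @export
read_structure <- function(path, dialect = c("auto", "cif", "shelx_res", "pdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") dialect <- detect_dialect(path, lines)
  switch(dialect,
    cif = read_cif(lines, path),
    shelx_res = read_shelx(lines, path),
    pdb = read_pdb(lines, path),
    stop("unknown dialect: ", dialect)
  )
}

#' Write a crystal structure
#'
#' Writes `cif`, `shelx_res` or `pdb`. For CIF and SHELX the anisotropic
#' components are written on the cif_star basis at full precision; for PDB,
#' Cartesian ANISOU integers `round(U * 1e4)` are emitted, so a PDB round
#' trip quantizes U to 1e-4 Angstrom^2.
#'
#' @param s a [crystal_structure()]
#' @param path output file path
#' @param dialect `"cif"`, `"shelx_res"` or `"pdb"`
#' @return `path`, invisibly
#' @export
write_structure <- function(s, path, dialect = c("cif", "shelx_res", "pdb")) {
  dialect <- match.arg(dialect)
  lines <- switch(dialect,
    cif = format_cif(s),
    shelx_res = format_shelx(s),
    pdb = format_pdb(s)
  )
  writeLines(lines, path)
  invisible(path)
}

detect_dialect <- function(path, lines) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "cif") return("cif")
  if (ext %in% c("res", "ins")) return("shelx_res")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- lines[seq_len(min(50, length(lines)))]
  if (any(grepl("^_cell_length", head))) return("cif")
  if (any(grepl("^(CRYST1|ATOM  |HETATM)", head))) return("pdb")
  if (any(grepl("^CELL\\s", head))) return("shelx_res")
  stop("cannot auto-detect dialect of ", path)
}

# strip a standard-uncertainty suffix: "0.0123(4)" -> 0.0123
num_su <- function(x) {
  as.numeric(sub("\\(.*\\)$", "", x))
}

## ---- CIF -------------------------------------------------------------------

cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_cif_blocks <- function(lines) {
  lines <- sub("^#.*", "", lines)
  items <- list()
  loops <- list()
  i <- 1
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^data_", ln)) { i <- i + 1; next }
    if (tolower(ln) == "loop_") {
      i <- i + 1
      keys <- character(0)
      while (i <= n && grepl("^_", trimws(lines[i]))) {
        keys <- c(keys, tolower(trimws(lines[i])))
        i <- i + 1
      }
      rows <- list()
      buf <- character(0)
      while (i <= n) {
        ln2 <- trimws(lines[i])
        if (!nzchar(ln2)) { i <- i + 1; if (length(buf)) next else break }
        if (grepl("^(_|loop_|data_)", ln2, ignore.case = TRUE)) break
        buf <- c(buf, cif_tokens(ln2))
        while (length(buf) >= length(keys)) {
          rows[[length(rows) + 1]] <- buf[seq_along(keys)]
          buf <- buf[-seq_along(keys)]
        }
        i <- i + 1
      }
      if (length(rows)) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- keys
        loops[[length(loops) + 1]] <- tab
      }
    } else if (grepl("^_", ln)) {
      toks <- cif_tokens(ln)
      key <- tolower(toks[1])
      if (length(toks) >= 2) {
        items[[key]] <- paste(toks[-1], collapse = " ")
      } else if (i < n) {
        items[[key]] <- trimws(lines[i + 1])
        i <- i + 1
      }
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  list(items = items, loops = loops)
}

read_cif <- function(lines, path) {
  p <- parse_cif_blocks(lines)
  it <- p$items
  need <- c("_cell_length_a", "_cell_length_b", "_cell_length_c",
            "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma")
  if (!all(need %in% names(it))) {
    stop("CIF ", path, ": missing cell items (",
         paste(setdiff(need, names(it)), collapse = ", "), ")")
  }
  cell <- unit_cell(num_su(it[["_cell_length_a"]]), num_su(it[["_cell_length_b"]]),
                    num_su(it[["_cell_length_c"]]), num_su(it[["_cell_angle_alpha"]]),
                    num_su(it[["_cell_angle_beta"]]), num_su(it[["_cell_angle_gamma"]]))
  temperature <- if ("_diffrn_ambient_temperature" %in% names(it)) {
    num_su(it[["_diffrn_ambient_temperature"]])
  } else NA_real_

  symmetry <- "x,y,z"
  site <- NULL
  aniso <- NULL
  for (lp in p$loops) {
    if (any(grepl("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                  names(lp)))) {
      col <- grep("as_xyz|operation_xyz", names(lp))[1]
      symmetry <- tolower(gsub(" ", "", lp[[col]]))
    } else if ("_atom_site_aniso_label" %in% names(lp)) {
      aniso <- lp
    } else if ("_atom_site_label" %in% names(lp)) {
      site <- lp
    }
  }
  if (is.null(site)) stop("CIF ", path, ": no atom_site loop")
  lab <- site[["_atom_site_label"]]
  el <- if ("_atom_site_type_symbol" %in% names(site)) {
    gsub("[^A-Za-z].*", "", site[["_atom_site_type_symbol"]])
  } else gsub("[^A-Za-z].*|[0-9].*", "", lab)
  atoms <- data.frame(
    label = lab, element = el,
    fx = num_su(site[["_atom_site_fract_x"]]),
    fy = num_su(site[["_atom_site_fract_y"]]),
    fz = num_su(site[["_atom_site_fract_z"]]),
    occ = if ("_atom_site_occupancy" %in% names(site))
      num_su(site[["_atom_site_occupancy"]]) else 1,
    uiso = if ("_atom_site_u_iso_or_equiv" %in% names(site))
      num_su(site[["_atom_site_u_iso_or_equiv"]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  for (cmp in c("u11", "u22", "u33", "u23", "u13", "u12")) atoms[[cmp]] <- NA_real_
  if (!is.null(aniso)) {
    idx <- match(aniso[["_atom_site_aniso_label"]], atoms$label)
    if (anyNA(idx)) {
      stop("CIF ", path, ": aniso loop references undefined atom label(s): ",
           paste(aniso[["_atom_site_aniso_label"]][is.na(idx)], collapse = ", "))
    }
    key <- function(k) paste0("_atom_site_aniso_u_", k)
    for (cmp in c("11", "22", "33", "23", "13", "12")) {
      if (!key(cmp) %in% names(aniso)) {
        stop("CIF ", path, ": aniso loop missing component U_", cmp)
      }
      atoms[[paste0("u", cmp)]][idx] <- num_su(aniso[[key(cmp)]])
    }
  }
  crystal_structure(cell, atoms, symmetry = symmetry,
                    temperature = temperature, dialect = "cif")
}

format_cif <- function(s) {
  a <- s$atoms
  out <- c("data_hadp",
           sprintf("_cell_length_a    %.6f", s$cell$a),
           sprintf("_cell_length_b    %.6f", s$cell$b),
           sprintf("_cell_length_c    %.6f", s$cell$c),
           sprintf("_cell_angle_alpha %.6f", s$cell$alpha),
           sprintf("_cell_angle_beta  %.6f", s$cell$beta),
           sprintf("_cell_angle_gamma %.6f", s$cell$gamma))
  if (!is.na(s$temperature)) {
    out <- c(out, sprintf("_diffrn_ambient_temperature %.2f", s$temperature))
  }
  out <- c(out, "loop_", "_symmetry_equiv_pos_as_xyz",
           sprintf("'%s'", s$symmetry))
  out <- c(out, "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "_atom_site_occupancy", "_atom_site_U_iso_or_equiv")
  uiso_out <- ifelse(is.na(a$uiso),
                     ifelse(is.na(a$u11), 0,
                            vapply(seq_len(nrow(a)), function(i) {
                              u_iso(atom_adp_cart(s, i))
                            }, numeric(1))),
                     a$uiso)
  out <- c(out, sprintf("%-6s %-2s %12.9f %12.9f %12.9f %8.5f %12.9f",
                        a$label, a$element, a$fx, a$fy, a$fz, a$occ, uiso_out))
  ha <- !is.na(a$u11)
  if (any(ha)) {
    out <- c(out, "loop_", "_atom_site_aniso_label",
             "_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
             "_atom_site_aniso_U_33", "_atom_site_aniso_U_23",
             "_atom_site_aniso_U_13", "_atom_site_aniso_U_12")
    out <- c(out, sprintf("%-6s %12.9f %12.9f %12.9f %12.9f %12.9f %12.9f",
                          a$label[ha], a$u11[ha], a$u22[ha], a$u33[ha],
                          a$u23[ha], a$u13[ha], a$u12[ha]))
  }
  out
}

## ---- SHELX .res ------------------------------------------------------------

# decode the SHELX fixed-parameter convention (p = value + 10 marks a fixed
# parameter; free-variable coding beyond |p| > 15 is not interpreted)
decode_shelx_par <- function(v) {
  ifelse(v > 5 & v < 15, v - 10, v)
}

read_shelx <- function(lines, path) {
  cards <- c("TITL", "CELL", "ZERR", "LATT", "SYMM", "SFAC", "UNIT", "TEMP",
             "FVAR", "HKLF", "END", "REM", "MORE", "L.S.", "WGHT", "FMAP",
             "PLAN", "ACTA", "BOND", "CONF", "LIST", "SIZE", "AFIX", "PART",
             "EQIV", "ANIS", "EXTI", "ABIN", "SHEL", "OMIT", "TWIN", "BASF")
  # join continuation lines (trailing "=")
  joined <- character(0)
  buf <- ""
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (nzchar(buf)) ln <- paste(buf, trimws(ln))
    if (grepl("=\\s*$", ln) && !grepl("^TITL", ln)) {
      buf <- sub("=\\s*$", "", ln)
    } else {
      joined <- c(joined, ln)
      buf <- ""
    }
  }
  cell <- NULL
  sfac <- character(0)
  symmetry <- "x,y,z"
  latt <- 1
  temperature <- NA_real_
  atoms <- list()
  passthrough <- character(0)
  part <- 0
  for (ln in joined) {
    if (!nzchar(trimws(ln))) next
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    card <- toupper(toks[1])
    if (card == "CELL") {
      v <- as.numeric(toks[-1])
      if (length(v) < 7) stop("SHELX ", path, ": malformed CELL card")
      cell <- unit_cell(v[2], v[3], v[4], v[5], v[6], v[7])
    } else if (card == "LATT") {
      latt <- as.numeric(toks[2])
    } else if (card == "SYMM") {
      symmetry <- c(symmetry,
                    tolower(gsub(" ", "", paste(toks[-1], collapse = ""))))
    } else if (card == "SFAC") {
      sfac <- c(sfac, toks[-1][is.na(suppressWarnings(as.numeric(toks[-1])))])
      if (length(sfac) == 0) sfac <- toks[-1]
    } else if (card == "TEMP") {
      temperature <- as.numeric(toks[2]) + 273.15
    } else if (card == "PART") {
      part <- as.numeric(toks[2])
    } else if (card %in% c("HKLF", "END")) {
      break
    } else if (card %in% cards) {
      passthrough <- c(passthrough, ln)
    } else if (grepl("^Q[0-9]+$", card)) {
      next  # Q peaks dropped
    } else if (grepl("^[A-Za-z]", toks[1]) && length(toks) >= 5) {
      v <- suppressWarnings(as.numeric(toks[-1]))
      if (anyNA(v[1:4])) {
        stop("SHELX ", path, ": malformed atom line: ", ln)
      }
      isf <- as.integer(v[1])
      if (isf < 1 || isf > length(sfac)) {
        stop("SHELX ", path, ": atom ", toks[1], " references SFAC index ", isf)
      }
      at <- list(label = toks[1], element = sfac[isf],
                 fx = decode_shelx_par(v[2]), fy = decode_shelx_par(v[3]),
                 fz = decode_shelx_par(v[4]),
                 occ = if (length(v) >= 5) decode_shelx_par(v[5]) else 1,
                 uiso = NA_real_, u11 = NA_real_, u22 = NA_real_,
                 u33 = NA_real_, u23 = NA_real_, u13 = NA_real_,
                 u12 = NA_real_, part = part)
      if (length(v) >= 11) {
        # SHELX atom-line order: U11 U22 U33 U23 U13 U12
        at[c("u11", "u22", "u33", "u23", "u13", "u12")] <- as.list(v[6:11])
      } else if (length(v) >= 6) {
        at$uiso <- v[6]
      }
      atoms[[length(atoms) + 1]] <- at
    }
  }
  if (is.null(cell)) stop("SHELX ", path, ": no CELL card")
  if (length(atoms) == 0) stop("SHELX ", path, ": no atom lines")
  tab <- do.call(rbind, lapply(atoms, function(a) {
    as.data.frame(a, stringsAsFactors = FALSE)
  }))
  if (latt > 0) symmetry <- unique(c(symmetry, "-x,-y,-z"))
  s <- crystal_structure(cell, tab[, setdiff(names(tab), "part")],
                         symmetry = symmetry, temperature = temperature,
                         dialect = "shelx_res")
  s$shelx_part <- tab$part
  s$shelx_passthrough <- passthrough
  s
}

format_shelx <- function(s) {
  a <- s$atoms
  bad <- a$label[nchar(a$label) > 4]
  if (length(bad)) {
    stop("SHELX labels limited to 4 characters; offending atoms: ",
         paste(bad, collapse = ", "))
  }
  sfac <- unique(a$element)
  out <- c("TITL hadp output",
           sprintf("CELL 0.71073 %10.6f %10.6f %10.6f %10.6f %10.6f %10.6f",
                   s$cell$a, s$cell$b, s$cell$c, s$cell$alpha, s$cell$beta,
                   s$cell$gamma),
           sprintf("ZERR 1 %s", paste(rep("0.0001", 6), collapse = " ")),
           "LATT -1")
  for (op in setdiff(s$symmetry, c("x,y,z", "-x,-y,-z"))) {
    out <- c(out, paste("SYMM", toupper(op)))
  }
  out <- c(out, paste("SFAC", paste(sfac, collapse = " ")),
           paste("UNIT", paste(as.integer(table(factor(a$element, sfac))),
                               collapse = " ")))
  if (!is.na(s$temperature)) {
    out <- c(out, sprintf("TEMP %.2f", s$temperature - 273.15))
  }
  out <- c(out, "FVAR 1.00000")
  for (i in seq_len(nrow(a))) {
    isf <- match(a$element[i], sfac)
    sof <- 10 + a$occ[i]
    if (!is.na(a$u11[i])) {
      out <- c(out, sprintf(
        "%-4s %d %11.9f %11.9f %11.9f %9.5f %11.9f %11.9f =",
        a$label[i], isf, a$fx[i], a$fy[i], a$fz[i], sof, a$u11[i], a$u22[i]),
        sprintf("   %11.9f %11.9f %11.9f %11.9f",
                a$u33[i], a$u23[i], a$u13[i], a$u12[i]))
    } else {
      u <- if (is.na(a$uiso[i])) 0.05 else a$uiso[i]
      out <- c(out, sprintf("%-4s %d %11.9f %11.9f %11.9f %9.5f %11.9f",
                            a$label[i], isf, a$fx[i], a$fy[i], a$fz[i], sof, u))
    }
  }
  c(out, "HKLF 4", "END")
}

## ---- PDB -------------------------------------------------------------------

read_pdb <- function(lines, path) {
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry) == 0) stop("PDB ", path, ": missing CRYST1 record")
  cv <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                     substr(cry[1], 25, 33), substr(cry[1], 34, 40),
                     substr(cry[1], 41, 47), substr(cry[1], 48, 54)))
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  temperature <- NA_real_
  trem <- grep("REMARK 200\\s+TEMPERATURE\\s+\\(KELVIN\\)", lines, value = TRUE)
  if (length(trem)) {
    tv <- suppressWarnings(as.numeric(sub(".*:\\s*", "", trem[1])))
    if (!is.na(tv)) temperature <- tv
  }
  atoms <- list()
  aniso <- list()
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec %in% c("ATOM  ", "HETATM")) {
      name <- trimws(substr(ln, 13, 16))
      el <- trimws(substr(ln, 77, 78))
      if (!nzchar(el)) el <- gsub("[^A-Za-z].*", "", name)
      atoms[[length(atoms) + 1]] <- list(
        label = name, element = el,
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        occ = as.numeric(substr(ln, 55, 60)))
    } else if (rec == "ANISOU") {
      name <- trimws(substr(ln, 13, 16))
      u <- as.numeric(c(substr(ln, 29, 35), substr(ln, 36, 42),
                        substr(ln, 43, 49), substr(ln, 50, 56),
                        substr(ln, 57, 63), substr(ln, 64, 70))) / 1e4
      # PDB order U11 U22 U33 U12 U13 U23 (Cartesian)
      aniso[[name]] <- c(u[1], u[2], u[3], u[6], u[5], u[4])
    }
  }
  if (length(atoms) == 0) stop("PDB ", path, ": no ATOM records")
  tab <- do.call(rbind, lapply(atoms, as.data.frame, stringsAsFactors = FALSE))
  frac <- cart_to_frac(as.matrix(tab[, c("x", "y", "z")]), cell)
  df <- data.frame(label = tab$label, element = tab$element,
                   fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                   occ = tab$occ, uiso = NA_real_, stringsAsFactors = FALSE)
  s <- crystal_structure(cell, df, temperature = temperature, dialect = "pdb")
  for (nm in names(aniso)) {
    i <- match(nm, s$atoms$label)
    if (is.na(i)) stop("PDB ", path, ": ANISOU for undefined atom ", nm)
    s <- set_atom_adp_cart(s, i, aniso[[nm]])
  }
  s
}

format_pdb <- function(s) {
  bad <- s$atoms$label[nchar(s$atoms$label) > 4]
  if (length(bad)) {
    stop("PDB atom names limited to 4 characters; offending atoms: ",
         paste(bad, collapse = ", "))
  }
  pos <- atom_positions(s)
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 s$cell$a, s$cell$b, s$cell$c, s$cell$alpha, s$cell$beta,
                 s$cell$gamma)
  if (!is.na(s$temperature)) {
    out <- c(out, sprintf("REMARK 200  TEMPERATURE           (KELVIN) : %.1f",
                          s$temperature))
  }
  for (i in seq_len(nrow(s$atoms))) {
    a <- s$atoms[i, ]
    ucart <- atom_adp_cart(s, i)
    biso <- if (!is.null(ucart)) {
      8 * pi^2 * u_iso(ucart)
    } else if (!is.na(a$uiso)) 8 * pi^2 * a$uiso else 0
    out <- c(out, sprintf(
      "ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$label, pos[i, 1], pos[i, 2], pos[i, 3], a$occ, biso,
      toupper(a$element)))
    if (!is.null(ucart)) {
      ui <- round(ucart * 1e4)
      out <- c(out, sprintf(
        "ANISOU%5d %-4s MOL A   1  %7d%7d%7d%7d%7d%7d      %2s",
        i, a$label, ui[1], ui[2], ui[3], ui[6], ui[5], ui[4],
        toupper(a$element)))
    }
  }
  c(out, "END")
}
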