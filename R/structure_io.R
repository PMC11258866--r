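## Structure container and readers/writers for POSCAR, extended XYZ and P1 CIF.

## Element symbol <-> atomic number lookup (Z 1..96 is ample for framework
## materials). Deuterium/tritium map to Z = 1.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm")

#' Resolve element symbols to atomic numbers
#'
#' Symbols are case-normalized; `D` and `T` map to hydrogen (Z = 1).
#' @param symbols character vector of element symbols
#' @return integer vector of atomic numbers
#' @export
element_number <- function(symbols) {
  s <- paste0(toupper(substr(symbols, 1L, 1L)),
              tolower(substr(symbols, 2L, nchar(symbols))))
  s[s %in% c("D", "T")] <- "H"
  z <- match(s, .element_symbols)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' @rdname element_number
#' @param z integer vector of atomic numbers
#' @export
element_symbol <- function(z) .element_symbols[z]

#' Construct a periodic structure
#'
#' The central container: lattice vectors (rows of a 3x3 matrix, Angstrom),
#' per-atom atomic numbers, and Cartesian positions (Angstrom). Non-periodic
#' molecules use `periodic = FALSE`; their lattice is only a bounding box and
#' no image arithmetic is performed on them.
#'
#' @param lattice 3x3 numeric matrix; row i is lattice vector i (Angstrom)
#' @param elements integer atomic numbers or character element symbols
#' @param positions N x 3 numeric matrix of Cartesian positions (Angstrom)
#' @param periodic logical; treat the lattice as periodic boundary conditions
#' @param wrap wrap fractional coordinates into `[0, 1)` (periodic only)
#' @return an object of class `periodic_structure`
#' @export
periodic_structure <- function(lattice, elements, positions, periodic = TRUE,
                               wrap = TRUE) {
  lattice <- matrix(as.numeric(lattice), 3L, 3L)
  if (is.character(elements)) elements <- element_number(elements)
  positions <- matrix(as.numeric(positions), ncol = 3L)
  if (nrow(positions) < 1L) stop("structure must contain at least one atom")
  if (length(elements) != nrow(positions)) {
    stop("elements and positions disagree on the number of atoms")
  }
  if (periodic && abs(det(lattice)) < 1e-8) {
    stop("lattice vectors are not linearly independent")
  }
  x <- structure(
    list(lattice = lattice, elements = as.integer(elements),
         positions = positions, periodic = isTRUE(periodic)),
    class = "periodic_structure")
  if (periodic && wrap) x <- wrap_positions(x) else x
}

#' Number of atoms in a structure
#' @param structure a `periodic_structure`
#' @return integer atom count
#' @export
n_atoms <- function(structure) nrow(structure$positions)

#' @export
print.periodic_structure <- function(x, ...) {
  cat(sprintf("periodic_structure: %d atoms (%s), %s\n",
              n_atoms(x),
              paste(names(table(element_symbol(x$elements))), collapse = " "),
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

#' Read a structure file
#'
#' Supported formats: VASP POSCAR (`poscar`; direct and Cartesian dialects),
#' extended XYZ with a `Lattice="..."` tag (`xyz`; absent tag gives a
#' non-periodic molecule in a bounding box), and P1 CIF (`cif`; cell
#' parameters plus a fractional `atom_site` loop). CIF files carrying symmetry
#' operations beyond P1, partial occupancies or disorder records are rejected.
#'
#' @param path file path
#' @param format one of `"cif"`, `"poscar"`, `"xyz"`; default guesses from the
#'   file extension
#' @return a `periodic_structure` with positions wrapped into the cell
#' @export
read_structure <- function(path, format = c("auto", "cif", "poscar", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "cif") "cif"
      else if (ext %in% c("xyz", "extxyz")) "xyz"
      else "poscar"
  }
  switch(format,
         cif = read_cif(path),
         poscar = read_poscar(path),
         xyz = read_extxyz(path))
}

read_poscar <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 8L) stop("POSCAR parse error: file too short (", path, ")")
  scale <- as.numeric(strsplit(trimws(ln[2L]), "\\s+")[[1L]][1L])
  if (is.na(scale)) stop("POSCAR parse error at line 2: bad scale factor")
  lat <- t(vapply(3:5, function(i) {
    v <- as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1L]])
    if (length(v) < 3L || anyNA(v[1:3])) {
      stop("POSCAR parse error at line ", i, ": bad lattice vector")
    }
    v[1:3]
  }, numeric(3L))) * scale
  if (abs(det(lat)) < 1e-8) {
    stop("POSCAR lattice vectors are not linearly independent")
  }
  symline <- strsplit(trimws(ln[6L]), "\\s+")[[1L]]
  if (all(grepl("^[0-9]+$", symline))) {
    stop("POSCAR without element-symbol line (VASP4 dialect) is not supported; ",
         "add the symbols line")
  }
  counts <- as.integer(strsplit(trimws(ln[7L]), "\\s+")[[1L]])
  if (anyNA(counts)) stop("POSCAR parse error at line 7: bad atom counts")
  idx <- 8L
  if (grepl("^[Ss]", trimws(ln[idx]))) idx <- idx + 1L  # Selective dynamics
  mode <- trimws(ln[idx])
  cartesian <- grepl("^[CcKk]", mode)
  idx <- idx + 1L
  n <- sum(counts)
  coords <- t(vapply(seq_len(n), function(i) {
    v <- as.numeric(strsplit(trimws(ln[idx + i - 1L]), "\\s+")[[1L]])
    if (length(v) < 3L || anyNA(v[1:3])) {
      stop("POSCAR parse error at line ", idx + i - 1L, ": bad coordinates")
    }
    v[1:3]
  }, numeric(3L)))
  pos <- if (cartesian) coords * scale else coords %*% lat
  periodic_structure(lat, rep(element_number(symline), counts), pos)
}

#' Write a structure as a VASP POSCAR
#' @param structure a `periodic_structure`
#' @param path output path
#' @param comment header comment line
#' @return invisibly, `path`
#' @export
write_poscar <- function(structure, path, comment = "flexff") {
  sym <- element_symbol(structure$elements)
  ord <- order(match(sym, unique(sym)))
  frac <- structure$positions %*% solve(structure$lattice)
  lines <- c(comment, "1.0",
             apply(structure$lattice, 1L, function(v)
               sprintf("%20.12f %20.12f %20.12f", v[1L], v[2L], v[3L])),
             paste(unique(sym), collapse = " "),
             paste(as.integer(table(factor(sym, levels = unique(sym)))),
                   collapse = " "),
             "Direct",
             apply(frac[ord, , drop = FALSE], 1L, function(v)
               sprintf("%18.12f %18.12f %18.12f", v[1L], v[2L], v[3L])))
  writeLines(lines, path)
  invisible(path)
}

read_extxyz <- function(path) {
  ln <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(ln[1L])))
  if (is.na(n)) stop("XYZ parse error at line 1: expected atom count")
  if (length(ln) < n + 2L) stop("XYZ parse error: truncated file")
  comment <- ln[2L]
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  rows <- strsplit(trimws(ln[3:(n + 2L)]), "\\s+")
  sym <- vapply(rows, `[[`, character(1L), 1L)
  pos <- t(vapply(rows, function(r) {
    v <- suppressWarnings(as.numeric(r[2:4]))
    if (anyNA(v)) stop("XYZ parse error: bad coordinate row")
    v
  }, numeric(3L)))
  if (length(m) == 1L) {
    lv <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", m), "\\s+")[[1L]])
    if (length(lv) != 9L || anyNA(lv)) stop("XYZ parse error: bad Lattice tag")
    lat <- matrix(lv, 3L, 3L, byrow = TRUE)
    periodic_structure(lat, element_number(sym), pos)
  } else {
    span <- apply(pos, 2L, function(x) diff(range(x)))
    lat <- diag(pmax(span + 15, 20))
    periodic_structure(lat, element_number(sym), pos, periodic = FALSE)
  }
}

#' Write one or more geometries as (multi-frame) extended XYZ
#' @param structures a `periodic_structure` or list of them (shared topology)
#' @param path output path
#' @param comments optional per-frame comment suffixes
#' @return invisibly, `path`
#' @export
write_extxyz <- function(structures, path, comments = NULL) {
  if (inherits(structures, "periodic_structure")) structures <- list(structures)
  out <- unlist(lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    lat <- paste(sprintf("%.10f", t(s$lattice)), collapse = " ")
    head <- sprintf('Lattice="%s" Properties=species:S:1:pos:R:3%s', lat,
                    if (is.null(comments)) "" else paste0(" ", comments[[i]]))
    body <- sprintf("%-2s %18.12f %18.12f %18.12f",
                    element_symbol(s$elements),
                    s$positions[, 1L], s$positions[, 2L], s$positions[, 3L])
    c(as.character(n_atoms(s)), head, body)
  }))
  writeLines(out, path)
  invisible(path)
}

## --- minimal P1 CIF ---------------------------------------------------------

lattice_from_cell <- function(a, b, c, alpha, beta, gamma) {
  al <- alpha * pi / 180; be <- beta * pi / 180; ga <- gamma * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- c * cos(be)
  cy <- c * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(c^2 - cx^2 - cy^2, 0))
  rbind(v1, v2, c(cx, cy, cz))
}

read_cif <- function(path) {
  ln <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    i <- grep(paste0("^\\s*", tag, "\\b"), ln)
    if (!length(i)) return(NA_real_)
    val <- strsplit(trimws(ln[i[1L]]), "\\s+")[[1L]][2L]
    as.numeric(sub("\\(.*\\)", "", val))  # strip esd parentheses
  }
  cell <- c(a = grab("_cell_length_a"), b = grab("_cell_length_b"),
            c = grab("_cell_length_c"), alpha = grab("_cell_angle_alpha"),
            beta = grab("_cell_angle_beta"), gamma = grab("_cell_angle_gamma"))
  if (anyNA(cell)) stop("CIF parse error: missing cell parameters in ", path)
  symops <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop", ln)
  if (length(symops)) {
    ops <- grep("^\\s*[0-9']*\\s*'?[xyz, +\\-0-9/']+'?\\s*$", ln, value = TRUE)
    nontrivial <- ops[!grepl("^\\s*[0-9]*\\s*'?\\s*x\\s*,\\s*y\\s*,\\s*z\\s*'?\\s*$",
                             ops)]
    if (length(nontrivial)) {
      stop("CIF carries symmetry operations beyond P1; expand to P1 first")
    }
  }
  loops <- grep("^\\s*loop_", ln)
  site <- NULL
  for (l in loops) {
    i <- l + 1L
    headers <- character()
    while (i <= length(ln) && grepl("^\\s*_", ln[i])) {
      headers <- c(headers, trimws(ln[i])); i <- i + 1L
    }
    if (any(grepl("^_atom_site_fract_x", headers))) {
      rows <- list()
      while (i <= length(ln) && nzchar(trimws(ln[i])) &&
             !grepl("^\\s*(loop_|_|#|data_)", ln[i])) {
        rows[[length(rows) + 1L]] <- strsplit(trimws(ln[i]), "\\s+")[[1L]]
        i <- i + 1L
      }
      site <- list(headers = headers, rows = rows)
      break
    }
  }
  if (is.null(site)) stop("CIF parse error: no atom_site loop in ", path)
  col <- function(tag) match(tag, site$headers)
  ix <- col("_atom_site_fract_x"); iy <- col("_atom_site_fract_y")
  iz <- col("_atom_site_fract_z")
  ity <- col("_atom_site_type_symbol")
  if (is.na(ity)) ity <- col("_atom_site_label")
  iocc <- col("_atom_site_occupancy")
  num <- function(s) as.numeric(sub("\\(.*\\)", "", s))
  sym <- character(); frac <- NULL
  for (r in site$rows) {
    if (!is.na(iocc)) {
      occ <- num(r[iocc])
      if (is.finite(occ) && abs(occ - 1) > 1e-4) {
        stop("CIF records fractional occupancy/disorder; structure rejected")
      }
    }
    sym <- c(sym, sub("[0-9].*$", "", r[ity]))
    frac <- rbind(frac, c(num(r[ix]), num(r[iy]), num(r[iz])))
  }
  if (anyNA(frac)) stop("CIF parse error: bad fractional coordinates")
  lat <- lattice_from_cell(cell["a"], cell["b"], cell["c"],
                           cell["alpha"], cell["beta"], cell["gamma"])
  periodic_structure(lat, element_number(sym), frac %*% lat)
}

#' Write a structure as a P1 CIF
#' @param structure a `periodic_structure`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_cif <- function(structure, path) {
  lat <- structure$lattice
  a <- vnorm(lat[1L, ]); b <- vnorm(lat[2L, ]); cc <- vnorm(lat[3L, ])
  ang <- function(u, v) acos(sum(u * v) / (vnorm(u) * vnorm(v))) * 180 / pi
  frac <- structure$positions %*% solve(lat)
  frac <- frac - floor(frac)
  sym <- element_symbol(structure$elements)
  lines <- c(
    "data_flexff",
    sprintf("_cell_length_a %.10f", a),
    sprintf("_cell_length_b %.10f", b),
    sprintf("_cell_length_c %.10f", cc),
    sprintf("_cell_angle_alpha %.10f", ang(lat[2L, ], lat[3L, ])),
    sprintf("_cell_angle_beta %.10f", ang(lat[1L, ], lat[3L, ])),
    sprintf("_cell_angle_gamma %.10f", ang(lat[1L, ], lat[2L, ])),
    "_symmetry_space_group_name_H-M 'P 1'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    sprintf("%s%d %s %.10f %.10f %.10f", sym, seq_along(sym), sym,
            frac[, 1L], frac[, 2L], frac[, 3L]))
  writeLines(lines, path)
  invisible(path)
}
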