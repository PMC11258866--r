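## Bond perception over periodic images, second-neighbor atom typing, and
## unit-cell adequacy validation.

#' Default per-element typing radii
#'
#' Two atoms are perceived as bonded when their distance does not exceed the
#' sum of their typing radii (times `tolerance_scale`). The bundled table is a
#' covalent-radius-style default with a 0.10 Angstrom perception margin folded
#' in; it is a documented stand-in that callers can override element-wise via
#' the `radii` argument of [detect_bonds()].
#'
#' @return named numeric vector (Angstrom) keyed by element symbol
#' @export
default_typing_radii <- function() {
  c(H = 0.41, He = 0.38, Li = 1.38, Be = 1.06, B = 0.94, C = 0.86, N = 0.81,
    O = 0.76, F = 0.67, Ne = 0.68, Na = 1.76, Mg = 1.51, Al = 1.31, Si = 1.21,
    P = 1.17, S = 1.15, Cl = 1.12, Ar = 1.16, K = 2.13, Ca = 1.86, Sc = 1.80,
    Ti = 1.70, V = 1.63, Cr = 1.49, Mn = 1.49, Fe = 1.42, Co = 1.36, Ni = 1.34,
    Cu = 1.42, Zn = 1.32, Ga = 1.32, Ge = 1.30, As = 1.29, Se = 1.30,
    Br = 1.30, Kr = 1.26, Rb = 2.30, Sr = 2.05, Y = 2.00, Zr = 1.85,
    Nb = 1.74, Mo = 1.64, Tc = 1.57, Ru = 1.56, Rh = 1.52, Pd = 1.49,
    Ag = 1.55, Cd = 1.54, In = 1.52, Sn = 1.49, Sb = 1.49, Te = 1.48,
    I = 1.49, Xe = 1.50, Cs = 2.54, Ba = 2.25, La = 2.17, Ce = 2.14,
    Hf = 1.85, Ta = 1.80, W = 1.72, Re = 1.61, Os = 1.54, Ir = 1.51,
    Pt = 1.46, Au = 1.46, Hg = 1.42, Tl = 1.55, Pb = 1.56, Bi = 1.58,
    U = 2.06)
}

.all_translations27 <- as.matrix(expand.grid(t1 = -1:1, t2 = -1:1, t3 = -1:1))

#' Perceive bonds across periodic images
#'
#' Every reference-cell atom is checked for bonds to atoms in the reference
#' cell and in the 26 surrounding image cells. Two atoms are bonded iff their
#' distance is at most `tolerance_scale` times the sum of their typing radii.
#' Each physical bond is stored once as a canonical edge
#' `(a, b, translation)` meaning atom `a` in the reference cell bonded to the
#' image of atom `b` translated by `translation`; the edge is symmetric under
#' swapping endpoints with negated translation.
#'
#' @param structure a `periodic_structure`
#' @param radii named numeric vector of per-element typing radii (Angstrom);
#'   defaults to [default_typing_radii()]
#' @param tolerance_scale positive scalar multiplying the radius sum
#' @param min_distance atoms closer than this (Angstrom) raise an
#'   overlapping-atom error
#' @return object of class `bond_graph`: a data frame of edges
#'   (`a`, `b`, `t1`, `t2`, `t3`, `length`) plus a neighbor-list attribute
#' @export
detect_bonds <- function(structure, radii = default_typing_radii(),
                         tolerance_scale = 1.0, min_distance = 0.4) {
  n <- n_atoms(structure)
  sym <- element_symbol(structure$elements)
  miss <- setdiff(unique(sym), names(radii))
  if (length(miss)) {
    stop("no typing radius defined for element(s): ",
         paste(miss, collapse = ", "))
  }
  r <- unname(radii[sym])
  trans <- if (structure$periodic) .all_translations27 else
    matrix(0L, 1L, 3L, dimnames = list(NULL, c("t1", "t2", "t3")))
  pos <- structure$positions
  edges <- list()
  for (k in seq_len(nrow(trans))) {
    tvec <- as.numeric(trans[k, ] %*% structure$lattice)
    shifted <- sweep(pos, 2L, tvec, FUN = "+")
    for (a in seq_len(n)) {
      d2 <- rowSums(sweep(shifted, 2L, pos[a, ])^2)
      cut <- (tolerance_scale * (r[a] + r))^2
      self <- all(trans[k, ] == 0L)
      hit <- which(d2 <= cut)
      if (self) hit <- hit[hit != a]
      for (b in hit) {
        d <- sqrt(d2[b])
        if (d < min_distance) {
          stop(sprintf("overlapping atoms: %d and %d (image %s) at %.3f A",
                       a, b, paste(trans[k, ], collapse = ","), d))
        }
        ## canonical form: a < b, or a == b with lexicographically positive t
        tt <- as.integer(trans[k, ])
        if (a < b || (a == b && .lex_positive(tt))) {
          edges[[length(edges) + 1L]] <- c(a, b, tt, d)
        }
      }
    }
  }
  if (!length(edges)) stop("no bonds perceived in structure")
  e <- do.call(rbind, edges)
  e <- unique(as.data.frame(e))
  names(e) <- c("a", "b", "t1", "t2", "t3", "length")
  rownames(e) <- NULL
  e <- e[order(e$a, e$b, e$t1, e$t2, e$t3), , drop = FALSE]
  isolated <- setdiff(seq_len(n), unique(c(e$a, e$b)))
  if (length(isolated)) {
    stop("isolated atom(s) with zero bonds: ", paste(isolated, collapse = ", "))
  }
  g <- structure(e, class = c("bond_graph", "data.frame"))
  attr(g, "neighbors") <- .neighbor_list(g, n)
  g
}

.lex_positive <- function(t) {
  if (t[1L] != 0L) return(t[1L] > 0L)
  if (t[2L] != 0L) return(t[2L] > 0L)
  t[3L] > 0L
}

## per-atom neighbor images: matrix (b, t1, t2, t3) for each reference atom
.neighbor_list <- function(graph, n) {
  nb <- vector("list", n)
  for (i in seq_len(nrow(graph))) {
    a <- graph$a[i]; b <- graph$b[i]
    tt <- as.integer(c(graph$t1[i], graph$t2[i], graph$t3[i]))
    nb[[a]] <- rbind(nb[[a]], c(b, tt))
    nb[[b]] <- rbind(nb[[b]], c(a, -tt))
  }
  lapply(nb, function(m) {
    m <- m[order(m[, 1L], m[, 2L], m[, 3L], m[, 4L]), , drop = FALSE]
    colnames(m) <- c("atom", "t1", "t2", "t3")
    m
  })
}

#' Neighbor images of an atom
#' @param graph a `bond_graph`
#' @param atom reference-cell atom index
#' @return matrix with columns `atom`, `t1`, `t2`, `t3`
#' @export
bond_neighbors <- function(graph, atom) attr(graph, "neighbors")[[atom]]

#' @export
print.bond_graph <- function(x, ...) {
  if (is.null(x$length)) {
    print.data.frame(x)
  } else {
    cat(sprintf("bond_graph: %d edges, mean length %.3f A\n", nrow(x),
                mean(x$length)))
  }
  invisible(x)
}

#' Assign second-neighbor atom-type signatures
#'
#' Each atom's type signature lists its atomic number, then its sorted first
#' neighbors, each annotated with the sorted atomic numbers of that neighbor's
#' other neighbors (an H atom with no other neighbor is annotated `(0)`).
#' Two atoms in identical first-and-second-neighbor environments produce
#' byte-identical signatures.
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph` for the structure
#' @return character vector of per-atom signatures, e.g.
#'   `"6[1-(0),1-(0),1-(0),6-(1,1,8)]"`
#' @export
assign_atom_types <- function(structure, graph) {
  n <- n_atoms(structure)
  z <- structure$elements
  nbrs <- attr(graph, "neighbors")
  vapply(seq_len(n), function(a) {
    nb <- nbrs[[a]]
    entries <- vapply(seq_len(nrow(nb)), function(i) {
      b <- nb[i, 1L]
      ## the neighbor's other neighbors: all its bonds minus one bond back to a
      bnb <- nbrs[[b]][, 1L]
      back <- match(a, bnb)
      others <- sort(z[bnb[-back]])
      ann <- if (length(others)) paste(others, collapse = ",") else "0"
      sprintf("%d-(%s)", z[b], ann)
    }, character(1L))
    ord <- order(z[nb[, 1L]], entries)
    sprintf("%d[%s]", z[a], paste(entries[ord], collapse = ","))
  }, character(1L))
}

#' Validate unit-cell adequacy for flexibility typing
#'
#' The protocol requires that each atom is bonded to only one image of any
#' particular neighbor atom; otherwise periodic images move in unison and
#' vibrational stretches between them cannot exist. Fails iff some ordered
#' atom pair has two or more bonds with distinct translations (a cell too
#' small along some direction); fix by expanding to a supercell.
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph`
#' @return list with `ok` (logical) and `offending` (data frame of pairs)
#' @export
validate_unit_cell <- function(structure, graph) {
  nbrs <- attr(graph, "neighbors")
  bad <- list()
  for (a in seq_len(n_atoms(structure))) {
    nb <- nbrs[[a]]
    for (b in unique(nb[, 1L])) {
      k <- sum(nb[, 1L] == b)
      if (k >= 2L) bad[[length(bad) + 1L]] <- c(a = a, b = b, n_images = k)
    }
  }
  offending <- if (length(bad)) {
    unique(as.data.frame(do.call(rbind, bad)))
  } else {
    data.frame(a = integer(), b = integer(), n_images = integer())
  }
  list(ok = nrow(offending) == 0L, offending = offending)
}
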