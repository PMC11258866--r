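## Ring detection on the periodic image graph: exhaustive 3-/4-membered ring
## search (for angle flags and Urey-Bradley diagonals) and a bounded cycle
## search deciding whether a bond belongs to any bond-path cycle. In a periodic
## crystal, if a bond is part of a cycle then some cycle through it contains
## fewer than 4*N_atoms + 1 atoms, so the search depth is capped there.

node_key <- function(atom, t) paste(atom, t[1L], t[2L], t[3L], sep = "_")

## canonical identity of a physical bond (edge modulo translation):
## orient so the (atom, translation-difference) pair is lexicographically
## minimal with the first atom in the reference cell.
edge_id <- function(a, ta, b, tb) {
  dt <- tb - ta
  k1 <- c(a, b, dt)
  k2 <- c(b, a, -dt)
  key <- if (.edge_lt(k1, k2)) k1 else k2
  paste(key, collapse = "_")
}

.edge_lt <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] != y[i]) return(x[i] < y[i])
  }
  FALSE
}

#' Find all 3- and 4-membered rings in the bond graph
#'
#' Rings are searched on the image graph so that rings closing through
#' periodic boundaries are found; each ring is reported once, anchored at a
#' reference-cell atom, as a matrix of image rows `(atom, t1, t2, t3)`.
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph`
#' @return list with elements `ring3` and `ring4`, each a list of image
#'   matrices, plus `ring3_edges`/`ring4_edges`: character sets of member
#'   bond ids
#' @keywords internal
find_small_rings <- function(structure, graph) {
  nbrs <- attr(graph, "neighbors")
  n <- n_atoms(structure)
  ring3 <- list(); ring4 <- list()
  seen3 <- character(); seen4 <- character()
  canon_ring <- function(imgs) {
    ## normalize under rotation/reflection/translation
    m <- nrow(imgs)
    best <- NULL
    for (s in seq_len(m)) for (dir in c(1L, -1L)) {
      idx <- ((seq_len(m) - 1L) * dir + (s - 1L)) %% m + 1L
      mm <- imgs[idx, , drop = FALSE]
      mm[, 2:4] <- sweep(mm[, 2:4, drop = FALSE], 2L, as.integer(mm[1L, 2:4]))
      key <- paste(t(mm), collapse = "_")
      if (is.null(best) || key < best) best <- key
    }
    best
  }
  for (a in seq_len(n)) {
    nb <- nbrs[[a]]
    k <- nrow(nb)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      bi <- nb[i, 1L]; ti <- as.integer(nb[i, 2:4])
      bj <- nb[j, 1L]; tj <- as.integer(nb[j, 2:4])
      ## 3-ring: neighbors i and j bonded to each other
      if (.images_bonded(nbrs, bi, ti, bj, tj)) {
        imgs <- rbind(c(a, 0L, 0L, 0L), c(bi, ti), c(bj, tj))
        key <- canon_ring(imgs)
        if (!(key %in% seen3)) {
          seen3 <- c(seen3, key); ring3[[length(ring3) + 1L]] <- imgs
        }
      }
      ## 4-ring: a common fourth image bonded to both i and j, not a itself
      nbi <- nbrs[[bi]]; nbj <- nbrs[[bj]]
      for (u in seq_len(nrow(nbi))) {
        cu <- nbi[u, 1L]; tu <- as.integer(nbi[u, 2:4]) + ti
        if (cu == a && all(tu == 0L)) next
        if (cu == bj && all(tu == tj)) next
        for (v in seq_len(nrow(nbj))) {
          cv <- nbj[v, 1L]; tv <- as.integer(nbj[v, 2:4]) + tj
          if (cu == cv && all(tu == tv)) {
            imgs <- rbind(c(a, 0L, 0L, 0L), c(bi, ti), c(cu, tu), c(bj, tj))
            key <- canon_ring(imgs)
            if (!(key %in% seen4)) {
              seen4 <- c(seen4, key); ring4[[length(ring4) + 1L]] <- imgs
            }
          }
        }
      }
    }
  }
  ring_edges <- function(rings) {
    unique(unlist(lapply(rings, function(imgs) {
      m <- nrow(imgs)
      vapply(seq_len(m), function(i) {
        j <- i %% m + 1L
        edge_id(imgs[i, 1L], as.integer(imgs[i, 2:4]),
                imgs[j, 1L], as.integer(imgs[j, 2:4]))
      }, character(1L))
    })))
  }
  list(ring3 = ring3, ring4 = ring4,
       ring3_edges = ring_edges(ring3) %||% character(),
       ring4_edges = ring_edges(ring4) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.images_bonded <- function(nbrs, a, ta, b, tb) {
  nb <- nbrs[[a]]
  dt <- tb - ta
  any(nb[, 1L] == b & nb[, 2L] == dt[1L] & nb[, 3L] == dt[2L] &
        nb[, 4L] == dt[3L])
}

#' Is a bond part of any bond-path cycle?
#'
#' A bond belongs to a ring iff a closed bond walk through it exists. On the
#' periodic image graph this means: starting from the bond's endpoint image
#' `(b, t)` there is a bond path, never re-traversing the starting bond
#' instance itself, that reaches *any* image of atom `a` (reaching a
#' translated image closes the cycle through the quotient bond graph; for a
#' one-atom periodic chain the bond's own translated copies legitimately
#' continue the walk, so such a bond is in a ring). If any cycle through a
#' bond exists, one with fewer than `4 * N_atoms + 1` atoms exists, so the
#' breadth-first search is depth-capped there and remains exact.
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph`
#' @param bond integer vector `c(a, b, t1, t2, t3)`: atom `a` in the reference
#'   cell bonded to image `(b, t)`
#' @return logical
#' @export
middle_bond_in_ring <- function(structure, graph, bond) {
  a <- bond[1L]; b <- bond[2L]; tb <- as.integer(bond[3:5])
  nbrs <- attr(graph, "neighbors")
  if (!.images_bonded(nbrs, a, c(0L, 0L, 0L), b, tb)) {
    stop("bond not present in graph")
  }
  nmax <- 4L * n_atoms(structure)
  forbid_from <- node_key(b, tb)   # the one lifted copy of the starting bond
  forbid_to <- node_key(a, c(0L, 0L, 0L))
  frontier <- list(list(atom = b, t = tb))
  visited <- new.env(parent = emptyenv())
  assign(forbid_from, TRUE, envir = visited)
  depth <- 1L
  while (length(frontier) && depth < nmax) {
    nxt <- list()
    for (node in frontier) {
      nb <- nbrs[[node$atom]]
      from_key <- node_key(node$atom, node$t)
      for (i in seq_len(nrow(nb))) {
        at2 <- nb[i, 1L]
        t2 <- as.integer(nb[i, 2:4]) + node$t
        key <- node_key(at2, t2)
        if (from_key == forbid_from && key == forbid_to) next
        if (at2 == a) return(TRUE)
        if (!exists(key, envir = visited, inherits = FALSE)) {
          assign(key, TRUE, envir = visited)
          nxt[[length(nxt) + 1L]] <- list(atom = at2, t = t2)
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  FALSE
}
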