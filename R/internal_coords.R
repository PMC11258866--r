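## Enumeration and typing of stretch/angle/dihedral instances with periodic
## bookkeeping: duplicate weights for translated copies, 3-/4-ring flags,
## Urey-Bradley diagonals, and the redundancy measure.

tkey <- function(t) paste(t[1L], t[2L], t[3L], sep = ",")

#' Enumerate stretch instances (bonds + Urey-Bradley diagonals)
#'
#' Every perceived bond becomes a bond-stretch instance; the two diagonals of
#' every 4-membered ring become Urey-Bradley stretch instances. A stretch
#' whose endpoints lie in different cells appears twice in the list (once per
#' endpoint shifted into the reference cell) and carries `n_duplicates = 2`;
#' energy bookkeeping weights each copy by `1/n_duplicates`. Endpoints are
#' ordered so their type signatures are in alphabetical order (ties broken by
#' atom index, then translation).
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph`
#' @param atom_types per-atom signatures from [assign_atom_types()]
#' @param rings ring search result from `find_small_rings()`
#' @return data frame of stretch instances
#' @export
enumerate_stretches <- function(structure, graph,
                                atom_types = assign_atom_types(structure, graph),
                                rings = find_small_rings(structure, graph)) {
  rows <- list()
  add <- function(p, tp, q, tq, kind) {
    ## order endpoints alphabetically by signature (tie: index, translation)
    o1 <- list(at = p, t = tp); o2 <- list(at = q, t = tq)
    k1 <- c(atom_types[p], sprintf("%09d", p), tkey(tp))
    k2 <- c(atom_types[q], sprintf("%09d", q), tkey(tq))
    if (paste(k2, collapse = "|") < paste(k1, collapse = "|")) {
      tmp <- o1; o1 <- o2; o2 <- tmp
    }
    d <- vnorm(image_position(structure, o2$at, o2$t) -
                 image_position(structure, o1$at, o1$t))
    dup <- !all((o2$t - o1$t) == 0L)
    base <- o1$t
    for (shift in if (dup) list(-o1$t, -o2$t) else list(-o1$t)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        a = o1$at, ta1 = o1$t[1L] + shift[1L], ta2 = o1$t[2L] + shift[2L],
        ta3 = o1$t[3L] + shift[3L],
        b = o2$at, tb1 = o2$t[1L] + shift[1L], tb2 = o2$t[2L] + shift[2L],
        tb3 = o2$t[3L] + shift[3L],
        kind = kind, d_eq = d, n_duplicates = if (dup) 2L else 1L,
        edge = edge_id(o1$at, o1$t, o2$at, o2$t),
        stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(graph))) {
    add(graph$a[i], c(0L, 0L, 0L), graph$b[i],
        as.integer(c(graph$t1[i], graph$t2[i], graph$t3[i])), "bond")
  }
  for (ring in rings$ring4) {
    add(ring[1L, 1L], as.integer(ring[1L, 2:4]),
        ring[3L, 1L], as.integer(ring[3L, 2:4]), "urey_bradley")
    add(ring[2L, 1L], as.integer(ring[2L, 2:4]),
        ring[4L, 1L], as.integer(ring[4L, 2:4]), "urey_bradley")
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$kind, out$a, out$b, out$ta1, out$ta2, out$ta3,
                   out$tb1, out$tb2, out$tb3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate angle instances
#'
#' One instance per pair of bonds sharing a reference-cell center atom; no
#' duplicates. The ring flag is `ring3`/`ring4` iff both constituent bonds
#' belong to the same 3-/4-membered ring, `none` otherwise.
#'
#' @inheritParams enumerate_stretches
#' @return data frame of angle instances
#' @export
enumerate_angles <- function(structure, graph,
                             atom_types = assign_atom_types(structure, graph),
                             rings = find_small_rings(structure, graph)) {
  nbrs <- attr(graph, "neighbors")
  rows <- list()
  for (b in seq_len(n_atoms(structure))) {
    nb <- nbrs[[b]]
    k <- nrow(nb)
    if (k < 2L) next
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      p <- nb[i, 1L]; tp <- as.integer(nb[i, 2:4])
      q <- nb[j, 1L]; tq <- as.integer(nb[j, 2:4])
      k1 <- paste(atom_types[p], sprintf("%09d", p), tkey(tp), sep = "|")
      k2 <- paste(atom_types[q], sprintf("%09d", q), tkey(tq), sep = "|")
      if (k2 < k1) {
        tmp <- p; p <- q; q <- tmp
        tmpt <- tp; tp <- tq; tq <- tmpt
      }
      th <- geom_angle(image_position(structure, p, tp),
                       structure$positions[b, ],
                       image_position(structure, q, tq))
      rows[[length(rows) + 1L]] <- data.frame(
        center = b, p = p, tp1 = tp[1L], tp2 = tp[2L], tp3 = tp[3L],
        q = q, tq1 = tq[1L], tq2 = tq[2L], tq3 = tq[3L],
        theta_eq = th,
        edge_p = edge_id(b, c(0L, 0L, 0L), p, tp),
        edge_q = edge_id(b, c(0L, 0L, 0L), q, tq),
        ring_flag = "none", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(center = integer(), p = integer(), tp1 = integer(),
                      tp2 = integer(), tp3 = integer(), q = integer(),
                      tq1 = integer(), tq2 = integer(), tq3 = integer(),
                      theta_eq = numeric(), edge_p = character(),
                      edge_q = character(), ring_flag = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ## ring flags: both bonds of the angle consecutive in the same ring
  flag_ring <- function(out, ring_list, label) {
    for (imgs in ring_list) {
      m <- nrow(imgs)
      for (i in seq_len(m)) {
        prev <- (i - 2L) %% m + 1L
        nxt <- i %% m + 1L
        ctr <- imgs[i, 1L]; tc <- as.integer(imgs[i, 2:4])
        e1 <- edge_id(ctr, c(0L, 0L, 0L), imgs[prev, 1L],
                      as.integer(imgs[prev, 2:4]) - tc)
        e2 <- edge_id(ctr, c(0L, 0L, 0L), imgs[nxt, 1L],
                      as.integer(imgs[nxt, 2:4]) - tc)
        hit <- out$center == ctr &
          ((out$edge_p == e1 & out$edge_q == e2) |
             (out$edge_p == e2 & out$edge_q == e1))
        out$ring_flag[hit & out$ring_flag == "none"] <- label
      }
    }
    out
  }
  out <- flag_ring(out, rings$ring4, "ring4")
  out <- flag_ring(out, rings$ring3, "ring3")
  out[order(out$center, out$p, out$q, out$tp1, out$tp2, out$tp3,
            out$tq1, out$tq2, out$tq3), , drop = FALSE]
}

## normalized identity of an angle modulo translation (center shifted to the
## reference cell, outer images sorted)
.angle_norm_key <- function(center, tc, p, tp, q, tq) {
  tp <- tp - tc; tq <- tq - tc
  kp <- paste(sprintf("%09d", p), tkey(tp), sep = "|")
  kq <- paste(sprintf("%09d", q), tkey(tq), sep = "|")
  if (kq < kp) paste(center, kq, kp, sep = "#") else paste(center, kp, kq, sep = "#")
}

#' Enumerate proper dihedral instances
#'
#' Dihedrals are generated by adding a bond to either end of each angle whose
#' center atom lies in the reference cell, so every instance has at least one
#' middle atom in the reference cell. An instance with identical translation
#' indices is kept once; a translated copy of the same physical dihedral may
#' appear twice (`n_duplicates = 2`). Instances containing a 3-membered ring,
#' or whose contained angles lie inside a 4-membered ring, are deleted.
#'
#' @inheritParams enumerate_stretches
#' @param angles angle instances from [enumerate_angles()]
#' @return data frame of dihedral instances with `middle_in_ring` set
#' @export
enumerate_dihedrals <- function(structure, graph,
                                angles,
                                atom_types = assign_atom_types(structure, graph)) {
  nbrs <- attr(graph, "neighbors")
  cand <- new.env(parent = emptyenv())
  add_cand <- function(A, tA, B, tB, C, tC, D, tD) {
    if (A == D && all(tA == tD)) return(invisible())
    ## dedupe identical translation sets incl. reversal
    fwd <- paste(A, tkey(tA), B, tkey(tB), C, tkey(tC), D, tkey(tD), sep = "#")
    rev <- paste(D, tkey(tD), C, tkey(tC), B, tkey(tB), A, tkey(tA), sep = "#")
    key <- min(fwd, rev)
    if (!exists(key, envir = cand, inherits = FALSE)) {
      assign(key, list(A = A, tA = tA, B = B, tB = tB, C = C, tC = tC,
                       D = D, tD = tD), envir = cand)
    }
    invisible()
  }
  for (i in seq_len(nrow(angles))) {
    B <- angles$center[i]; tB <- c(0L, 0L, 0L)
    P <- angles$p[i]; tP <- as.integer(c(angles$tp1[i], angles$tp2[i], angles$tp3[i]))
    Q <- angles$q[i]; tQ <- as.integer(c(angles$tq1[i], angles$tq2[i], angles$tq3[i]))
    ## extend at each end: angle is P-B-Q; bonds from P give dihedrals X-P-B-Q,
    ## bonds from Q give P-B-Q-Y
    for (end in list(list(o = P, to = tP, b2 = Q, t2 = tQ),
                     list(o = Q, to = tQ, b2 = P, t2 = tP))) {
      nb <- nbrs[[end$o]]
      for (k in seq_len(nrow(nb))) {
        X <- nb[k, 1L]; tX <- as.integer(nb[k, 2:4]) + end$to
        if (X == B && all(tX == tB)) next
        add_cand(X, tX, end$o, end$to, B, tB, end$b2, end$t2)
      }
    }
  }
  keys <- sort(ls(cand))
  if (!length(keys)) {
    return(data.frame(a = integer(), b = integer(), c = integer(), d = integer()))
  }
  ## angle lookup: normalized key -> row / ring flag / theta
  akey <- vapply(seq_len(nrow(angles)), function(i) {
    .angle_norm_key(angles$center[i], c(0L, 0L, 0L), angles$p[i],
                    as.integer(c(angles$tp1[i], angles$tp2[i], angles$tp3[i])),
                    angles$q[i],
                    as.integer(c(angles$tq1[i], angles$tq2[i], angles$tq3[i])))
  }, character(1L))
  rows <- list()
  for (key in keys) {
    z <- get(key, envir = cand)
    ## canonical direction: lexicographically smaller signature tuple
    sig_f <- paste(atom_types[c(z$A, z$B, z$C, z$D)], collapse = "|")
    sig_r <- paste(atom_types[c(z$D, z$C, z$B, z$A)], collapse = "|")
    flip <- sig_r < sig_f
    if (!flip && sig_r == sig_f) {
      idx_f <- paste(sprintf("%09d", c(z$A, z$B, z$C, z$D)),
                     tkey(z$tA), tkey(z$tB), tkey(z$tC), tkey(z$tD),
                     collapse = "|")
      idx_r <- paste(sprintf("%09d", c(z$D, z$C, z$B, z$A)),
                     tkey(z$tD), tkey(z$tC), tkey(z$tB), tkey(z$tA),
                     collapse = "|")
      flip <- idx_r < idx_f
    }
    if (flip) {
      z <- list(A = z$D, tA = z$tD, B = z$C, tB = z$tC, C = z$B, tC = z$tB,
                D = z$A, tD = z$tA)
    }
    ang1 <- match(.angle_norm_key(z$B, z$tB, z$A, z$tA, z$C, z$tC), akey)
    ang2 <- match(.angle_norm_key(z$C, z$tC, z$B, z$tB, z$D, z$tD), akey)
    if (is.na(ang1) || is.na(ang2)) {
      stop("internal error: contained angle of dihedral not found")
    }
    ## deletion rules: any contained angle inside a 3- or 4-membered ring
    if (angles$ring_flag[ang1] != "none" || angles$ring_flag[ang2] != "none") next
    ## contains a 3-membered ring: A bonded to C, or B bonded to D
    if (.images_bonded(nbrs, z$A, z$tA, z$C, z$tC) ||
        .images_bonded(nbrs, z$B, z$tB, z$D, z$tD)) next
    phi <- geom_dihedral(image_position(structure, z$A, z$tA),
                         image_position(structure, z$B, z$tB),
                         image_position(structure, z$C, z$tC),
                         image_position(structure, z$D, z$tD))
    ## physical identity modulo translation (and reversal)
    ids <- c(paste(z$A, z$B, z$C, z$D,
                   tkey(z$tA - z$tB), tkey(z$tC - z$tB), tkey(z$tD - z$tB),
                   sep = "#"),
             paste(z$D, z$C, z$B, z$A,
                   tkey(z$tD - z$tC), tkey(z$tB - z$tC), tkey(z$tA - z$tC),
                   sep = "#"))
    rows[[length(rows) + 1L]] <- data.frame(
      a = z$A, ta1 = z$tA[1L], ta2 = z$tA[2L], ta3 = z$tA[3L],
      b = z$B, tb1 = z$tB[1L], tb2 = z$tB[2L], tb3 = z$tB[3L],
      c = z$C, tc1 = z$tC[1L], tc2 = z$tC[2L], tc3 = z$tC[3L],
      d = z$D, td1 = z$tD[1L], td2 = z$tD[2L], td3 = z$tD[3L],
      phi_eq = phi, sign_eq = if (phi >= 0) 1L else -1L,
      ang1 = ang1, ang2 = ang2,
      middle = edge_id(z$B, z$tB, z$C, z$tC),
      phys_id = min(ids), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(a = integer(), b = integer(), c = integer(), d = integer()))
  }
  rownames(out) <- NULL
  dupes <- table(out$phys_id)
  out$n_duplicates <- as.integer(dupes[out$phys_id])
  if (any(out$n_duplicates > 2L)) {
    stop("internal error: dihedral instance repeated more than twice")
  }
  ## middle-bond-in-ring per physical middle bond
  mids <- unique(out$middle)
  in_ring <- vapply(mids, function(id) {
    parts <- strsplit(id, "_")[[1L]]
    middle_bond_in_ring(structure, graph,
                        as.integer(parts))
  }, logical(1L))
  out$middle_in_ring <- in_ring[match(out$middle, mids)]
  out[order(out$a, out$b, out$c, out$d, out$ta1, out$ta2, out$ta3,
            out$td1, out$td2, out$td3), , drop = FALSE]
}

#' Group internal-coordinate instances into types
#'
#' Stretches group by atom-type pair and kind, with each instance joining an
#' existing type iff its equilibrium length is within 1 percent of the type's
#' first (reference) member; angles group by bond-type pair and equilibrium
#' angle rounded to 0.01 rad; dihedrals group by contained-angle-type pair and
#' `|phi_eq|` rounded to 0.01 rad. Disambiguation numbers count 0, 1, 2, ...
#' per atom-type combination in order of first appearance. Instance counts per
#' type count translated duplicates once.
#'
#' @param structure a `periodic_structure`
#' @param graph a `bond_graph`
#' @param stretch_tol relative window for stretch equilibrium lengths (0.01)
#' @param round_digits decimal digits of radians for angle/dihedral rounding
#' @return an object of class `icoord_set`
#' @export
type_internal_coords <- function(structure, graph, stretch_tol = 0.01,
                                 round_digits = 2L) {
  atom_types <- assign_atom_types(structure, graph)
  rings <- find_small_rings(structure, graph)
  st <- enumerate_stretches(structure, graph, atom_types, rings)
  an <- enumerate_angles(structure, graph, atom_types, rings)
  di <- enumerate_dihedrals(structure, graph, an, atom_types)

  ## --- stretch types (anchored 1% window) ---
  st$pair <- paste(st$kind, atom_types[st$a], atom_types[st$b], sep = " | ")
  st$type <- NA_integer_
  stypes <- list()
  for (i in seq_len(nrow(st))) {
    assigned <- FALSE
    for (k in seq_along(stypes)) {
      ty <- stypes[[k]]
      if (ty$pair == st$pair[i] &&
          abs(st$d_eq[i] - ty$ref) < stretch_tol * ty$ref) {
        st$type[i] <- k; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      stypes[[length(stypes) + 1L]] <- list(pair = st$pair[i], ref = st$d_eq[i],
                                            kind = st$kind[i])
      st$type[i] <- length(stypes)
    }
  }
  stretch_types <- do.call(rbind, lapply(seq_along(stypes), function(k) {
    sel <- st[st$type == k, , drop = FALSE]
    data.frame(type = k, kind = stypes[[k]]$kind, pair = stypes[[k]]$pair,
               d_eq_ref = stypes[[k]]$ref, d_eq_mean = mean(unique(sel$edge) |>
                 vapply(function(e) sel$d_eq[match(e, sel$edge)], numeric(1L))),
               n_instances = length(unique(sel$edge)),
               stringsAsFactors = FALSE)
  }))
  stretch_types$disambig <- stats::ave(seq_len(nrow(stretch_types)),
                                       stretch_types$pair,
                                       FUN = seq_along) - 1L

  ## --- angle types ---
  bond_rows <- st[st$kind == "bond", , drop = FALSE]
  edge2btype <- bond_rows$type[match(unique(bond_rows$edge), bond_rows$edge)]
  names(edge2btype) <- unique(bond_rows$edge)
  an$bt_p <- unname(edge2btype[an$edge_p])
  an$bt_q <- unname(edge2btype[an$edge_q])
  ## order outer atoms further by bond type where signatures tie
  swap <- atom_types[an$p] == atom_types[an$q] & an$bt_q < an$bt_p
  if (any(swap)) {
    tmp <- an[swap, c("p", "tp1", "tp2", "tp3", "edge_p", "bt_p")]
    an[swap, c("p", "tp1", "tp2", "tp3", "edge_p", "bt_p")] <-
      an[swap, c("q", "tq1", "tq2", "tq3", "edge_q", "bt_q")]
    an[swap, c("q", "tq1", "tq2", "tq3", "edge_q", "bt_q")] <- tmp
  }
  an$theta_round <- round(an$theta_eq, round_digits)
  akey <- paste(an$bt_p, an$bt_q, sprintf("%.*f", round_digits, an$theta_round))
  an$type <- match(akey, unique(akey))
  angle_types <- do.call(rbind, lapply(seq_len(length(unique(akey))), function(k) {
    sel <- an[an$type == k, , drop = FALSE]
    data.frame(type = k, bt_p = sel$bt_p[1L], bt_q = sel$bt_q[1L],
               trip = paste(atom_types[sel$p[1L]], atom_types[sel$center[1L]],
                            atom_types[sel$q[1L]], sep = " | "),
               theta_round = sel$theta_round[1L],
               theta_eq_mean = mean(sel$theta_eq),
               ring_flag = sel$ring_flag[1L],
               n_instances = nrow(sel), stringsAsFactors = FALSE)
  }))
  if (is.null(angle_types)) {
    angle_types <- data.frame(type = integer(), bt_p = integer(),
                              bt_q = integer(), trip = character(),
                              theta_round = numeric(),
                              theta_eq_mean = numeric(),
                              ring_flag = character(),
                              n_instances = integer())
  }
  angle_types$disambig <- if (nrow(angle_types)) {
    stats::ave(seq_len(nrow(angle_types)), angle_types$trip,
               FUN = seq_along) - 1L
  } else integer()

  ## --- dihedral types ---
  if (nrow(di)) {
    di$angtype1 <- an$type[di$ang1]
    di$angtype2 <- an$type[di$ang2]
    di$abs_phi_round <- round(abs(di$phi_eq), round_digits)
    dkey <- paste(di$angtype1, di$angtype2,
                  sprintf("%.*f", round_digits, di$abs_phi_round))
    di$type <- match(dkey, unique(dkey))
    dihedral_types <- do.call(rbind, lapply(seq_len(max(di$type)), function(k) {
      sel <- di[di$type == k, , drop = FALSE]
      data.frame(type = k, angtype1 = sel$angtype1[1L],
                 angtype2 = sel$angtype2[1L],
                 quad = paste(atom_types[sel$a[1L]], atom_types[sel$b[1L]],
                              atom_types[sel$c[1L]], atom_types[sel$d[1L]],
                              sep = " | "),
                 abs_phi_round = sel$abs_phi_round[1L],
                 abs_phi_mean = mean(abs(sel$phi_eq[!duplicated(sel$phys_id)])),
                 theta_eq_1 = angle_types$theta_eq_mean[an$type[sel$ang1[1L]]],
                 theta_eq_2 = angle_types$theta_eq_mean[an$type[sel$ang2[1L]]],
                 any_middle_in_ring = any(sel$middle_in_ring),
                 n_instances = length(unique(sel$phys_id)),
                 classification = "unset", stringsAsFactors = FALSE)
    }))
    dihedral_types$disambig <- stats::ave(seq_len(nrow(dihedral_types)),
                                          dihedral_types$quad,
                                          FUN = seq_along) - 1L
  } else {
    di$type <- integer(0)
    dihedral_types <- data.frame(type = integer(), classification = character())
  }

  out <- list(structure = structure, graph = graph, atom_types = atom_types,
              rings = rings,
              stretch_instances = st, stretch_types = stretch_types,
              angle_instances = an, angle_types = angle_types,
              dihedral_instances = di, dihedral_types = dihedral_types,
              stretch_active = rep(TRUE, nrow(stretch_types)),
              angle_active = angle_types$ring_flag == "none",
              dihedral_active = rep(TRUE, nrow(dihedral_types)))
  class(out) <- "icoord_set"
  out
}

#' @export
print.icoord_set <- function(x, ...) {
  cat(sprintf(paste0("icoord_set: %d stretch instances (%d types), ",
                     "%d angles (%d types, %d active), ",
                     "%d dihedral instances (%d types, %d active)\n"),
              nrow(x$stretch_instances), nrow(x$stretch_types),
              nrow(x$angle_instances), nrow(x$angle_types),
              sum(x$angle_active),
              nrow(x$dihedral_instances), nrow(x$dihedral_types),
              sum(x$dihedral_active)))
  invisible(x)
}

#' Internal coordinate redundancy (percent)
#'
#' `100 * (num_active_instances - (3 N - 3)) / (3 N - 3)` where active
#' instances count bond and Urey-Bradley stretches, angles outside 3-/4-rings,
#' and dihedrals surviving the ring rules and pruning; translated duplicates
#' count once.
#'
#' @param icset an `icoord_set`
#' @param n_atoms_ override atom count (defaults to the set's structure)
#' @return percentage (numeric scalar)
#' @export
compute_icr <- function(icset, n_atoms_ = n_atoms(icset$structure)) {
  if (n_atoms_ < 2L) stop("internal coordinate redundancy undefined for n < 2")
  st <- icset$stretch_instances
  n_st <- length(unique(st$edge[icset$stretch_active[st$type]]))
  n_an <- sum(icset$angle_active[icset$angle_instances$type])
  di <- icset$dihedral_instances
  n_di <- if (nrow(di)) {
    length(unique(di$phys_id[icset$dihedral_active[di$type]]))
  } else 0L
  dof <- 3L * n_atoms_ - 3L
  100 * (n_st + n_an + n_di - dof) / dof
}

#' Replace per-instance equilibria by type averages
#'
#' Stretch and angle equilibria are averaged over the (deduplicated) members
#' of each type; dihedral equilibria average the absolute values, each
#' instance keeping its own sign.
#'
#' @param icset an `icoord_set`
#' @return the set with instance equilibrium columns replaced by averages
#' @export
average_equilibrium_values <- function(icset) {
  st <- icset$stretch_instances
  for (k in seq_len(nrow(icset$stretch_types))) {
    sel <- st$type == k
    m <- mean(st$d_eq[sel & !duplicated(st$edge)])
    st$d_eq[sel] <- m
  }
  icset$stretch_instances <- st
  an <- icset$angle_instances
  for (k in seq_len(nrow(icset$angle_types))) {
    sel <- an$type == k
    an$theta_eq[sel] <- mean(an$theta_eq[sel])
  }
  icset$angle_instances <- an
  di <- icset$dihedral_instances
  if (nrow(di)) {
    for (k in seq_len(nrow(icset$dihedral_types))) {
      sel <- di$type == k
      m <- mean(abs(di$phi_eq[sel & !duplicated(di$phys_id)]))
      di$phi_eq[sel] <- di$sign_eq[sel] * m
    }
    icset$dihedral_instances <- di
  }
  icset
}

#' Write the typed internal-coordinate inventory to CSV files
#'
#' Emits `<prefix>_stretches.csv`, `<prefix>_angles.csv`,
#' `<prefix>_dihedrals.csv` mirroring the instance record layouts
#' (atom numbers, translation triples, type and disambiguation numbers, ring
#' flags, duplicate counts).
#'
#' @param icset an `icoord_set`
#' @param prefix output path prefix
#' @return invisibly, the vector of files written
#' @export
write_icoords_csv <- function(icset, prefix) {
  f1 <- paste0(prefix, "_stretches.csv")
  st <- icset$stretch_instances
  st$disambig <- icset$stretch_types$disambig[st$type]
  utils::write.csv(st, f1, row.names = FALSE)
  f2 <- paste0(prefix, "_angles.csv")
  an <- icset$angle_instances
  an$disambig <- icset$angle_types$disambig[an$type]
  utils::write.csv(an, f2, row.names = FALSE)
  f3 <- paste0(prefix, "_dihedrals.csv")
  di <- icset$dihedral_instances
  if (nrow(di)) {
    di$disambig <- icset$dihedral_types$disambig[di$type]
    di$classification <- icset$dihedral_types$classification[di$type]
  }
  utils::write.csv(di, f3, row.names = FALSE)
  invisible(c(f1, f2, f3))
}
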