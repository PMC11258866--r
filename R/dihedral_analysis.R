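## Dihedral-type classification, symmetry-preserving pruning of coupled
## dihedral types, rigid torsion-scan generation (Rodrigues rotation), and
## hindered-rotor detection by atom-type comparison along the scan.

#' Classify dihedral types as linear / nonrotatable / provisional-rotatable
#'
#' A type is `linear` iff either contained equilibrium bond angle is within
#' `eps_linear` of pi; else `nonrotatable` iff any one or more of its
#' instances has a middle bond belonging to a bond-path cycle (mixed
#' ring/no-ring types are wholly nonrotatable); else
#' `provisional_rotatable`, to be resolved to rotatable/hindered by
#' [detect_hindered()].
#'
#' @param icset an `icoord_set`
#' @param eps_linear tolerance (radians) on pi minus the equilibrium angle
#' @return the set with `dihedral_types$classification` filled
#' @export
classify_dihedral_types <- function(icset, eps_linear = 0.03) {
  dt <- icset$dihedral_types
  if (!nrow(dt)) return(icset)
  cls <- ifelse(pi - dt$theta_eq_1 < eps_linear |
                  pi - dt$theta_eq_2 < eps_linear, "linear",
                ifelse(dt$any_middle_in_ring, "nonrotatable",
                       "provisional_rotatable"))
  icset$dihedral_types$classification <- cls
  icset
}

## deduplicated middle-bond set per dihedral type, as a canonical string
.middle_bond_sets <- function(icset) {
  di <- icset$dihedral_instances
  vapply(icset$dihedral_types$type, function(k) {
    paste(sort(unique(di$middle[di$type == k])), collapse = ";")
  }, character(1L))
}

#' Prune coupled dihedral types
#'
#' Dihedral types sharing an identical deduplicated set of middle-bond
#' instances are coupled: rotating one rotates all, so only one is retained.
#' Within each coupled group the type maximizing
#' `(180 deg - max(theta_eq_ABC, theta_eq_BCD)) / num_instances`
#' is kept (ties broken by a seeded random draw); all instances of discarded
#' types are deactivated together, preserving symmetry equivalency. Pruning
#' whole types, never single instances, and is idempotent.
#'
#' @param icset an `icoord_set` with classifications assigned
#' @param seed integer seed for tie-breaking
#' @return list with the pruned `icoord_set` (`icset`) and a `report` data
#'   frame (type, group, metric, retained)
#' @export
prune_dihedral_types <- function(icset, seed = 1L) {
  dt <- icset$dihedral_types
  if (!nrow(dt)) {
    return(list(icset = icset, report = data.frame()))
  }
  active <- which(icset$dihedral_active)
  sets <- .middle_bond_sets(icset)
  metric <- (180 - pmax(dt$theta_eq_1, dt$theta_eq_2) * 180 / pi) /
    dt$n_instances
  groups <- split(active, sets[active])
  rng <- .seeded_rng(seed, "prune")
  retained <- logical(nrow(dt))
  group_id <- integer(nrow(dt))
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    group_id[g] <- gi
    best <- g[metric[g] == max(metric[g])]
    keep <- if (length(best) == 1L) best else best[.rng_int(rng, length(best))]
    retained[keep] <- TRUE
  }
  icset$dihedral_active <- icset$dihedral_active & retained
  report <- data.frame(type = dt$type, group = group_id,
                       classification = dt$classification,
                       metric = metric, n_instances = dt$n_instances,
                       retained = icset$dihedral_active)
  list(icset = icset, report = report)
}

## small deterministic RNG stream independent of the global seed state
.seeded_rng <- function(seed, tag) {
  env <- new.env(parent = emptyenv())
  env$state <- (as.numeric(seed) * 2654435761 +
                  sum(utf8ToInt(tag))) %% 2147483647
  if (env$state == 0) env$state <- 42
  env
}

.rng_unif <- function(rng) {
  ## Park-Miller minimal standard generator
  rng$state <- (rng$state * 16807) %% 2147483647
  rng$state / 2147483647
}

.rng_int <- function(rng, n) 1L + as.integer(floor(.rng_unif(rng) * n)) %% n

.rng_norm <- function(rng, n = 1L) {
  ## Box-Muller
  u1 <- vapply(seq_len(n), function(i) .rng_unif(rng), numeric(1L))
  u2 <- vapply(seq_len(n), function(i) .rng_unif(rng), numeric(1L))
  sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
}

## bonded group attached through one middle atom of a dihedral: the connected
## component grown from the middle-atom image with the middle bond itself
## removed, excluding the middle atom. Returns image rows (atom, t1, t2, t3),
## or NULL if the component is unbounded (periodic through-bond continuation).
.bonded_group <- function(icset, mid, tmid, other, tother, max_radius = 3L) {
  nbrs <- attr(icset$graph, "neighbors")
  res <- list()
  frontier <- list(list(atom = mid, t = as.integer(tmid)))
  visited <- new.env(parent = emptyenv())
  start_key <- node_key(mid, tmid)
  other_key <- node_key(other, tother)
  assign(start_key, TRUE, envir = visited)
  while (length(frontier)) {
    node <- frontier[[1L]]
    frontier <- frontier[-1L]
    from_key <- node_key(node$atom, node$t)
    if (from_key != start_key) res[[length(res) + 1L]] <- c(node$atom, node$t)
    nb <- nbrs[[node$atom]]
    for (i in seq_len(nrow(nb))) {
      at2 <- nb[i, 1L]
      t2 <- as.integer(nb[i, 2:4]) + node$t
      key <- node_key(at2, t2)
      if (from_key == start_key && key == other_key) next  # the middle bond
      if (key == other_key) {
        stop("middle bond closes a bond-path cycle; dihedral is not rotatable")
      }
      if (any(abs(t2) > max_radius)) return(NULL)  # unbounded through bonds
      if (!exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        frontier[[length(frontier) + 1L]] <- list(atom = at2, t = t2)
      }
    }
  }
  if (!length(res)) return(matrix(integer(), 0L, 4L))
  do.call(rbind, res)
}

#' Generate a rigid torsion scan for one dihedral instance
#'
#' The smaller bonded group (the component attached to atom A or to atom D
#' after conceptually removing the middle bond B-C) is rigidly rotated about
#' the middle-bond axis by `theta_rot = phi_desired - phi_eq` (Rodrigues'
#' rotation), with the rotation origin at the middle atom adjacent to the
#' rotated group (B for the A-side, C for the D-side; equal group sizes
#' rotate the D side). Rotated positions are re-wrapped into the cell; all
#' other atoms are untouched, so every bond length and angle is preserved and
#' each dihedral across the middle bond shifts by exactly `theta_rot`.
#'
#' @param icset an `icoord_set`
#' @param instance_row row index into `icset$dihedral_instances`
#' @param step_deg scan increment in degrees (default 10: 36 geometries at
#'   -170, -160, ..., 180)
#' @return object of class `torsion_scan`: list with `phi_deg`,
#'   `theta_rot`, `geometries` (list of `periodic_structure`), and scanned
#'   instance bookkeeping
#' @export
generate_torsion_scan <- function(icset, instance_row, step_deg = 10) {
  di <- icset$dihedral_instances[instance_row, ]
  if (isTRUE(di$middle_in_ring)) {
    stop("refusing to scan a dihedral whose middle bond is part of a ring")
  }
  structure0 <- icset$structure
  tA <- as.integer(c(di$ta1, di$ta2, di$ta3))
  tB <- as.integer(c(di$tb1, di$tb2, di$tb3))
  tC <- as.integer(c(di$tc1, di$tc2, di$tc3))
  tD <- as.integer(c(di$td1, di$td2, di$td3))
  grpA <- .bonded_group(icset, di$b, tB, di$c, tC)  # A side, through B
  grpD <- .bonded_group(icset, di$c, tC, di$b, tB)  # D side, through C
  if (is.null(grpA) && is.null(grpD)) {
    stop("both bonded groups are unbounded; dihedral cannot be rigidly rotated")
  }
  ## an unbounded side (periodic through-bond continuation) counts as the
  ## larger group: the finite side is rotated
  sizeA <- if (is.null(grpA)) Inf else nrow(grpA)
  sizeD <- if (is.null(grpD)) Inf else nrow(grpD)
  rotate_A <- sizeA < sizeD
  grp <- if (rotate_A) grpA else grpD
  posB <- image_position(structure0, di$b, tB)
  posC <- image_position(structure0, di$c, tC)
  if (rotate_A) {
    origin <- posB
    axis <- (posB - posC)          # pointing toward the chosen origin
  } else {
    origin <- posC
    axis <- (posC - posB)
  }
  phi_eq <- di$phi_eq
  phi_deg <- seq(-180 + step_deg, 180, by = step_deg)
  theta_rot <- phi_deg * pi / 180 - phi_eq
  ## rotating the A group by +theta about the axis toward B decreases phi by
  ## theta with the standard sign convention; flip accordingly
  sgn <- .rotation_sign(structure0, di, tA, tB, tC, tD, grp, axis, origin,
                        rotate_A)
  parents <- grp[, 1L]
  if (anyDuplicated(parents)) {
    stop("rotated group contains two images of the same atom; unit cell too small")
  }
  offsets <- grp[, 2:4, drop = FALSE] %*% structure0$lattice
  ## positions are kept unwrapped so the reference image bookkeeping stays
  ## valid on every scan geometry (wrapping is applied by the writers)
  geoms <- lapply(theta_rot, function(th) {
    s <- structure0
    pts <- s$positions[parents, , drop = FALSE] + offsets
    rot <- rodrigues_rotate(pts, axis, origin, sgn * th)
    s$positions[parents, ] <- rot - offsets
    s
  })
  structure(list(instance_row = instance_row, type = di$type,
                 phi_deg = phi_deg, theta_rot = theta_rot,
                 phi_eq = phi_eq, geometries = geoms, energies = NULL,
                 step_deg = step_deg),
            class = "torsion_scan")
}

## empirical sign: rotate by a small test angle and see which way phi moves
.rotation_sign <- function(structure0, di, tA, tB, tC, tD, grp, axis, origin,
                           rotate_A) {
  eps <- 1e-3
  parents <- grp[, 1L]
  offsets <- grp[, 2:4, drop = FALSE] %*% structure0$lattice
  pts <- structure0$positions[parents, , drop = FALSE] + offsets
  rot <- rodrigues_rotate(pts, axis, origin, eps)
  s <- structure0
  s$positions[parents, ] <- rot - offsets
  p <- function(s, atom, t) image_position(s, atom, t)
  phi0 <- geom_dihedral(p(structure0, di$a, tA), p(structure0, di$b, tB),
                        p(structure0, di$c, tC), p(structure0, di$d, tD))
  phi1 <- geom_dihedral(p(s, di$a, tA), p(s, di$b, tB),
                        p(s, di$c, tC), p(s, di$d, tD))
  d <- phi1 - phi0
  if (d > pi) d <- d - 2 * pi
  if (d < -pi) d <- d + 2 * pi
  if (abs(d) < eps / 10) stop("degenerate dihedral: cannot determine rotation sign")
  if (d > 0) 1 else -1
}

#' Measure a dihedral instance's value on an arbitrary geometry
#' @param icset an `icoord_set`
#' @param instance_row row index into the dihedral instances
#' @param geometry a `periodic_structure` sharing the set's topology
#' @return dihedral value (radians)
#' @export
measure_dihedral <- function(icset, instance_row, geometry) {
  di <- icset$dihedral_instances[instance_row, ]
  geom_dihedral(
    image_position(geometry, di$a, as.integer(c(di$ta1, di$ta2, di$ta3))),
    image_position(geometry, di$b, as.integer(c(di$tb1, di$tb2, di$tb3))),
    image_position(geometry, di$c, as.integer(c(di$tc1, di$tc2, di$tc3))),
    image_position(geometry, di$d, as.integer(c(di$td1, di$td2, di$td3))))
}

#' Resolve provisional-rotatable types to rotatable or hindered
#'
#' For each provisional-rotatable type one instance is selected (seeded
#' random draw) and its rigid torsion scan generated, always starting from
#' the optimized reference geometry. If the per-atom type signatures of every
#' scan geometry match the reference geometry's, the type is `rotatable`;
#' any connectivity change (new contact or broken bond anywhere on the scan)
#' makes it `hindered`. The same scans must be reused for the subsequent
#' single-point energies, so they are returned.
#'
#' @param icset an `icoord_set` (classified, pruned)
#' @param seed integer seed for the instance draws
#' @param step_deg scan increment (degrees)
#' @param radii,tolerance_scale bond-perception parameters for the re-typing
#' @return list with the updated `icset` and `scans`: named list (by type)
#'   of `torsion_scan` objects for the types that remained rotatable
#' @export
detect_hindered <- function(icset, seed = 1L, step_deg = 10,
                            radii = default_typing_radii(),
                            tolerance_scale = 1.0) {
  dt <- icset$dihedral_types
  scans <- list()
  if (!nrow(dt)) return(list(icset = icset, scans = scans))
  rng <- .seeded_rng(seed, "scan")
  ref_types <- icset$atom_types
  prov <- which(dt$classification == "provisional_rotatable" &
                  icset$dihedral_active)
  for (k in prov) {
    rows <- which(icset$dihedral_instances$type == k)
    ## pick among deduplicated physical instances
    phys <- icset$dihedral_instances$phys_id[rows]
    reps <- rows[!duplicated(phys)]
    pick <- reps[if (length(reps) == 1L) 1L else .rng_int(rng, length(reps))]
    scan <- generate_torsion_scan(icset, pick, step_deg = step_deg)
    ok <- TRUE
    for (g in scan$geometries) {
      types_g <- tryCatch({
        gg <- detect_bonds(g, radii = radii, tolerance_scale = tolerance_scale)
        assign_atom_types(g, gg)
      }, error = function(e) NULL)
      if (is.null(types_g) || !identical(types_g, ref_types)) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      icset$dihedral_types$classification[k] <- "rotatable"
      scans[[as.character(k)]] <- scan
    } else {
      icset$dihedral_types$classification[k] <- "hindered"
    }
  }
  ## provisional types pruned away are never scanned; mark them unset
  still <- icset$dihedral_types$classification == "provisional_rotatable"
  icset$dihedral_types$classification[still] <- "unset"
  list(icset = icset, scans = scans)
}

#' Export scan geometries and manifest
#' @param scan a `torsion_scan`
#' @param prefix output path prefix (writes `<prefix>.extxyz` and
#'   `<prefix>_manifest.csv`)
#' @return invisibly, the files written
#' @export
write_torsion_scan <- function(scan, prefix) {
  f1 <- paste0(prefix, ".extxyz")
  write_extxyz(scan$geometries, f1,
               comments = sprintf("phi_deg=%g", scan$phi_deg))
  f2 <- paste0(prefix, "_manifest.csv")
  utils::write.csv(data.frame(type = scan$type,
                              instance_row = scan$instance_row,
                              phi_deg = scan$phi_deg,
                              theta_rot = scan$theta_rot,
                              energy = if (is.null(scan$energies)) NA else
                                scan$energies),
                   f2, row.names = FALSE)
  invisible(c(f1, f2))
}
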