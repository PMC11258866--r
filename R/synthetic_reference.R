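## Synthetic-reference oracle: idealized fixture structures, hidden
## ground-truth flexibility models, and generation of complete reference
## datasets (optimized geometry, finite-displacement sets, pseudo-dynamics
## trajectories, rigid-torsion-scan energies) that stand in for the
## quantum-chemistry engine, so the whole pipeline is testable at desk scale.

.unit <- function(v) v / vnorm(v)

#' Construct a named fixture structure
#'
#' Deterministic idealized geometries: staggered ethane; linear carbon
#' dioxide; bent water; octahedral sulfur hexafluoride; cyclopropane;
#' a planar cyclobutane ring with one exocyclic hydrogen per ring atom;
#' a small periodic framework (`toy_rotor_framework`) combining a
#' periodically bonded near-linear backbone, a two-bond rotor side group,
#' and a square 4-membered ring; a one-atom-per-cell periodic chain
#' (`chain_1atom`, deliberately failing the unit-cell adequacy check); and a
#' four-atom rock-salt-like chain supercell (`nacl_supercell`) that passes it.
#'
#' @param name fixture name
#' @return a `periodic_structure`
#' @export
make_fixture <- function(name = c("ethane", "co2", "h2o", "sf6",
                                  "cyclopropane", "cyclobutane_capped",
                                  "toy_rotor_framework", "chain_1atom",
                                  "nacl_supercell")) {
  name <- match.arg(name)
  box <- function(l) diag(rep(l, 3L))
  switch(name,
    ethane = {
      ccz <- 1.54 / 2
      zc <- 1.09 * cos(69 * pi / 180)
      rr <- 1.09 * sin(69 * pi / 180)
      pos <- rbind(c(0, 0, ccz), c(0, 0, -ccz))
      for (az in c(0, 120, 240) * pi / 180) {
        pos <- rbind(pos, c(rr * cos(az), rr * sin(az), ccz + zc))
      }
      for (az in c(60, 180, 300) * pi / 180) {
        pos <- rbind(pos, c(rr * cos(az), rr * sin(az), -ccz - zc))
      }
      periodic_structure(box(20), c("C", "C", rep("H", 6L)), pos,
                         periodic = FALSE)
    },
    co2 = periodic_structure(box(20), c("C", "O", "O"),
                             rbind(c(0, 0, 0), c(0, 0, 1.16), c(0, 0, -1.16)),
                             periodic = FALSE),
    h2o = {
      a <- 104.5 / 2 * pi / 180
      periodic_structure(box(20), c("O", "H", "H"),
                         rbind(c(0, 0, 0),
                               c(0.96 * sin(a), 0, 0.96 * cos(a)),
                               c(-0.96 * sin(a), 0, 0.96 * cos(a))),
                         periodic = FALSE)
    },
    sf6 = periodic_structure(box(20), c("S", rep("F", 6L)),
                             rbind(c(0, 0, 0),
                                   1.56 * diag(3L), -1.56 * diag(3L)),
                             periodic = FALSE),
    cyclopropane = {
      r <- 1.51 / (2 * sin(pi / 3))
      pos <- NULL
      el <- c()
      for (az in c(90, 210, 330) * pi / 180) {
        u <- c(cos(az), sin(az), 0)
        cpos <- r * u
        pos <- rbind(pos, cpos, cpos + c(0.53 * u[1:2], 0.95),
                     cpos + c(0.53 * u[1:2], -0.95))
        el <- c(el, "C", "H", "H")
      }
      periodic_structure(box(20), el, pos, periodic = FALSE)
    },
    cyclobutane_capped = {
      r <- 1.55 / sqrt(2)
      pos <- NULL
      el <- c()
      sgn <- 1
      for (az in c(45, 135, 225, 315) * pi / 180) {
        u <- c(cos(az), sin(az), 0)
        cpos <- r * u
        pos <- rbind(pos, cpos, cpos + c(0.70 * u[1:2], sgn * 0.835))
        el <- c(el, "C", "H")
        sgn <- -sgn
      }
      periodic_structure(box(20), el, pos, periodic = FALSE)
    },
    toy_rotor_framework = {
      lat <- rbind(c(4.5, 0, 0), c(0, 14, 0), c(0, 0, 14))
      dy <- 0.010
      c1 <- c(0.0, dy, 0)
      c2 <- c(1.5, -dy, 0)
      c3 <- c(3.0, dy, 0)
      h1 <- c1 + 1.09 * .unit(c(0, 0.40, 1.00))
      h2 <- c3 + 1.09 * .unit(c(0, 0.40, -1.00))
      or <- c2 + 1.43 * .unit(c(0, -1.30, -0.60))
      u1 <- .unit(c2 - or)
      v1 <- .unit(cross3(u1, c(1, 0, 0)))
      cr <- or + 1.43 * (cos(111 * pi / 180) * u1 + sin(111 * pi / 180) * v1)
      u2 <- .unit(or - cr)
      w1 <- .unit(cross3(u2, c(1, 0, 0)))
      w2 <- cross3(u2, w1)
      hr <- lapply(c(90, 270) * pi / 180, function(g) {
        cr + 1.09 * (cos(109.5 * pi / 180) * u2 +
                       sin(109.5 * pi / 180) * (cos(g) * w1 + sin(g) * w2))
      })
      nc <- c(2.2, 5.0, 7.0)
      nring <- rbind(nc + c(0.65, 0.65, 0), nc + c(-0.65, 0.65, 0),
                     nc + c(-0.65, -0.65, 0), nc + c(0.65, -0.65, 0))
      periodic_structure(lat,
                         c("C", "C", "C", "H", "H", "O", "C", "H", "H",
                           rep("N", 4L)),
                         rbind(c1, c2, c3, h1, h2, or, cr, hr[[1L]], hr[[2L]],
                               nring))
    },
    chain_1atom = periodic_structure(rbind(c(1.5, 0, 0), c(0, 15, 0),
                                           c(0, 0, 15)),
                                     "C", rbind(c(0, 0, 0))),
    nacl_supercell = periodic_structure(rbind(c(11.2, 0, 0), c(0, 15, 0),
                                              c(0, 0, 15)),
                                        c("Na", "Cl", "Na", "Cl"),
                                        rbind(c(0, 0, 0), c(2.8, 0, 0),
                                              c(5.6, 0, 0), c(8.4, 0, 0)))
  )
}

#' Define a synthetic-reference oracle
#'
#' Builds the fixture's typed internal-coordinate set through the standard
#' pipeline front end (typing, classification, pruning, hindered detection),
#' assembles a hidden flexibility model with planted torsion modes, and
#' assigns hidden force constants: deterministic seeded draws in
#' physically plausible ranges (bond stretches 15-35 eV/A^2, Urey-Bradley
#' 3-8 eV/A^2, angle bends 2-6 eV, single-mode torsions 0.1-0.5 eV, rotor
#' modes 0.3-1 eV), with linear-dihedral modes and bond-bond cross terms
#' planted at zero unless `k_override` says otherwise. The hidden model is
#' stationary at the fixture's reference geometry by construction.
#'
#' @param fixture fixture name (see [make_fixture()]) or a
#'   `periodic_structure`
#' @param seed integer seed governing pruning ties, scan-instance draws and
#'   the hidden force constants
#' @param planted_modes named list (by dihedral type index as character) of
#'   mode vectors for rotatable types; unnamed default plants mode 3
#' @param noise_sigma_force additive Gaussian noise on forces (eV/A)
#' @param noise_sigma_energy additive Gaussian noise on scan energies (eV)
#' @param cross_terms include bond-bond cross terms in the hidden model
#' @param k_override named numeric vector, label pattern -> force constant,
#'   matched against term labels by regular expression
#' @param anharmonic add a small cubic perturbation to the stretch forces
#'   (model misspecification test)
#' @param config pipeline configuration, see [pipeline_config()]
#' @return an object of class `oracle_spec`
#' @export
oracle_spec <- function(fixture, seed = 1L, planted_modes = list(),
                        noise_sigma_force = 0, noise_sigma_energy = 0,
                        cross_terms = FALSE, k_override = NULL,
                        anharmonic = FALSE, config = pipeline_config(seed = seed)) {
  structure0 <- if (inherits(fixture, "periodic_structure")) fixture
    else make_fixture(fixture)
  config$seed <- seed
  config$cross_terms <- cross_terms  # fitting mirrors the hidden model family
  prep <- prepare_icset(structure0, config)
  icset <- prep$icset
  rot <- which(icset$dihedral_types$classification == "rotatable" &
                 icset$dihedral_active)
  modes <- list()
  for (k in rot) {
    kk <- as.character(k)
    modes[[kk]] <- if (!is.null(planted_modes[[kk]])) {
      as.integer(planted_modes[[kk]])
    } else 3L
  }
  model <- assign_term_kinds(icset, selected_modes = modes,
                             cross_terms = cross_terms,
                             addt_linear = config$addt_linear,
                             case_threshold_deg = config$case_threshold_deg)
  rng <- .seeded_rng(seed, "oracle-k")
  k <- vapply(model$terms, function(tm) {
    draw <- function(lo, hi) lo + (hi - lo) * .rng_unif(rng)
    switch(tm$kind,
           bond_stretch = draw(15, 35),
           ub_stretch = draw(3, 8),
           angle_bend = draw(2, 6),
           torsion_cadt_mode = if (identical(tm$classification, "rotatable"))
             draw(0.3, 1.0) else draw(0.1, 0.5),
           torsion_addt_mode = if (identical(tm$classification, "rotatable"))
             draw(0.3, 1.0) else draw(0.1, 0.5),
           torsion_addt_linear_mode = 0,
           bond_bond_cross = 0)
  }, numeric(1L))
  if (!is.null(k_override)) {
    labels <- vapply(model$terms, `[[`, character(1L), "label")
    for (pat in names(k_override)) {
      k[grepl(pat, labels)] <- k_override[[pat]]
    }
  }
  model$k <- k
  ## the hidden model must be stationary at the reference geometry
  f0 <- evaluate_forces(model, structure0, mode = "analytic")
  if (max(abs(f0)) > 1e-8) {
    stop("hidden model is not stationary at the reference geometry (max |F| = ",
         format(max(abs(f0))), ")")
  }
  structure(list(structure = structure0, icset = icset, scans = prep$scans,
                 prune_report = prep$prune_report, model = model, seed = seed,
                 noise_sigma_force = noise_sigma_force,
                 noise_sigma_energy = noise_sigma_energy,
                 anharmonic = anharmonic, config = config),
            class = "oracle_spec")
}

#' @export
print.oracle_spec <- function(x, ...) {
  cat(sprintf("oracle_spec: %d-atom fixture, %d hidden terms (%d nonzero), seed %d\n",
              n_atoms(x$structure), length(x$model$terms),
              sum(x$model$k != 0), x$seed))
  invisible(x)
}

## oracle forces (analytic, with optional cubic stretch perturbation)
.oracle_forces <- function(oracle, geometry) {
  f <- evaluate_forces(oracle$model, geometry, mode = "analytic")
  if (oracle$anharmonic) {
    ## small cubic correction on bond stretches: dE = 0.1 k (d-d_eq)^3
    for (j in seq_along(oracle$model$terms)) {
      tm <- oracle$model$terms[[j]]
      if (tm$kind != "bond_stretch" || oracle$model$k[j] == 0) next
      inst <- tm$instances
      for (i in seq_len(nrow(inst))) {
        p1 <- image_position(geometry, inst$a[i],
                             c(inst$ta1[i], inst$ta2[i], inst$ta3[i]))
        p2 <- image_position(geometry, inst$b[i],
                             c(inst$tb1[i], inst$tb2[i], inst$tb3[i]))
        gd <- grad_distance(p1, p2)
        coef <- 0.1 * oracle$model$k[j] * inst$w[i] * 3 *
          (gd$value - inst$d_eq[i])^2
        f[inst$a[i], ] <- f[inst$a[i], ] - coef * gd$grad[1L, ]
        f[inst$b[i], ] <- f[inst$b[i], ] - coef * gd$grad[2L, ]
      }
    }
  }
  f
}

.oracle_energy <- function(oracle, geometry) {
  e <- evaluate_energy(oracle$model, geometry)
  if (oracle$anharmonic) {
    for (j in seq_along(oracle$model$terms)) {
      tm <- oracle$model$terms[[j]]
      if (tm$kind != "bond_stretch" || oracle$model$k[j] == 0) next
      inst <- tm$instances
      for (i in seq_len(nrow(inst))) {
        p1 <- image_position(geometry, inst$a[i],
                             c(inst$ta1[i], inst$ta2[i], inst$ta3[i]))
        p2 <- image_position(geometry, inst$b[i],
                             c(inst$tb1[i], inst$tb2[i], inst$tb3[i]))
        d <- vnorm(p2 - p1)
        e <- e + 0.1 * oracle$model$k[j] * inst$w[i] * (d - inst$d_eq[i])^3
      }
    }
  }
  e
}

#' Generate a complete synthetic reference dataset
#'
#' Emits, from the oracle's hidden model: (i) the optimized geometry with
#' exactly-zero forces; (ii) finite-displacement geometries, each atom
#' displaced by -0.14, -0.07, +0.07, +0.14 Angstrom along x, y and z (12 per
#' atom); (iii) pseudo-dynamics trajectories integrated with velocity Verlet
#' under the hidden model (NVE, seeded Maxwell-Boltzmann start at
#' `temperature` K), split into training and validation runs; and (iv)
#' 36-point rigid-torsion-scan energies for each rotatable dihedral type,
#' evaluated on exactly the scan geometries the classification step used.
#' Optional Gaussian noise is added to forces and scan energies.
#'
#' @param oracle an `oracle_spec`
#' @param n_train_runs,n_valid_runs number of pseudo-dynamics runs
#' @param steps_per_run integration steps per run (1 fs steps)
#' @param displacements finite-displacement amplitudes (Angstrom)
#' @param temperature start temperature (K) for the velocity draw
#' @param dt_fs integration time step (fs)
#' @return object of class `reference_dataset`
#' @export
generate_reference_data <- function(oracle, n_train_runs = 10L,
                                    n_valid_runs = 10L, steps_per_run = 100L,
                                    displacements = c(-0.14, -0.07, 0.07, 0.14),
                                    temperature = 300, dt_fs = 1.0) {
  structure0 <- oracle$structure
  n <- n_atoms(structure0)
  rng <- .seeded_rng(oracle$seed, "refdata")
  sigf <- oracle$noise_sigma_force
  noise_f <- function(f) {
    if (sigf > 0) f + matrix(.rng_norm(rng, length(f)) * sigf, nrow(f)) else f
  }
  geoms <- list()
  add_geom <- function(tag, positions, forces) {
    geoms[[length(geoms) + 1L]] <<- list(tag = tag, positions = positions,
                                         forces = forces)
  }
  ## (i) optimized geometry, exactly-zero reference forces
  add_geom("optimized", structure0$positions, matrix(0, n, 3L))
  ## (ii) finite displacements: 12 per atom
  for (a in seq_len(n)) for (x in 1:3) for (dd in displacements) {
    g <- structure0
    g$positions[a, x] <- g$positions[a, x] + dd
    add_geom("hessian_displacement", g$positions,
             noise_f(.oracle_forces(oracle, g)))
  }
  ## (iii) pseudo-dynamics (velocity Verlet, NVE)
  conv <- 0.00964853  # (eV/A/amu) -> A/fs^2
  kB <- 8.617333e-5   # eV/K
  mass <- atomic_mass(structure0$elements)
  run_md <- function(tag, run_id) {
    g <- structure0
    v <- matrix(.rng_norm(rng, 3L * n), n, 3L) *
      sqrt(kB * temperature * conv / mass)
    f <- .oracle_forces(oracle, g)
    for (s in seq_len(steps_per_run)) {
      acc <- f / mass * conv
      g$positions <- g$positions + v * dt_fs + 0.5 * acc * dt_fs^2
      f_new <- .oracle_forces(oracle, g)
      v <- v + 0.5 * (acc + f_new / mass * conv) * dt_fs
      f <- f_new
      add_geom(tag, g$positions, noise_f(f))
    }
  }
  for (r in seq_len(n_train_runs)) run_md("aimd_train", r)
  for (r in seq_len(n_valid_runs)) run_md("aimd_validation", r)
  ## (iv) rigid-torsion-scan energies for rotatable types
  sige <- oracle$noise_sigma_energy
  scans <- lapply(oracle$scans, function(scan) {
    e <- vapply(scan$geometries, function(g) .oracle_energy(oracle, g),
                numeric(1L))
    if (sige > 0) e <- e + .rng_norm(rng, length(e)) * sige
    list(type = scan$type, phi_deg = scan$phi_deg, energies = e,
         instance_row = scan$instance_row)
  })
  structure(list(structure = structure0, geometries = geoms, scans = scans),
            class = "reference_dataset")
}

#' @export
print.reference_dataset <- function(x, ...) {
  tags <- vapply(x$geometries, `[[`, character(1L), "tag")
  cat("reference_dataset:\n")
  print(table(tags))
  cat(sprintf("  torsion scans: %d rotatable type(s)\n", length(x$scans)))
  invisible(x)
}

#' Write a reference dataset to the CSV schema
#'
#' Two files: `<prefix>_geometries.csv` with one row per atom per geometry
#' (`geometry_id`, `tag`, `atom`, `x`, `y`, `z` in Angstrom, `fx`, `fy`,
#' `fz` in eV/Angstrom) and `<prefix>_scans.csv` with one row per scan point
#' (`dihedral_type`, `phi_deg`, `energy_ev`). The same schema is read back by
#' [read_reference_csv()], so synthetic data and externally extracted data
#' are interchangeable.
#' @param dataset a `reference_dataset`
#' @param prefix output path prefix
#' @return invisibly, the files written
#' @export
write_reference_csv <- function(dataset, prefix) {
  n <- n_atoms(dataset$structure)
  rows <- lapply(seq_along(dataset$geometries), function(i) {
    g <- dataset$geometries[[i]]
    data.frame(geometry_id = i, tag = g$tag, atom = seq_len(n),
               x = g$positions[, 1L], y = g$positions[, 2L],
               z = g$positions[, 3L],
               fx = g$forces[, 1L], fy = g$forces[, 2L], fz = g$forces[, 3L])
  })
  f1 <- paste0(prefix, "_geometries.csv")
  utils::write.csv(do.call(rbind, rows), f1, row.names = FALSE)
  f2 <- paste0(prefix, "_scans.csv")
  srows <- lapply(dataset$scans, function(s) {
    data.frame(dihedral_type = s$type, phi_deg = s$phi_deg,
               energy_ev = s$energies)
  })
  if (length(srows)) {
    utils::write.csv(do.call(rbind, srows), f2, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(dihedral_type = integer(), phi_deg = numeric(),
                                energy_ev = numeric()), f2, row.names = FALSE)
  }
  invisible(c(f1, f2))
}

#' @rdname write_reference_csv
#' @param structure the `periodic_structure` the data refer to
#' @export
read_reference_csv <- function(prefix, structure) {
  g <- utils::read.csv(paste0(prefix, "_geometries.csv"))
  s <- utils::read.csv(paste0(prefix, "_scans.csv"))
  n <- n_atoms(structure)
  ids <- sort(unique(g$geometry_id))
  geoms <- lapply(ids, function(id) {
    gg <- g[g$geometry_id == id, , drop = FALSE]
    gg <- gg[order(gg$atom), ]
    if (nrow(gg) != n) stop("geometry row count does not match structure")
    list(tag = gg$tag[1L],
         positions = as.matrix(gg[, c("x", "y", "z")]),
         forces = as.matrix(gg[, c("fx", "fy", "fz")]))
  })
  scans <- lapply(split(s, s$dihedral_type), function(ss) {
    list(type = ss$dihedral_type[1L], phi_deg = ss$phi_deg,
         energies = ss$energy_ev, instance_row = NA_integer_)
  })
  structure(list(structure = structure, geometries = geoms, scans = scans),
            class = "reference_dataset")
}
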