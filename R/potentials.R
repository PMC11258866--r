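## Flexibility model potentials: harmonic stretch, the smooth angle-bending
## potential, constant-amplitude (CADT) and angle-damped (ADDT) dihedral
## torsion modes, bond-bond cross terms; the orthogonal seven-mode torsion
## basis with smart selection; and the energy/force engine over typed
## instances with duplicate weighting.

#' Torsion angle-damping constants
#'
#' `K` is the dimensionless damping stiffness; `tanh_K = tanh(K)` normalizes
#' the damping factor to 1 at a right angle.
#' @return list with `K` and `tanh_K`
#' @export
damping_constants <- function() {
  list(K = 2.815891616117388, tanh_K = tanh(2.815891616117388))
}

#' Harmonic stretch basis function
#'
#' `g = (d - d_eq)^2 / 2`; multiplied by the force constant it gives the
#' harmonic bond (or Urey-Bradley) stretch energy.
#' @param d current distance (Angstrom)
#' @param d_eq equilibrium distance (Angstrom)
#' @return dimensionless * Angstrom^2
#' @export
g_harmonic_stretch <- function(d, d_eq) {
  stopifnot(all(d > 0))
  0.5 * (d - d_eq)^2
}

#' Smooth angle-bending basis function
#'
#' `g = (cos(theta) - cos(theta_eq))^2 / (1 - cos(theta))`. Being a rational
#' function of `cos(theta)` it has continuous derivatives of all orders in
#' the Cartesian coordinates, including through linear angles (`theta = pi`);
#' it diverges as `theta -> 0`, mimicking Pauli repulsion; it is stationary
#' and quadratic-like about `theta_eq`; and the force constant is its single
#' adjustable parameter.
#' @param theta bond angle (radians), in (0, pi]
#' @param theta_eq equilibrium bond angle (radians), in (0, pi]
#' @return dimensionless
#' @export
g_manz_bend <- function(theta, theta_eq) {
  if (any(theta <= 0)) stop("bond angle must be positive")
  stopifnot(all(theta_eq > 0), all(theta_eq <= pi))
  .g_bend_cos(cos(theta), cos(theta_eq))
}

.g_bend_cos <- function(u, u0) (u - u0)^2 / (1 - u)

.dg_bend_cos <- function(u, u0) {
  (2 * (u - u0) * (1 - u) + (u - u0)^2) / (1 - u)^2
}

#' Torsion angle-damping factor
#'
#' `D(theta) = tanh(K * sin(theta)^2) / tanh(K)`: equal to 1 at right angles,
#' decaying smoothly to 0 as the flanking bond angle approaches 0 or pi
#' (where the dihedral becomes undefined). As a function of `cos(theta)^2`
#' it is smooth in the Cartesian coordinates everywhere, and it vanishes
#' fast enough to cancel the dihedral gradient's divergence at linearity, so
#' angle-damped torsion forces stay continuous.
#' @param theta flanking bond angle (radians)
#' @return damping factor in `[0, 1]`
#' @export
angle_damping <- function(theta) {
  .damping_cos(cos(theta))
}

.damping_cos <- function(u) {
  dc <- damping_constants()
  tanh(dc$K * (1 - u^2)) / dc$tanh_K
}

.ddamping_cos <- function(u) {
  dc <- damping_constants()
  x <- dc$K * (1 - u^2)
  (1 - tanh(x)^2) * dc$K * (-2 * u) / dc$tanh_K
}

## torsion mode base functions of the phase difference; modes 1..4 are the
## cosine modes 1 - cos(m * d), modes 5..7 the sine modes sign * sin(n * d)
.mode_base <- function(m, d, sign_eq = 1) {
  if (m <= 4) 1 - cos(m * d) else sign_eq * sin((m - 4) * d)
}

.dmode_base <- function(m, d, sign_eq = 1) {
  if (m <= 4) m * sin(m * d) else sign_eq * (m - 4) * cos((m - 4) * d)
}

#' Constant-amplitude dihedral torsion (CADT) mode basis function
#'
#' Modes 1-4 are the cosine modes `1 - cos(m (phi - phi_eq))` (even in the
#' displacement, zero and stationary at `phi_eq`); modes 5-7 are the sine
#' modes `sin(n (phi - phi_eq))`, `n = m - 4` (odd in the displacement).
#' All are 2 pi periodic. For instances whose equilibrium dihedral has
#' negative sign the sine modes are mirrored via `sign_eq`, so mirror-image
#' instances of one type share force constants.
#' @param m mode index 1..7
#' @param phi dihedral value (radians)
#' @param phi_eq equilibrium dihedral (radians)
#' @param sign_eq +1 or -1 mirror factor for sine modes
#' @return dimensionless
#' @export
g_cadt_mode <- function(m, phi, phi_eq, sign_eq = 1) {
  if (!(m %in% 1:7)) stop("torsion mode index must be in 1..7")
  .mode_base(m, phi - phi_eq, sign_eq)
}

#' Angle-damped dihedral torsion (ADDT) mode basis function
#'
#' The CADT mode of `phi` multiplied by the damping factors of both flanking
#' bond angles: `D(theta_ABC) * D(theta_BCD) * g_cadt`. The damping removes
#' the force discontinuity of bare torsions at linear bond angles; when both
#' instantaneous angles sit at (non-linear) equilibrium values the mode
#' reduces to the CADT dependence times a constant amplitude.
#' @inheritParams g_cadt_mode
#' @param theta_abc,theta_bcd instantaneous flanking bond angles (radians)
#' @return dimensionless
#' @export
g_addt_mode <- function(m, theta_abc, theta_bcd, phi, phi_eq, sign_eq = 1) {
  if (!(m %in% 1:7)) stop("torsion mode index must be in 1..7")
  angle_damping(theta_abc) * angle_damping(theta_bcd) *
    .mode_base(m, phi - phi_eq, sign_eq)
}

#' Bond-bond cross basis function
#'
#' `g = (d_AB - d_eq_AB) * (d_BC - d_eq_BC)` for two bonds sharing an atom.
#' @param d_ab,d_bc current bond lengths (Angstrom)
#' @param d_eq_ab,d_eq_bc equilibrium lengths (Angstrom)
#' @return Angstrom^2 (sign free)
#' @export
g_bond_bond_cross <- function(d_ab, d_bc, d_eq_ab, d_eq_bc) {
  (d_ab - d_eq_ab) * (d_bc - d_eq_bc)
}

#' Centered orthogonal torsion-mode basis on a scan grid
#'
#' Column `m` holds the zero-average basis function of mode `m` evaluated on
#' the grid: `-cos(m (phi - phi_eq))` for the cosine modes (the centered form
#' of `1 - cos`) and `sin(n (phi - phi_eq))` for the sine modes. On any grid
#' uniformly covering (-pi, pi] the seven columns are mutually orthogonal.
#' @param phi numeric vector of dihedral values (radians)
#' @param phi_eq reference dihedral (radians)
#' @return length(phi) x 7 matrix
#' @export
torsion_mode_basis <- function(phi, phi_eq = pi) {
  d <- phi - phi_eq
  cbind(-cos(d), -cos(2 * d), -cos(3 * d), -cos(4 * d),
        sin(d), sin(2 * d), sin(3 * d))
}

#' Project a rigid-torsion-scan energy curve onto the seven-mode basis
#'
#' With `Ebar` the arithmetic mean energy over the `T` grid points and
#' `S = sum((E - Ebar)^2)` the self-overlap of the centered curve, the mode
#' coefficients are the normalized projections
#' `c_m = sum((E - Ebar) f_m) / sqrt(S * sum(f_m^2))`, so that the goodness
#' of fit of the full seven-mode model is exactly `R^2 = sum(c_m^2)` (and of
#' any truncated model, the sum over its modes).
#' @param phi_deg scan grid in degrees, uniformly spaced over (-180, 180]
#' @param energies energies on the grid (eV)
#' @param phi_eq reference dihedral (radians)
#' @return object of class `mode_coefficients`: list with `c` (length 7),
#'   `E_avg`, `r2_full`, `amplitude` (per-mode energy amplitudes, eV)
#' @export
project_torsion_modes <- function(phi_deg, energies, phi_eq) {
  if (inherits(phi_deg, "torsion_scan")) {
    scan <- phi_deg
    energies <- scan$energies
    phi_eq <- scan$phi_eq
    phi_deg <- scan$phi_deg
  }
  steps <- diff(sort(phi_deg))
  if (max(abs(steps - steps[1L])) > 1e-9) {
    stop("torsion scan grid must be uniformly spaced")
  }
  if (abs(max(phi_deg) - 180) > 1e-9 || abs(min(phi_deg) + 180 - steps[1L]) > 1e-9) {
    stop("torsion scan grid must cover (-180, 180] degrees")
  }
  phi <- phi_deg * pi / 180
  e_avg <- mean(energies)
  ec <- energies - e_avg
  s <- sum(ec^2)
  if (s < .Machine$double.eps * length(ec)) {
    stop("zero energy variance along scan; mode coefficients undefined")
  }
  f <- torsion_mode_basis(phi, phi_eq)
  fsq <- colSums(f^2)
  cm <- as.numeric(crossprod(f, ec)) / sqrt(s * fsq)
  amp <- cm * sqrt(s / fsq)
  structure(list(c = cm, E_avg = e_avg, r2_full = sum(cm^2),
                 amplitude = amp, phi_eq = phi_eq),
            class = "mode_coefficients")
}

#' @export
print.mode_coefficients <- function(x, ...) {
  cat("mode coefficients c_1..c_7:",
      paste(sprintf("%.4f", x$c), collapse = " "),
      sprintf("\n  E_avg = %.6f eV, R2(all 7) = %.6f\n", x$E_avg, x$r2_full))
  invisible(x)
}

#' Smart-select active torsion modes
#'
#' Mode `m` is active iff `|c_m| >` `threshold`. An empty selection is
#' reported with a warning and falls back to the single largest-|c| mode. A
#' selection containing only sine modes is physically inconsistent (the
#' equilibrium would not be an energy minimum) and raises an error.
#' @param coeffs a `mode_coefficients` object
#' @param threshold absolute-coefficient cutoff (default 0.1)
#' @return integer vector of selected mode indices
#' @export
smart_select <- function(coeffs, threshold = 0.1) {
  sel <- which(abs(coeffs$c) > threshold)
  if (!length(sel)) {
    warning("no torsion mode exceeds |c| > ", threshold,
            "; falling back to the largest-|c| mode")
    sel <- which.max(abs(coeffs$c))
  }
  if (all(sel >= 5L)) {
    stop("smart selection returned only sine modes; ",
         "a torsion potential must include at least one cosine mode")
  }
  sort(as.integer(sel))
}

## --- flexibility terms ------------------------------------------------------

#' Assemble the flexibility-term list for a typed structure
#'
#' One term (one force constant) per: active bond-stretch type (harmonic),
#' active Urey-Bradley type (harmonic), active angle type outside 3-/4-rings
#' (smooth bend), dihedral torsion per active dihedral type -- smart-selected
#' CADT/ADDT modes for rotatable types (ADDT iff either contained equilibrium
#' angle is at least `case_threshold_deg`), a single mode-1 CADT/ADDT term
#' for nonrotatable or hindered types, and the two angle-damped modes for
#' linear types (optional); plus optional bond-bond cross terms built from
#' every angle instance including those inside 3-/4-rings.
#'
#' @param icset a classified, pruned `icoord_set`
#' @param selected_modes named list (by dihedral type) of smart-selected mode
#'   vectors for rotatable types
#' @param cross_terms include bond-bond cross terms
#' @param addt_linear include the two-mode linear-dihedral potential
#' @param case_threshold_deg bond-angle threshold (degrees) switching CADT to
#'   ADDT (default 130)
#' @return object of class `flex_model` (list of terms)
#' @export
assign_term_kinds <- function(icset, selected_modes = list(),
                              cross_terms = FALSE, addt_linear = TRUE,
                              case_threshold_deg = 130) {
  terms <- list()
  st <- icset$stretch_instances
  for (k in seq_len(nrow(icset$stretch_types))) {
    if (!icset$stretch_active[k]) next
    sel <- st[st$type == k, , drop = FALSE]
    kind <- if (icset$stretch_types$kind[k] == "bond") "bond_stretch"
      else "ub_stretch"
    terms[[length(terms) + 1L]] <- list(
      kind = kind, type = k,
      label = sprintf("%s type %d (%s, disambig %d)", kind, k,
                      icset$stretch_types$pair[k],
                      icset$stretch_types$disambig[k]),
      instances = data.frame(
        a = sel$a, ta1 = sel$ta1, ta2 = sel$ta2, ta3 = sel$ta3,
        b = sel$b, tb1 = sel$tb1, tb2 = sel$tb2, tb3 = sel$tb3,
        w = 1 / sel$n_duplicates, d_eq = sel$d_eq))
  }
  an <- icset$angle_instances
  for (k in seq_len(nrow(icset$angle_types))) {
    if (!icset$angle_active[k]) next
    sel <- an[an$type == k, , drop = FALSE]
    terms[[length(terms) + 1L]] <- list(
      kind = "angle_bend", type = k,
      label = sprintf("angle_bend type %d (%s, disambig %d)", k,
                      icset$angle_types$trip[k],
                      icset$angle_types$disambig[k]),
      instances = data.frame(
        p = sel$p, tp1 = sel$tp1, tp2 = sel$tp2, tp3 = sel$tp3,
        center = sel$center,
        q = sel$q, tq1 = sel$tq1, tq2 = sel$tq2, tq3 = sel$tq3,
        w = 1, cos_eq = cos(sel$theta_eq)))
  }
  di <- icset$dihedral_instances
  dt <- icset$dihedral_types
  if (nrow(dt)) {
    for (k in seq_len(nrow(dt))) {
      if (!icset$dihedral_active[k]) next
      cls <- dt$classification[k]
      damped <- max(dt$theta_eq_1[k], dt$theta_eq_2[k]) >=
        case_threshold_deg * pi / 180
      sel <- di[di$type == k, , drop = FALSE]
      inst <- data.frame(
        a = sel$a, ta1 = sel$ta1, ta2 = sel$ta2, ta3 = sel$ta3,
        b = sel$b, tb1 = sel$tb1, tb2 = sel$tb2, tb3 = sel$tb3,
        c = sel$c, tc1 = sel$tc1, tc2 = sel$tc2, tc3 = sel$tc3,
        d = sel$d, td1 = sel$td1, td2 = sel$td2, td3 = sel$td3,
        w = 1 / sel$n_duplicates, phi_eq = sel$phi_eq,
        sign_eq = sel$sign_eq)
      modes <- if (cls == "rotatable") {
        mk <- selected_modes[[as.character(k)]]
        if (is.null(mk)) stop("no smart-selected modes for rotatable type ", k)
        mk
      } else if (cls %in% c("nonrotatable", "hindered")) {
        1L
      } else if (cls == "linear") {
        if (!addt_linear) next
        c(1L, 5L)
      } else {
        stop("dihedral type ", k, " has unresolved classification ", cls)
      }
      base_kind <- if (cls == "linear") "torsion_addt_linear_mode"
        else if (damped) "torsion_addt_mode" else "torsion_cadt_mode"
      for (m in modes) {
        terms[[length(terms) + 1L]] <- list(
          kind = base_kind, type = k, mode = as.integer(m),
          classification = cls,
          label = sprintf("%s %d, dihedral type %d (%s, |phi_eq| %.1f deg, %s)",
                          base_kind, m, k, dt$quad[k],
                          dt$abs_phi_round[k] * 180 / pi, cls),
          instances = inst)
      }
    }
  }
  if (cross_terms) {
    ## cross terms use all angle instances, ring or not
    bond_rows <- st[st$kind == "bond", , drop = FALSE]
    deq_of_edge <- function(e) bond_rows$d_eq[match(e, bond_rows$edge)]
    for (k in seq_len(nrow(icset$angle_types))) {
      sel <- an[an$type == k, , drop = FALSE]
      terms[[length(terms) + 1L]] <- list(
        kind = "bond_bond_cross", type = k,
        label = sprintf("bond_bond_cross on angle type %d (%s)", k,
                        icset$angle_types$trip[k]),
        instances = data.frame(
          p = sel$p, tp1 = sel$tp1, tp2 = sel$tp2, tp3 = sel$tp3,
          center = sel$center,
          q = sel$q, tq1 = sel$tq1, tq2 = sel$tq2, tq3 = sel$tq3,
          w = 1, d_eq_p = deq_of_edge(sel$edge_p),
          d_eq_q = deq_of_edge(sel$edge_q)))
    }
  }
  structure(list(terms = terms, n_atoms = n_atoms(icset$structure),
                 k = rep(NA_real_, length(terms))),
            class = "flex_model")
}

#' @export
print.flex_model <- function(x, ...) {
  kinds <- vapply(x$terms, `[[`, character(1L), "kind")
  cat(sprintf("flex_model: %d terms\n", length(x$terms)))
  print(table(kinds))
  invisible(x)
}

## evaluate one term's summed basis function (and optionally the gradient
## of that sum) on a geometry
eval_term <- function(term, geometry, grad = FALSE) {
  inst <- unclass(term$instances)  # plain column list: fast indexing
  total <- 0
  gmat <- if (grad) matrix(0, n_atoms(geometry), 3L) else NULL
  addg <- function(atom, g) gmat[atom, ] <<- gmat[atom, ] + g
  for (i in seq_along(inst$w)) {
    w <- inst$w[i]
    if (term$kind %in% c("bond_stretch", "ub_stretch")) {
      p1 <- image_position(geometry, inst$a[i],
                           c(inst$ta1[i], inst$ta2[i], inst$ta3[i]))
      p2 <- image_position(geometry, inst$b[i],
                           c(inst$tb1[i], inst$tb2[i], inst$tb3[i]))
      gd <- grad_distance(p1, p2)
      delta <- gd$value - inst$d_eq[i]
      total <- total + w * 0.5 * delta * delta
      if (grad) {
        addg(inst$a[i], w * delta * gd$grad[1L, ])
        addg(inst$b[i], w * delta * gd$grad[2L, ])
      }
    } else if (term$kind == "angle_bend") {
      pp <- image_position(geometry, inst$p[i],
                           c(inst$tp1[i], inst$tp2[i], inst$tp3[i]))
      pc <- geometry$positions[inst$center[i], ]
      pq <- image_position(geometry, inst$q[i],
                           c(inst$tq1[i], inst$tq2[i], inst$tq3[i]))
      ga <- grad_cos_angle(pp, pc, pq)
      total <- total + w * .g_bend_cos(ga$value, inst$cos_eq[i])
      if (grad) {
        du <- w * .dg_bend_cos(ga$value, inst$cos_eq[i])
        addg(inst$p[i], du * ga$grad[1L, ])
        addg(inst$center[i], du * ga$grad[2L, ])
        addg(inst$q[i], du * ga$grad[3L, ])
      }
    } else if (term$kind == "bond_bond_cross") {
      pp <- image_position(geometry, inst$p[i],
                           c(inst$tp1[i], inst$tp2[i], inst$tp3[i]))
      pc <- geometry$positions[inst$center[i], ]
      pq <- image_position(geometry, inst$q[i],
                           c(inst$tq1[i], inst$tq2[i], inst$tq3[i]))
      g1 <- grad_distance(pc, pp)
      g2 <- grad_distance(pc, pq)
      e1 <- g1$value - inst$d_eq_p[i]
      e2 <- g2$value - inst$d_eq_q[i]
      total <- total + w * e1 * e2
      if (grad) {
        addg(inst$center[i], w * (e2 * g1$grad[1L, ] + e1 * g2$grad[1L, ]))
        addg(inst$p[i], w * e2 * g1$grad[2L, ])
        addg(inst$q[i], w * e1 * g2$grad[2L, ])
      }
    } else {  # torsion kinds
      pa <- image_position(geometry, inst$a[i],
                           c(inst$ta1[i], inst$ta2[i], inst$ta3[i]))
      pb <- image_position(geometry, inst$b[i],
                           c(inst$tb1[i], inst$tb2[i], inst$tb3[i]))
      pc <- image_position(geometry, inst$c[i],
                           c(inst$tc1[i], inst$tc2[i], inst$tc3[i]))
      pd <- image_position(geometry, inst$d[i],
                           c(inst$td1[i], inst$td2[i], inst$td3[i]))
      gphi <- grad_dihedral(pa, pb, pc, pd)
      dphi <- gphi$value - inst$phi_eq[i]
      m <- term$mode
      s <- inst$sign_eq[i]
      base <- .mode_base(m, dphi, s)
      dbase <- .dmode_base(m, dphi, s)
      if (term$kind == "torsion_cadt_mode") {
        total <- total + w * base
        if (grad) {
          for (jj in 1:4) {
            at <- inst[[c("a", "b", "c", "d")[jj]]][i]
            addg(at, w * dbase * gphi$grad[jj, ])
          }
        }
      } else {  # angle-damped kinds
        g1 <- grad_cos_angle(pa, pb, pc)
        g2 <- grad_cos_angle(pb, pc, pd)
        d1 <- .damping_cos(g1$value)
        d2 <- .damping_cos(g2$value)
        total <- total + w * d1 * d2 * base
        if (grad) {
          dd1 <- .ddamping_cos(g1$value)
          dd2 <- .ddamping_cos(g2$value)
          for (jj in 1:4) {
            at <- inst[[c("a", "b", "c", "d")[jj]]][i]
            g <- w * d1 * d2 * dbase * gphi$grad[jj, ]
            if (jj <= 3L) g <- g + w * dd1 * d2 * base * g1$grad[jj, ]
            if (jj >= 2L) g <- g + w * d1 * dd2 * base * g2$grad[jj - 1L, ]
            addg(at, g)
          }
        }
      }
    }
  }
  list(g = total, grad = gmat)
}

#' Evaluate the flexibility-model energy of a geometry
#'
#' `E = sum_j k_j * sum_instances (1/n_duplicates) g_j`; exactly zero at the
#' reference geometry by construction.
#' @param model a `flex_model` with force constants `k` set
#' @param geometry a `periodic_structure` compatible with the model topology
#' @return energy (eV)
#' @export
evaluate_energy <- function(model, geometry) {
  k <- model$k
  if (anyNA(k)) stop("model force constants are not set")
  tot <- 0
  for (j in seq_along(model$terms)) {
    if (k[j] == 0) next
    tot <- tot + k[j] * eval_term(model$terms[[j]], geometry)$g
  }
  tot
}

#' Evaluate per-atom forces of the flexibility model
#'
#' `F = -grad E`. The default differentiates the total energy by central
#' differences with step `h`; the analytic mode accumulates the closed-form
#' internal-coordinate gradients and matches the numeric mode to tight
#' tolerance.
#' @param model a `flex_model` with `k` set
#' @param geometry a `periodic_structure`
#' @param mode `"numeric"` or `"analytic"`
#' @param h finite-difference step (Angstrom)
#' @return N x 3 matrix of forces (eV/Angstrom)
#' @export
evaluate_forces <- function(model, geometry, mode = c("numeric", "analytic"),
                            h = 1e-5) {
  mode <- match.arg(mode)
  n <- n_atoms(geometry)
  if (mode == "analytic") {
    f <- matrix(0, n, 3L)
    for (j in seq_along(model$terms)) {
      if (model$k[j] == 0) next
      f <- f - model$k[j] * eval_term(model$terms[[j]], geometry,
                                      grad = TRUE)$grad
    }
    return(f)
  }
  f <- matrix(0, n, 3L)
  for (a in seq_len(n)) for (x in 1:3) {
    gp <- geometry; gp$positions[a, x] <- gp$positions[a, x] + h
    gm <- geometry; gm$positions[a, x] <- gm$positions[a, x] - h
    f[a, x] <- -(evaluate_energy(model, gp) - evaluate_energy(model, gm)) /
      (2 * h)
  }
  f
}

#' Serialize a flexibility model to JSON
#'
#' The parameter file lists every term: kind, type index, mode, equilibrium
#' values of its instances, and the force constant. [read_flex_model()]
#' restores it round-trip.
#' @param model a `flex_model`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_flex_model <- function(model, path) {
  payload <- list(
    n_atoms = model$n_atoms,
    k = model$k,
    terms = lapply(model$terms, function(tm) {
      tm$instances <- as.list(tm$instances)
      tm
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_flex_model
#' @export
read_flex_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- lapply(payload$terms, function(tm) {
    tm$instances <- as.data.frame(lapply(tm$instances, unlist))
    if (!is.null(tm$mode)) tm$mode <- as.integer(tm$mode)
    tm$type <- as.integer(tm$type)
    tm
  })
  k <- vapply(payload$k, function(x) if (is.null(x)) NA_real_ else
    as.numeric(x), numeric(1L))
  structure(list(terms = terms, n_atoms = as.integer(payload$n_atoms), k = k),
            class = "flex_model")
}
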