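test_that("harmonic stretch: values, symmetry, zero at equilibrium", {
  expect_equal(g_harmonic_stretch(1.5, 1.0), 0.125)
  expect_equal(g_harmonic_stretch(1.0, 1.0), 0)
  expect_equal(g_harmonic_stretch(1.3, 1.0), g_harmonic_stretch(0.7, 1.0))
})

test_that("angle-bending potential satisfies its four defining properties", {
  # zero and stationary at every equilibrium angle
  for (te in c(0.4, pi / 2, 2.0, 3.0, pi)) {
    expect_equal(g_manz_bend(te, te), 0)
    h <- 1e-6
    d1 <- (g_manz_bend(te + h, te) - g_manz_bend(te - h, te)) / (2 * h)
    expect_lt(abs(d1), 1e-8)
    expect_gte(g_manz_bend(te + 0.05, te), 0)
  }
  # monotone blow-up towards theta = 0
  expect_gt(g_manz_bend(0.05, pi / 2), g_manz_bend(0.5, pi / 2))
  expect_gt(g_manz_bend(0.5, pi / 2), 0)
  seqth <- c(0.3, 0.1, 0.03, 0.01, 0.003)
  vals <- g_manz_bend(seqth, pi / 2)
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[length(vals)], 1e3 * g_manz_bend(1.0, pi / 2))
  # continuity through theta = pi: smooth function of cos(theta)
  left <- g_manz_bend(pi - 1e-7, 2.0)
  at <- g_manz_bend(pi, 2.0)
  expect_lt(abs(left - at), 1e-8)
  expect_error(g_manz_bend(-0.1, 2.0), "positive")
})

test_that("CADT modes: values, parity, periodicity", {
  # m = 3 at a 60-degree displacement: 1 - cos(180 deg) = 2
  expect_equal(g_cadt_mode(3, pi / 3 + 0.2, 0.2), 2)
  for (m in 1:4) expect_equal(g_cadt_mode(m, 0.7, 0.7), 0)
  d <- 0.43
  for (m in 1:4) {
    expect_equal(g_cadt_mode(m, 0.1 + d, 0.1), g_cadt_mode(m, 0.1 - d, 0.1))
  }
  for (m in 5:7) {
    expect_equal(g_cadt_mode(m, 0.1 + d, 0.1), -g_cadt_mode(m, 0.1 - d, 0.1))
    # mirror-image instances flip the sine modes
    expect_equal(g_cadt_mode(m, 0.1 + d, 0.1, sign_eq = -1),
                 -g_cadt_mode(m, 0.1 + d, 0.1))
  }
  for (m in 1:7) {
    expect_equal(g_cadt_mode(m, 0.3 + 2 * pi, 0.1), g_cadt_mode(m, 0.3, 0.1))
  }
  expect_error(g_cadt_mode(8, 0, 0), "1..7")
})

test_that("damping constants and factor: printed values, range, smoothness", {
  dc <- damping_constants()
  expect_equal(dc$K, 2.815891616117388)
  expect_equal(dc$tanh_K, 0.992861208914406, tolerance = 1e-15)
  th <- seq(0.001, pi, length.out = 2000)
  d <- angle_damping(th)
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  expect_equal(angle_damping(pi / 2), 1)
  expect_equal(angle_damping(pi), 0)
})

test_that("ADDT modes: equilibrium offset zero, continuity through linearity", {
  te1 <- 1.9; te2 <- 2.1; pe <- 0.4
  expect_equal(g_addt_mode(1, te1, te2, pe, pe), 0)
  # reduces to a constant multiple of the CADT dependence at fixed angles
  phis <- seq(-3, 3, by = 0.25)
  ratio <- g_addt_mode(2, te1, te2, phis, pe) / g_cadt_mode(2, phis, pe)
  ratio <- ratio[is.finite(ratio)]
  expect_lt(diff(range(ratio)), 1e-12)
  # derivative w.r.t. each angle is finite and continuous across theta -> pi
  th_seq <- pi - c(1e-2, 1e-4, 1e-6, 0)
  g_of_th <- vapply(th_seq, function(th) g_addt_mode(1, th, te2, 1.0, pe),
                    numeric(1L))
  expect_true(all(is.finite(g_of_th)))
  expect_lt(abs(g_of_th[3] - g_of_th[4]), 1e-8)
  h <- 1e-7
  d_near <- (g_addt_mode(1, pi - 1e-6 + h, te2, 1.0, pe) -
               g_addt_mode(1, pi - 1e-6 - h, te2, 1.0, pe)) / (2 * h)
  expect_true(is.finite(d_near))
  expect_lt(abs(d_near), 1e-3)  # damping has flattened the angle dependence
})

test_that("Cartesian forces of an angle-damped torsion stay bounded near linearity", {
  # 4-atom chain with the first angle nearly linear
  mk <- function(eps) {
    periodic_structure(diag(rep(20, 3)), rep("C", 4),
                       rbind(c(-1.5 * cos(eps), 1.5 * sin(eps), 0),
                             c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0.4)),
                       periodic = FALSE)
  }
  term <- list(kind = "torsion_addt_mode", mode = 1L,
               instances = data.frame(
                 a = 1L, ta1 = 0L, ta2 = 0L, ta3 = 0L,
                 b = 2L, tb1 = 0L, tb2 = 0L, tb3 = 0L,
                 c = 3L, tc1 = 0L, tc2 = 0L, tc3 = 0L,
                 d = 4L, td1 = 0L, td2 = 0L, td3 = 0L,
                 w = 1, phi_eq = 0.5, sign_eq = 1L))
  for (eps in c(1e-2, 1e-4, 1e-6)) {
    gr <- flexff:::eval_term(term, mk(eps), grad = TRUE)$grad
    expect_true(all(is.finite(gr)))
    expect_lt(max(abs(gr)), 10)
  }
})

test_that("bond-bond cross: product form and antisymmetry", {
  expect_equal(g_bond_bond_cross(1.1, 1.2, 1.0, 1.0), 0.02)
  expect_equal(g_bond_bond_cross(1.0, 1.7, 1.0, 1.2), 0)
  expect_equal(g_bond_bond_cross(0.9, 1.2, 1.0, 1.0),
               -g_bond_bond_cross(1.1, 1.2, 1.0, 1.0))
})

test_that("seven-mode basis is orthogonal on the uniform 36-point grid", {
  phi <- seq(-170, 180, by = 10) * pi / 180
  B <- torsion_mode_basis(phi, phi_eq = 0.83)
  G <- crossprod(B)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-10)
})

test_that("projection: pure mode 3, parity, shift invariance, error cases", {
  grid <- seq(-170, 180, by = 10)
  phi <- grid * pi / 180
  pe <- 0.3
  co <- project_torsion_modes(grid, 0.7 * (1 - cos(3 * (phi - pe))), pe)
  expect_equal(co$c[3]^2, 1, tolerance = 1e-10)
  expect_lt(max(abs(co$c[-3])), 1e-10)
  expect_equal(co$r2_full, 1, tolerance = 1e-10)
  expect_equal(smart_select(co), 3L)

  # even mixture of cosine modes leaves the sine coefficients at zero
  e_even <- 0.4 * (1 - cos(phi - pe)) + 0.2 * (1 - cos(4 * (phi - pe)))
  co2 <- project_torsion_modes(grid, e_even, pe)
  expect_lt(max(abs(co2$c[5:7])), 1e-12)

  # constant shifts do not change the coefficients
  co3 <- project_torsion_modes(grid, e_even + 3.7, pe)
  expect_equal(co3$c, co2$c, tolerance = 1e-12)

  expect_error(project_torsion_modes(c(grid[-1], 185), rnorm(36), pe),
               "uniform")
  expect_error(project_torsion_modes(grid, rep(1.0, 36), pe), "variance")
})

test_that("smart selection thresholds, fallback and sine-only error", {
  co <- structure(list(c = c(0.05, 0.2, 0.9, 0, 0.15, 0, 0)),
                  class = "mode_coefficients")
  expect_equal(smart_select(co), c(2L, 3L, 5L))
  co_small <- structure(list(c = rep(0.05, 7)), class = "mode_coefficients")
  expect_warning(sel <- smart_select(co_small), "falling back")
  expect_length(sel, 1L)
  co_sine <- structure(list(c = c(0, 0, 0, 0, 0.9, 0, 0)),
                       class = "mode_coefficients")
  expect_error(smart_select(co_sine), "cosine")
})

test_that("term assignment follows the five torsion cases", {
  # toy rotor: linear types -> two damped modes; nonrotatable with both
  # angles < 130 deg -> one CADT mode-1 term; rotatable -> selected modes
  s <- make_fixture("toy_rotor_framework")
  prep <- prepare_icset(s, pipeline_config(seed = 3))
  ic <- prep$icset
  sel <- lapply(prep$scans, function(x) c(1L, 3L))
  model <- assign_term_kinds(ic, selected_modes = sel, cross_terms = TRUE)
  kinds <- vapply(model$terms, `[[`, character(1L), "kind")
  cls <- vapply(model$terms, function(tm)
    if (is.null(tm$classification)) "" else tm$classification, character(1L))
  expect_true(any(kinds == "torsion_addt_linear_mode"))
  expect_equal(sum(kinds == "torsion_addt_linear_mode"),
               2L * sum(ic$dihedral_active &
                          ic$dihedral_types$classification == "linear"))
  nonrot <- which(cls %in% c("nonrotatable", "hindered"))
  expect_true(all(vapply(model$terms[nonrot], `[[`, integer(1L), "mode") == 1L))
  rot <- which(cls == "rotatable")
  expect_equal(length(rot), 2L * length(prep$scans))
  # both rotatable types here have flanking angles < 130 deg -> CADT
  expect_true(all(kinds[rot] == "torsion_cadt_mode"))
  # cross terms exist for every angle type, ring or not
  expect_equal(sum(kinds == "bond_bond_cross"), nrow(ic$angle_types))

  # damped single-mode case: a nonrotatable type with one angle >= 130 deg
  dt <- ic$dihedral_types
  damped_needed <- ic$dihedral_active &
    dt$classification %in% c("nonrotatable", "hindered") &
    pmax(dt$theta_eq_1, dt$theta_eq_2) >= 130 * pi / 180
  if (any(damped_needed)) {
    expect_true(any(kinds == "torsion_addt_mode" &
                      cls %in% c("nonrotatable", "hindered")))
  }
})

test_that("model energy: zero at reference, closed form, linear in k", {
  s <- make_fixture("h2o")
  ic <- classify_dihedral_types(type_internal_coords(s, detect_bonds(s)))
  m <- assign_term_kinds(ic)
  m$k <- c(10, 2)[seq_along(m$terms)]
  expect_equal(evaluate_energy(m, s), 0)
  # stretch a single O-H by 0.1 A along the bond direction
  g <- s
  u <- (s$positions[2, ] - s$positions[1, ]) / 0.96
  g$positions[2, ] <- g$positions[2, ] + 0.1 * u
  e1 <- evaluate_energy(m, g)
  kb <- m$k[vapply(m$terms, `[[`, character(1L), "kind") == "bond_stretch"]
  expect_equal(e1, kb * 0.5 * 0.1^2, tolerance = 1e-6)
  m2 <- m; m2$k <- 2 * m$k
  expect_equal(evaluate_energy(m2, g), 2 * e1)
})

test_that("forces: stationary reference, zero net force, numeric = analytic", {
  orc <- oracle_spec("toy_rotor_framework", seed = 13)
  m <- orc$model
  s <- orc$structure
  f0 <- evaluate_forces(m, s, mode = "analytic")
  expect_lt(max(abs(f0)), 1e-10)
  set.seed(5)
  g <- s
  g$positions <- g$positions + matrix(rnorm(3 * n_atoms(s), sd = 0.04), ncol = 3)
  fa <- evaluate_forces(m, g, mode = "analytic")
  fn <- evaluate_forces(m, g, mode = "numeric")
  expect_lt(max(abs(fa - fn)) / max(abs(fa)), 1e-6)
  expect_lt(max(abs(colSums(fa))), 1e-10)
})

test_that("single harmonic bond: |F| = k * delta along the bond, opposite signs", {
  s <- periodic_structure(diag(rep(20, 3)), c("C", "C"),
                          rbind(c(0, 0, 0), c(1.5, 0, 0)), periodic = FALSE)
  ic <- classify_dihedral_types(type_internal_coords(s, detect_bonds(s)))
  m <- assign_term_kinds(ic)
  m$k <- 12
  g <- s; g$positions[2, 1] <- 1.6
  f <- evaluate_forces(m, g, mode = "analytic")
  expect_equal(f[2, 1], -12 * 0.1, tolerance = 1e-9)
  expect_equal(f[1, 1], 12 * 0.1, tolerance = 1e-9)
  expect_lt(max(abs(f[, 2:3])), 1e-12)
})

test_that("energy and forces are invariant under rigid translation with re-wrap", {
  orc <- oracle_spec("toy_rotor_framework", seed = 13)
  set.seed(8)
  g <- orc$structure
  g$positions <- g$positions + matrix(rnorm(3 * n_atoms(g), sd = 0.03), ncol = 3)
  e0 <- evaluate_energy(orc$model, g)
  f0 <- evaluate_forces(orc$model, g, mode = "analytic")
  g2 <- g
  g2$positions <- g2$positions + matrix(rep(c(3.1, -0.7, 2.2),
                                            each = n_atoms(g)), ncol = 3)
  expect_equal(evaluate_energy(orc$model, g2), e0, tolerance = 1e-10)
  expect_equal(evaluate_forces(orc$model, g2, mode = "analytic"), f0,
               tolerance = 1e-8)
})

test_that("linear triatomic stretch degeneracy: equal without cross term, split with it", {
  s <- make_fixture("co2")
  ic <- classify_dihedral_types(type_internal_coords(s, detect_bonds(s)))
  stretch_block <- function(k_cross) {
    m <- assign_term_kinds(ic, cross_terms = k_cross != 0)
    kinds <- vapply(m$terms, `[[`, character(1L), "kind")
    m$k <- ifelse(kinds == "bond_stretch", 16,
                  ifelse(kinds == "angle_bend", 2, k_cross))
    # internal Hessian in the two C=O stretch coordinates: displace each O
    # along the molecular axis (z); mass-weighting by the equal O masses
    # rescales both eigenvalues identically
    h <- 1e-4
    H <- matrix(0, 2, 2)
    disp <- function(d1, d2) {
      g <- s
      g$positions[2, 3] <- g$positions[2, 3] + d1
      g$positions[3, 3] <- g$positions[3, 3] - d2
      evaluate_energy(m, g)
    }
    H[1, 1] <- (disp(h, 0) - 2 * disp(0, 0) + disp(-h, 0)) / h^2
    H[2, 2] <- (disp(0, h) - 2 * disp(0, 0) + disp(0, -h)) / h^2
    H[1, 2] <- H[2, 1] <- (disp(h, h) - disp(h, -h) - disp(-h, h) +
                             disp(-h, -h)) / (4 * h^2)
    eigen(H / atomic_mass(8L), symmetric = TRUE)$values
  }
  ev0 <- stretch_block(0)
  expect_equal(ev0[1], ev0[2], tolerance = 1e-6)
  ev1 <- stretch_block(3)
  expect_gt(abs(ev1[1] - ev1[2]) / mean(ev1), 0.1)
  expect_equal(ev1[1] - ev1[2], 2 * 3 / atomic_mass(8L), tolerance = 1e-4)
})

test_that("model JSON serialization round trips", {
  orc <- oracle_spec("ethane", seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_flex_model(orc$model, f)
  m2 <- read_flex_model(f)
  expect_equal(m2$k, orc$model$k, tolerance = 1e-12)
  expect_equal(length(m2$terms), length(orc$model$terms))
  set.seed(4)
  g <- orc$structure
  g$positions <- g$positions + matrix(rnorm(3 * n_atoms(g), sd = 0.05), ncol = 3)
  expect_equal(evaluate_energy(m2, g), evaluate_energy(orc$model, g),
               tolerance = 1e-10)
})
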