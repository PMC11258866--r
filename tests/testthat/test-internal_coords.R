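test_that("stretch enumeration: ethane bonds, 4-ring Urey-Bradley diagonals", {
  s <- make_fixture("ethane")
  ic <- type_internal_coords(s, detect_bonds(s))
  st <- ic$stretch_instances
  expect_equal(sum(st$kind == "bond"), 7L)
  expect_equal(sum(st$kind == "urey_bradley"), 0L)

  s4 <- make_fixture("cyclobutane_capped")
  ic4 <- type_internal_coords(s4, detect_bonds(s4))
  st4 <- ic4$stretch_instances
  expect_equal(sum(st4$kind == "bond"), 8L)          # 4 ring C-C + 4 C-H
  expect_equal(sum(st4$kind == "urey_bradley"), 2L)  # the two diagonals
  # diagonals are longer than the ring edges
  expect_true(all(st4$d_eq[st4$kind == "urey_bradley"] >
                    max(st4$d_eq[st4$kind == "bond"])))
})

test_that("periodic bonds appear as translated duplicates with n_duplicates = 2", {
  s <- make_fixture("toy_rotor_framework")
  ic <- type_internal_coords(s, detect_bonds(s))
  st <- ic$stretch_instances
  cross_cell <- st[st$n_duplicates == 2L, ]
  expect_true(nrow(cross_cell) >= 2L)
  # every physical stretch contributes total weight exactly 1
  wsum <- tapply(1 / st$n_duplicates, st$edge, sum)
  expect_true(all(abs(wsum - 1) < 1e-12))
  # duplicate rows are translated copies of each other
  for (e in unique(cross_cell$edge)) {
    rows <- st[st$edge == e, ]
    expect_equal(nrow(rows), 2L)
    shift <- unlist(rows[1L, c("ta1", "ta2", "ta3")]) -
      unlist(rows[2L, c("ta1", "ta2", "ta3")])
    expect_equal(unlist(rows[1L, c("tb1", "tb2", "tb3")]) -
                   unlist(rows[2L, c("tb1", "tb2", "tb3")]),
                 shift, ignore_attr = TRUE)
  }
})

test_that("angle enumeration: CO2, cyclopropane ring flags, SF6 pair count", {
  ic <- type_internal_coords(make_fixture("co2"),
                             detect_bonds(make_fixture("co2")))
  expect_equal(nrow(ic$angle_instances), 1L)

  s3 <- make_fixture("cyclopropane")
  ic3 <- type_internal_coords(s3, detect_bonds(s3))
  ccc <- ic3$angle_instances[ic3$angle_instances$ring_flag == "ring3", ]
  expect_equal(nrow(ccc), 3L)
  expect_false(any(ic3$angle_active[unique(ccc$type)]))

  s6 <- make_fixture("sf6")
  ic6 <- type_internal_coords(s6, detect_bonds(s6))
  expect_equal(nrow(ic6$angle_instances), choose(6, 2))  # 15 F-S-F pairs
  th <- round(ic6$angle_instances$theta_eq * 180 / pi)
  expect_equal(sum(th == 90), 12L)
  expect_equal(sum(th == 180), 3L)
})

test_that("SF6 yields exactly two F-S-F angle types", {
  s <- make_fixture("sf6")
  ic <- type_internal_coords(s, detect_bonds(s))
  expect_equal(nrow(ic$angle_types), 2L)
  expect_equal(sort(ic$angle_types$n_instances), c(3L, 12L))
})

test_that("same-element bonds of different equilibrium length form two stretch types", {
  # Jahn-Teller-like triangle: two short bonds, one long (same atom types)
  s <- periodic_structure(diag(rep(20, 3)), c("Li", "Li", "Li"),
                          rbind(c(0, 0, 0), c(2.70, 0, 0),
                                c(1.35, 2.396, 0)), periodic = FALSE)
  ic <- type_internal_coords(s, detect_bonds(s))
  bond_types <- ic$stretch_types[ic$stretch_types$kind == "bond", ]
  expect_equal(nrow(bond_types), 2L)
  expect_equal(sort(bond_types$n_instances), c(1L, 2L))
})

test_that("dihedral enumeration: ethane 9 instances in types of 3 and 6; CO2 none", {
  s <- make_fixture("ethane")
  ic <- type_internal_coords(s, detect_bonds(s))
  expect_equal(length(unique(ic$dihedral_instances$phys_id)), 9L)
  expect_equal(sort(ic$dihedral_types$n_instances), c(3L, 6L))
  # the 3-instance type is the anti (|phi_eq| = 180 deg) one
  anti <- ic$dihedral_types[ic$dihedral_types$n_instances == 3L, ]
  expect_equal(anti$abs_phi_round, round(pi, 2))

  ic2 <- type_internal_coords(make_fixture("co2"),
                              detect_bonds(make_fixture("co2")))
  expect_equal(nrow(ic2$dihedral_instances), 0L)
})

test_that("dihedrals using angles inside 3-/4-rings are deleted", {
  s <- make_fixture("cyclobutane_capped")
  ic <- type_internal_coords(s, detect_bonds(s))
  di <- ic$dihedral_instances
  # only H-C-C-H dihedrals survive (one per ring edge)
  expect_equal(length(unique(di$phys_id)), 4L)
  expect_true(all(di$a %in% which(s$elements == 1L)))
  expect_true(all(di$d %in% which(s$elements == 1L)))

  s3 <- make_fixture("cyclopropane")
  ic3 <- type_internal_coords(s3, detect_bonds(s3))
  # no surviving dihedral contains the in-ring C-C-C angles
  ang_flags <- ic3$angle_instances$ring_flag
  expect_true(all(ang_flags[ic3$dihedral_instances$ang1] == "none"))
  expect_true(all(ang_flags[ic3$dihedral_instances$ang2] == "none"))
})

test_that("ring membership of middle bonds agrees with the bridge oracle", {
  for (nm in list(make_benzene(), make_fixture("ethane"),
                  make_fixture("cyclobutane_capped"))) {
    g <- detect_bonds(nm)
    for (row in seq_len(nrow(g))) {
      bond <- as.integer(unlist(g[row, c("a", "b", "t1", "t2", "t3")]))
      expect_equal(middle_bond_in_ring(nm, g, bond),
                   bond_in_ring_igraph(nm, g, row))
    }
  }
})

test_that("a one-atom periodic chain bond is part of a ring through its images", {
  s <- make_fixture("chain_1atom")
  g <- detect_bonds(s)
  bond <- as.integer(unlist(g[1L, c("a", "b", "t1", "t2", "t3")]))
  expect_true(middle_bond_in_ring(s, g, bond))
  # and the equivalent bond in a 3x supercell is still in a ring
  s3 <- make_supercell(s, c(3L, 1L, 1L))
  g3 <- detect_bonds(s3)
  bond3 <- as.integer(unlist(g3[1L, c("a", "b", "t1", "t2", "t3")]))
  expect_true(middle_bond_in_ring(s3, g3, bond3))
})

test_that("typing is deterministic and order-independent up to relabeling", {
  s <- make_fixture("toy_rotor_framework")
  ic0 <- type_internal_coords(s, detect_bonds(s))
  set.seed(7)
  perm <- sample(n_atoms(s))
  s2 <- s
  s2$elements <- s$elements[perm]
  s2$positions <- s$positions[perm, ]
  ic2 <- type_internal_coords(s2, detect_bonds(s2))
  expect_equal(nrow(ic2$stretch_types), nrow(ic0$stretch_types))
  expect_equal(nrow(ic2$angle_types), nrow(ic0$angle_types))
  expect_equal(nrow(ic2$dihedral_types), nrow(ic0$dihedral_types))
  expect_equal(sort(ic2$dihedral_types$n_instances),
               sort(ic0$dihedral_types$n_instances))
  expect_equal(sort(round(ic2$stretch_types$d_eq_ref, 9)),
               sort(round(ic0$stretch_types$d_eq_ref, 9)))
})

test_that("internal coordinate redundancy formula and edge cases", {
  s <- make_fixture("toy_rotor_framework")
  ic <- type_internal_coords(s, detect_bonds(s))
  ic <- classify_dihedral_types(ic)
  n <- n_atoms(s)
  # hand count of active instances
  n_st <- length(unique(ic$stretch_instances$edge))
  n_an <- sum(ic$angle_instances$ring_flag == "none")
  n_di <- length(unique(ic$dihedral_instances$phys_id))
  expect_equal(compute_icr(ic),
               100 * (n_st + n_an + n_di - (3 * n - 3)) / (3 * n - 3))
  expect_error(compute_icr(ic, n_atoms_ = 1L), "undefined")
})

test_that("average equilibrium values: means per type, dihedral signs kept", {
  s <- make_twisted_ethane(0.2)
  ic <- type_internal_coords(s, detect_bonds(s))
  av <- average_equilibrium_values(ic)
  # stretch: every instance of a type carries the type mean
  for (k in seq_len(nrow(av$stretch_types))) {
    sel <- av$stretch_instances[av$stretch_instances$type == k, ]
    orig <- ic$stretch_instances[ic$stretch_instances$type == k, ]
    expect_equal(unique(round(sel$d_eq, 12)),
                 round(mean(orig$d_eq[!duplicated(orig$edge)]), 12))
  }
  # dihedral: |phi_eq| averaged over members, per-instance sign retained
  for (k in seq_len(nrow(av$dihedral_types))) {
    sel <- av$dihedral_instances[av$dihedral_instances$type == k, ]
    orig <- ic$dihedral_instances[ic$dihedral_instances$type == k, ]
    m <- mean(abs(orig$phi_eq[!duplicated(orig$phys_id)]))
    expect_equal(sel$phi_eq, sel$sign_eq * m)
    expect_identical(sel$sign_eq, orig$sign_eq)
  }
})
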