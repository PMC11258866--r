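# Shared fixtures and small independent oracles used across the test files.

# planar benzene ring (C6H6), for ring-membership checks
make_benzene <- function() {
  pos <- NULL
  el <- c()
  for (az in seq(0, 300, by = 60) * pi / 180) {
    u <- c(cos(az), sin(az), 0)
    pos <- rbind(pos, 1.39 * u, 2.48 * u)
    el <- c(el, "C", "H")
  }
  periodic_structure(diag(rep(20, 3)), el, pos, periodic = FALSE)
}

# five-atom chain where rotating D about the B-C axis sweeps it within
# bonding distance of E (a steric clash that changes the bond graph)
make_clash_rotor <- function() {
  pos <- rbind(
    c(-0.5, 1.40, 0),     # A
    c(0.0, 0.00, 0),      # B
    c(1.5, 0.00, 0),      # C
    c(0.99, -1.41, 0),    # D, trans to A
    c(-0.51, 0.00, -1.41) # E bonded to B, out of plane
  )
  periodic_structure(diag(rep(20, 3)), rep("C", 5), pos, periodic = FALSE)
}

# ethane with the top methyl twisted by a small angle (splits dihedral
# equilibria away from the ideal staggered values)
make_twisted_ethane <- function(delta_deg = 0.2) {
  s <- make_fixture("ethane")
  th <- delta_deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  top <- c(1, 3, 4, 5)  # C1 and its hydrogens
  s$positions[top, ] <- s$positions[top, ] %*% t(rot)
  s
}

# brute-force bond detection oracle: all pairs over the 27-cell block
brute_force_bonds <- function(structure, radii = default_typing_radii(),
                              tolerance_scale = 1.0) {
  n <- n_atoms(structure)
  sym <- element_symbol(structure$elements)
  r <- unname(radii[sym])
  trans <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  if (!structure$periodic) trans <- trans[rowSums(abs(trans)) == 0, , drop = FALSE]
  hits <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) for (k in seq_len(nrow(trans))) {
    tt <- as.integer(trans[k, ])
    if (a == b && all(tt == 0L)) next
    d <- sqrt(sum((image_position(structure, b, tt) -
                     structure$positions[a, ])^2))
    if (d <= tolerance_scale * (r[a] + r[b])) {
      key <- if (a < b || (a == b && flexff:::.lex_positive(tt))) {
        paste(c(a, b, tt), collapse = "_")
      } else {
        paste(c(b, a, -tt), collapse = "_")
      }
      hits[[key]] <- TRUE
    }
  }
  sort(names(hits))
}

edge_keys <- function(graph) {
  sort(paste(graph$a, graph$b, graph$t1, graph$t2, graph$t3, sep = "_"))
}

# independent ring oracle: a bond is on a bond-path cycle iff it is not a
# bridge of the quotient multigraph (loops and parallel edges allowed)
bond_in_ring_igraph <- function(structure, graph, row) {
  skip_if_not_installed("igraph")
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$a, to = graph$b), directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(structure))))
  br <- igraph::bridges(g)
  !(igraph::get_edge_ids(g, c(graph$a[row], graph$b[row])) %in% br)
}

# numeric central-difference forces used as the independent force oracle
numeric_forces <- function(energy_fn, geometry, h = 1e-5) {
  n <- n_atoms(geometry)
  f <- matrix(0, n, 3)
  for (a in seq_len(n)) for (x in 1:3) {
    gp <- geometry; gp$positions[a, x] <- gp$positions[a, x] + h
    gm <- geometry; gm$positions[a, x] <- gm$positions[a, x] - h
    f[a, x] <- -(energy_fn(gp) - energy_fn(gm)) / (2 * h)
  }
  f
}
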