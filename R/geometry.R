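## Low-level periodic geometry: image positions, wrapping, internal-coordinate
## values and their analytic Cartesian gradients. Positions are Cartesian
## Angstroms; angles radians; dihedrals on (-pi, pi].

#' Cartesian position of an atom image
#'
#' @param structure a `periodic_structure`
#' @param atom atom index (reference cell)
#' @param translation integer length-3 lattice translation
#' @return numeric length-3 Cartesian position (Angstrom)
#' @keywords internal
image_position <- function(structure, atom, translation = c(0L, 0L, 0L)) {
  p <- structure$positions[atom, ]
  if (any(translation != 0L)) {
    p <- p + as.numeric(translation %*% structure$lattice)
  }
  p
}

## positions for a matrix of (atom, t1, t2, t3) rows
image_positions <- function(structure, images) {
  structure$positions[images[, 1L], , drop = FALSE] +
    images[, 2:4, drop = FALSE] %*% structure$lattice
}

#' Wrap Cartesian positions into the reference cell
#'
#' Fractional coordinates are reduced to [0, 1). Non-periodic structures are
#' returned unchanged.
#' @param structure a `periodic_structure`
#' @return the structure with wrapped positions
#' @export
wrap_positions <- function(structure) {
  if (!structure$periodic) return(structure)
  frac <- structure$positions %*% solve(structure$lattice)
  frac <- frac - floor(frac)
  ## guard against 1 - eps rounding back up to 1
  frac[frac >= 1] <- 0
  structure$positions <- frac %*% structure$lattice
  structure
}

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## distance between two images given their Cartesian positions
geom_distance <- function(p1, p2) vnorm(p2 - p1)

## angle at p2 formed by p1-p2-p3, radians in [0, pi]
geom_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  cs <- min(1, max(-1, cs))
  acos(cs)
}

## signed dihedral p1-p2-p3-p4 on (-pi, pi]
geom_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  phi <- atan2(y, x)
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

## Analytic gradients. Each returns a list(value, grad) where grad is a
## (n_points x 3) matrix of d(value)/d(point_i).

grad_distance <- function(p1, p2) {
  d <- p2 - p1
  r <- vnorm(d)
  u <- d / r
  list(value = r, grad = rbind(-u, u))
}

## gradient of cos(theta) for angle p1-p2-p3 (smooth through theta = pi)
grad_cos_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  ru <- vnorm(u)
  rv <- vnorm(v)
  uh <- u / ru
  vh <- v / rv
  cs <- sum(uh * vh)
  g1 <- (vh - cs * uh) / ru
  g3 <- (uh - cs * vh) / rv
  g2 <- -(g1 + g3)
  list(value = min(1, max(-1, cs)), grad = rbind(g1, g2, g3))
}

## gradient of the signed dihedral (standard rigid-rotor formulas)
grad_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- vnorm(b2)
  n1sq <- sum(n1 * n1)
  n2sq <- sum(n2 * n2)
  if (n1sq < 1e-24 || n2sq < 1e-24) {
    ## exactly linear flanking angle: the dihedral is undefined and any
    ## angle-damped amplitude vanishes there; return a zero gradient
    return(list(value = 0, grad = matrix(0, 4L, 3L)))
  }
  g1 <- nb2 / n1sq * n1
  g4 <- -nb2 / n2sq * n2
  f12 <- sum(b1 * b2) / (nb2 * nb2)
  f32 <- sum(b3 * b2) / (nb2 * nb2)
  g2 <- -(1 + f12) * g1 + f32 * g4
  g3 <- f12 * g1 - (1 + f32) * g4
  m1 <- cross3(n1, b2 / nb2)
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (phi <= -pi) phi <- phi + 2 * pi
  list(value = phi, grad = rbind(g1, g2, g3, g4))
}

## Rodrigues rotation of points (n x 3) about unit axis through origin
rodrigues_rotate <- function(points, axis, origin, theta) {
  u <- axis / vnorm(axis)
  ct <- cos(theta)
  st <- sin(theta)
  rel <- sweep(points, 2L, origin)
  dotp <- as.numeric(rel %*% u)
  crossp <- t(apply(rel, 1L, function(v) cross3(u, v)))
  if (nrow(points) == 1L) crossp <- matrix(crossp, nrow = 1L)
  rot <- rel * ct + crossp * st + outer(dotp * (1 - ct), u)
  sweep(rot, 2L, origin, FUN = "+")
}

## build an n1 x n2 x n3 supercell (used by tests and cell-adequacy repair)
#' Expand a structure into a supercell
#'
#' @param structure a `periodic_structure`
#' @param factors integer length-3 repetition factors
#' @return the expanded `periodic_structure`
#' @export
make_supercell <- function(structure, factors) {
  stopifnot(structure$periodic, length(factors) == 3L, all(factors >= 1L))
  reps <- as.matrix(expand.grid(0:(factors[1L] - 1L),
                                0:(factors[2L] - 1L),
                                0:(factors[3L] - 1L)))
  n <- n_atoms(structure)
  pos <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    structure$positions + matrix(rep(as.numeric(reps[i, ] %*% structure$lattice),
                                     each = n), ncol = 3L)
  }))
  periodic_structure(
    lattice = structure$lattice * factors,  # row i scaled by factors[i]
    elements = rep(structure$elements, nrow(reps)),
    positions = pos,
    periodic = TRUE)
}
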