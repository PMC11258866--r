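## Standard atomic masses (amu), indexed by atomic number; used by the
## pseudo-dynamics sampler and the mass-weighted Hessian diagnostics.
.element_masses <- c(
  1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999, 18.998, 20.180,
  22.990, 24.305, 26.982, 28.085, 30.974, 32.06, 35.45, 39.948, 39.098,
  40.078, 44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693,
  63.546, 65.38, 69.723, 72.630, 74.922, 78.971, 79.904, 83.798, 85.468,
  87.62, 88.906, 91.224, 92.906, 95.95, 98.0, 101.07, 102.906, 106.42,
  107.868, 112.414, 114.818, 118.710, 121.760, 127.60, 126.904, 131.293,
  132.905, 137.327, 138.905, 140.116, 140.908, 144.242, 145.0, 150.36,
  151.964, 157.25, 158.925, 162.500, 164.930, 167.259, 168.934, 173.045,
  174.967, 178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084,
  196.967, 200.592, 204.38, 207.2, 208.980, 209.0, 210.0, 222.0, 223.0,
  226.0, 227.0, 232.038, 231.036, 238.029, 237.0, 244.0, 243.0, 247.0)

#' Standard atomic mass
#' @param z integer atomic number(s)
#' @return mass in amu
#' @export
atomic_mass <- function(z) .element_masses[z]
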