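---
title: "Flexibility force-field parameterization: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexibility force-field parameterization: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexff)
```

# The problem and the model

`flexff` parameterizes the bonded ("flexibility") part of a classical force
field for a periodic crystal or molecule. The bonded energy is a linear
combination of flexibility terms,

$$U = \sum_j k_j \sum_{\text{instances}} \frac{1}{N_\text{dup}}\,
g_j(\text{geometry}),$$

with one force constant $k_j$ per *type* of internal coordinate, each basis
function $g_j$ constructed to be zero and stationary at the optimized
reference geometry. Because every $g_j$ is fixed once typing is done, the
$k_j$ enter linearly and can be fitted simultaneously by (regularized)
linear least squares against reference forces and torsion-scan energies —
no nonlinear optimization, no sequential one-at-a-time fitting of coupled,
redundant coordinates.

Key assumptions: the reference geometry is a true stationary point of the
reference engine (the fit reproduces it exactly as an equilibrium when
per-instance equilibrium values are used); non-bonded contributions are
separated out upstream and are not modeled here; and the harmonic/cosine
forms below are adequate up to second order, with redundancy among internal
coordinates providing some self-correction beyond it.

## Term catalogue

* **Bond and Urey–Bradley stretches.** Harmonic,
  $g = \tfrac12 (d - d_\mathrm{eq})^2$ (Å²; $k$ in eV Å⁻²). Urey–Bradley
  stretches are added for the two diagonals of every 4-membered ring, which
  (with the 4 edge bonds) describe the ring's six internal distances more
  compactly than 4 bends + 4 stretches. Angles inside 3-/4-membered rings
  are typed and kept in the inventory but excluded from the bending
  potential, since those degrees of freedom are already spanned.

* **Angle bends.**
  $g = (\cos\theta - \cos\theta_\mathrm{eq})^2 / (1 - \cos\theta)$
  (dimensionless; $k$ in eV). As a rational function of $\cos\theta$ it has
  continuous derivatives of all orders in the Cartesian coordinates,
  including through $\theta = \pi$ where $\theta$ itself is non-smooth; it
  diverges as $\theta \to 0^{+}$, mimicking Pauli repulsion; it is zero and
  stationary at every $0 < \theta_\mathrm{eq} \le \pi$; and the force
  constant is its only parameter. Near a non-linear equilibrium it behaves
  as $(1+\cos\theta_\mathrm{eq})\,(\theta-\theta_\mathrm{eq})^2$; at
  $\theta_\mathrm{eq} = \pi$ the leading term is quadratic in the smooth
  variable $1+\cos\theta$ (quartic in $\theta - \pi$), which is the correct
  smooth behavior for a linear equilibrium.

* **Torsions.** Up to seven modes per dihedral type: cosine modes
  $1 - \cos m(\phi - \phi_\mathrm{eq})$, $m \in 1..4$ (even in the
  displacement, zero and stationary at $\phi_\mathrm{eq}$) and sine modes
  $\sin n(\phi - \phi_\mathrm{eq})$, $n \in 1..3$ (odd). Instances whose
  equilibrium dihedral has the opposite sign use mirrored sine modes, so
  mirror-image instances of one type legitimately share force constants.
  Four torsion potentials are assigned per type: rotatable types get their
  smart-selected modes; non-rotatable and hindered types get a single
  mode-1 term; types containing a near-linear equilibrium angle get a
  two-mode (cosine-1 + sine-1) angle-damped potential; and every torsion is
  *angle-damped* — multiplied by
  $D(\theta) = \tanh(K \sin^2\theta)/\tanh K$ with
  $K = 2.815891616117388$ for both flanking angles — whenever either
  contained equilibrium angle is $\ge 130^\circ$. $D$ is a smooth function
  of $\cos^2\theta$, equals 1 at right angles, and vanishes as
  $\sin^2\theta$ at linearity — exactly fast enough to cancel the
  $1/\sin\theta$ divergence of the dihedral gradient, so forces remain
  continuous where the dihedral itself becomes undefined.

* **Bond–bond cross terms** (optional, default off):
  $g = (d_1 - d_1^\mathrm{eq})(d_2 - d_2^\mathrm{eq})$ for the two bonds of
  every angle instance, including angles inside small rings. These set the
  splitting between symmetric and antisymmetric stretch combinations; a
  linear symmetric triatomic is the canonical case where two equal-$k$
  stretches plus a bend predict exactly degenerate stretch eigenvalues
  until a cross term splits them (asserted in the test suite).

## Typing and redundancy

Atoms are typed by their first and second bonded neighbors
(`6[1-(0),1-(0),1-(0),6-(1,1,8)]`-style signatures); bonds are perceived
when the interatomic distance does not exceed the sum of per-element typing
radii, searched over the reference cell and its 26 neighbors. Instances
group into types only if atom/bond/angle-type composition *and* equilibrium
values agree: stretches within 1 % of the type's first member, angles and
dihedral absolute values rounded to 0.01 rad (round-half-to-even; two
instances falling on opposite sides of a rounding boundary deliberately
form distinct types). The 1 % stretch window is anchored to the first
member in a deterministic enumeration order (ascending atom indices, then
translations) rather than chained, so typing is reproducible and cannot
drift.

Coupled dihedral types — types whose deduplicated middle-bond sets are
identical, so that rotating one necessarily rotates all — are pruned to a
single representative maximizing
$(180^\circ - \max[\theta^\mathrm{eq}_{ABC},
\theta^\mathrm{eq}_{BCD}])/n_\text{instances}$ (prefer far-from-linear,
prefer fewer instances); ties are broken by a seeded draw, and whole types
are always kept or discarded together, preserving symmetry equivalency.
The remaining redundancy is reported as
$\mathrm{ICR} = 100\,(n_\text{active} - (3N-3))/(3N-3)$.

## Classification and scans

A dihedral type is *linear* if either contained equilibrium angle is within
0.03 rad of $\pi$; otherwise *non-rotatable* if **any** of its instances
has a middle bond on a bond-path cycle (mixed ring/no-ring types are wholly
non-rotatable — treating the no-ring instances as restricted only
undercounts large displacements); otherwise it is provisionally rotatable.
Ring membership is decided on the periodic image graph: a bond is in a ring
iff a bond walk from one endpoint image reaches *any* image of the other
parent atom without retraversing the starting bond instance (so a
one-atom-per-cell chain bond, whose quotient-graph edge is a loop, is
correctly in a ring). If a cycle exists, one exists with fewer than
$4N+1$ atoms, so the breadth-first search is depth-capped there and exact.

Rigid torsion scans rotate the *smaller* bonded group about the middle-bond
axis by $\theta_\mathrm{rot} = \phi_\mathrm{desired} - \phi_\mathrm{eq}$
(Rodrigues rotation; origin at the middle atom adjacent to the rotated
group; equal-sized groups rotate the D side — the convention is only
specified for the strict inequality, so a deterministic choice was made).
An unbounded group (periodic through-bond continuation) simply forces the
other side to rotate. The 36-point, 10°-step grid over $(-180^\circ,
180^\circ]$ is shared between the hindered test — one seeded instance per
provisional type is scanned and re-typed at every point; any atom-type
change anywhere reclassifies the type as *hindered* — and the subsequent
energy fitting, which is essential: the rotatable label certifies exactly
these geometries keep the bond graph intact.

Scan geometries are kept **unwrapped**: re-wrapping rotated atoms into the
cell would silently invalidate the stored image translations of every
instance touching them. Wrapping is applied only by the file writers.

## Mode projection and smart selection

On the uniform grid the centered basis functions
($-\cos m(\phi-\phi_\mathrm{eq})$, $\sin n(\phi-\phi_\mathrm{eq})$) are
exactly mutually orthogonal, so with
$c_m = \sum_t (E_t - \bar E) f_m(\phi_t) \big/
\sqrt{\sum_t (E_t-\bar E)^2 \sum_t f_m(\phi_t)^2}$
the $R^2$ of the full seven-mode model is exactly $\sum_m c_m^2$, and of any
truncated model the sum over its modes. This normalization is what pins the
discrete realization of the projection down. Modes with $|c_m| > 0.1$ are
selected; an empty selection falls back, with a warning, to the single
largest-$|c_m|$ mode (the behavior here is otherwise unspecified, and a
rotatable torsion with no potential at all would be worse); a selection
containing only sine modes is rejected as inconsistent — at an energy
minimum the curve must have even content.

## The regression

Observations are (a) all force components of the optimized geometry, the
finite-displacement set, and the training trajectories, and (b) the
per-scan-centered torsion energies. Design entries are minus the analytic
internal-coordinate gradients of each term's duplicate-weighted basis sum
(validated against central differences in the tests; the analytic route is
what makes the Å→bohr invariance hold to 1e-8 and the sampler affordable).
Scan columns are centered per scan, which, with the no-intercept model,
makes torsion rows couple only to rotatable-dihedral columns.

Weights are constant within each training part and inversely proportional
to the part's total (no-intercept) sum of squares, rescaled to sum to the
number of observations: the weighted SSE then equals
$N_\text{parts} - \sum_p R^2_p$, so the fit maximizes the summed per-part
$R^2$. Penalty factors are the weighted root-sum-of-squares of each column,
making $\nu_j |\beta_j|$ — and hence the selected model and all reported
statistics — independent of measurement units. Bounds: zero lower bounds on
stretches, bends, single-mode torsions, and linear-dihedral modes
(displacements away from equilibrium must not lower the energy through a
single such term); no bounds on multi-mode rotatable torsions and cross
terms, whose signs can legitimately compete.

The solver is a self-contained cyclic coordinate descent with
soft-thresholding, box clipping, and warm starts along a 100-point
geometric $\lambda$ path from the analytically computed $\lambda_{\max}$
(the smallest value zeroing every coefficient, accounting for one-sided
bounds) down by a factor of $10^{-5}$, converging each point to a
$10^{-10}$-scaled update threshold. It is cross-checked in the test suite
against both the weighted normal equations (at $\lambda \to 0$) and an
independent LASSO implementation under identical weights, penalty factors
and bounds.

$\lambda_\text{best}$ walks the path from the least-regularized end,
keeping per distinct surviving-constant count the highest-$R^2$ point, and
accepts each sparser model only while the SSE increase per dropped force
constant stays at or below half the *formal per-degree-of-freedom amount*,
read as the current residual SSE divided by $3N$ degrees of freedom (the
total sum of squares cancels out of the test). On noiseless data the
residual is essentially zero, so nothing genuinely needed is ever dropped
and planted models are recovered exactly; on noisy data the rule prunes
terms whose contribution is below the noise floor. Per-part and per-atom
$R^2$ and RMSE are reported for training and validation, the validation set
being the optimized geometry plus held-out trajectories only — never
finite-displacement geometries.

`eq_mode = "individual"` (default) uses each instance's own equilibrium
value, guaranteeing exact stationarity of the fitted model at the reference
geometry; `eq_mode = "average"` replaces equilibria by type means (dihedral
absolute values averaged, per-instance signs kept). Both are first-class;
comparing them diagnoses types defined too loosely.

# The synthetic-reference oracle

`oracle_spec()` + `generate_reference_data()` stand in for the reference
quantum-chemistry engine. The oracle builds the fixture's typed coordinate
set through the same front end as the fit, plants a hidden flexibility
model on it (seeded force constants in plausible ranges: stretches
15–35 eV Å⁻², Urey–Bradley 3–8 eV Å⁻², bends 2–6 eV, single-mode torsions
0.1–0.5 eV, rotor modes 0.3–1 eV; linear-dihedral modes and cross terms
zero unless overridden), verifies stationarity at the reference geometry,
and emits: the optimized geometry with exactly-zero forces; 12
finite-displacement geometries per atom at ±0.07/±0.14 Å per Cartesian
axis; 10 training + 10 validation pseudo-dynamics runs of 100 velocity-
Verlet steps (1 fs, NVE, seeded 300 K Maxwell–Boltzmann start) under the
hidden model; and 36-point scan energies evaluated on exactly the scan
geometries the classification step produced. Optional Gaussian noise
(eV Å⁻¹ on forces, eV on energies) and a small cubic stretch perturbation
emulate measurement error and model misspecification.

What this emulates — and what it does not: the data have exactly the
statistical structure the fit assumes (the potential *is* a flexibility
model; there are no non-bonded forces, no electronic effects, no thermostat
artifacts, no geometry-optimization residuals). Passing the end-to-end
recovery tests therefore certifies the machinery — typing, pruning,
classification, scan generation, design assembly, solver, selection rule,
statistics — not the physical accuracy of the term catalogue on real
materials. The noise and anharmonic switches probe robustness, not realism.

# Defaults and problem sizes

| parameter | default | units | role |
|---|---|---|---|
| stretch typing window | 1 % | relative | type-splitting on $d_\mathrm{eq}$ |
| angle/dihedral rounding | 0.01 | rad | type-splitting on $\theta$, $|\phi|$ |
| linear tolerance $\varepsilon$ | 0.03 | rad | linear-dihedral classification |
| damped-case threshold | 130 | deg | CADT vs angle-damped torsion |
| smart-selection cutoff | 0.1 | — | $|c_m|$ threshold |
| scan step | 10 | deg | 36 geometries over $(-180, 180]$ |
| $\lambda$ path | 100 pts, ratio $10^{-5}$ | — | geometric grid |
| solver threshold | $10^{-10}$ | — | scaled update convergence |
| overlap/typing radii | bundled table (+0.10 Å margin) | Å | bond perception; overridable |
| overlap error cutoff | 0.4 | Å | structure screening |
| seed | 1 | — | pruning ties, scan instance, sampler |

One pipeline seed governs every stochastic choice and is recorded in the
artifacts; reruns are bit-identical. The acceptance script and the
end-to-end tests run the full sampling design (12 displacements per atom,
10 + 10 runs × 100 steps — about 2 200 geometries and 45 000 force
components on the 13-atom toy framework); the orchestration unit tests use
1–3 runs of 10–40 steps, which the recovery properties do not depend on.

# Known limitations

* The bond-perception radii table is a documented covalent-radius-style
  default; counts that hinge on borderline bonds can change under a
  different table (it is overridable per element).
* No improper dihedrals, out-of-plane or concurrence terms; no Morse or
  quartic stretches; no non-bonded terms. Anharmonicity beyond the cosine
  torsion series is absorbed, or not, by redundancy.
* Dihedral values are ill-conditioned near linear contained angles; bare
  (undamped) torsions are therefore never assigned there, and exactly
  singular configurations evaluate to a zero torsion gradient (the damped
  amplitude vanishes at the same rate).
* The unit cell must be large enough that no atom bonds to two images of
  the same neighbor (`validate_unit_cell()` reports offenders); expand to a
  supercell otherwise.
* Hindered-rotor detection inherits the scan grid: a clash narrower than
  the 10° step could be missed. The grid is configurable.
* The pseudo-dynamics sampler is NVE without a thermostat and makes no
  thermodynamic claims; temperature only scales the sampling amplitude.
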