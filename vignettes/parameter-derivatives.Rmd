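---
title: "Analytic parameter derivatives and Hessian-based parameterization of an MNDO engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic parameter derivatives and Hessian-based parameterization of an MNDO engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mndopt)
```

## The model

`mndopt` implements an MNDO-class semi-empirical Hamiltonian for the
elements H, C, N, O and F in the minimal valence s,p basis.  NDDO methods
of this family operate formally in the Löwdin-orthogonalized basis, so the
overlap matrix is the identity and the electronic problem is an
(unrestricted) Hartree–Fock problem

$$ {}^\sigma F = H + J(P) - K({}^\sigma P), \qquad
   P = {}^\alpha P + {}^\beta P, $$

where the core matrix carries the one-center one-electron energies
$U_{ss}, U_{pp}$, two-center core–electron attractions
$V_{\mu\nu,B} = -Z_B\,(\mu\nu|s_Bs_B)$, and interatomic resonance terms
$\beta_{\mu\nu} = \tfrac12(\beta_\mu+\beta_\nu)S_{\mu\nu}$ built from
Slater-orbital overlaps.  Closed shells are treated as the restricted
special case; open shells are spin-unrestricted.

Two-electron integrals survive only when each charge distribution lives on
one atom.  One-center integrals are the fixed empirical constants
$G_{ss}, G_{sp}, G_{pp}, G_{p2}, H_{sp}$.  Two-center integrals use the
classical point-multipole model: each distribution $\mu\nu$ is replaced by
a point-charge configuration carrying its exact leading multipole moment
(monopole, dipole of length $D_1$, linear or square quadrupole of length
$D_2$), and charges interact through the damped kernel
$e^2/\sqrt{r^2 + (\rho_{l_A}+\rho_{l_B})^2}$.

### Calibration of the damping terms

$\rho_0 = e^2/2G_{ss}$ follows in closed form.  The dipole term $\rho_1$
solves $[\mu\mu]_{R=0} = H_{sp}$.  For the quadrupole term the defining
condition is not uniquely fixed by the multipole construction; we
calibrated the choice against the original published MNDO results.  With
the linear-quadrupole self-interaction matched to $G_{pp}-G_{p2}$, the
engine reproduces the published MNDO heats of formation of
H2, CH4, NH3, H2O, HF, N2, F2, CO, CO2, C2H2, C2H4 and C2H6 to about
1 kcal/mol (geometry differences account for the remainder), along with
the published ionization energies and dipole moments; the plausible
alternative conditions (square-quadrupole configuration, or half the
target) are off by 10–100 kcal/mol on multiply-bonded molecules.  This
calibration is therefore adopted as part of the engine definition.

The core–core repulsion is the classic exponential form
$V^{CRF}_{AB} = Z_AZ_B(s_As_A|s_Bs_B)\,[1 + e^{-\alpha_A R} +
e^{-\alpha_B R}]$, with the N–H/O–H variant in which the heavy atom's
exponential is multiplied by $R$ (in Å).

### Units

Coordinates are in Å, energies internally in eV, Slater exponents in
bohr$^{-1}$, $\alpha$ in Å$^{-1}$.  Heats of formation are reported in
kcal/mol with $k_{conv} = 23.060548$, gradients in kcal mol$^{-1}$
bohr$^{-1}$ with $1\,\mathrm{bohr} = 0.52917721$ Å, dipoles in Debye with
$4.8032045$ D per e·Å, and $e^2 = 14.399645$ eV·Å.

## Analytic parameter derivatives

The objective couples four properties per molecule — heat of formation,
Koopmans ionization energy ($-\varepsilon_{HOMO}$), dipole magnitude, and
the norm of the Cartesian gradient at a reference geometry — and the
optimization needs their first *and second* derivatives with respect to
the 37 optimizable parameters ($\alpha, \beta_s, \beta_p, U_{ss}, U_{pp},
\zeta_s, \zeta_p, E_{isol}$ per element, hydrogen without p-fields).

### Integral-level derivatives

All integral derivatives — with respect to $\zeta_s,\zeta_p$ (through the
overlap radial factors, the multipole distances $D_1(\zeta), D_2(\zeta)$
and the implicitly defined $\rho_1,\rho_2$), $\alpha$, and Cartesian
coordinates, up to the mixed third order (one coordinate × two
parameters) needed by the gradient-norm Hessian chain — are produced by a
small forward-mode truncated-Taylor ("jet") arithmetic built into the
package.  Every intermediate of the closed-form integral routines carries
its Taylor coefficients over a capped monomial basis, so the chain rule is
applied mechanically and *exactly*; this is analytic differentiation, not
finite differencing, and the finite-difference oracles used by the test
suite remain fully independent.  The implicit roots $\rho_1,\rho_2$ are
propagated by Newton iteration in jet space, which converges to the exact
Taylor coefficients in two steps per order.  Overlaps are evaluated in the
local diatomic frame from auxiliary integrals $A_k(p), B_k(q)$ with a
series branch for $|q|\!\to\!0$ (near-equal exponents), and rotated with
jet-valued rotation matrices so Cartesian derivatives flow through both
the distance dependence and the frame.

### Response equations

First- and second-order coupled-perturbed Hartree–Fock equations in the
orthogonalized basis supply the density response.  The occupied–virtual
equations couple both spins through the Coulomb operator; at the problem
sizes targeted here (tens of occupied–virtual pairs) the package builds
the coupled operator densely once per molecule, factorizes it, and reuses
the factorization for every first-order right-hand side (one per
parameter) and every second-order right-hand side (one per parameter
pair).  This replaces the iterative Krylov schemes customary at ab initio
scale: it is deterministic, exact to machine precision, and faster when
dozens of right-hand sides share one operator.

The full first-order rotation matrices (not only their occupied–virtual
blocks) enter the second-order equations.  Off-diagonal elements are
recovered by direct substitution; for degenerate same-occupancy pairs the
substitution denominator vanishes, but parameter perturbations are totally
symmetric, so the corresponding coupling element vanishes identically and
the rotation element is set to zero.  Density-level quantities are gauge
invariant under rotations inside degenerate blocks, which the test suite
checks explicitly on methane's triply degenerate HOMO.

Two details of the second-order equations deserve note.  First, the
gamma-independent part of $d^2P$ must restrict its leading sum to virtual
orbitals; extending it over all orbitals double-counts the
occupied–occupied block of $x^{q_1}x^{q_2}+x^{q_2}x^{q_1}$ and violates
$\mathrm{Tr}\,d^2P = 0$.  We derived the restricted form from
$d^2C = C\gamma$ and verified it against central finite differences
(agreement to $10^{-8}$, traces at $10^{-18}$).  Second, one superscript
pairing in the second-order right-hand side is printed inconsistently in
the formalism this package follows; the q1↔q2-symmetric combination is
used (the printed variant is kept behind a debug switch, and the symmetric
choice is confirmed by the FD oracles and by the exact symmetry of the
resulting $d^2P$ under argument exchange).

### Property chains

*Heat of formation.* First derivatives need only static integral
derivatives contracted with the converged density (SCF stationarity);
second derivatives additionally need the first-order density response but
never the second-order one.  $E_{isol}$ enters linearly
($-k_{conv} n_Z$) and $\alpha$ only through the core repulsion, giving
exact zero blocks that the tests assert.

*Ionization energy.* $d\varepsilon_i = (\mathfrak F^q + \mathfrak R^q)_{ii}$
and its second-order analogue evaluated at the highest occupied level.
A HOMO degenerate across the occupied/virtual boundary is an error; the
symmetric degeneracy within the occupied block is harmless for parameter
perturbations (all partners shift equally).

*Dipole.* Point-charge plus one-center sp-hybridization terms, with
$dD_1/d\zeta$ chains; restricted to closed shells.  The magnitude chain
uses the smoothed norm $\sqrt{v\cdot v + \delta^2}$ with
$\delta = 10^{-8}$ *in the derivative assembly only*, so that reference
geometries with vanishing dipole or gradient remain differentiable; the
property values themselves are plain norms (a symmetric molecule reports
exactly zero dipole).

*Gradient norm.* The frozen-density pairwise gradient is differentiated
once and twice more with respect to parameters; this brings in the density
responses contracted with mixed Cartesian–parameter integral derivatives
up to third order, all supplied analytically by the jet engine.

## The objective and its Hessians

$S = \sum_\alpha C_\alpha^2(\xi^{ref}_\alpha - \xi_\alpha)^2$ with default
weights 1 (kcal/mol)$^{-1}$, 10 eV$^{-1}$, 20 D$^{-1}$ and
0.5 mol·bohr/kcal.  The exact Hessian adds the residual-weighted property
second derivatives to the positive-semidefinite Gram term
$2\sum C^2 (\partial\xi)(\partial\xi)^T$; the Gram term alone is the
PM7-style approximant.  The modified Hessian replaces eigenvalues by their
absolute values, preserving eigenvectors while enforcing descent.
Non-converging molecules abort the objective (silent skipping would change
$S$ discontinuously during optimization).

### SCF robustness and the shape of the parameter surface

Parameter optimization explores regions far from physical parameter
values, where molecules can possess several SCF solutions.  If the SCF
always starts from one guess, the converged solution — and with it $S$ —
jumps discontinuously wherever the guess's basin boundary sweeps across
the parameter path.  The solver therefore converges from two deterministic
starts (core-Hamiltonian and spherically averaged atomic-superposition
densities) and keeps the lower-energy solution, anchoring the objective to
the lowest SCF branch.  Residual discontinuities at genuine branch
crossings remain a property of the physical model; trust-region steps that
cross such a wall uphill are simply rejected.  Within a branch, objective
values are reproducible to roughly the SCF convergence threshold
($10^{-9}$ eV), which sets a noise floor of order $10^{-7}$ on $S$; trust
radii that shrink to this scale indicate a valley floor rather than a
model failure.

## Optimizers

Three update schemes share the driver: the approximated line search
(normalized inverse-Hessian direction, step length minimizing the
linearized surrogate in closed form — the printed "argmax" has no finite
maximizer for a sum of squares, so the minimizer is implemented), the
trust-radius Hessian-descent step ($|d| = R_n$ along the Newton
direction), and the trust-region step solving
$d = -(B+\lambda I)^{-1}g$, $|d| \le R$ via the spectral shift (the
conventional stabilized sign; $\lambda \ge 0$ makes $B + \lambda I$
positive definite, with the hard case resolved on the boundary through an
explicit lowest-eigenvector component).  The radius update multiplies by
5/4 for $\rho > 0.8$ with a decrease, halves for $\rho < 0.25$ or any
increase, and is capped at $|d|_{max}$ (default 2); defaults are
$R_0 = 0.1$ for the trust region, 2.0 for Hessian descent, at most 300
iterations.  A trial point whose SCF fails counts as $S = +\infty$ (step
rejected); rejected ALS steps halve the step cap.  Accepted steps always
decrease $S$.

## Synthetic data and what the tests show

The fixture library holds ~29 small CHNOF molecules (including three
radicals) at literature-style geometries.  Reference data are generated by
the engine itself at a known parameter vector $p^\ast$ (the packaged
original MNDO values), optionally with Gaussian noise of realistic scale
(defaults chosen once: 1 kcal/mol on heats, 0.1 eV on ionization energies,
0.05 D on dipoles), so the objective has a known global minimum and
closed-loop parameter recovery can be tested without external data.
Reference-geometry terms use the gradient norm with target zero, exactly
as real parameterizations treat geometric data.

What this emulates well: the coupling structure of the objective, the
non-convexity of the surface, the near-unidentifiability of some
parameters (e.g. $\zeta_s$ of fluorine, whose curvature is orders of
magnitude below the dominant directions — matching the wildly unphysical
fluorine values that real reparameterizations of this model report).  What
it does not emulate: experimental error structure, the size and chemical
diversity of production training sets (a thousand-molecule set was used in
the original study), and geometry references from sources other than the
model itself.  Passing tests therefore validate the derivative machinery
and the optimizer contracts, not chemical accuracy.

A practical consequence of the genuine surface ruggedness: from a random
2% perturbation of all 37 parameters the trust-region optimizer with the
modified Hessian reliably drives $S$ down by three to five orders of
magnitude, but — exactly as the original study observed ("numerous local
minima with similar error function values"; three different starting
parameter sets ending at grossly different parameters with similar $S$;
identification of true minima "would require manual intervention") — it
settles into near-degenerate valleys rather than returning to the
generating point: long, almost flat directions are traversed at the
maximum step length with the quadratic model agreeing to four digits
while $S$ creeps downward, and the unidentifiable components (fluorine's
$\zeta_s$ and $\beta_s$ most prominently) drift far from $p^\ast$.  At
very small training sets the effect is extreme because the fit is
underdetermined outright (fewer weighted residuals than the 37
parameters).  Full closed-loop recovery of $p^\ast$ is therefore *not* a
property this surface grants a local second-order optimizer, and the
corresponding acceptance check documents that honestly rather than
asserting a pass.

## Problem sizes used by the automated checks

Chosen to keep the default suite fast while exercising every code path:
derivative validation uses a 10-molecule suite with all 37 first
derivatives checked against Richardson-extrapolated central differences
and a structured subset of second-derivative pairs covering every
parameter-class pair; the closed-loop recovery experiment runs the full
prescribed protocol on the first 8 fixture molecules with geometry terms
(the acceptance script adds a 0.5% perturbation variant probing the local
basin); the qualitative Gram-vs-modified Hessian comparison uses 40 noisy
entries built from the small-molecule subset (≤ 4 atoms) over 3 seeds.

## Known limitations

- Elements beyond CHNOF, d orbitals, and the PM7-corrected integral
  asymptotics are out of scope.
- Koopmans ionization energies and the point-multipole dipole are the
  standard semi-empirical approximations, not response properties.
- The geometry objective uses $|g|$ at the reference geometry; no internal
  geometry optimization is performed.
- Second derivatives of the gradient norm are assembled from the full
  analytic chain; they are the most expensive quantities in the package
  (mixed third-order integral derivatives), and dominate the cost of exact
  Hessians over training sets with geometry terms.
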