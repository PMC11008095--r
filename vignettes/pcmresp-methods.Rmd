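---
title: "Methods: electrostatic parametrization in continuum solvents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrostatic parametrization in continuum solvents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmresp)
```

## The problem

Fixed atomic charges fitted to gas-phase electrostatic potentials (ESPs)
transfer poorly to condensed-phase simulations: the molecular charge
distribution responds to its dielectric environment, and a parameter set
frozen in one medium misrepresents the ESP in another.  `pcmresp`
implements a parametrization scheme that derives atomic monopoles — and,
for polarizable Gaussian multipole (pGM) models, permanent bond-frame
dipoles — directly against ESPs computed in continuum solvents, with the
solvent's apparent surface charges entering the polarization equations as
static sources.  The same machinery quantifies how well a parameter set
fitted in one medium predicts the ESP in another (transfer RMSE/RRMSE),
and supports combined fits against two media at once.

## Models

Three model kinds are supported:

* **resp** — undamped point monopoles, no polarization.  The classic
  restrained ESP fit.
* **pgm-ind** — Gaussian monopoles plus induced point-of-response dipoles,
  all carried as spherical Gaussian densities of per-atom radius $R_i$.
* **pgm-perm** — pgm-ind plus *permanent* atomic dipoles expressed in the
  covalent-bond-vector (CBV) frame: one scalar coefficient per (atom,
  incident bond) slot, multiplying the unit vector toward the bonded
  neighbor.  Because the frame rotates with the molecule, the coefficients
  are conformation-local.

### Gaussian multipole electrostatics

Interactions between Gaussian densities are damped Coulomb interactions.
With the pair exponent $\beta_{ij} = 1/\sqrt{R_i^2+R_j^2}$ (a grid point
or point surface charge contributes $R_j = 0$) and reduced distance
$s=\beta_{ij} r$, the charge potential is $q\,\mathrm{erf}(s)/r$, and the
charge-field and dipole-tensor damping kernels are

$$f_e(s) = \mathrm{erf}(s) - \tfrac{2s}{\sqrt\pi} e^{-s^2},\qquad
  f_t(s) = \mathrm{erf}(s) - \tfrac{2s}{\sqrt\pi}
           \bigl(1+\tfrac{2s^2}{3}\bigr) e^{-s^2}.$$

These are the unique kernels consistent with the Gaussian-charge
potential: the field is its negative gradient ($q f_e/r^2$) and the
dipole tensor

$$T_{ij} = \frac{f_e}{r^3} I - \frac{3 f_t}{r^5} \, r r^T$$

is its negative Hessian.  The test suite enforces this by central
differences rather than trusting the closed forms.  Both kernels vanish
at contact — every quantity is finite everywhere, including at nuclei,
which is what prevents the polarization catastrophe of undamped
point-dipole models — and reach 1 in the far field, where all formulas
reduce to the familiar point-multipole ones.

**Sign convention** (global, used everywhere): the field at $i$ from a
dipole $p$ at $j$ is $-T_{ij}\,p$; the dipole–dipole interaction energy is
$p_i^T T_{ij} p_j$.

### Induced dipoles with surface charges

Induced dipoles solve the dense symmetric system $A\mu = E$, where $A$
has $\alpha_i^{-1} I$ diagonal blocks and $T_{ij}$ off-diagonal blocks,
and the static field collects three contributions,

$$E = C q + D p + C_s q_s,$$

from atomic monopoles, permanent dipoles, and — the distinguishing
ingredient — the continuum-solvent surface charges $q_s$, which are read
from the input (or produced by the synthetic generator) and stay fixed
during fitting.  Atoms with $\alpha_i=0$ are excluded from the system
rather than given infinite diagonal entries; no intramolecular exclusions
are applied (the model deliberately includes fields from bonded atoms).
The solve is a Cholesky factorization with a verified residual below
$10^{-10}\max(1,\|E\|_\infty)$.

### The fitting problem

The model ESP is affine in the parameters: stacking grid rows gives

$$V = \bigl(X + Y A^{-1} C\bigr) q + \bigl(Y + Y A^{-1} D\bigr) F\,p^{loc}
      + \underbrace{Y A^{-1} C_s q_s + S_{dir} q_s}_{\text{constant offset}},$$

with $X$/$Y$ the charge/dipole potential matrices, $F$ the CBV frame
matrix, and $S_{dir}$ the direct surface-charge potential.  Whether the
constant surface term is added to the model or subtracted from the target
is mathematically irrelevant (identical residuals); the implementation
carries it in the offset.  $A^{-1}$ is never formed explicitly — all
applications go through one Cholesky factorization per dataset.

The fit minimizes the weighted squared ESP residual plus the hyperbolic
restraint $a\sum_i(\sqrt{q_i^2+b^2}-b)$, subject to exact linear equality
constraints (total charge always; optional subset-charge constraints)
imposed via Lagrange multipliers.  Chemical equivalence is a parameter
*reduction*, not a penalty, so equivalenced parameters are bitwise equal.
The restraint is linearized and iterated to a fixed point in the standard
RESP manner (tolerance $10^{-8}$ e, at most 50 iterations), starting from
zero charges.  Rank-deficient constrained systems raise an error naming
the null-space dimension — deliberately collinear CBV columns (e.g. a
linear atom's two antiparallel slots) are reported, never silently
pseudo-inverted.

### Two-stage and dual-solvent protocols

Stage 1 fits everything (monopoles from zero, permanent dipoles from
zero) with equivalencing applied to all chemically equivalent atoms
except methyl/methylene groups.  Stage 2 refits only those groups, with
intra-group equivalencing, under a slightly stronger restraint
(`a_stage2`); all other parameters are frozen bitwise at their stage-1
values.  The rationale is rotational averaging: freely rotating groups
justify equivalencing their hydrogens without degrading the rest of the
fit.

Dual-solvent fits stack two media's design blocks exactly as
multi-conformation RESP stacks conformations, one parameter set fitted to
both.  The two dataset weights are normalized to sum to one, so fitting a
medium against a duplicate of itself reproduces the single-solvent fit
exactly, restraint included.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| restraint strength `a` (stage 1) | 5e-4 | a.u. | conventional RESP stage-1 value; paper-silent, documented as convention |
| restraint strength `a_stage2` | 1e-3 | a.u. | conventional stage-2 tightening |
| restraint tightness `b` | 0.1 | e | hyperbola width of the standard restraint |
| restraint scope | non-hydrogen | — | hydrogens conventionally unrestrained |
| grid shells | 1.4, 1.6, 1.8, 2.0 | × vdW radius | standard ESP-fitting shell construction |
| grid density | 6 | pts/Å² | standard ESP grid density |
| surface density | 5 | pts/Å² | conventional PCM cavity density |
| probe offset | 0.4 | Å | cavity at ≈1.2×vdW, the common PCM scaling |
| ESP point weights | 1 | — | no per-point weighting prescribed |
| restraint loop | tol 1e-8 e, max 50 | — | fixed-point control |

Permanent-dipole coefficients are unrestrained by default (configurable);
there is no published convention to follow.

## Units

Inputs are Angstrom and elementary charges; all electrostatics is
computed in Hartree atomic units with
1 Å = 1.889726124565062 Bohr.  ESP values and RMSEs are a.u.
(Hartree/e).  Molecular dipoles are reported in Debye with
1 e·Å = 4.803204 D.  For charged species the dipole origin is the
geometric center of the atoms (dipoles of ions are origin-dependent; the
convention is stated rather than hidden).

## Error metrics

RMSE is the weighted root-mean-square deviation between model and
reference ESP; RRMSE divides by the weighted root-mean-square of the
*reference* ESP.  Other programs use other denominators (mean absolute
potential, potential range), so percentages are not comparable across
conventions — this is flagged here prominently.  Transfer errors are the
same metrics evaluated with parameters from one medium against the ESP
data of another, after re-solving the induced dipoles in the *target*
medium's surface-charge environment: the polarization responds to the new
environment while $q$ and $p^{loc}$ are carried over.  Cross-medium
matrices report per-row, per-column and overall unweighted means, with
and without the gas phase.

## The synthetic data generator

No quantum-chemistry data ship with the package.  The generator builds a
complete, physically structured stand-in world:

* **Molecules** — templates (water-like bent triatomic with TIP3P-like
  charges, CO-like diatomic, alkane-like chain with two methyl ends, a
  seeded random heavy-atom chain) with Applequist-style polarizabilities
  (H 0.135, C 0.878, N 0.530, O 0.465 Å³) and covalent-scale Gaussian
  radii (H 0.4, C 0.8, N 0.75, O 0.7 Å).  Chosen once as
  field-plausible values; the paper-level data sets carry their own
  (external) parameters.
* **Grids** — Connolly-style union-of-spheres shells with deterministic
  Fibonacci coverings and a per-sphere budget of ⌈density × area⌉.
* **Surfaces** — a single solvent-accessible shell at vdW + probe, same
  covering, per-point area weights, and Gaussian radii chosen so each
  point's self-potential matches the COSMO diagonal
  $1.07\sqrt{4\pi/a}$.
* **Surface polarization** — a conductor-like screening model:
  $q_s = -\frac{\varepsilon-1}{\varepsilon} S^{-1}\Phi_{solute}$ with $S$
  the Gaussian-smoothed self-interaction matrix, iterated to $10^{-8}$
  self-consistency with the solute's induced dipoles.  Gauss's law
  ($\sum q_s \to -\frac{\varepsilon-1}{\varepsilon} Q$) is the built-in
  accuracy check.
* **Media** — gas (ε=1), diethyl ether (4.24), dichloroethane (10.125),
  acetone (20.493), water (78.3553).
* **Noise** — optional i.i.d. Gaussian noise on grid potentials; no
  correlated-noise model.

What the generator does *not* emulate: it is not IEF-PCM (no
dielectric-boundary integral operator, no York–Karplus smoothing, no
Lebedev grids, no SMD radii), the reference ESP is the forward model
itself rather than a quantum-mechanical density, and grid potentials
outside the cavity are strongly screened at high ε, so absolute RRMSE
magnitudes are not comparable to fits against real QM data.  A green
recovery or transferability test therefore establishes the correctness
and the *direction* of the physics (polarizable models transfer better
across media than fixed charges), not any dataset-specific percentage.

## Numerical and design choices

* Degenerate geometry (coincident interaction sites, zero-length bonds)
  raises errors; the dipole tensor at exactly coincident points is never
  needed by the fitting and is left undefined.
* Positive-definiteness of $A$ is checked (warning when violated, e.g.
  for unphysically close, highly polarizable atoms); the induced solve
  errors out on indefinite systems naming the offending eigenvalue bound.
* Equivalence groups are *inputs* (from the molecule file); no automatic
  symmetry perception.
* Surface-point Gaussian radii default to 0 (point charges) when a file
  does not provide them; the generator always provides the
  COSMO-consistent radii above.
* File formats are versioned plain text with declared units, parsed
  strictly (malformed lines are rejected with line numbers, never
  coerced); parameter files carry per-block provenance hashes so
  hand-edits are detected and named on verified reads.
* All tie-breaking is deterministic: Fibonacci coverings are seedless,
  and every stochastic step (random templates, noise) requires an
  explicit seed.

## Limitations

Quadrupoles and higher multipoles, periodic boundary conditions, energies
and forces for dynamics, and quantum-mechanics calculations are out of
scope.  Multi-molecule simultaneous fits beyond identical-geometry
dataset stacking are not supported.  The continuum stand-in is
conductor-like; fits against real IEF-PCM surface charges are supported
through the documented file format, not generated internally.
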