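---
title: "qmmd: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qmmd: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmd)
```

This vignette is the package's own account of the science it implements:
the energy model, the algorithms and their numerical conventions, the
parameters that matter, and — importantly — what the desk-scale synthetic
fixtures do and do not establish. Nothing stated here as an empirical
result goes beyond what the test suite and `scripts/acceptance.R` compute.

## 1. The additive QM/MM energy

The engine evaluates

$$E_\mathrm{tot} = E_\mathrm{QM} + E_\mathrm{MM} + E_\mathrm{QM/MM},
\qquad E_\mathrm{QM/MM} = E_\mathrm{ele} + E_\mathrm{vdW},$$

with electrostatic embedding: the MM point charges enter the one-electron
Hamiltonian of the QM region, so $E_\mathrm{ele}$ (charge–electron plus
charge–nucleus) is produced by the quantum calculation, while
$E_\mathrm{vdW}$ is the Lennard-Jones interaction between QM and MM atoms
evaluated classically. Both identities are asserted, exactly, on every
`qmmd_energy_report` the coupler produces. Bookkeeping choices a reader
should know:

* the charge–nucleus term is accounted inside $E_\mathrm{ele}$, not
  $E_\mathrm{QM}$;
* QM atoms keep their MM Lennard-Jones types for the QM–MM vdW term (their
  point charges are removed from the classical electrostatics, which the
  embedding replaces);
* bonded terms lying entirely inside the QM region are dropped from the MM
  sum; any bond, angle or torsion with at least one atom on each side of
  the boundary is kept and evaluated classically (boundary bonded terms);
* energies cross the interface in hartree and are converted once, with
  627.509474 kcal/mol per hartree (all conversion constants live in
  `qmmd_constants`).

## 2. Quantum core

**Integrals.** Contracted Cartesian Gaussians up to d functions
(components ordered xx, xy, xz, yy, yz, zz), McMurchie–Davidson Hermite
recursion with a Boys-function evaluator that switches from a damped
ascending series to the asymptotic form at $x = 35$ (the switch point is a
constant in `src/integrals.cpp`). Primitives are normalized at
construction and each contracted Cartesian component is normalized to unit
self-overlap, so the overlap diagonal is 1 by construction. Internally the
QM side works in atomic units with 1 Å = 1/0.52917721092 bohr; every file
interface is in Å.

**RHF.** Closed-shell Roothaan equations with a core-Hamiltonian guess.
Defaults (the reference program reports none): energy tolerance $10^{-8}$
hartree, density RMSD $10^{-6}$, at most 128 iterations, DIIS depth 8.
Convergence requires both tolerances. Two Fock-build routes exist behind
the same contract: a stored ERI tensor and a *direct* mode that recomputes
shell-quartet integrals every iteration; they agree to $10^{-9}$ hartree
(asserted). The orthogonalizer offers symmetric ($S^{-1/2}$) and Cholesky
back-ends, equivalent up to an orbital rotation. DIIS prunes the oldest
error vectors whenever the scaled error-overlap matrix becomes
ill-conditioned — with two-function bases the error space saturates after
a few iterations and near-singularity is the normal end-game, not a fault;
a genuinely singular system still falls back to the latest Fock matrix
with a warning. With DIIS disabled the solver runs damped Roothaan steps,
whose energy decreases monotonically (asserted).

**MP2 and CIS.** Canonical closed-shell MP2 over a four-quarter-transform
MO tensor; the transformation equals an $O(n^8)$ quadruple-loop oracle to
$10^{-10}$ (asserted). One caveat recorded here deliberately: the
*canonical* MP2 formula is invariant only under rotations within
degenerate orbital blocks, so the suite tests sign-flip invariance rather
than arbitrary occupied–occupied rotations. CIS builds the spin-adapted
singlet singles block only ($\dim = n_\mathrm{occ} n_\mathrm{virt}$; the
triplet block is excluded by construction) and diagonalizes it densely.

**CASCI.** Determinant basis (alpha/beta strings at fixed $M_s$), not
CSFs; spin purity is monitored via $\langle S^2\rangle$ computed per
state. The direct-CI sigma build uses the string factorization
$\sigma = \sum_{pq} h'_{pq} E_{pq} c + \tfrac12 \sum_{pq} E_{pq}
\sum_{rs} (pq|rs) E_{rs} c$ with sparse single-excitation tables, and
never materializes the Hamiltonian. An independent dense route
(Slater–Condon rules over spin-orbitals, alpha block first so that the
determinant phases match the string tables) exists purely as an oracle;
the two agree to $10^{-10}$ on every tested space. Davidson (diagonal
preconditioner, subspace collapse at 8 blocks) and LOBPCG (X/W/P blocks
with Rayleigh–Ritz) both converge each state to residual norms below
$10^{-6}$ and agree with dense LAPACK to $10^{-8}$ on random 200×200
matrices (asserted). Degenerate states are ordered by energy, then by the
index of the largest CI coefficient.

**SA-CASSCF.** Two-step optimization: CASCI at fixed orbitals alternates
with an orbital update from the state-averaged generalized Fock matrix
built with the SA 1- and 2-RDMs; a single orbital set serves all averaged
states. *Design deviation, recorded:* instead of a damped quasi-Newton
step with level shift, the update is a preconditioned steepest-descent
step (diagonal scaling $4|F_{nn}-F_{mm}|$, floored at 0.5) with a
backtracking line search that also greedily doubles the step while the SA
energy still drops — CASCI solves cost microseconds at desk scale, so
buying global convergence with extra energy evaluations is the simpler
robust choice. The SA energy history is monotonically non-increasing by
construction; convergence requires gradient max-norm $<10^{-5}$ and
energy change $<10^{-8}$ hartree within 100 macro-iterations, else an
error carrying the energy history. The rotation convention is
$C' = C\,e^{\kappa}$, under which $\partial E/\partial\kappa_{mn} =
2(F_{nm} - F_{mn})$; this sign was verified against finite differences of
the SA energy.

## 3. Boundary treatment

Cut bonds get a hydrogen link atom on the QM→MM bond axis at exactly
1.10 Å from the QM boundary atom (a fixed distance, so no extra degree of
freedom enters). The MM boundary atom and its MM-bonded neighbours are
excluded from the embedding charge set; their summed charge is
redistributed **uniformly** over the remaining MM atoms of the same
residue — the redistribution weighting is not specified by the reference
treatment, and uniform is the recorded choice. Total MM charge is
conserved to $10^{-12}$ e (property-tested on random topologies). If an
entire residue is excluded but its omitted charge is zero, redistribution
is a no-op; a nonzero orphaned charge is an error.

## 4. Forces

* MM forces are analytic throughout (bonds, angles, torsions, LJ, Coulomb,
  restraint) and match central finite differences to $10^{-5}$ relative on
  random configurations (asserted).
* QM-region nuclear forces are central finite differences of the followed
  state's embedded energy, displacement $10^{-3}$ Å by default — the
  gradient theory of the reference program is unstated, and FD keeps every
  post-HF method on the same footing. Link-atom forces are projected onto
  the two boundary atoms through the Jacobian of the placement rule.
* Forces on embedding charges use the frozen-density (Hellmann–Feynman)
  field of the converged state density plus the analytic nuclear Coulomb
  term. This is *exact* for variational wavefunctions (HF; the SA-CASSCF
  average) and an unrelaxed-density approximation for CIS/CASCI
  state-specific forces (no orbital response). Consequence: the
  force/energy consistency criterion is asserted at $10^{-4}$ relative on
  the HF fixture, where the treatment is exact; excited-state droplet
  dynamics carry the (standard, small) unrelaxed-density error.

## 5. Force field, droplet and dynamics conventions

* Electrostatic constant 332.0637128 kcal mol⁻¹ Å e⁻²; AMBER 1-4 scaling
  (ee ÷ 1.2, LJ ÷ 2), both configurable per topology.
* Harmonic terms use $k(x-x_0)^2$ *without* the ½ — including the droplet
  restraint $U = k\,\max(0,|r-c|-R)^2$ with $k = 100$ kcal/mol/Å² applied
  to water oxygens; the ½-vs-no-½ convention is not fixed by the source
  protocol, and this choice is recorded here and asserted in the tests.
* Nonbonded interactions are truncated atom-based at the cutoff (12 Å
  default), no switching function, no Ewald — appropriate for a
  non-periodic restrained droplet; the pair list is rebuilt every step by
  default.
* TIP3P is flexible here (OH bond 553 kcal/mol/Å² at 0.9572 Å, HOH angle
  100 kcal/mol/rad² at 104.52°) because no constraint algorithm is part of
  the model; at the 0.25 fs reference timestep the OH vibration is
  integrated with ~37 steps per period.
* Velocity Verlet; thermostat is plain velocity rescaling at a
  configurable interval (default 10 steps) — used for heating
  (linear target-temperature ramp) and equilibration; production runs are
  NVE unless configured otherwise. Trajectories are bitwise-deterministic
  given the seed, and each logged frame stores full-precision positions
  and velocities, which is the restart mechanism.
* Emission energies are vertical gaps $E_\mathrm{excited} -
  E_\mathrm{ground}$ per frame, converted with 27.211386 eV/hartree and
  1239.841984 eV·nm; histograms default to 10 nm bins.
* A note on integrator "drift": velocity Verlet shows a *bounded* energy
  oscillation of order $(\omega\,\Delta t)^2$ (about $4\times10^{-4}$
  relative at $\Delta t = T/100$ for a harmonic oscillator) and no secular
  trend; the suite therefore bounds the secular drift (difference of
  first- and last-window mean energies), which is what the symplectic
  property controls.

## 6. Parallel-efficiency metrics

`speedup`, `parallelization_ratio` (Amdahl) and `karp_flatt` implement
$S = T_1/T_N$, $P = \frac{N}{N-1}(1 - T_N/T_1)$ and
$f = \frac{1/S - 1/N}{1 - 1/N},\; P = 1-f$. The two $P$ routes coincide to
$10^{-12}$ when $S$ comes from the same timing pair (property-tested). The
reference row of a timing table is explicit — benchmark tables are not
always referenced to one core (the multireference-CI scaling analysis in
the source material uses a 2048-core reference) — and $N$ is the *core
multiple* relative to it. $P > 100\%$ is legal and flagged superlinear
(cache effects). Printed-value comparisons in the tests use ±0.01 in the
reported units, matching two-decimal rounding.

## 7. Synthetic fixtures: what a green test establishes

The generators in `R/fixtures.R` are pure functions of their seeds.

* `gen_water_sphere(radius, n_waters, solute, seed)` emulates the
  restrained-droplet setup: uniform random placement inside the sphere
  with O–O and solute clash rejection at 2.4 Å, random orientations,
  restraint centre at the solute's centre of mass. At the reference scale
  (15 Å, 449 waters around a 27-atom solute = 1374 atoms) it reproduces
  the atom counts; it does **not** reproduce an equilibrated liquid
  structure — no 10 ns relaxation is attempted, so droplet runs here probe
  machinery, not water thermodynamics.
* `gen_toy_chromophore()` is a 10-atom butadiene-like π system standing in
  for a real 27-atom chromophore, with CAS(4,4) as the natural active
  space; its MM topology is built so the generated geometry is a true
  local minimum (it is relaxed on its own force field at construction, and
  the per-atom gradient norm < 1 kcal/mol/Å is asserted).
* `gen_diatomic_solute()` (H₂) is the smallest QM solute; its CIS S₁ state
  is dissociative, which the 100-step excited-state demonstration handles
  with a rescaling thermostat.
* `gen_timing_table(f, t1, cores)` inverts Amdahl's law exactly, so the
  scaling report must recover $f$ to machine precision.

Hence: green tests establish *algorithmic correctness at desk scale*
(oracle equality, conservation laws, invariances, printed-value
reproduction of the parallel metrics) — they do not establish chemical
accuracy of the toy bases, the spectroscopy of the toy chromophore, or
paper-scale performance numbers, all of which are out of scope by design.

## 8. Known limitations

* Cartesian d components only (no f), no integral screening beyond the
  trivial, no density fitting — bases beyond ~30 functions get slow.
* RHF/closed-shell only; no UHF/ROHF, no DFT.
* CIS/CASCI state-specific forces omit orbital response (Section 4).
* No Ewald/PME, no constraint algorithms (SHAKE/SETTLE), no surface
  hopping — excited-state dynamics follow one adiabatic state index.
* The determinant CI basis means the CSF-count bookkeeping of
  internally-contracted or GUGA codes is not reproduced.
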