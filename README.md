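# qmmd — desk-scale QM/MM molecular dynamics in R

`qmmd` is a compact, fully self-contained hybrid quantum-mechanics /
molecular-mechanics (QM/MM) molecular-dynamics engine aimed at method
developers and teachers who want every ingredient of an on-the-fly
excited-state QM/MM simulation — integrals, SCF, multireference CI, force
field, coupling scheme, integrator — inspectable, testable, and small
enough to run on a laptop. It is not a production quantum-chemistry code;
it is the whole pipeline at toy scale, with the algorithms written out.

## The model

The total energy of a partitioned system is additive:

```
E_tot  = E_QM + E_MM + E_QM/MM,      E_QM/MM = E_ele + E_vdW
```

* **E_QM** — a Gaussian-basis quantum core: restricted Hartree–Fock with
  DIIS and direct-SCF Fock builds, MP2, CIS, determinant-based CASCI with
  direct-CI sigma builds (Davidson or LOBPCG eigensolvers), and two-step
  state-averaged CASSCF in which one orbital set is optimized for a
  weighted set of states. Integrals (overlap, kinetic, point-charge
  attraction, ERIs) are McMurchie–Davidson Hermite recursions over
  contracted Cartesian Gaussians up to d functions, implemented in C++.
* **E_ele** — electrostatic embedding: the MM point charges enter the QM
  one-electron Hamiltonian, so the wavefunction polarizes in the
  environment's field. Across covalent QM/MM boundaries a hydrogen link
  atom is placed on the cut-bond axis exactly 1.10 Å from the QM boundary
  atom, the MM boundary atom and its bonded MM neighbours are removed from
  the embedding set, and their omitted charge is redistributed over the
  rest of the residue (conserved to 1e-12 e).
* **E_MM, E_vdW** — an AMBER-functional-form force field (harmonic bonds
  and angles, periodic torsions, Lennard-Jones, Coulomb with atom-based
  cutoff truncation, AMBER 1-4 scaling), flexible TIP3P water, and a
  harmonic spherical droplet restraint `k·max(0, |r−c|−R)²`.
* **Dynamics** — velocity Verlet with Maxwell–Boltzmann initialization,
  optional linear heating with velocity rescaling, per-frame ground- and
  excited-state energies, and emission-energy analysis
  (`E_excited − E_ground`, histogrammed in nm).
* **Parallel metrics** — the speedup `S = T1/TN`, the Amdahl
  parallelization ratio `P = [N/(N−1)]·[1 − TN/T1]`, and the Karp–Flatt
  serial fraction `f = (1/S − 1/N)/(1 − 1/N)` with `P = 1 − f`, applied
  row-wise to timing tables with superlinear-speedup flagging.

## Worked example

A 100-step flavour of an excited-state droplet run: an H₂ solute treated
at HF+CIS following the S₁ state, solvated by 8 TIP3P waters in a 5 Å
restrained sphere.

```r
library(qmmd)

sol  <- gen_diatomic_solute()                      # H2 + MM parameters
ws   <- gen_water_sphere(radius = 5, n_waters = 8, solute = sol, seed = 4)
part <- build_partition(ws$topology, ws$qm_atoms)  # no covalent cuts here
qc   <- qm_config(method = "cis", basis = "toy-minimal",
                  state_index = 1, n_states = 2)

r <- total_energy_forces(ws$geometry$coords, ws$geometry, part, qc,
                         forces = FALSE)
r$report
#> <qmmd_energy_report (kcal/mol unless noted)>
#>   E_QM    =      -0.169921 hartree
#>   E_MM    =      -2.448727
#>   E_ele   =      -0.001000 hartree (-0.627524 kcal/mol)
#>   E_vdW   =      -0.111799
#>   E_QM/MM =      -0.739323
#>   E_tot   =    -109.815259
```

`E_QM` is the followed (S₁) state's embedded energy minus the
electrostatic coupling; `E_ele` is the charge–electron plus charge–nucleus
interaction with the redistributed water charges; the two identities above
hold exactly on every report. Propagating this backend:

```r
rs  <- spherical_restraint(ws$center, 5, 100, atoms = ws$water_oxygens)
bk  <- qmmm_backend(ws$geometry, part, qc, restraint = rs)
cfg <- md_config(timestep = 0.25, n_steps = 100, initial_temperature = 50,
                 thermostat = "rescale", rescale_interval = 5, seed = 3)
tr  <- run_md(ws$geometry$coords, ws$geometry$masses, bk, cfg)
emission_analysis(tr, bin_width_nm = 10)
```

logs ground/excited energies and the vertical emission (eV and nm) every
0.25 fs frame and histograms the wavelengths in 10 nm bins.

Parallel-efficiency analysis of a timing table (seconds; the reference row
is the 1-core measurement):

```r
tt <- timing_table(n_cpus = c(1, 1, 16), n_threads = c(1, 8, 8),
                   n_cores = c(1, 8, 128),
                   elapsed_time = c(16.676, 3.599, 1.444))
scaling_report(tt)
#>   n_cores elapsed_time core_multiple   speedup parallelization_ratio
#> 1       8        3.599             8  4.633509              89.62067
#> 2     128        1.444           128 11.548476              92.06007
#>   serial_fraction superlinear
#> 1      0.10379330       FALSE
#> 2      0.07939932       FALSE
```

A speedup of 4.63 on 8 cores corresponds to an Amdahl parallel fraction of
89.6 %; the 128-core row peaks at 92.06 %. `S > N` rows would be flagged
superlinear (cache effects).

There is also a small CLI (`cli_main()`), e.g.
`metrics --table timings.tsv`, `scf --geometry h2.xyz --basis toy-minimal`,
`md`/`qmmm-md --geometry ... --topology ... --config run.toml --out pre`,
and `genfix` for writing fixture inputs.

## Layout

* `R/` — geometry/basis handling, integrals interface, `scf`, `mointegrals`
  (MP2/CIS), `ci` (determinant CASCI, Davidson/LOBPCG), `casscf`, `mm`,
  `qmmm`, `dynamics`, `metrics`, `io`, `fixtures`.
* `src/integrals.cpp` — the Gaussian-integral kernels.
* `inst/extdata/` — two shipped toy basis sets (`toy-minimal`, `toy-dz`).
* `vignettes/qmmd-methods.Rmd` — the methods vignette: model, parameter
  choices, numerical conventions, and what the synthetic fixtures do and
  do not establish.
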