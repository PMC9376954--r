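# fibrilsim

Desk-scale toolkit for studying peptide fibrillation with a minimal
implicit-solvent coarse-grained model: two superatoms per residue (a
backbone bead B and a side-chain bead S) plus modified terminal caps
(TN, TC). The model carries no directional interactions — no hydrogen-bond
geometry, dipoles, or dihedrals — so the side-chain geometry (bond length
r0_BS, Lennard-Jones radius sigma_SS) is the knob that decides whether
chains assemble into amorphous aggregates, amyloid-glass, single- or
multi-ribbon fibrils, or annular (pore-like) structures. It is aimed at
people studying aggregation mechanisms with coarse-grained simulation who
want a self-contained, testable reference implementation of the model, its
structural descriptors, and its kinetic analysis.

The package provides four connected layers:

1. **Force field and topology** (`default_forcefield()`,
   `build_topology()`, `system_energy_forces()`): harmonic bonds
   (k_BB = 1250 kJ mol^-1 nm^-2, r0 = 0.35 nm; k_BS = 5000 with scanned
   r0_BS), cosine-harmonic angles (theta0_BBB = 150°, theta0_BBS = 105°,
   k = 1000 kJ/mol), pair-specific 12-6 Lennard-Jones with a purely
   repulsive r^-12 term between identical termini, and analytic forces
   (compiled, finite-difference-verified).
2. **Dynamics** (`run_dynamics()`, `minimize()`, `place_monomers()`):
   leapfrog Langevin integration at 15 fs / 303 K / tau = 0.17 ps with
   cubic periodic boundaries, plus steepest-descent + L-BFGS minimization.
3. **Structure analysis** (`find_clusters()`, `cn_parameter()`,
   `cbb_parameter()`, `classify_phase()`): 5.5 Å single-linkage
   clustering under minimum image, the end-to-end correlation

   C_n = (1 / M(M-1)) Σ_{i≠j} (n_i · n_j)²   (1 = parallel/antiparallel, 1/3 = random)

   and the backbone-backbone correlation C_BB (mean |cos| between
   shell-neighbor directions, shell 0.8-2.4 nm), with a (C_n, C_BB)-plane
   morphology classifier.
4. **Aggregation-fragmentation kinetics** (`solve_kinetics()`,
   `gillespie_ensemble()`, `master_equation_solve()`, `fit_kinetics()`):
   the reversible constant-kernel Smoluchowski model truncated at system
   size N,

   dc_i/dt = ½ Σ_{j+k=i} (k⁺_{jk} c_j c_k − k⁻_{jk} c_i) − Σ_{j≤N−i} (k⁺_{ij} c_i c_j − k⁻_{ij} c_{i+j})

   with the three-parameter rate rule k⁺_{ij} = q k⁺ and k⁻_{ij} = q k⁻
   when i or j = 1 (else k⁺, k⁻). The uniform channel ratio k⁺/k⁻
   preserves detailed balance, which the package verifies channel-wise.
   The exact Gillespie counterpart, an exact master-equation solver for
   N ≤ 10, and a global least-squares fitter returning a classed model
   object (`coef`, `predict`, `simulate`, `residuals`, `plot` methods)
   complete the layer.

## Worked example

Fit the three-parameter kinetic model to the averaged stochastic kinetics
of 72 monomers in a (35 nm)³ box:

```r
library(fibrilsim)

p <- kinetic_params(k_plus = 7.84, k_minus = 10.69e-5, q = 3.07,
                    N = 72, V = 35^3)
grid <- c(seq(0, 95, 5), seq(100, 975, 25), seq(1000, 12000, 100))

obs <- gillespie_ensemble(p, n_reps = 1000, sample_times = grid, seed = 42)
fit <- fit_kinetics(obs, kinetic_params(4, 5e-5, 2, N = 72, V = 35^3),
                    multi_start = 3, seed = 7)
fit
#> Three-parameter aggregation-fragmentation kinetic fit
#>   k+ = 7.519 nm^3/ns, k- = 0.0001107 ns^-1 (11.07 x 1e-5), q = 3.144
#>   cost (sum of squares) = 1.76 over 167 time points; converged
```

The fitted aggregation rate k⁺, fragmentation rate k⁻, and monomer factor
q land within a few percent of the generating values; the residual bias is
the mean-field error of the Smoluchowski closure at N = 72. A structural
companion in three lines:

```r
ff  <- default_forcefield(sigma_SS = 0.41, r0_BS = 0.55)
top <- build_topology(8, 10)
rib <- make_fixture("parallel_ribbon", n_chains = 10, ff = ff)
cn_parameter(end_to_end_units(rib, top))
#> [1] 1
classify_phase(1, as.numeric(cbb_parameter(rib, top)))
#> [1] "single-ribbon"
```

A command-line front end (`inst/cli/pepsim.R`) exposes the same pipeline
as subcommands (`fixture`, `simulate`, `clusters`, `order`, `ssa`,
`odefit`, ...); run it with `Rscript` and no arguments for usage.

## Layout

```
R/            force field, topology, engine wrappers, dynamics, clustering,
              order parameters, kinetics, fitter, fixtures, GRO/XYZ IO, config
src/          compiled energy/force kernel, Langevin leapfrog, contact scan
tests/        testthat suite (unit, property-based, acceptance)
scripts/      acceptance.R
vignettes/    model-and-kinetics.Rmd — the methods notes
inst/cli/     pepsim.R command-line front end
```
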