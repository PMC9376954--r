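---
title: "A minimal two-bead peptide model: force field, dynamics, order parameters, and aggregation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal two-bead peptide model: force field, dynamics, order parameters, and aggregation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsim)
```

## The model

`fibrilsim` implements an implicit-solvent coarse-grained peptide model in
which each residue is represented by two superatoms — a backbone bead `B`
and a side-chain bead `S` — plus two modified terminal caps (`TN`, `TC`)
at the chain ends. The model deliberately contains **no** directional
terms: no hydrogen-bond geometry, no dipoles, no dihedrals, no secondary
structure bias. Its point is that side-chain *geometry* alone (the
backbone-side-chain bond length `r0_BS` and the side-chain size
`sigma_SS`) decides whether chains aggregate into amorphous blobs,
glass-like assemblies with only local order, fibrillar ribbons, or closed
annular (pore-like) structures.

### Potential terms

* **Bonds** are harmonic, `V = k/2 (r - r0)^2`, with MARTINI-scale
  constants: `k_BB = k_BT = 1250` kJ mol^-1 nm^-2 at `r0 = 0.35` nm, and a
  stiff side-chain bond `k_BS = 5000` kJ mol^-1 nm^-2 whose equilibrium
  length `r0_BS` is one of the two scan parameters (0.40-0.70 nm).
* **Angles** are cosine-harmonic, `V = k/2 (cos t - cos t0)^2` with
  `k = 1000` kJ/mol, `t0_BBB = 150` degrees along the backbone and
  `t0_BBS = 105` degrees for backbone-side-chain angles. The two values
  are geometrically consistent: at a 150-degree backbone bend the exterior
  bisector makes exactly (360 - 150)/2 = 105 degrees with both backbone
  bonds, so a planar zigzag with exterior side chains is the exact bonded
  minimum. This is what `place_monomers()` builds and what bonded-only
  minimization recovers. A harmonic-in-angle form is available as a
  configuration switch.
* **Nonbonded** interactions are 12-6 Lennard-Jones with pair-specific
  parameters: the backbone-backbone attraction is strongest
  (`eps_BB = 4.5` kJ/mol, `sigma_BB = 0.47` nm), side chains are weak
  (`eps_SS = 1.0`, `sigma_SS` scanned over 0.37-0.45 nm), and opposite
  termini attract strongly (`eps = 4.0`) while *identical* termini repel
  through a purely repulsive `4 eps (sigma/r)^12` term — an isotropic
  stand-in for the like-charge repulsion of charged ends. Exclusions cover
  exactly the bonded pairs; 1-3 pairs interact.

### Choices the protocol leaves open

Several numerical details are not fixed by the model definition; the
package adopts explicit defaults, all tagged `"assumption"` in
`run_config()` and listed by `show_assumptions()`:

* `sigma_BS` combination rule: arithmetic mean `(sigma_BB + sigma_SS)/2`
  (geometric mean available). The combination affects only the B-S
  cross-interaction.
* Nonbonded truncation: 1.2 nm cutoff with the potential shifted to zero
  there, the common choice at this resolution; raw untruncated forms stay
  available (`lj_pair_energy()`, `replj_pair_energy()`) for analysis.
* Bead mass: 72 amu for every bead (four heavy atoms at MARTINI
  granularity). Masses only set the time scale of the dynamics, not the
  equilibrium structure.
* Terminus repulsion: the `r^-12`-only term; a WCA (cut-shifted at
  `2^(1/6) sigma`) variant is a switch.
* Placement floor: 0.5 nm between beads of different chains at insertion.

## Dynamics

`run_dynamics()` integrates Langevin dynamics with a leapfrog scheme:
deterministic kick `v <- v + F/m dt`, an exact Ornstein-Uhlenbeck velocity
update `v <- a v + sqrt((1 - a^2) kB T/m) xi` with `a = exp(-dt/tau)`
(fluctuation-dissipation matched, so the friction step *is* the
thermostat), then drift `x <- x + v dt`. The protocol defaults are 15 fs
steps, 303 K, `tau = 0.17` ps (the "inverse friction coefficient", read as
the GROMACS-style time constant with per-bead friction `gamma = m/tau`),
and a 35 nm cubic box with periodic boundaries. With `tau = Inf` the
scheme reduces to plain symplectic leapfrog; the tests verify energy
conservation to 0.1% over 1e4 steps in that limit, equipartition at 303 K
for free beads, and bit-reproducibility under a fixed seed. Velocities are
stored at half steps (leapfrog convention); the conserved-energy check
therefore pairs the on-step potential with the average of adjacent
half-step kinetic energies.

Coordinates are stored unwrapped; every distance computation (bonds,
angles, nonbonded terms, cluster contacts, order parameters) applies the
minimum-image convention, and `wrap_frame()` exists for export.

The minimizer runs steepest descent with a backtracking line search,
followed by an L-BFGS polish with the analytic gradient: steepest descent
alone converges only linearly on the stiff `k_BS = 5000` bonds, and the
quasi-Newton stage is what reaches force norms of 1e-5 kJ mol^-1 nm^-1 in
well under a second for a single chain.

## Cluster analysis and order parameters

A peptide belongs to a cluster when **any** of its beads (side chains and
terminal caps included — the contact rule is deliberately bead-agnostic,
and this inclusion is configurable in spirit via the cutoff) lies within
5.5 Å of a bead of another cluster member; clusters are connected
components of that contact graph (single linkage). The compiled pair scan
is checked against a brute-force R union-find oracle in the tests.

Two cluster-level descriptors classify morphology:

* `cn_parameter()`, the end-to-end correlation
  `C_n = 1/(M(M-1)) sum_{i != j} (n_i . n_j)^2` over normalized backbone
  end-to-end vectors. It is exactly 1 for parallel *or* antiparallel
  alignment (the squared dot product is blind to the flip, matching the
  antiparallel-pair motif of fibrils) and has expectation 1/3 for
  independent random orientations — the two limiting values the
  implementation is validated against. A nematic Q-tensor variant is
  available via `method = "qtensor"`.
* `cbb_parameter()`, the backbone-backbone correlation: for each peptide,
  neighbors are peptides whose backbone mass centers fall in the
  0.8-2.4 nm shell; over all pairs of neighbor directions the absolute
  cosine is averaged, and the result is averaged over peptides with at
  least two neighbors. A collinear lattice of centers scores 1 (a
  single laminated ribbon), orthogonal neighbor directions score 0.
  The absolute-value (rather than squared) cosine is the package's
  reconstruction choice; it preserves the collinear -> 1 / orthogonal -> 0
  limits that define the descriptor.

`classify_phase()` maps the `(C_n, C_BB)` plane to the four morphology
labels. The default thresholds in `phase_boundaries()` are **fitted to the
package's own geometric fixtures, not measured from any published data**
(the provenance string says so): `C_BB >= 0.8` reads single-ribbon,
`C_n >= 0.6` with `C_BB >= 0.5` multi-ribbon/annular, moderate values of
either descriptor amyloid-glass, the rest amorphous. Boundary ties resolve
toward the more ordered label, and classification is explicitly
boundary-set-dependent: users comparing against their own simulations
should calibrate the thresholds on reference structures.

## Aggregation-fragmentation kinetics

The kinetic observables are the numbers of free monomers `n1`, dimers
`n2`, trimers `n3`, and the total cluster count `n_c = sum_i n_i`
(monomers included). Their evolution is modeled by reversible
constant-kernel Smoluchowski equations truncated at the system size `N`
(the box is finite and closed — no channels beyond size `N`):

```
dc_i/dt = 1/2 sum_{j+k=i} (k+_{jk} c_j c_k  -  k-_{jk} c_i)
        - sum_{j=1}^{N-i} (k+_{ij} c_i c_j  -  k-_{ij} c_{i+j})
```

with the three-parameter rate rule `k+_{ij} = q k+`, `k-_{ij} = q k-`
whenever `i` or `j` is 1 (monomers attach and detach faster by the common
factor `q`), else `k+`, `k-`.

Two conventions deserve an explicit statement because they are easy to get
inconsistent:

* **Equal-size pairing.** The number of (i, i) pairs is `c_i^2/2`, so the
  aggregation flux of an equal-size channel carries the 1/2, and an
  `i + i` event consumes two `i`-clusters (the `(1 + delta)` stoichiometric
  factors of `2C_i -> C_2i` and `C_2i -> 2C_i` are built into the
  symmetric form above).
* **Equal-split fragmentation.** The event flux of the `i -> (j, j)`
  channel is `k-_{jj} c_i / 2`, mirroring the pairing factor on the
  forward side. This is not cosmetic: it is exactly what makes every
  channel's forward/backward ratio the same `k+/k-` and hence preserves
  detailed balance. With an un-halved equal-split rate, channels `(j, j)`
  would demand `c_{2j}/c_j^2 = k+/(2 k-)` while unequal channels demand
  `k+/k-`, no product-form equilibrium would exist, and the stationary
  state would carry circulating fluxes. The package uses the
  detailed-balance-preserving convention in the ODE, the Gillespie
  propensities, and the master equation alike, and
  `detailed_balance_residuals()` verifies channel-wise balance to 1e-8
  on stationary states. The analytic equilibrium
  `c_i = (k+/k-)^(i-1) c_1^i` (independent of `q`) is exposed as
  `equilibrium_state()` and used as a cross-check.

The stochastic counterpart (`gillespie_run()`, `gillespie_ensemble()`)
simulates the exact jump process with propensities
`k+_{ij} m_i m_j / V` (`i != j`), `k+_{ii} m_i (m_i - 1)/(2V)`, and
`k-_{jk} m_i / (1 + delta_{jk})` per unordered split channel; mass
`sum i m_i` is conserved exactly at every event. For `N <= 10` the master
equation over all integer partitions is solved exactly
(`master_equation_solve()`, 42 states at `N = 10`) and serves as the
independent oracle for the SSA means; at `N = 72` the mean-field ODE and
the SSA ensemble mean agree to a few percent, the finite-size error the
mean-field closure is expected to carry at this system size.

### Fitting

`fit_kinetics()` minimizes the plain sum of squared differences between
the model's four curves and observed curves over every time point, equal
weights per curve and point by default (configurable via `weights`). The
optimizer is Nelder-Mead on `log(k+, k-, q)` — positivity by
parameterization, no gradients of the ODE solution needed — restarted
from `multi_start` log-normally perturbed guesses. The result is a classed
`smol_fit` object with `print`, `summary`, `coef`, `predict`,
`residuals`, `simulate` (Gillespie at the fitted parameters), and `plot`
methods. On noiseless model-generated curves the fit recovers the
generating parameters to better than 0.1%; on means of 1000 stochastic
realizations at the reference parameter set
(`k+ = 7.84` nm^3/ns, `k- = 10.69e-5` ns^-1, `q = 3.07`, `N = 72`,
`V = 35^3` nm^3) all three parameters come back within ~5%, the residual
bias being the mean-field error noted above. Fragmentation is the
weakest-identified parameter: it is constrained mainly by the late-time
plateau of `n_c` and the small stationary monomer/dimer populations, so
its recovery is the most variable of the three.

## What the synthetic fixtures do and do not show

All test configurations are generated programmatically
(`make_fixture()`): a random orientation gas, a parallel ribbon lattice,
an antiparallel pair, an annular ring, and a dense amorphous blob. Each
asserts its declared geometric property at generation time. These
fixtures pin the *limiting values* and invariances of every descriptor
and the correctness of every algorithmic component; they do not emulate
thermalized aggregate geometry (thermal disorder, fibril twist, surface
roughness). Passing tests therefore certify the machinery — not that any
particular `(sigma_SS, r0_BS)` pair will fibrillate in a production run,
which is a question for actual simulation campaigns at scales this
package deliberately keeps out of its test budget.

## Numerical choices and problem sizes

* ODE integration: `deSolve::lsoda` (stiff-capable), `rtol = 1e-8`,
  `atol = 1e-12` for reported solutions; `1e-7/1e-10` inside the fit
  objective where thousands of solves occur. Mass conservation is checked
  against `1e-6 N` after every solve.
* The fit grid for the reference experiments is dense early (5 ns steps
  while monomers decay, ~25 ns through the oligomer regime) and coarse
  late (100 ns), 167 points to 12 us.
* Test-suite problem sizes are chosen for a laptop-class budget: 1000-run
  ensembles at `N = 72` for parameter recovery, 4000-run ensembles at
  `N = 8` against the exact master equation (the 3-standard-error
  criterion scales with the ensemble size, so a larger ensemble tests the
  same property more stringently, not differently), a few hundred
  thousand MD steps for the aggregation smoke test at elevated density
  (8 chains in a 10 nm box rather than 72 in 35 nm, trading realism for a
  collision time short enough to observe).
* Minimization tolerance: max force component below `1e-4` kJ mol^-1
  nm^-1 by default (`1e-5` in the geometry-recovery checks); at that
  level bond lengths and angles are reproduced to six figures.
* Degenerate inputs: zero-length end-to-end vectors, clusters without two
  shell neighbors, `M < 2` order parameters, empty ensembles, and
  non-partition initial counts are all rejected or flagged (`NA` with a
  warning) rather than silently computed.

## Known limitations

* No electrostatics, dihedrals, or directional interactions — by design;
  the model's scientific point is that fibrillation survives their
  absence.
* The mean-field ODE inherits a few-percent finite-size bias at `N = 72`;
  fitted rate constants absorb it.
* The brute-force nonbonded pair scan is quadratic in bead count; it is
  sized for desk-scale systems (up to a few thousand beads), not
  production campaigns.
* GRO/XYZ output rounds to the dialects' printed precision (0.001 nm /
  1e-6 nm); round-trips are exact only to that precision.
* The phase boundaries ship as fixture-calibrated defaults and must be
  re-calibrated for quantitative use on real trajectories.
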