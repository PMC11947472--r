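# cellmatch

Simulation of cell matching at a one-dimensional tissue–tissue interface,
modelled on the two contralateral cardioblast rows that align to form the
embryonic *Drosophila* heart tube. The package is for tissue biophysicists
and developmental biologists who want to ask how far short-range,
type-specific adhesion energies — competing with cell compressibility under
mechanical noise — can go in aligning two rows of cells, without cell
rearrangements or long-range signalling.

## The model

Each row is a line of `N` cells; cell `i` spans vertices `(x[i], x[i+1])`,
and the rows' end vertices are pinned together. Two complementary
simulators evolve this geometry:

* **Equilibrium Metropolis model.** Energy
  `E = Σ K (L_i − L0_i)² − Σ_segments ε · length`, where interface segments
  are typed `SS`, `TT` or `ST` by the facing cell pair and
  `ε ∈ {ε_SS, ε_TT, ε_ST}` (favorable-adhesion sign convention). Vertices
  take Gaussian proposal steps (`δX = 0.05` µm), cell flips are forbidden,
  and moves are accepted with probability `min(1, exp(−ΔE/E0))` at
  effective temperature `E0 = 0.1 K`. The steady-state tissue mismatch is
  governed by a single order parameter
  `γ = ((ε_TT − ε_ST) + (ε_SS − ε_ST)) / K` (µm).
* **Overdamped vertex dynamics.** `ξ dx/dt = (T_right − T_left) +
  K log(L_right/L0_right) − K log(L_left/L0_left)`, with per-interface-type
  tensions (negative tension extends a contact; canonical family
  `T_SS = T_TT = −t0`, `T_ST = 0`), explicit Euler at `dt = 0.01` min.

The readout is the **mismatch ratio**: the fraction of a cell's length not
overlapping its sister (same index, opposite row), averaged over sister
pairs — 0 for perfect alignment, 1 for none.

The experiment layer replicates everything over ensembles of simulated
embryos: size scaling of the no-adhesion mismatch, γ sweeps and the
collapse of different `ε` triples at equal γ, spatial mismatch profiles
over the `TTTTSS` pattern, effective-temperature sweeps, genotype → γ
mapping with inverse inference from the master curve, cell-specification
defect studies, and stiffness sweeps in the dynamic model.

## Worked example

```r
library(cellmatch)

set.seed(1)
labels <- make_pattern("TTTTSS", 52)      # 36 T + 16 S cells
cfg <- deposit_rows(labels, labels)       # random sequential deposition
tissue_mismatch(cfg)
#> [1] 0.2404832

p <- params_for_gamma(2, K = 1)           # eps_SS = eps_TT = 1, eps_ST = 0
traj <- run_metropolis(cfg, p, mcmc_settings())
traj
#> <mcmc_trajectory> 510000 proposals (converged), acceptance 0.888, final mismatch 0.1285
steady_state_mismatch(traj)$mean
#> [1] 0.113642

tr <- run_dynamics(cfg, vertex_params(t0 = 2000, K = 100, t_end = 600))
tail(tr$mismatch, 1)
#> [1] 0.07704577
```

The deposited geometry starts at mismatch ≈ 0.24 (pure geometric disorder,
no adhesion). Equilibrating at γ = 2 µm pulls it down to ≈ 0.11; the
deterministic vertex model at large tension reaches the geometry-limited
plateau ≈ 0.077 for the same starting configuration. Ensembles are
reproducible bit-for-bit from a master seed:

```r
sweep_gamma(c(0, 0.5, 1, 2), n_replicates = 30, master_seed = 1)
```

A thin command-line front end over the same functions lives in
`inst/cli/cellmatch.R` (subcommands `equilibrate`, `dynamics`,
`sweep-gamma`, `sweep-size`, `sweep-temperature`, `genotype`,
`sweep-stiffness`), driven by a YAML config (`load_config()` documents the
keys).

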