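---
title: "Energy-based modelling of cell matching at a 1D tissue interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based modelling of cell matching at a 1D tissue interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellmatch)
```

## The problem

During the closure of the embryonic *Drosophila* heart, two contralateral
rows of cardioblasts meet at a midline and each cell must align with its
designated partner ("sister") on the opposing row. The rows carry a
repeating pattern of two cell types — Tin-positive (T) and Svp-positive (S)
cardioblasts, in blocks of four and two — which express different adhesion
molecules (Fas3 high in T cells, Ten-m high in S cells). `cellmatch` asks a
narrowly-posed biophysical question: are short-range, type-specific
interfacial energies, competing with cell deformability under mechanical
noise, sufficient to align the two rows?

The tissue is reduced to its essential geometry: each row is a line of `N`
cells, cell `i` being the interval between vertices `x[i]` and `x[i+1]`.
The first and last vertices of the two rows coincide and are pinned
(the tissue ends are assumed aligned and confined), so total row length is
conserved exactly. The *mismatch* of a cell is the fraction of its length
not overlapping its sister (same index, other row); a column's value is the
mean of its two sisters', and the *tissue mismatch* averages the columns:
0 is perfect matching, 1 none.

## The equilibrium model

Each cell has a rest length `L0` and elastic energy `K (L - L0)^2`; each
interface segment (obtained by merging and sorting the two rows' vertices)
contributes adhesion energy `-eps * length`, with `eps` in
`{eps_SS, eps_TT, eps_ST}` by the types of the two cells covering the
segment. We use the favorable-adhesion sign convention (larger `eps`
rewards contact; some formulations write the same energy with the opposite
sign on `eps`). Configurations are sampled by a Metropolis chain: a uniform
choice among the `2(N-1)` interior vertices, a Gaussian displacement of
standard deviation `deltaX`, rejection of moves that would flip a cell or
overlap cells within a row, and acceptance probability
`min(1, exp(-dE/E0))`. `E0` is an effective temperature summarising
filopodia-driven mechanical fluctuations: the assumption is that
cell-cell contact dynamics are fast relative to alignment, so the
late, local phase of matching behaves as an equilibrium system.

Defaults follow the modelled system: `deltaX = 0.05` um, `E0 = 0.1 * K`
(i.e. `E0/K = 0.1` um^2). Energies are in arbitrary units; only the ratios
`eps/K` (um) and `E0/K` (um^2) matter.

The single control parameter is

```
gamma = ((eps_TT - eps_ST) + (eps_SS - eps_ST)) / K    [um]
```

the typical length change that the adhesion *differences* can impose on one
cell against its compressibility. Steady-state mismatch is a function of
gamma alone (different `eps` triples with equal gamma collapse onto one
curve), decreasing from the no-adhesion level to a plateau set by the
residual geometric disorder inside same-type blocks.

```{r, eval = FALSE}
set.seed(1)
cfg <- deposit_rows(make_pattern("TTTTSS", 52))
traj <- run_metropolis(cfg, params_for_gamma(1), mcmc_settings())
steady_state_mismatch(traj)
```

## The dynamic vertex model

The same geometry evolved in time: each interior vertex moves with velocity
`F / xi`, where `F` combines the interfacial tensions of the two segments
flanking the vertex (negative tension extends a favorable contact; the
canonical family is `T_SS = T_TT = -t0`, `T_ST = 0`) with logarithmic
elastic forces `K log(L/L0)` of its two cells. The logarithmic form matches
`K (L - L0)` for small deformations and avoids artifacts at large
compression. Integration is explicit Euler, `dt = 0.01` min, synchronous
updates, fully deterministic. Tensions and `K` are in pN, `xi` in
pN·min/um.

The printed force law of this class of models is ambiguous about which
segment's tension acts at a vertex when the two rows' breakpoints
interleave; we resolve it by typing the two segments immediately flanking
the vertex along the shared midline, each by (own-row cell on that side,
opposing-row cell covering that side). This reduces to the usual
`T[i+1] - T[i]` difference when breakpoints coincide and gives negative
tensions their intended contact-extending effect.

## The synthetic-geometry generator

All inputs are generated. Rest lengths are sampled per cell from
type-specific Gaussians, truncated positive by redrawing (clipping would
put an atom at zero length). The published distributions for the heart
exist only graphically, so the package defaults are stated placeholders,
chosen to be realistic rather than canonical: T cells 4 um mean with 10%
CV, S cells 6 um mean with 20% CV (S-type geometric variability exceeds
T-type, which is what inverts the spatial mismatch pattern at small gamma).
Rows are built by random sequential deposition: row 1 is laid end-to-end
once; row 2 is resampled until its total length matches row 1 within
`mu * 1e-3` (`mu` the smaller type-mean in the configuration), then
uniformly rescaled so the pinned ends coincide exactly. Cells start at
their rest lengths, and rest lengths are held fixed for the whole run.

What the generator does *not* emulate: measured (non-Gaussian) length
distributions, correlations between neighbouring cell sizes, cell-number
differences between the rows, migration before contact, and any 2D/3D
geometry. Tests passing under this generator validate the mechanism and
the implementation, not quantitative agreement with measured hearts.

## Numerical choices

- **Incremental energies.** A vertex move can only change its two flanking
  cells and the interface segments inside the window between its
  neighbours; the sampler recomputes exactly that window. A full-recompute
  reference implementation exists and the suite holds the two routes
  together to 1e-9 relative error.
- **Steady state.** The chain stops early when the OLS slope of the
  recorded mismatch over a 1000-record window falls below 1e-6 per record
  (records default to one sweep, `2(N-1)` proposals), with a hard cap of
  2e6 proposals for N = 52. The steady-state mean uses the trailing half of
  the records with an autocorrelation-corrected SEM.
- **Boundary cases.** A move to exactly zero cell length is allowed (the
  forbidden set uses strict inequalities); a transiently zero-length cell
  takes the limiting mismatch value 1 (its overlap is necessarily zero).
  In the vertex model a step that would push a cell below 1e-6 um is
  clamped to half the available slack, and a step larger than both
  adjacent cells aborts with advice to reduce `dt` (first-order
  convergence was checked by halving `dt`).
- **Replicates and seeds.** Ensembles default to 30 simulated embryos;
  replicate `k` derives its seed as `master_seed + k - 1` and uses a
  single RNG stream for geometry and chain, making every ensemble
  bit-reproducible from the master seed.
- **Gamma inference.** The master curve is regularized by an isotonic
  (non-increasing) fit before inversion; measured mismatch above the
  gamma = 0 level clamps to 0, values below the plateau return the largest
  grid gamma as a lower bound — on the flat part of the curve only a bound
  is identifiable.
- **Problem sizes.** The shipped tests use N = 52 with 30 replicates for
  ensemble claims, 1e6-proposal chains for sampling-accuracy checks
  against an exactly enumerated 2-cell Boltzmann law, and 600-min horizons
  for the vertex model; these sizes resolve every asserted effect at its
  stated tolerance.

## Design choices where the design was open

- **Cross-model comparison.** The vertex model is noiseless, so when its
  endpoint is compared with the equilibrium model at matched gamma
  (`gamma = 2 t0 / K`), the equilibrium chain is run near its
  zero-temperature limit (`E0 = 0.01 K`). At the default `E0/K = 0.1` the
  equilibrium plateau carries a small thermal excess (~0.007 mismatch at
  gamma = 20) above the deterministic endpoint; the two agree as
  `E0 -> 0`.
- **Stiffness optimality.** The three regimes of the stiffness sweep
  (stiff tissues stall near their initial mismatch, soft tissues relax too
  slowly for a ~1 h developmental window, intermediate stiffness aligns
  best) separate cleanly on a `K in {1, 1e2, 1e4}` grid for small
  homotypic tension and moderate friction (`t0 = 10`, `xi = 100`); at
  large `t0` even very stiff tissues realign, because the per-cell
  deformation `t0 L / K` accumulates along the row as chain tension.
- **High-gamma reference.** "High gamma" claims (block-limited interior
  mismatch) are evaluated at gamma = 20, deep in the plateau; at
  moderate gamma (e.g. 2) thermal boundary wander still contributes to
  within-block mismatch.
- **Pattern truncation.** 52 is not a multiple of 6; the TTTTSS unit is
  tiled from the left and truncated, giving 36 T and 16 S cells. Spatial
  profiles use only complete units; tissue averages use all cells.
- **Sister pairing in defect studies.** When the two rows carry different
  type patterns (cell-specification defects), pairing stays by index and
  the additional readout is the alignment offset of type boundaries,
  matched in order across the rows.

## Limitations

The model is strictly one-dimensional and conserves nothing but row
length: no cell volumes, no neighbour exchanges, no long-range structures
spanning multiple cells, no viscoelastic relaxation of rest lengths, and
no active noise in the dynamic model. The equilibrium assumption holds
only for the final, local adjustment phase of matching, not for the
preceding directed-migration phase. Quantities quoted in micrometres
depend on the placeholder rest-length distributions; users with measured
leading-edge lengths should supply them (`config_from_lengths_csv()` or
`length_params()`) before interpreting absolute gamma values.
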