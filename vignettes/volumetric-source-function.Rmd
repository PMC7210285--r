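---
title: "The volumetric source function: method, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The volumetric source function: method, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volsource)
```

## The problem

Hydrogen bonds carry a bond critical point (BCP), so the source function —
which decomposes the electron density at a point into contributions from
QTAIM atomic basins — tells you directly which atoms build the contact. Van
der Waals interactions do not: they are non-directional, diffuse, and carry
no single well-defined critical point. `volsource` implements the volumetric
extension of the source function: instead of a point, the reference object is
a *volume* — the region that reduced-density-gradient (NCI) analysis marks as
a vdW contact — and the source function is integrated over it by Monte Carlo,
giving each atom's electron contribution to the contact.

## The method, stage by stage

**1. Derivative fields.** From a density $\rho(\mathbf r)$ on a grid (a
Gaussian cube file, or a built-in analytic model), the package computes by
finite differences the gradient, Hessian, Laplacian, the ordered Hessian
eigenvalues $\lambda_1 \le \lambda_2 \le \lambda_3$, and the reduced density
gradient

$$ s(\mathbf r) = \frac{|\nabla\rho|}{2(3\pi^2)^{1/3}\rho^{4/3}}, $$

the dimensionless measure of deviation from a homogeneous electron gas.
$s \to 0$ marks bonding and non-bonded contact regions; the sign of
$\lambda_2$ separates attraction from repulsion, with
$\rho\,\mathrm{sign}(\lambda_2)$ in $[-0.02, +0.02]$ a.u. conventionally
labelled van der Waals.

**2. The vdW volume.** A voxel enters $V_{vdW}$ when
$s \le s_{iso}$ (default $0.5$, the midpoint of the customary
$0.45$–$0.55$ range for computed densities), $10^{-6} \le \rho \le 10^{-3}$
e/bohr$^3$, and $|\rho\,\mathrm{sign}(\lambda_2)| \le 0.02$ a.u. Connected
components (26-connectivity, so surfaces one voxel thick do not fragment;
periodic grids wrap) isolate individual contacts; by default the largest is
analysed. The volume is $V_{vdW} = N_{vox} V_{vox}$ and its electron content
$n_e$ comes from direct density quadrature (see *Numerical choices*).

**3. Atomic basins.** The grid is partitioned into QTAIM basins with the
Yu–Trinkle fractional-weight scheme: voxels are swept in descending density;
a voxel whose uphill flux (density difference times Voronoi facet area over
distance, through the six face neighbours) drains into a single basin is
interior; boundary voxels receive fractional weights proportional to the
uphill flux, which is the discrete realisation of the zero-flux condition
$\nabla\rho\cdot\hat n = 0$. Weights sum to one per voxel, and basin
populations sum to the total grid charge.

**4. The volumetric source function.** With the Laplacian field and the
basin weights, the source function of basin $\Omega$ at a point $\mathbf r$
is

$$ \mathrm{SF}(\mathbf r, \Omega) = -\frac{1}{4\pi}\int_\Omega
   \frac{\nabla^2\rho(\mathbf r')}{|\mathbf r - \mathbf r'|}\,d\mathbf r' ,
$$

and summing over all basins reconstructs $\rho(\mathbf r)$ for a closed
system whose density decays at the box boundary (the package enforces a
$10^{-8}$ e/bohr$^3$ boundary ceiling on its model grids; the surface term
of the underlying Green-function identity then vanishes). The volumetric
source function is the volume integral of SF over $V_{vdW}$, estimated by
Monte Carlo:

$$ \mathrm{VSF}(V_{vdW},\Omega) \approx V_{vdW}\cdot\frac1N\sum_{i=1}^N
   \mathrm{SF}(\mathbf r_i, \Omega), $$

with $\mathbf r_i$ uniform in the volume. Results are reported as
$\mathrm{VSF}\% = 100\,\mathrm{VSF}/n_e$ together with the Gatti reliability
parameter $f_1 = 100\,(n_e - \sum_\Omega \mathrm{VSF})/n_e$, the percentage
error of reconstructing the volume's electron count from the summed basin
sources. Keeping $n_e$ an independent quadrature (rather than the summed
VSF itself) makes $f_1$ a genuine check, not a tautology; both routes are
reported. The per-basin Monte-Carlo standard error is
$V_{vdW}\,\mathrm{sd}(\mathrm{SF})/\sqrt N$.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `s_iso` | 0.5 | – | RDG isovalue bounding the NCI region |
| `rho_window` | $[10^{-6}, 10^{-3}]$ | e/bohr$^3$ | density window of sampled points |
| `band` | 0.02 | a.u. | $\rho\,\mathrm{sign}(\lambda_2)$ half-width for the vdW class |
| `n_samples` | 1000 | – | Monte-Carlo points; the integration error plateaus near 1000 |
| `seed` | 42 | – | RNG seed, recorded in every output |
| `lambda2_tol` | $10^{-10}$ | a.u. | snap tolerance for $\mathrm{sign}(\lambda_2)$ |
| `low_thresh` | $10^{-10}$ | e/bohr$^3$ | density below which basin weights are inherited, not flux-computed |
| `f1_warn` | 5 | % | reliability threshold above which the pipeline warns |

Exact boundary values $\pm 0.02$ are assigned to the vdW class (the strict
and non-strict forms of the convention differ only on a measure-zero set;
one choice is fixed for reproducibility). Where $|\lambda_2|$ falls below
`lambda2_tol` its sign is taken as $+1$: the vdW regime is characterised by
$\lambda_2 \approx 0$ and a bare `sign()` would be noise-driven there, so
the tolerance is exposed as a parameter rather than hard-coded.

## The synthetic generator

Real inputs are externally computed densities consumed as cube files. For
validation the package generates its own: Gaussian atoms
($\rho_a = n_e(\alpha/\pi)^{3/2}e^{-\alpha r^2}$, exact gradient and
Laplacian in closed form) and a promolecular model (sums of exponential
shells for H, C, N, O derived from Slater screening constants, normalised
to the atomic electron count). The standard study fixture is a symmetric
two-Gaussian "dimer" at separation 6 bohr, $\alpha = 1$: its midpoint
density $2(1/\pi)^{3/2}e^{-9} \approx 4.4\times10^{-5}$ e/bohr$^3$ sits
inside the sampling window, the midplane carries a zero-gradient (hence
$s = 0$) disc exactly like the inter-molecular contact the method targets,
and mirror symmetry supplies parameter-free expected values (equal
populations, equal VSF, 50/50 VSF%).

What the fixtures do **not** emulate: shell structure and core–valence
oscillations of the Laplacian, plane-wave pseudo-density artefacts, basis-set
noise at low density, and the multi-atom crowding of a real molecular
crystal. Passing tests therefore demonstrate the correctness of the
machinery (partitioning, quadrature, sampling, bookkeeping), not the
physical accuracy of any particular external density; with such densities
the $f_1$ diagnostic is the user's guide, and the pipeline warns when it
exceeds `f1_warn` (reconstruction from densities that are poorly resolved
in the $10^{-6}$–$10^{-3}$ window is known to degrade substantially).

Fixture grids use 0.1875 bohr spacing (fine enough that basin populations
are converged to $\sim 10^{-4}$ electrons and the Poisson reconstruction
error stays near 1%), boxes padded 4.8 bohr beyond each nucleus to meet the
boundary ceiling, and odd voxel counts so the lattice is exactly
mirror-symmetric. The heavier statistical checks (fluctuation scaling over
20 seeds, the exhaustive oracle) run on a 0.32 bohr lattice where the whole
density window — a few thousand voxels — can be integrated exhaustively.

## Numerical choices

- **Finite differences.** 5-point central stencils ($O(h^4)$) in the grid
  interior, one- and two-sided $O(h^2)$ stencils at non-periodic boundaries,
  wrap-around for periodic grids. Derivatives are taken along lattice axes
  and mapped to Cartesian form through the inverse cell matrix, so
  non-orthogonal cells work. Hessian eigenvalues come from the closed-form
  trigonometric solution for symmetric $3\times3$ matrices, vectorised over
  the grid; the middle eigenvalue is computed trace-preservingly and clamped
  into $[\lambda_1, \lambda_3]$ against rounding.
- **Source-function quadrature.** Every voxel of every basin contributes to
  every SF evaluation — no cutoff radius, because the reliability analysis
  depends on full reconstruction. The voxel containing the reference point
  and its 26 neighbours are re-integrated on a $6^3$ subdivision (the kernel
  varies strongly there), and the subcell holding the point itself uses the
  equal-volume-sphere rule $-\nabla^2\rho\,R^2/2$, $R = (3V/4\pi)^{1/3}$ —
  the standard treatment of the integrable singularity. The resulting
  reconstruction error is $O(h^2)$ and about 1% at 0.1875 bohr spacing.
- **Volume quadrature.** $n_e$ uses the voxel-average rule (midpoint value
  plus $\tfrac{h^2}{24}\nabla^2\rho$), fourth-order accurate, because the
  Monte-Carlo estimator targets the true volume integral: at 0.1875 bohr a
  plain midpoint sum differs from the true integral by several percent for
  Gaussian model densities (where $\nabla^2\rho/\rho \sim 30$ bohr$^{-2}$),
  which would masquerade as a reconstruction error in $f_1$. The exhaustive
  quadrature oracle applies the matching correction through the identity
  $\nabla^2 \mathrm{SF}(\mathbf r,\Omega) = w(\mathbf r,\Omega)
  \nabla^2\rho(\mathbf r)$, and the plain midpoint sum is kept as
  `n_e_midpoint`.
- **Ties and degeneracies.** The YT sweep orders exact density ties by flat
  voxel index (determinism under identical input). Fallback assignments
  (sub-threshold voxels, ridge voxels with no uphill face neighbour) inherit
  the *full* weight row of the steepest uphill neighbour, averaging over
  exactly tied alternatives — this keeps an exactly mirror-symmetric density
  exactly mirror-symmetrically partitioned, which the symmetry tests verify
  to $10^{-6}$ and better. Maxima on plateau peaks are reduced to one per
  plateau by the same index rule; a constant grid has no maxima and errors.
- **Sampling.** The default sampler draws a member voxel uniformly and
  jitters uniformly within it — exact uniform sampling on the volume, no
  autocorrelation. A Metropolis–Hastings walker (symmetric 26-neighbour
  proposals, uniform target, burn-in 100, thinning 5 — the walk parameters
  are package choices) is provided for convergence assessment in the style
  the method was originally validated with. Points in voxels below
  $10^{-6}$ e/bohr$^3$ are rejected. Fixed seeds make every run
  bit-reproducible.
- **RDG error propagation.** The reported RDG convergence diagnostic is
  $\sqrt{(\delta\rho/\rho)^2 + c(\delta\rho/\rho)^2}$ with $c = (4/3)^2$
  from the $\rho^{4/3}$ term. The derivation behind this combination is
  heuristic (its gradient term is taken at the same relative scale as the
  density term), so the package labels it a diagnostic, not an error bar.

## Design decisions that were genuinely open

- **Periodicity** is not encoded in the cube format, so it is an explicit
  flag (`--periodic` on the command line) attached to the grid; plane-wave
  densities are periodic, localized-basis ones are not.
- **Negative axis counts** in cube headers are read as the Ångström dialect
  and converted ($1\,\text{Å} = 1.8897259886$ bohr); positive counts mean
  Bohr.
- **Pseudo-densities are integrated as given**: no core-charge augmentation
  is attempted, so basin populations from pseudopotential grids reflect the
  valence density only; gross deviations from $Z$ are the user's cue.
- The **surface flux term** of the underlying two-term decomposition is
  dropped under the closed-system contract (boundary density below
  $10^{-8}$ e/bohr$^3$), which the grid generators enforce with a warning.
- **Eq-style constants**: the local-source proportionality is fixed to
  $-1/4\pi$ so that basin sources sum exactly to the density; no free
  constant is exposed.

## A worked run

```{r dimer, eval = FALSE}
dx <- dimer_density_grid()          # sep 6 bohr, alpha 1, 0.1875 bohr grid
res <- vsf(dx$grid, geom = dx$geometry, n_samples = 1000, seed = 42)
print(res)
plot(res)                           # running-mean convergence per basin
```

On the symmetric dimer this prints two basins holding $1.0000$ electron
each, a one-voxel vdW volume at the midplane with
$n_e \approx 3.05\times10^{-7}$ e, VSF% of $50.1$ and $49.3$ ($\pm 0.4$),
and $f_1$ under 1% — the half-and-half split that mirror symmetry demands,
recovered entirely numerically.

## Known limitations

- Voxel membership is binary (no sub-voxel interpolation of the mask), so
  $V_{vdW}$ is quantised to whole voxels; thin NCI discs can be a single
  voxel wide at realistic spacings.
- The Monte-Carlo standard error assumes independent samples; it is correct
  for the uniform sampler and approximate for thinned Metropolis chains.
- $f_1$ degrades on coarse grids and on densities that are inaccurate in
  the $10^{-6}$–$10^{-3}$ e/bohr$^3$ window (plane-wave pseudo-densities
  are the documented offender); the package reports and warns but does not
  attempt correction.
- Critical-point search, surface meshing, spin-resolved sources and energy
  decomposition are out of scope.
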