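---
title: "Medial permeability from microstructure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medial permeability from microstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediaperm)
```

## The problem and the model

The tunica media of an artery is a porous composite: smooth muscle cells
(SMCs) and impervious fibres embedded in extracellular matrix (ECM) that is
itself a fine porous medium.  Water driven across the wall by the transmural
pressure difference percolates through the ECM and around the cells.  At the
voxel scale this flow is described by Brinkman's equation,

$$\mu \nabla^2 \mathbf{u} - \frac{\mu}{k(\mathbf{x})}\,\mathbf{u} - \nabla p = 0,
\qquad \nabla\cdot\mathbf{u} = 0,$$

with a binary permeability field: $k = k_\mathrm{ECM}$ in matrix voxels and
$k = k_\mathrm{ECM}/\mathrm{penalty}$ in cell/fibre voxels.  The penalty is
the standard device for impermeable inclusions — a drag so large that flow
goes around rather than through.  Volume averages of flow solutions driven
along each cylindrical axis (radial $r$, axial $z$, circumferential
$\theta$) obey Darcy's law $\langle\mathbf{u}\rangle = (\mathbf{k}/\mu)
\langle\nabla p\rangle$; three directional solves give nine scalar equations
for the six independent entries of the symmetric tensor $\mathbf{k}$, solved
by least squares.  Its eigenvalues are the principal permeabilities: $K_{11}$
is assigned to the eigenvector closest to $\hat{e}_r$ (ties resolved toward
the smaller eigenvalue, so an ambiguous radial direction is never credited
with the easier pathway), and $K_{12} \ge K_{13}$ are the transverse pair.

Because the Brinkman screening length $\sqrt{k_\mathrm{ECM}} \approx 1\,$nm
is far below the voxel size, the viscous term is a small regularisation and
the problem is drag-dominated: a domain with impermeable inclusions can only
be *less* permeable than the bare matrix, so $K_{11} \le k_\mathrm{ECM}$
always.  Published per-block permeability tables for this preparation print
values without units; interpreting them on the $10^{-18}\,\mathrm{m}^2$
scale of $k_\mathrm{ECM}$ would place them *above* the matrix permeability,
which is impossible under this model, so that unit inference is flagged
wherever those fixtures are used — the package reports its own tensors in
m² and prints them scaled by $10^{-18}$.

Wall resistance decomposes in series: $R_\mathrm{WALL} = 1/L_p$ from the
measured hydraulic conductance, $R_\mathrm{MED} = \mu T / K_{11}$ from the
simulated permeability and measured medial thickness $T$, and
$R_\mathrm{INT} = R_\mathrm{WALL} - R_\mathrm{MED}$ by subtraction.  A
negative $R_\mathrm{INT}$ is physically inconsistent; it is reported with a
warning rather than clamped, because clamping would hide inconsistent
inputs.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k_ecm` | 1.32e-18 | m² | mean of published interstitial-matrix measurements; a config value, not a constant |
| `viscosity_mu` | 6.913e-4 | Pa·s | water at 37 °C; the source analysis names only "viscosity of water" |
| `penalty_ratio` | 1e6 | — | solid voxels are 10⁶× more resistive; raising it to 10⁸ changes volume-averaged velocities by <1% (penalty-converged) |
| `bc_mode` | periodic | — | macroscopic gradient imposed as a body force over a periodic cell, standard homogenisation practice; a fixed-pressure-faces mode with free-slip lateral walls is exposed as an alternative |
| `tolerance` | 1e-10 | — | outer relative residual; bounds the discrete divergence directly |
| `target_phi_ecm` | 0.60 / 0.68 | — | preset ECM volume fractions for the relaxed and constricted states; generation stops within ±0.02 |

Internally the solver is dimensionless — lengths in voxels, permeability in
units of `k_ecm`, unit driving gradient — so the assembled operators are
well scaled regardless of the SI magnitudes (velocities of order
$10^{-12}\,$m/s would otherwise meet matrix entries of order $10^{14}$).
Equation bookkeeping uses the dynamic viscosity $\mu$ throughout; a
kinematic formulation would divide by density, and `density_rho` is carried
in the config for that conversion only.

## The synthetic generator: what it emulates, and what it does not

No imaging data accompany the source study, so every downstream stage is
exercised on synthetic microstructures.  Cells are fusiform — tapered
ellipsoids whose transverse radius falls off as $1 - t^2$ along the long
axis — with long axes in the $z$–$\theta$ plane at a helix angle from the
circumferential direction (medial SMCs wind helically rather than
circumferentially), jittered per cell.  Placement is sequential with overlap
allowed, so cells touch, as they do in confocal images; centres seed on
radial layers (SMC layers between elastic lamellae), which makes the radial
direction the most obstructed and yields transverse-dominant anisotropy
($K_{12}, K_{13} > K_{11}$), as observed in tissue.  The volume fraction is
controlled by cell count: cells are carved until the measured φ_ECM is
within ±0.02 of target, rejecting placements that overshoot.

Preset geometry is **calibration, not ground truth**: the study reports no
cell dimensions or helix angles, so the presets were chosen once to
reproduce the published targets — φ_ECM 0.60/0.68, per-slice median aspect
ratios near 0.52/0.42, thickness 27.7/33.2 μm — using the plane-section
identity $z_\mathrm{semi} = (\sin^2\beta/a^2 + \cos^2\beta/b_t^2)^{-1/2}$
to pick the helix angle (60°) and the constricted radial flattening (0.72).
The contracted preset follows from the baseline via `apply_contraction()`:
cells shorten along the long axis, widen transversely and flatten radially,
and the derived volume fraction follows from conservation of cell count,
$\varphi' = 1 - (1-\varphi)\,v_\mathrm{cell}/s_T$ with $s_T$ the thickness
scale — so the φ_ECM rise under constriction emerges from wall thickening
at near-conserved cell volume rather than being imposed.

The confocal emulator applies phase intensities (ECM bright, since the
tracer fills the matrix), exponential depth attenuation, Gaussian blur and
additive (optionally signal-dependent) noise.  It does **not** model tracer
transport kinetics, fixation artefacts, laser power drift, anisotropic
point-spread functions, or elastin autofluorescence — so green tests
demonstrate that the pipeline's operations are correct and internally
consistent, not that they are robust to every artefact of real confocal
data.

## Numerical choices

* **Discretisation** — staggered (MAC) finite volumes on the voxel lattice:
  velocities on faces, pressure at cell centres; face drag coefficients are
  arithmetic means of the adjacent cell drags.  Discrete incompressibility
  holds to the solver tolerance (typically ~1e-13 relative in practice).
* **Linear solver** — the velocity blocks are drag-dominated and nearly
  diagonal (off-diagonal viscous entries ~$10^{-5}$ of the diagonal), so
  inner solves use Jacobi-preconditioned conjugate gradients; the pressure
  Schur complement is solved by CG preconditioned with a supernodal
  Cholesky factorisation of the diagonal-lumped operator, which converges
  in a handful of outer iterations and is reused across the three drive
  directions.  Non-convergence aborts with the residual history.
* **Percolation gate** — a flood fill checks that the ECM spans the driven
  direction before solving; a non-spanning pore phase is a hard error
  (an entirely solid domain is still solvable — uniform penalty drag — and
  is used to verify penalty suppression).
* **Degenerate inputs** — constant volumes cannot be thresholded;
  attenuation correction rejects all-zero slices; thickness measurement
  fails when half the columns carry no tissue; parallel drive gradients are
  a rank error in the Darcy fit.
* **Thresholding** — Otsu on the intensity histogram by default with a
  manual fixed override, since the original thresholding was manual; the
  reported ~2% inter-observer sensitivity becomes an automated check that
  ±5% threshold shifts move φ_ECM by ≤0.03.
* **Attenuation correction** — per-slice mean normalisation to the first
  slice by default (no optics assumptions; reproduces the stated outcome of
  a depth-flat profile), with a fitted single-exponential alternative.
* **Segmentation** — per-slice (the aspect-ratio analysis is 2-D in the
  $r$–$z$ plane; no volumetric segmentation), watershed flooding of the
  inverted distance transform so touching cells split along basin ridges.
  Basin merging uses a tolerance of 2 distance units — about half the
  typical cell minor radius in voxels — in place of explicit marker
  seeding; cells touching the slice border (censored diameters) and regions
  under 16 px are excluded.  Aspect ratio is minor/major of the
  equivalent (second-moment) ellipse, the natural reading of
  "minor diameter over major diameter".
* **Thickness** — mean radial extent of tissue signal over all
  $(z,\theta)$ columns; the averaging rule is this package's choice, as the
  source states only where thickness was measured.
* **Statistics** — SEM uses the $n-1$ standard deviation; t-tests are
  two-sided, classical (equal-variance) by default with Welch as an option
  — on the printed permeability blocks both give $p \ll 10^{-6}$.
  Volumetric strain is reported as computed, $J = \varphi/\varphi_B$
  (1.1333 for the group means 0.68/0.60), without forcing agreement with
  the ~12% figure quoted from unrounded data.

## Problem sizes

Solver fixtures in the tests use 12³–32³ grids and the acceptance checks
64³ generation and a 32³ analytic Darcy limit; the demo pipeline runs 2+2
specimens on periodic 24³ grids at 1.25 μm voxels.  These sizes were chosen
so that the full suite completes in well under a minute on a laptop while
the self-convergence check (16³ vs. 32³ at matched physical geometry,
within 5%) shows the coarse grids are already adequate for the volume
averages the analysis needs.

## Known limitations

* Lp is an experimental input; the shipped demo conductances are synthetic
  plausible values, so resistance *levels* in the demo are illustrative —
  only the simulated permeabilities and directions of change are
  substantive.
* The generator's ellipsoidal cells omit elastin/collagen fibre
  architecture; impervious fibres are absorbed into the cell phase, exactly
  as binary thresholding of tracer images does.
* Periodic homogenisation on ~30 μm cells assumes the block is a
  representative volume; block-to-block heterogeneity appears only through
  seeds.
* The original study solved Brinkman flow with a spectral/hp element
  method whose boundary conditions and penalty magnitude are documented
  elsewhere; this implementation is validated by its analytic limits,
  penalty- and grid-convergence, and exact tensor round trips rather than
  by matching that solver's configuration.
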