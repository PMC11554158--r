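---
title: "A center-based multicellular model of Hippo-YAP/TAZ contact inhibition: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A center-based multicellular model of Hippo-YAP/TAZ contact inhibition: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipposim)
```

## The model in one page

`hipposim` couples two dynamical layers, exchanged once per global step of
`dt = 3.75` s:

1. **Cell dynamics.** Every cell is a sphere with center position, velocity,
   size parameter $\sigma$ (radius $= \zeta\sigma$), age and a cycle state.
   Cells interact through a softcore Lennard-Jones (12-6) pair potential and
   linear friction, integrated by velocity-Verlet. This layer produces each
   cell's local packing fraction $\rho_i$.
2. **Intracellular dynamics.** Each cell carries concentrations of
   cytoplasmic, nuclear and phosphorylated YAP/TAZ, $(X_{1i}, X_{2i},
   X_{3i})$, governed by a linear reaction network whose phosphorylation
   rate is proportional to $\rho_i$: the Hippo kinase cascade is lumped into
   the single density-dependent term $b_1 \rho_i X_0$. This layer produces
   the growth signal: a cell grows only while $X_{2i} > X_{\mathrm{th}}$.

Each global step applies, in order: growth/arrest discrimination and growth;
division of cells that reached $2^{1/3}\sigma_0$; mechanics; density update
followed by reaction propagation at frozen density. A run starts from two
birth-size daughters at $\mp\gamma\sigma_0'$ around the origin, where
$\gamma = 2^{1/3}-1$ guarantees that two daughters of radius $\sigma_0'$
exactly fill the volume of a mother of radius $2^{1/3}\sigma_0'$ and sit
inside her footprint.

The two presets differ only in initial YAP/TAZ pools — normal
$(0.05, 0.2, 0)$ µM and cancer $(0.1, 0.4, 0)$ µM. Everything downstream
(arrest onset, growth suppression) is emergent.

## Exact propagation of the reaction layer

At frozen $\rho$, the reaction system is $\dot X = A(\rho) X$ with

$$A(\rho) = \begin{pmatrix} -a_1 - b_1\rho X_0 & a_2 & a_3 \\
a_1 & -a_2 & 0 \\ b_1 \rho X_0 & 0 & -a_3 \end{pmatrix},$$

whose columns sum to zero (per-cell mass conservation) and whose
off-diagonal entries are non-negative (a Metzler matrix, so non-negative
states stay non-negative). `propagate()` applies the exact step propagator
$e^{A\,dt}$ via eigendecomposition of the $3\times 3$ matrix; if the
eigenbasis condition number exceeds $10^8$ it falls back to Padé
scaling-and-squaring (`Matrix::expm`). The tests cross-check both paths
against an independent adaptive Runge-Kutta integration (`deSolve`) to
$10^{-9}$ relative error, and verify conservation to $10^{-12}$ over
$10^4$ steps.

Because $A$ depends on the cell state only through $\rho$,
`propagate_population()` quantizes densities on a grid (default width
$10^{-3}$) and caches one propagator per distinct quantized density across
the whole run: per step this costs one $3\times3$ matrix product per cell
rather than one eigendecomposition per cell. The grid width bounds the
density error fed to the reaction layer at half a grid cell, far below the
natural step-to-step fluctuation of $\rho_i$.

Closed forms used throughout: the steady state at density $\rho$ and pool
$T = X_1+X_2+X_3$ is $X_1^* = T/(1 + a_1/a_2 + b_1\rho X_0/a_3)$ with
$X_2^* = (a_1/a_2) X_1^*$, $X_3^* = (b_1\rho X_0/a_3)X_1^*$; inverting
$X_2^*(\rho) = X_{\mathrm{th}}$ gives the critical arrest density
`critical_density()`, 1.3216 for the normal pool (0.25 µM) and 2.7104 for
the cancer pool (0.5 µM). This factor-two gap in critical density is the
mechanistic reading of why a twofold YAP/TAZ dose evades contact
inhibition.

## Mechanics: functional forms and defaults

The softcore pair potential is
$U(r) = 4\epsilon\,[S^{-2} - S^{-1}]$ with
$S(r) = \alpha_{LJ}(1-\lambda)^2 + (r/\sigma_{ij})^6$ — the standard
soft-core modification of LJ(12-6) in which the constant
$c = \alpha_{LJ}(1-\lambda)^2$ keeps $U(0)$ finite, so overlapping cells
(inevitable immediately after division) never produce divergent forces. Its
minimum sits at $r = \zeta\sigma_{ij}$ with
$\zeta = (2 - c)^{1/6}$.

Design choices, each open in principle, fixed as follows:

* **Pair scale (mixing rule).** $\sigma_{ij} = \sigma_i + \sigma_j$, so the
  potential minimum is at the sum of the two cell radii
  ($\zeta\sigma_i + \zeta\sigma_j$) for unequal sizes — contact-based
  equilibrium.
* **$\zeta$, $\lambda$ defaults.** With birth radius $\sigma_0' = 5$ µm and
  birth size parameter $\sigma_0 = 4.53$ µm, $\zeta = 5/4.53$; holding
  $\alpha_{LJ} = 0.5$, `lambda_for_zeta()` inverts the softcore relation to
  get $\lambda \approx 0.3813$. All three are configurable; the identity
  $\sigma_0 = \sigma_0'/\zeta$ is re-derived and enforced at config load.
* **Friction.** Linear Stokes drag $-\mu v$ with default $\mu = m_0/60$ s
  ng/s, i.e. a velocity relaxation time of 60 s — strongly damped relative
  to the mitosis phase (1 h), as expected for cells in tissue. The drag
  enters the Verlet update semi-implicitly at the half-step velocity, which
  keeps the force-free decay exact to second order in the substep.
* **Well depth $\epsilon$.** Calibrated, not invented:
  `calibrate_epsilon()` (also shipped as `scripts/calibrate-epsilon.R`)
  bisects for the $\epsilon$ at which a two-cell pair released at
  $0.9\times$ its equilibrium separation settles within 1% of equilibrium
  in exactly one mitosis phase under the default friction. The result,
  $1.2674\times10^{-5}$ ng µm²/s², is recorded in the presets; it leaves
  the two-body relaxation overdamped (monotone), which the tests pin down
  against a reference ODE solution.
* **Cutoff.** $r_{\mathrm{cut}} = 2.5\,\zeta\sigma_{ij}$ per pair — the
  conventional LJ truncation — with the energy shifted to zero at the
  cutoff for continuity.
* **Integration.** Velocity-Verlet at the global `dt` with `n_sub = 1`
  substep by default; a stability guard aborts with a diagnostic if any
  substep displacement exceeds half the smallest cell radius, directing the
  user to raise `n_sub`. Without friction the integrator is symplectic; the
  tests bound total-energy drift at $10^{-4}$ relative over $10^4$
  substeps.
* **Neighbor search.** Cell-linked lists with bin size equal to the largest
  pair cutoff; an exact brute-force path is kept for small populations and
  doubles as the oracle in tests (both paths agree to machine precision).
* **Boundaries.** Unbounded free space: tissues grow freely from the
  origin.
* **Mass.** A single constant $m_0 = 2$ ng per cell; mass is not scaled
  with volume during growth. In the overdamped regime the mass only sets
  the (short) velocity relaxation time, so this simplification has no
  visible effect on tissue-scale behavior.

## The density signal

The packing fraction is
$$\rho_i = \frac{1}{12}\sum_{j\neq i} \exp\!\big(-(s_{ij}-1)/\delta_\rho\big),
\qquad s_{ij} = \frac{|r_i - r_j|}{\zeta(\sigma_i+\sigma_j)},$$
truncated at the mechanical cutoff, with decay width $\delta_\rho = 0.25$.
The $1/12$ prefactor calibrates the kernel so that twelve touching
neighbors — the coordination number of close packing — give exactly
$\rho = 1$, matching the convention that a tightly packed tissue sits at
$\rho \approx 1$; an isolated cell has $\rho = 0$, and compressed or
second-shell neighbors push interior cells into the 1–1.5 range. The kernel
is a declared design choice (normalization, size scaling and width are all
configurable), not a reconstruction of any particular reference; the tests
pin its calibration points (12 neighbors $\to$ 1, 6 $\to$ 0.5), its
monotone decay, and the interior-exceeds-surface property on packed
clusters. No cap is applied to $\rho$ before it enters the reaction rates.

## Cell-cycle rules and tie-breaks

* Growth requires $X_{2i}$ **strictly above** $X_{\mathrm{th}}$; the
  measure-zero tie $X_{2i} = X_{\mathrm{th}}$ classifies as arrest, fixed
  for determinism.
* The M phase is `age < T_M` (age exactly $T_M$ is G1). Colors 0–3 (cyan,
  orange, blue, red) encode arrest/growth × M/G1 and are purely diagnostic
  labels — nothing downstream reads them.
* Division triggers at $\sigma \ge 2^{1/3}\sigma_0$ with a $10^{-12}$
  relative tolerance, so that the $T_{CC}/dt$ accumulated float increments
  of $d\sigma = \gamma\,dt\,\sigma_0/T_{CC}$ divide on the intended step;
  a permanently growing cell divides every $\lceil T_{CC}/dt\rceil$ steps
  exactly.
* Simultaneous divisions are processed in ascending cell id; daughters are
  appended with fresh ids and are not re-checked within the step. Daughters
  inherit the mother's concentrations bit-exactly and keep their
  separation velocities regardless of any later arrest (mechanics acts on
  all cells every step).
* Division directions sample the azimuth uniformly on $[0, 2\pi)$ and the
  polar angle uniformly on $[0, \pi)$ — the model's stated convention,
  deliberately kept even though it is not area-uniform on the sphere; a
  `sphere_uniform` config switch provides cosine-weighted sampling for
  sensitivity checks (default off).

## What a run emulates, and what it does not

A simulation generates all of its own state: the presets *are* the study
conditions (the published rate constants, twofold initial YAP/TAZ for cancer,
$X_{\mathrm{th}} = 0.012$ µM, 20 h cycle, 3.75 s step, two-cell start). What
passing tests demonstrate is therefore internal: conservation laws,
closed-form limits, integrator contracts, and the emergent ordering that
the normal preset arrests at least as strongly as the cancer preset at
matched times. Real epithelia add much that this model omits: cell death
and extrusion, S/G2 phases and checkpoint noise, explicit MST1/2–LATS1/2
kinetics (lumped here into $b_1\rho X_0$), stochastic reaction noise, cell
shape and polarity, substrate adhesion and boundary geometry, and
heterogeneous YAP/TAZ pools. Conclusions about those features are out of
scope by construction.

## Problem sizes

The test suite and the acceptance script use scaled runs chosen to exercise
every mechanism at meaningful population sizes: the doubling-law check runs
three full 20 h cycles to 16 cells; the contact-inhibition check runs five
cycles (96 000 steps) per preset across three seeds with a majority vote;
the acceptance script runs the normal tissue to 140 h (134 400 steps,
populations of order $10^2$) to capture the arrest onset, and the cancer
tissue to 120 h. The full published-scale experiment (200 000 steps,
$\approx 10^3$ cells) runs with the same code path — `default_config()`
ships `L = 200000` — and is reproducible via the CLI, e.g.
`hipposim run --preset cancer --seed 1 --steps 200000`.

## Known limitations

* The reaction layer is deterministic and linear per step; no intrinsic
  noise, so population heterogeneity arises only from geometry and division
  order.
* The frozen-density approximation updates $\rho_i$ once per global step;
  at `dt = 3.75` s this lag is negligible against the hours-scale reaction
  dynamics, but very stiff custom parameterizations would need a smaller
  step.
* With the calibrated (weak, overdamped) adhesion, tissues remain somewhat
  compressible; the packing fraction of interior cells is an emergent
  quantity and can exceed 1.5 transiently after dense division bursts.
* No cell removal: populations are monotone non-decreasing, so late-time
  arrested tissues accumulate rather than turn over.
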