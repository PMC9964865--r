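---
title: "Simulating and reconstructing 2D EIT images with eitrecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and reconstructing 2D EIT images with eitrecon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitrecon)
```

## The problem

Electrical impedance tomography (EIT) images the conductivity distribution
$\sigma(x)$ inside a domain $\Omega$ from current/voltage measurements on
boundary electrodes. `eitrecon` implements the standard 2D tank setting: a
disk of radius 0.095 m with 16 equally spaced boundary electrodes, an
adjacent drive / adjacent measurement protocol (each of the 16 adjacent
electrode pairs is driven in turn; for each drive the voltage is read on
the 13 adjacent pairs not touching the drive electrodes, giving
$16 \times 13 = 208$ measurements per frame), a 4.5 mA drive current, a
1 S/m homogeneous background, and near-insulating circular inclusions
(conductivity floored at $10^{-12}$ S/m). The model is quasi-static with
real-valued conductivity; drive frequency is treated as metadata only.

## Forward model

The interior potential satisfies $\nabla\cdot(\sigma\nabla\varphi) = 0$,
closed by the complete electrode model (CEM): zero normal current off the
electrodes, prescribed total current $I_L$ through electrode $L$, a
contact-impedance voltage drop
$\varphi + \rho_L\,\sigma\,\partial\varphi/\partial n = U_L$ on each
electrode, and the conservation constraints $\sum_L I_L = 0$ and
$\sum_L U_L = 0$. We discretize with standard P1 Galerkin finite elements
(piecewise-linear nodal potentials, piecewise-constant element
conductivities) and enforce the zero-sum potential constraint with an
explicit Lagrange multiplier rather than by grounding a node, so the
constraint holds to machine precision.

The mesh generator is a deterministic structured triangulation: ring $k$ of
$N$ carries $16k$ equally spaced nodes, triangulated sector by sector into
$16N^2$ congruent-quality triangles. Two properties motivate this choice
over a general unstructured mesher (none is available in this R stack, and
none is needed): meshes are bit-reproducible for fixed inputs, and they are
exactly symmetric under rotation by one electrode pitch, which makes
homogeneous-disk frames rotation-invariant up to solver round-off — a sharp
oracle the test suite exploits. Contact impedance defaults to
$10^{-5}\ \Omega\,\mathrm{m}^2$ per electrode and the electrode arc to
10 mm, both configurable; the published setup states 1 mm rod electrodes in
3D but no 2D arc, so the arc is a modelling choice.

The sensitivity (Jacobian) matrix of the linearized difference-imaging
model $y = Ax$ (with $y = U - U_0$, $x = \sigma - \sigma_0$) is computed by
the Geselowitz adjoint formula
$A_{ij} = -\tfrac{1}{I}\int_{e_j}\nabla\varphi_p\cdot\nabla\varphi_q\,d\Omega$,
using the 16 drive-field solutions as both drive and measurement fields.
For the discrete P1 model this is the exact derivative of the forward map,
which is why the finite-difference check below agrees to ~0.01%.

**Inverse-crime guard.** Simulated data are generated on a ~3136-element
mesh, while the Jacobian is assembled on an independent ~1600-element mesh
and aggregated onto a 64×64 pixel grid (in-disk pixels only,
area-overlap-weighted, a partition of unity so row sums are preserved
exactly). Reconstruction therefore never inverts the discretization that
produced the data.

## Solvers

All solvers act on the pixel-basis linear model $y = Ax$.

The LASSO objective is
$F(x) = \tfrac12\|Ax - y\|_2^2 + \lambda\|x\|_1$. ISTA iterates
$x^{(k+1)} = T_\alpha[x^{(k)} - \mu A^T(Ax^{(k)} - y)]$ where
$T_a(v) = \mathrm{sign}(v)\max(|v| - a, 0)$ is the shrinkage operator;
FISTA adds Nesterov momentum with
$t^{(k+1)} = (1 + \sqrt{1 + 4 (t^{(k)})^2})/2$, improving the objective
rate from $O(1/k)$ to $O(1/k^2)$. The shrinkage threshold $\alpha$
(default $10^{-9}$) is applied directly, so the implied LASSO weight is
$\alpha/\mu$. Step sizes follow each method's own printed rule: FISTA-type
loops use $\mu = 1/L$ with $L = 2\lambda_{max}(A^TA)$ by default
(`lipschitz_mode = "half-objective"` exposes the
$L = \lambda_{max}(A^TA)$ constant consistent with the half-quadratic data
term — both are valid upper bounds, the default is simply more
conservative); ISTA and Landweber use
$1/(\lambda_{min}+\lambda_{max})$-style relaxations over the positive
spectrum of $A^TA$.

**RS-FISTA** warm-starts FISTA at an adaptive-regularization Tikhonov
solution: repeatedly solve $x^k = (A^TA + \lambda^k I)^{-1}A^Ty$ (through
the thin SVD of $A$, which is exact and cheap at $208 \times N$), lowering
$\lambda^{k+1} = \max(\lambda_{floor},\ \lambda^k - \gamma\|Ax^k - y\|_1)$
until the L1 misfit drops below `rs_tol`. Defaults:
$\lambda^0 = 0.01\,\lambda_{max}(A^TA)$,
$\gamma = 10^{-3}\lambda^0/\|y\|_1$, floor $10^{-12}\lambda^0$, stop at
$10^{-2}$. The published update rule subtracts a quantity whose printed
form is not well-typed (a gradient symbol applied to a scalar); the
implementation keeps its evident structure — $\lambda$ decreases
proportionally to the L1 residual — as the well-defined rule above.

One scale sensitivity worth knowing: with a 4.5 mA drive the difference
signals are $\sim 10^{-4}$ V, so $\|Ax - y\|_1$ of the very first Tikhonov
solve is already below the absolute stop $10^{-2}$ and the adaptive loop
terminates after one pass. The warm start is then a single Tikhonov solve
at $\lambda^0$. On data in other units (or with `rs_tol` lowered) the loop
adapts over many passes; the default honors the published tolerance.

Comparison methods: Landweber relaxation
$x^{k+1} = x^k + \lambda_{rel} A^T(y - Ax^k)$; CGNR (conjugate gradients on
$A^TA x = A^Ty$ — the printed recurrence mixes symbols from two notations
and is implemented as standard CGNR); NOSER, the one-step diagonally
regularized Gauss–Newton $x = (A^TA + r\,\mathrm{diag}(A^TA))^{-1}A^Ty$
(the printed inverse $[A(x^{(0)})]^{-1}$ does not exist for a
$208 \times N$ matrix); and damped Newton–Raphson
$x^{(k+1)} = x^{(k)} - (A^TA + rI)^{-1}A^T(Ax^{(k)} - y)$ with $r = 0.1$.
NOSER and Newton–Raphson solves use the push-through identity so only
$208 \times 208$ systems are factorized. All comparison methods start from
the zero vector. Convergence of the FISTA-type loops is declared when the
relative change of the residual norm $\|y - Ax^{(k)}\|_2$ falls below
$\varepsilon = 10^{-5}$ (the published pseudo-code leaves the error norm
and criterion unspecified; the Euclidean norm and relative-change rule are
our reading), or at `iter_max`.

## Phantoms, noise and metrics

Phantoms are homogeneous backgrounds plus circular inclusions, with a 2 mm
wall margin and no overlap. `random_phantom()` draws 1–4 inclusions with
radii uniform in 12–25 mm — a visually similar range to the published
figure set, whose exact geometries are only depicted graphically and are
therefore unrecoverable; the generator stands in for them. Element
membership is by centroid (consistent with the piecewise-constant basis);
rasterized ground truth uses pixel-center membership.

Gaussian noise is added to the inhomogeneous frame only (the reference
stays noiseless) and each draw is rescaled so the realized
$10\log_{10}(\sum v^2/\sum e^2)$ hits the requested SNR exactly, making
SNR assertions sharp. SNR is defined on the raw voltage vector, i.e.
sensor noise, not on the difference signal.

Reconstructions are scored on the 64×64 in-disk pixels after min–max
normalization of both images to the 8-bit range: global (single-window)
SSIM with the standard constants $C_1 = (0.01\cdot255)^2$,
$C_2 = (0.03\cdot255)^2$ (the published SSIM formula is typographically
garbled and omits the constants; a `raw = TRUE` mode drops them), RMSE in
8-bit pixel units, $PSNR = 10\log_{10}(255^2/RMSE^2)$, and
$CAM = |AVE_{ref} - AVE_{other}|/AVE_{other}\times 100\%$ across methods
with RS-FISTA as the (configurable) reference.

## Study drivers and problem sizes

`study_setup()` builds the shared objects at the published operating point
(3136-element forward mesh, 1600-element Jacobian mesh, 64×64 grid).
`run_benchmark()` reproduces the methods × models comparison structure,
`run_noise_study()` the SNR ∈ {∞, 60, 50, 40, 30} dB sweep, and
`run_convergence_study()` the SSIM-versus-iteration curves (NOSER is
excluded — it is one-step). The packaged studies use a 200-iteration
budget, 10 noise realizations per SNR level and convergence checkpoints
{1, 5, …, 100}: large enough that every method's curve has flattened
visibly, small enough that the whole suite runs in minutes on one CPU.
All randomness flows through explicit seeds via `with_seed()`, so any rerun
is bit-identical.

```{r example}
setup <- study_setup()
spec <- random_phantom(7, n_inclusions = 1)
dat <- simulate_phantom_data(setup, spec)
fit <- eit_reconstruct(setup$A, dat$y, "RS-FISTA",
                       solver_config(iter_max = 200))
summary(fit)
metrics_report(fit, dat$truth)
```

## Numerical choices and degenerate inputs

* The assembled CEM matrix is symmetric and solved sparsely (one
  factorization per conductivity, 16 right-hand sides).
* `lipschitz_bound()` uses power iteration with a fixed internal start
  vector (relative tolerance $10^{-10}$), so step sizes are deterministic.
* Zero data short-circuit: every solver maps $y = 0$ to $x = 0$.
* CGNR stops early with a `breakdown` flag when the search direction
  annihilates; ISTA raises an error after ten consecutive objective
  increases (a diverging step size).
* Pixels are assigned by sub-triangle centroids from a deterministic
  barycentric refinement finer than half a pixel; the few boundary slivers
  whose pixel center falls outside the disk are snapped to the nearest
  in-disk pixel so the aggregation remains an exact partition of unity.
* A constant image min–max normalizes to all zeros by declared convention;
  zero RMSE reports PSNR as `Inf`.

## What the synthetic studies do and do not show

The generator emulates idealized tank conditions: exact circular
inclusions, a noiseless reference frame, perfectly known electrode
geometry and contact impedance, and additive white Gaussian sensor noise.
Real tank data additionally carry electrode placement and contact-impedance
uncertainty, drift, correlated amplifier noise and 3D current spreading —
none of which are modelled. Passing the packaged studies therefore
demonstrates correctness of the solvers and of the linearized pipeline
under the stated conditions, not field performance on hardware data. The
published tank-study tables are bundled as printed values for arithmetic
validation only; reproducing their absolute metric levels is out of reach
by construction, since the underlying phantom geometries exist only as
figures.

Known limitations: 2D quasi-static real conductivity only (no complex
admittivity or frequency sweep); linearized difference imaging only (no
nonlinear Gauss–Newton with Jacobian reassembly); global SSIM rather than
windowed; the convergence ripple of momentum methods is not smoothed by
restarts, matching the published algorithm.
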