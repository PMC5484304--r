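---
title: "Sequence-level PTx shimming: model, solvers, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-level PTx shimming: model, solvers, and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptxshim)
```

## The physical model

An RF pulse is a low-level waveform `p(t)` in field units (μT). At position
**r** the transmit chain scales it by a dimensionless, complex sensitivity
`S(r)`, and on an n-channel array the total excitation is the
shim-weighted sum over channels. The on-resonance flip angle is the time
integral of the field, which factorizes into pulse-shape and spatial parts:

$$\theta(\mathbf r) = \delta_1\, p_{\max}\, \tau\, \gamma
  \sum_j S_j(\mathbf r)\, w_j ,$$

where `delta1` is the pulse's *relative duration* (its area divided by that
of a block pulse with the same peak and duration) and `p_max` the peak
amplitude. A second shape factor, the *relative energy* `delta2`, governs
power: the sequence's power duty cycle is `Delta = delta2 * tau / TR`. For
any peak-normalized nonnegative envelope the Cauchy–Schwarz inequality
forces `delta1^2 <= delta2 <= delta1`; both factors are computed by
trapezoidal quadrature on the uniform sample grid (smooth envelopes reach
the closed forms for block and half-sine pulses to 1e-6 by ~2000 intervals).
Pulses may instead be named presets carrying stored factors; the default
`"gaussian"` preset (δ₁ = 0.53, δ₂ = 0.40) represents a vendor-style
truncated Gaussian whose exact truncation is not reproducible analytically,
so its measured factors are stored rather than recomputed. Slice-profile
changes with flip angle are deliberately ignored: for the short, simple
excitation pulses used with bSSFP this affects only the profile edges, not
the center-of-slice flip angle being optimized.

Units: milliseconds and μT at every interface; seconds internally wherever
γ (267.522 rad s⁻¹ μT⁻¹ for ¹H, configurable) enters a product.

## Constraints as functions of the operating point

Four constraint families apply to the shim vector, and all four move when
the operating point `(tau, TR)` moves:

* **timing**: `TR >= max(tau + t_enc, tau / delta0)` — the pulse and the
  spatial-encoding gradients (`t_enc`, default 1.7 ms) must fit into TR,
  and the amplifier gating duty cycle is capped at `delta0` (default 0.5);
* **peak power**: `|w_j| <= sqrt(P_peak/A)/p_max` with `A` (W/μT², default
  2.5) the chain gain and `P_peak` = 1 kW per channel — since
  `p_max ∝ θ0/(δ1 γ τ)`, shorter pulses tighten this cap;
* **average power**: the same with `P_av = 100` W and the duty cycle:
  `|w_j| <= sqrt(P_av/(A Δ))/p_max`;
* **SAR**: `w* Q_i w · B1_achieved² · Δ <= lSAR_max` over the local 10 g
  Q-matrices (IEC normal mode, 10 W/kg) and the analogous whole-body bound
  (2 W/kg). `B1_achieved = p_max · mean|S w_quad|` calibrates the Q-matrix
  scale to the measured maps: the model fields are normalized so that
  quadrature drive produces mean B1+ of exactly 1 μT over the ROI, and the
  same spatial mean measured in vivo ties the two together.

`build_constraints()` assembles all caps at a given `(tau, TR)`; they are
rebuilt on every move of the outer search.

## Inner problems and the convex engine

Three inner solvers share the constraint set:

* `solve_quadrature()` scales the fixed birdcage mode `w = d·w_quad`; the
  optimum is closed-form (the zero-bias scale, clipped by whichever cap
  binds first) and cannot change the flip-angle homogeneity.
* `solve_min_bias()` drives the *mean* ROI flip angle to target,
  `|mean(z* ∘ S_θ w) − θ0|²`, leaving the variance free.
* `solve_mse()` minimizes the magnitude least squares cost
  `‖|S_θ w| − θ0‖²`, which decomposes into squared bias plus variance and
  therefore also homogenizes.

The magnitude costs are nonconvex; both PTx solvers use the variable
exchange method: fix a unit-modulus auxiliary phase `z`, solve the convex
problem `‖S_θ w − θ0 ∘ z‖²` under the caps, then set `z` to the phase of
the achieved excitation, and repeat until the cost changes by less than
1e-4 relative or 20 exchanges. The joint cost is nonincreasing across
exchanges. Because the exchange can stall in local minima, it is run from a
small deterministic set of starts — the quadrature-mode phase, a flat
phase, the dominant-singular-vector phase, and the two strongest single
channels — and the best run is kept. A final global rescale (optimal for
each objective, applied only if it stays feasible) removes the last-ulp
slack an interior-point solution necessarily carries, so an unconstrained
minimum-bias solve reports a bias of exactly zero.

The convex subproblem is a QCQP in the real `2n` representation
(`x = [Re w; Im w]`): quadratic objective, per-channel modulus caps and PSD
quadratic SAR caps. It is solved by a primal log-barrier interior-point
method with Newton centering. Design points: `w = 0` is strictly feasible
whenever all caps are positive, so no phase-I is needed and genuinely
infeasible inputs (a nonpositive cap) return a typed `"infeasible"` status
rather than an error, letting the outer loop absorb them into a large
finite cost (10⁶). The modulus caps contribute a full-rank barrier Hessian
term, so Newton steps stay well posed even for the rank-2 minimum-bias
objective. Constraints are rescaled to `x'Ax <= 1`, the objective to order
one; the barrier parameter grows by 20× per centering stage until the
duality gap `m/t` is below 1e-9, and per-constraint work is batched into
matrix products so several hundred SAR matrices remain fast.

## SAR model and VOP compression

`build_q_matrices()` forms, per voxel,
`Q[j,k] = σ/(2ρ) conj(E_j)·E_k`, then averages over the smallest centered
cubic neighborhood reaching 10 g (a square of side `s` voxels in-plane,
extruded to `s` slices through-plane; the extrusion cancels in the
power/mass ratio). The whole-body matrix is the mass-weighted mean. All
matrices are Hermitian PSD by construction.

`compress_vops()` reduces the local set by greedy domination: visiting
candidates in decreasing spectral norm, a candidate `Q` is dropped if some
retained VOP `V` satisfies `V + εZ − Q ⪰ 0`, where `Z` is the *arithmetic
mean* of the set. The stored matrices are the inflated `V + εZ`, so the
VOP-set maximum never underestimates the true maximum, and since
`w*Zw = mean_i w*Q_i w ≤ max_i w*Q_i w` the overestimation is at most the
fraction `ε` of the true maximum for *every* shim. (An identity-scaled `Z`
was tried first and rejected: its overestimate grows with `|w|²` rather
than with the SAR level, which is exactly wrong for power-limited spread
shims.) The default working bound is `ε = 0.03`; on the default phantom
this keeps ~350 of ~1400 matrices and realizes ≲0.3% overestimation, so a
solution driven to the working cap recomputes on the full set within a
fraction of a percent of the limit. Final SAR is always reported from the
full uncompressed set when it is available.

## Outer search

The outer cost is `TR_min(τ) + penalty(bias)` with `TR_min` the timing
floor above. The penalty is the squared percent bias — always, for
minimum-bias and quadrature runs; only beyond an accepted ±5% for MSE runs
(a 5% bias at θ0 = 45° is 2.25°, an accepted trade for shorter TR). The
absolute value of the bias is penalized; the bias at short τ is always a
shortfall (negative), so the distinction only matters pathologically.

The search over τ is derivative-free on `log τ` within a [0.2, 5] ms
bracket: it starts at the closed-form quadrature feasibility boundary
(bisection on cap margins, no inner solves — PTx optima lie at or below
it), brackets the minimum by geometric descent (ratio 0.62), then refines
with a deterministic two-point Nelder–Mead simplex (default 10 iterations,
relative tolerance 1e-3, one restart from a perturbed point if the first
run ends on a bracket edge). In accelerated mode (default) the auxiliary
phase `z` is computed by full variable exchange once, at the first
evaluation, and reused for every subsequent τ — the final solution is
re-solved with full exchange. Cost units: TR in ms against squared-percent
bias with weight 1, so a 5% violation (penalty 25) dwarfs any attainable
TR gain; the weight is exposed (`penalty_weight`) for other regimes.

## What the synthetic phantom emulates — and what it does not

`generate_phantom()` stands in for an electromagnetic simulation of a
loaded body coil. It emulates, with analytic kernels on a 64×64 grid of
5 mm voxels: an eight-channel circular array (radius 150 mm) around an
elliptical torso slice (semi-axes 130×85 mm, 0.5 S/m, 1000 kg/m³); a
distance-decaying per-channel field with a phase roll (2π over ~30 cm)
that makes quadrature drive constructively interfere at the center — the
high-field B1+ center-brightening; a sharper near-field kernel (∝1/d²,
decay length 0.07 m) for the surrogate electric field, so deposition is
peripheral; an off-axis conductive inclusion near the lower-right surface
that localizes the quadrature SAR hotspot away from the phantom axis; a
seeded ±3% per-channel gain/phase jitter; and a myocardium-like annulus
ROI around an excluded blood-pool disc, as flow-corrupted voxels are
excluded from measured cardiac maps. The surrogate electric-field
amplitude (`e_scale = 2.42`) was fixed once so that a quadrature 45° bSSFP
protocol is limited by the 10 W/kg local SAR cap at τ in the 1–2 ms range,
with the local-to-whole-body SAR ratio of a loaded 3 T body coil — the
regime in which sequence-level optimization is interesting. At these
defaults the whole 64×64 pipeline (fields, Q-matrices, VOPs, three
sequence optimizations) runs in well under a minute on one CPU, which is
the problem size the test-suite and the acceptance script use.

The generator does **not** model full-wave electromagnetics, coil
tuning/matching/decoupling, 3D anatomy, or inter-subject variability
beyond its seed; passing tests on it show the optimizer's contracts
(feasibility, activity of constraints, orderings, scalings), not clinical
magnitudes. TR reductions and homogeneity gains on this phantom are
analogues of the in vivo effect, with phantom-specific sizes.

## Numerical choices and degenerate inputs

* Degenerate ROIs (fewer voxels than channels) are allowed with a warning;
  a single-voxel ROI still solves.
* Voxels where the excitation is exactly zero get a unit auxiliary phase.
* The 10 g averaging square is clipped at the grid edge and grown until
  the mass target is met; a phantom lighter than the target is an error.
* VOP domination tests use an eigenvalue tolerance of 1e-9 relative to the
  largest spectral norm; ties in the visiting order break by original
  index, so compression is deterministic.
* Map containers store doubles as base64 IEEE bytes inside JSON: decimal
  JSON loses the last ulp, and bit-exact round trips make container
  equality a meaningful test.
* Solutions are re-verified against the uncompressed Q set within 1e-6
  relative before being reported.

## Known limitations

Whether the whole-body SAR bound ever activates depends entirely on the
load geometry; the inner solver tolerance and both SAR bounds are config
fields. Temperature-based (rather than SAR-based) constraints, multi-slice
joint shimming, phase-only shimming, and slice-selective or spokes pulse
design are out of scope. The quadrature comparison point is itself
optimized (same outer search, scalar inner problem); comparisons against a
fixed default protocol would look more favorable and are deliberately not
made.
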