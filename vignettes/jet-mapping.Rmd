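---
title: "Mapping neuron traces with derivative information: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neuron traces with derivative information: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jetmap)
```

## The problem

Digital neuron reconstructions are stored as sequences of 3D sample points
("knots"), most commonly in the SWC format, and are interpreted as trees of
piecewise linear curves. To compare morphologies across brains, traces are
mapped into a common coordinate system by a registration transformation
$\varphi : \mathbb{R}^3 \to \mathbb{R}^3$, in practice a diffeomorphism
composed of an affine part and a nonlinear deformation represented as a
gridded displacement field $\varphi(x) = x + u(x)$.

Standard pipelines perform what we call *zeroth-order mapping*: only the
knot positions are transformed, and the mapped trace is read as the
polyline through $\varphi(x_i)$. When $\varphi$ is nonlinear this bends the
true image of each line segment away from the chord between its mapped
endpoints, so the mapped morphology depends on how the curve happened to be
sampled.

## The jet action

jetmap treats a sampled curve as a sequence of *jets*: the position
together with the first $k$ derivatives of the underlying curve at each
knot parameter $t_i$. A diffeomorphism acts naturally on jets; for
$k \le 2$,

$$
(x_0, x_1, x_2) \;\longmapsto\;
\bigl(\varphi(x_0),\; D\varphi(x_0)\,x_1,\;
      D\varphi(x_0)\,x_2 + D^2\varphi(x_0)[x_1, x_1]\bigr),
$$

with timestamps unchanged. This is a genuine group action: the identity
map fixes every jet sequence, and applying a composition equals applying
the factors in succession (`apply_jet_action()` is tested against both
axioms numerically in the test suite).

After the action, the mapped curve is reconstructed as a spline of order
$2k + 1$ over the **original** arc-length parameters: a piecewise linear
spline for $k = 0$, and for $k = 1$ a cubic Hermite spline whose piece on
$[t_i, t_{i+1}]$ matches four constraints — mapped positions at both knots,
the mapped *right* one-sided derivative at $t_i$ and the mapped *left*
one-sided derivative at $t_{i+1}$. One-sided derivatives are the chord
slopes of the source polyline, which is the exact derivative information a
piecewise linear trace possesses; as a consequence the first-order spline
need not be differentiable at knots, and both orders reproduce the input
exactly under affine maps.

Keeping the original parameters (rather than re-parameterizing by mapped
arc length) is deliberate: the jet action preserves timestamps, and it is
what makes a parameter-matched error $\max_t |f(t) - g(t)|$, with
$f = \varphi \circ c$, well defined. Order-2 jets are implemented for the
action itself, but curve-level second derivatives are only accepted from
analytic curve specifications — estimating them from a first-order spline
is not meaningful, since they vanish between knots and are undefined at
them.

### Junctions

Neuron trees are decomposed into non-branching branches by recursively
removing the root-to-leaf path of maximal arc length (ties broken toward
the smallest leaf id, for determinism). Junction knots are *duplicated*:
they terminate or begin every incident branch, so each branch is a
standalone curve and the branch segments partition the tree's edge set.
Branches are mapped independently with their own one-sided derivatives;
at a junction the mapped branches agree in position but not necessarily in
derivative, which mirrors the non-differentiability of the source trace at
bifurcations.

## Error bounds

For an arc-length-parameterized curve with maximal knot gap $\delta$, the
package provides three a priori bounds on the parameter-matched deviation
between $f = \varphi \circ c$ and the reconstructed spline $g$:

* **Piecewise-$C^1$ bound** (`bound_c1`): per segment,
  $C\,\delta_i \max |D\varphi(c(t))|$ with default $C = \sqrt{3}$. Valid for
  any piecewise differentiable curve, but it does not vanish for the
  identity map.
* **Piecewise-linear bound** (`bound_piecewise_linear`): per segment,
  $\tfrac12 \max |D\varphi(c(t)) - I|\,\delta_i + |\epsilon_i -
  \epsilon_{i-1}|$ with $\epsilon_i = c(t_i) - \varphi(c(t_i))$. This one
  tends to zero as $\varphi$ tends to the identity, and is linear in the
  deformation for small deformations.
* **Smooth-curve bounds** (`bound_smooth_orders`): for $C^4$ curves and
  transforms, with $h = \delta/2$ and $M_k$ the largest coordinate-wise
  $k$-th derivative of $f$ ($M_4$ over the interval, $M_3, M_2$ at knots),
  the first-order bound is $\tfrac{\sqrt3}{4!} M_4 h^4$ — the classical
  per-coordinate cubic Hermite bound $M_4 \delta^4/384$ combined across
  three coordinates — and the zeroth-order bound adds
  $\tfrac{\sqrt3}{2}(M_3 h^3 + M_2 h^2)$. The first-order bound is
  structurally never larger, and the two decay as $O(\delta^4)$ versus
  $O(\delta^2)$, which the convergence tests confirm empirically with
  log–log slopes within $\pm 0.5$ of 4 and 2.

The prefactors $C$, $\sqrt3/4!$ and $\sqrt3/2$ are exposed as arguments:
they are conventional Lipschitz/Hermite constants, and every validity and
ordering property asserted by the test suite holds for any constants at
least this large. Maxima over continua are estimated by dense sampling:
Jacobians along segments at steps of $\min(0.5\ \mu m,\ \delta_i/50)$, and
derivatives of $f$ by central finite differences with step
$h_{fd} = 0.05\ \mu m$ (chosen so that fourth-difference round-off,
$\sim \varepsilon |f| / h_{fd}^4$, stays orders of magnitude below the
derivative scales of micron-amplitude curves).

Applying the piecewise-linear bound to a single straight segment of length
$L$ anywhere in a transform's domain gives a length-linear form
$a L + b$ with $a = \tfrac12 \sup |D\varphi - I|$ and
$b = 2 \sup |u|$ (`affine_bound_in_length`; the intercept uses the
triangle inequality on $|\epsilon_i - \epsilon_{i-1}|$). Its corollary
$L^*(e) = \max\{L \in \mathbb{N} : aL + b \le e\}$ is the coarsest
admissible sampling of a straight branch under an error budget $e$. For
the registration constants $a = 0.011/\mu m$, $b = 0.022\,\mu m$ this
yields bounds of $0.132\,\mu m$ at $L = 10\,\mu m$, $11.022\,\mu m$ at
$L = 1\,mm$, and $L^*(1\,\mu m) = 88\,\mu m$.

## Evaluation protocol

Ground truth for a mapped branch is its *dense reference*: the piecewise
linear branch resampled at arc-length steps of at most 2 µm (original
knots retained), every point mapped through $\varphi$. Mapped splines are
sampled on the same parameter grid, and curves are compared with the
discrete Fréchet distance — the minimax distance over monotone couplings
of the two point sequences, computed by the standard dynamic program (in
compiled code; verified against exhaustive coupling enumeration on small
instances). Discrete Fréchet distance upper-bounds the continuous Fréchet
distance, and the parameter-matched deviation upper-bounds both.

`evaluate_mapping` follows the downsampling protocol used to study coarse
traces: the ground truth is always built from the *original* branch; the
branch handed to the two mapping orders is optionally downsampled by
retaining both end knots and every one-out-of-$p$ knots in between
($p = 100$ for the headline comparison). Both orders therefore receive the
same information — the downsampled knot positions. The summary reports the
median error difference (order 0 minus order 1) and the Pearson
correlation between error difference and mean sampling period, tested at
$\alpha = 0.01$. The per-branch "average sampling period" is the *mean*
segment length (the choice between mean and median is immaterial for the
qualitative result; we document the mean).

## The synthetic generator

All validation runs on synthetic data with known smoothness:

* **Curves** (`make_curve`): straight lines, unit-speed helices,
  sinusoids, and seeded random-Fourier curves whose harmonic amplitudes
  decay as $1/m^2$, giving smooth curves with bounded derivatives and
  closed-form first and second derivatives. Regularity $|\dot c| > 0$ is
  verified by sampling and violating specs are rejected.
* **Deformations** (`make_field`, `bump_transform`): sums of radial
  Gaussian bumps, cyclic sinusoids, or small linear perturbations. Each
  family has a closed-form bound on $\sup |Du|$ (for one bump of amplitude
  $a$ and scale $\sigma$, the maximal gradient is $a/(\sigma\sqrt{e})$),
  and specs with $\sup|Du| \ge 1$ are rejected, so $x + u(x)$ is a
  diffeomorphism by construction rather than by post-hoc checking.
  Generated grids additionally pass `validate_diffeomorphism` on a finer
  verification grid.

Default scales mimic the regime of whole-brain registration applied to
single-neuron traces: displacement fields sampled on 100 µm grids
(registration is computed at the scale of brain regions), deformation
length scale $\sigma = 300\,\mu m$, three bumps of 45 µm amplitude
($\sup|Du| \approx 0.27$, a moderate orientation-preserving warp), and
curve knot spacing around 10 µm (traces are sampled at the
tens-of-microns scale). Evaluation curves are about 2.5 mm long so that
downsampling by 100 still retains interior knots.

What the generator does *not* emulate: imaging noise, tracing errors,
radius profiles, knot-spacing heterogeneity along a branch, and the
spatial statistics of real brain registrations (our bump fields are
isotropic and stationary in character). Passing tests therefore establish
correctness of the mapping machinery and validity of the bounds under
certified diffeomorphisms — not performance claims about any particular
real registration.

## What the comparisons show

At native sampling (~10 µm knots under a deformation varying at the
hundreds-of-microns scale) the registration barely bends individual
segments and the two orders are nearly indistinguishable: the median
absolute Fréchet difference across seeds is a small fraction of a micron.
After 100-fold downsampling, segments become comparable in length to the
deformation scale and first-order mapping is more accurate *in the
median* — but the effect is weak, with wide per-curve variability: across
regime scans (curve amplitudes 30–120 µm, $\sigma$ 300–500 µm) medians
are consistently positive while only roughly 55–60% of individual curves
favor first order. Two mechanisms compete: the mapped one-sided
derivatives correct the spline near knots, but after heavy downsampling
the chord slope is a secant over ~1 mm and approximates the underlying
tangent only where the curve is straight at that scale. The advantage is
systematic where branches are straight over long stretches, and noisy
where they curve below the segment scale.

## Numerical choices and degenerate inputs

* Displacement-field Jacobians are the analytic gradient of the trilinear
  interpolant — exact within each grid cell; points on a cell face use
  the gradient of the cell with larger indices (determinism at faces).
  The within-cell Hessian of a trilinear interpolant carries mixed
  partials only. Points outside the grid raise an error unless
  zero-displacement padding is requested explicitly, because silent
  extrapolation corrupts mappings.
* The generic finite-difference fallback for Jacobians uses central
  differences with step $\max(10^{-3}\,\mu m,\ 10^{-6}|x|)$, appropriate
  for micron-scale coordinates.
* Duplicate consecutive knots (present in real SWC exports) are dropped
  with a warning, since regularity is required throughout; a curve that is
  entirely one repeated point is an error.
* Downsampling retains interior knots at indices $\equiv 0 \pmod p$
  (0-based): the retention rule fixes both end knots, and this phase
  convention makes the operation deterministic.
* Ties in the longest root-to-leaf path are broken toward the smallest
  leaf id.
* Mapped SWC output stores knot positions only (the format has no
  derivative fields); one-sided mapped derivatives are emitted as a
  sidecar CSV, and densely resampled output inherits the type code and
  radius of the preceding original knot — radius geometry is out of
  scope.
* The displacement-field container on disk is JSON (`read_transform` /
  `write_transform`): origin, spacing, dimensions, and the flattened
  displacement array. Fields at validation scale are small, the format is
  self-describing, and plain text keeps fixtures diff-able.

## Problem sizes

The shipped validation suite uses problem sizes chosen to exercise every
regime while staying desk-scale: bound-validity sweeps run 200 randomized
curve/field cases on curves of 60–140 µm with 4–12 µm knot spacing; the
mapping-order comparison runs 50 seeds of 2.5 mm curves; convergence
studies halve knot spacing over 16–2 µm. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at
comparable sizes under a caller-supplied seed.

## Limitations

* Jet orders above 2 (general Faà di Bruno machinery) are not
  implemented; order 2 requires analytic curve input.
* Transforms are not inverted and registrations are not computed here;
  the package consumes transformations produced elsewhere.
* The continuous Fréchet distance is not computed; the discrete variant
  on 2 µm samplings is the evaluation metric.
* The bound constants are conservative reconstructions of classical
  interpolation constants; tightness is not analyzed.
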