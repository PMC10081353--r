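# jetmap

Derivative-preserving mapping of neuron traces through nonlinear
coordinate transformations.

## The problem

Single-neuron reconstructions are stored as sequences of 3D sample points
(SWC format) and interpreted as trees of piecewise linear curves. To build
atlases of neuron morphology, traces from individual brains are mapped
into a common coordinate system by a registration transformation
φ: ℝ³ → ℝ³ — typically an affine map composed with a nonlinear
deformation given as a gridded displacement field φ(x) = x + u(x).
Standard pipelines transform only the knot positions (*zeroth-order
mapping*), which ignores how φ bends the line segments between knots: the
mapped morphology then depends on how the neuron happened to be sampled
during tracing.

jetmap is for researchers mapping traced neurons between coordinate
systems who want to (i) preserve derivative information through the
transformation, and (ii) know a priori how much error position-only
mapping can introduce at their sampling density.

## The method

A sampled curve is extended to a sequence of *jets* — position plus the
first k derivatives at each knot parameter tᵢ. A diffeomorphism acts on
jets through its derivatives; for k ≤ 2:

    x0 ↦ φ(x0),   x1 ↦ Dφ(x0) x1,   x2 ↦ Dφ(x0) x2 + D²φ(x0)[x1, x1]

with timestamps unchanged (a genuine group action). The mapped curve is
reconstructed as a spline of order 2k + 1 over the original arc-length
parameters: piecewise linear for k = 0; for k = 1 a cubic Hermite spline
matching, on each segment, the mapped positions at both knots and the
mapped one-sided chord-slope derivatives (four constraints per segment).
First-order mapping converges to the true transformed curve at O(δ⁴) in
the knot spacing δ, versus O(δ²) for zeroth-order mapping, and both are
exact under affine maps.

The package also implements the matching error bounds — a piecewise-C¹
bound C δ max|Dφ|, a piecewise-linear bound
½ max|Dφ − I| δᵢ + |εᵢ − εᵢ₋₁| that vanishes as φ → id, comparable
O(δ⁴)/O(δ²) bounds for smooth curves, and a length-linear corollary
a·L + b giving the coarsest admissible sampling L*(e) of a straight
branch under an error budget e — plus discrete Fréchet distance for
evaluation, gridded displacement-field transforms with analytic trilinear
Jacobians, diffeomorphism validation, field statistics, and a synthetic
generator of regular curves and certified-diffeomorphic deformation
fields. See the vignette `vignettes/jet-mapping.Rmd` for the full
methods account.

## Worked example

```r
library(jetmap)

# a coarsely sampled smooth curve (25-um knots on a helix)
cur    <- make_curve("helix", length = 200, radius = 30, pitch = 15)
branch <- sample_knots(cur, 25)

# a smooth nonlinear warp, a diffeomorphism by construction
warp <- bump_transform(centers    = rbind(c(40, 10, 20), c(-20, -15, 60)),
                       amplitudes = c(20, 15),
                       directions = rbind(c(0, 1, 0), c(1, 0, 0)), sigma = 80)

# map with both orders and compare to the densely mapped ground truth
truth <- map_dense_reference(branch, warp, spacing = 2)
f0 <- discrete_frechet(sample_curve(map_zeroth(branch, warp), 2), truth)$distance
f1 <- discrete_frechet(sample_curve(map_first(branch, warp),  2), truth)$distance
cat(sprintf("order 0 = %.3f um, order 1 = %.3f um\n", f0, f1))
#> order 0 = 0.249 um, order 1 = 0.001 um

# the a priori bound dominates the observed deviation
rep <- bound_piecewise_linear(branch, warp)
cat(sprintf("observed %.3f um <= bound %.3f um\n",
            mapping_error(branch, warp, 0L), rep$overall))
#> observed 0.249 um <= bound 4.716 um

# length-linear bound for a registration with a = 0.011/um, b = 0.022 um
length_bound_value(0.011, 0.022, 10)    #> 0.132
length_bound_value(0.011, 0.022, 1000)  #> 11.022
max_segment_length(0.011, 0.022, 1)     #> 88
```

At a 25-µm sampling period the position-only mapping deviates a quarter
micron from the true transformed curve while first-order mapping is two
orders of magnitude closer; the piecewise-linear bound (4.7 µm) is a
worst-case certificate over the branch. The length-linear constants say a
straight branch under that registration can be sampled every 88 µm while
keeping zeroth-order mapping error below 1 µm.

Whole neurons work the same way through the tree-level API
(`read_swc`, `decompose_to_branches`, `map_neuron`, `evaluate_mapping`,
`compute_bounds`), and a thin command-line front end with
`map` / `evaluate` / `bounds` / `simulate` subcommands is installed at
`inst/cli/jetmap.R`.

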