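---
title: "Discrete tomographic reconstruction as quadratic binary optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete tomographic reconstruction as quadratic binary optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annealtomo)
```

## The problem

Emission tomography measures line integrals of an activity distribution:
a sinogram `y` related to the image `x` by a linear system `y = M x`,
where `M` is the system matrix of the scanner geometry. Reconstruction —
recovering `x` from `y` — is an ill-conditioned inverse problem: `M` is
singular, often underdetermined, and the data are noisy.

Discrete tomography restricts the pixel values to a small set of gray
levels (in the simplest case binary, `x_i ∈ {0, 1}`). That restriction
turns reconstruction into combinatorial optimization, which is exactly the
problem class that annealing samplers — classical or quantum — address.
This package builds the whole experimental loop around that idea: generate
a discrete phantom, simulate its sinogram, pose least-squares
reconstruction as a quadratic binary model, solve it by sampling, and
benchmark against the standard classical reconstructions.

## From least squares to QUBO

The reconstruction objective is

$$H(x) = \lVert Mx - y\rVert^2
       = x^\top M^\top M x - 2\, y^\top M x + y^\top y .$$

For binary variables $x_i^2 = x_i$, so the diagonal of $M^\top M$ folds
into the linear bias and the objective is exactly a QUBO:

* linear bias: $\mathrm{linear}_i = (M^\top M)_{ii} - 2 (M^\top y)_i$,
* coupler ($i < j$): $\mathrm{coupler}_{ij} = 2 (M^\top M)_{ij}$
  (the cross term counts both orders),
* constant offset: $y^\top y$.

The factor of two on the couplers and the folded diagonal are forced by
the requirement that the model energy of *every* binary assignment equal
the squared residual — the package's governing contract, tested by full
enumeration. The offset is kept inside the model so a reported energy is
directly interpretable: energy 0 means the sample reproduces the data
exactly.

`qubo_to_ising()` applies the exact substitution $x = (s+1)/2$; the two
formulations are energy-identical over all assignments.

For gray-level images (`levels > 2`) the package builds a bounded-integer
quadratic model. Since $x_i^2 \ne x_i$ for integers, the squared-term
coefficients $(M^\top M)_{ii}$ are stored explicitly rather than folded
into the linear part; off-diagonal pairs are stored once with the doubled
coefficient. `encode_integer_as_binary()` then expands every pixel into
`R` bits with weights $2^0 \dots 2^{R-1}$, giving $N^2 R$ fully coupled
binary variables — the qubit count a hardware annealer would need.

## Forward model and conventions

The projector is rotate-then-sum: for a view at angle $\theta$ the image
is rotated about its center $((N-1)/2$, 0-based$)$ with bilinear
interpolation and zero padding, then summed vertically into $N$ bins.
Angles are equally spaced on $[0°, 180°)$; the $0°$ view looks at the
image from the top and increasing angles rotate clockwise. Rotation is a
fixed sparse linear map, so each view is one sparse matrix and the dense
system matrix is assembled from exactly the same operators that
`project()` uses — `M %*% vec_image(x)` equals the projected sinogram to
machine precision by construction, not by approximation. Images are
vectorized row-major from the top-left pixel everywhere.

This rotate-and-sum discretization (rather than exact ray tracing) was
chosen deliberately: it keeps the projector linear, makes the
matrix/operator consistency exact, and matches the convention of the
widely used image-processing Radon implementations, so the classical
baselines and the QUBO path consume one and the same forward model.

### Count noise

Low-count emission data are dominated by Poisson noise. The package uses
a deliberately simple signal-dependent surrogate: for each projection view
independently, every pixel of the ground-truth image is perturbed by an
integer offset drawn uniformly from $\{-1, 0, 1\}$ where the pixel is
nonzero and from $\{0, 1\}$ where it is zero, and that perturbed image is
projected for that view only. The perturbed image is non-negative by
construction, each view sees an independent noise realization, and —
because the noise enters the object, not the sinogram — it also breaks the
inverse crime. This is a surrogate, not Poisson sampling: its variance
does not scale with intensity beyond the zero/nonzero distinction.

### Avoiding the inverse crime

Testing a reconstruction against data generated by the very same discrete
operator is the "inverse crime". The package avoids it by simulating on a
4× finer grid (pixel-replicated phantom, 128 bins for a 32-pixel target)
and rebinning: groups of 4 adjacent bins are averaged and multiplied by
`1/factor`, which converts fine-grid line integrals into coarse-pixel
units (a ray through the refined grid crosses `factor` times more
samples). The rebinned sinogram agrees with the direct coarse projection
to well under 5% of the sinogram maximum — small but nonzero model
mismatch, which is the point.

## Samplers

* `solve_exact()` enumerates all $2^n$ assignments (refusing above 22
  variables) and returns every global minimizer plus up to 100 next-best
  states. It is the ground-truth oracle that every stochastic result is
  audited against.
* `solve_simulated_annealing()` is the classical stand-in for annealing
  hardware: independent single-spin-flip Metropolis restarts over a
  geometric inverse-temperature ladder from $\beta = 1/\Delta E_{\max}$
  to $1000/\Delta E_{\max}$, where $\Delta E_{\max}$ bounds the largest
  single-flip energy change, followed by zero-temperature sweeps until no
  flip improves. The kernel is compiled code with its own deterministic
  PRNG, so results are bitwise reproducible per seed. Occurrence counts
  aggregate identical samples, and all stored energies are re-evaluated
  in R against the model.
* `solve_qpu_stub()` is a disabled-by-default interface stub for physical
  hardware behind the same sample-set contract; no test or example ever
  needs network access. `scale_chain_strength()` (the largest absolute
  coefficient) is supplied to it, the usual relative chain-strength
  convention for minor-embedded annealers.

Tie-breaking everywhere is lexicographic on the bit tuple, purely for
reproducibility. The `time_limit` argument of remote hybrid solvers is
accepted and logged but deliberately not emulated — the hybrid search
heuristic is proprietary and unpublished; energy, which any sampler
exposes, is the auditable quantity.

## Classical baselines

All baselines consume the identical sinogram and geometry as the QUBO
path — one forward model, many inverters — and their continuous outputs
pass through a shared discretization (clip to `[0, levels-1]`, round half
up) before comparison.

* **FBP**: ramp (Ram-Lak) filtering per view in the frequency domain
  (band-limited real-space kernel, zero-padded to a power of two) and
  bilinear backprojection with the same angle conventions as the
  projector. Matrix-free.
* **SART**: per-view additive updates with row/column-sum normalization
  and relaxation $\lambda = 0.5$ (exposed; the usual stable default).
* **DART**: seeds from 10 SART sweeps, then two segmentation cycles:
  discretize, mark every pixel with a 4-neighbor of a different level as
  free, fix the rest, subtract the fixed pixels' forward projection from
  the data, and re-solve the free pixels with one SART sweep. Canonical
  DART draws a random fraction of additional free pixels; this
  implementation is fully deterministic instead, so paired comparisons
  (DART vs its own discretized SART seed) are exactly reproducible. That
  is a deliberate deviation, and it makes the variant slightly
  conservative on images with large homogeneous errors.
* **Truncated pseudoinverse**: SVD of `M` with singular values below
  `cutoff` times the largest zeroed (plus a `1e-12` relative floor for the
  exact zeros of the singular tomographic matrix). The cutoff is
  interpreted relative to the largest singular value — the common library
  convention; 0.001 is the noise-robust setting used in the noisy and
  model-mismatch experiments.

## Metrics

RMSE is the root of the mean squared pixel difference. SSIM follows the
standard windowed formulation with uniform windows, sample covariances,
and stabilizers $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$ on data range
$L = \mathrm{levels} - 1$; it is computed over all fully-contained
windows and matches the reference scikit-image implementation to
$10^{-6}$ on random pairs (frozen-value test). The window is 7×7 by
default and drops to 3×3 when the image is smaller than 7.

## Phantoms

The four binary structures are procedural: thresholded smoothed Gaussian
noise (`foam`), recursive branching strokes (`tree`), 6-fold mirrored
random rays (`snowflake`), and disjoint filled disks (`molecule`). They
are drawn on a 4× finer grid, block-mean downsampled, and thresholded at
0.5 (ties to 1; if the midpoint threshold ever collapses a very small
image to a single class, a median split is used instead so binary
phantoms always contain both classes). Generating fine and downsampling
keeps the same seed's object recognizable across the size sweep, the same
workflow used to derive the smaller study images from the 32×32 ones.
The Shepp–Logan phantom is the standard modified ellipse table scaled to
`[0, levels-1]` and rounded half up. `digit` images are soft
Bezier-stroke blobs normalized to the requested bit range; with
`levels = 17` they span `[0, 16]`, matching the value range of the
classic 8×8 handwritten-digit rasters they emulate. (A "4-bit" range is
nominally 0–15; the digit data these images mimic actually use 17 values,
so the level count is an explicit argument rather than a hidden
assumption.)

These generators emulate the *character* of the study images — frequency
variety, connectedness, symmetry — not any specific pixel content, and no
anatomical realism or attenuation is attempted. Passing tests therefore
demonstrate correctness of the optimization and reconstruction machinery
on representative discrete structures, not clinical performance.

## Experiments and problem sizes

`run_experiment()` packages five study designs: `size_sweep` (binary,
N = 4–32, fully determined V = N), `integer_sweep` (quantized
Shepp–Logan), `noise` (8×8 digits, per-view count noise, truncated PI at
0.001), `few_view` (N = 32 from 2, 4, and 32 views), and `inverse_crime`
(128→32 rebinned acquisition). Defaults run each design at desk scale —
e.g. two seeds and `reads = 20`, `sweeps = 500` — chosen so a full design
completes in minutes on one core while leaving the annealer's success on
fully determined binary problems comfortably reproducible; all knobs are
arguments.

## Numerical choices and known limitations

* **SA effort.** Fully determined binary problems up to 32×32 (1024
  variables) reach energy 0 (exact data agreement) reliably with as few
  as 6 reads × 300 sweeps, thanks to the greedy tail of the schedule.
* **Integer encodings are harder.** The positional bit encoding gives the
  high-order bits couplings 256× stronger than the low-order ones; the
  single-flip landscape is correspondingly rugged, and on 8×8, 17-level
  problems the annealer typically stalls at a small positive residual
  where a hybrid large-neighborhood solver would continue. Decreasing
  energy does not always decrease pixel RMSE in that regime. This is a
  faithful property of plain simulated annealing on such encodings and is
  surfaced, not hidden, by the benchmarks.
* **Homogeneous regions.** Like all least-squares discrete
  reconstructions without smoothness priors, integer reconstructions
  scatter isolated errors in flat regions; adding a regularization term
  to the objective is a natural extension and deliberately out of scope.
* **Degenerate inputs.** Zero-norm SART rows/columns are skipped; DART
  returns the current discrete image if no pixel is free; the exact
  solver retains at most 512 candidate states per problem (ties beyond
  that are not reported); couplers below `1e-12` in magnitude are dropped
  when building models.
* **Mass consistency** across views holds to ~1% only for objects inside
  the inscribed circle; corners leave the rotated grid at oblique angles.
  Study phantoms occupy the full square, which is fine for
  reconstruction (the same operator generates and inverts the data) but
  means per-view sums are not exactly conserved.
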