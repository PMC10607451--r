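# annealtomo

Discrete tomographic reconstruction posed as quadratic binary
optimization, with annealing samplers and classical baselines.

## What this is for

Emission tomography (SPECT/PET-style imaging) recovers an activity image
`x` from its sinogram `y = M x`, where `M` is the system matrix of the
acquisition geometry. When the image is *discrete* — binary or a few gray
levels, as in homogeneous-material or tracer-presence imaging —
reconstruction becomes combinatorial, and the least-squares objective

    H(x) = ||M x − y||²
         = xᵀ MᵀM x − 2 yᵀM x + yᵀy

maps exactly onto a quadratic unconstrained binary optimization (QUBO)
problem: for binary pixels (`x_i² = x_i`) the biases are
`Q_ii = (MᵀM)_ii − 2(Mᵀy)_i` and the couplers `Q_ij = 2(MᵀM)_ij` (i < j),
with constant offset `yᵀy`, so a sample's energy *is* its squared data
residual. That is the problem class annealing samplers — simulated or
quantum — natively address. Gray-level images go through a bounded-integer
quadratic model and a positional binary encoding (`N²R` coupled variables
for `R` bits per pixel).

The package is a self-contained toy-problem framework for studying this
reconstruction route: procedural phantoms, a parallel-beam projector whose
explicit system matrix is consistent with it to machine precision, QUBO /
Ising / integer model builders with exact energy bookkeeping, an exact
enumeration oracle plus a compiled simulated-annealing sampler (the
classical stand-in for annealing hardware, plus an inert QPU interface
stub), the classical baselines the field compares against (discretized
FBP, SART/DART, truncated Moore–Penrose pseudoinverse), a signal-dependent
count-noise model, inverse-crime-avoiding fine-grid simulation with
sinogram rebinning, and RMSE/SSIM evaluation drivers.

## Worked example

Reconstruct a 16×16 binary branching phantom from a fully determined
noiseless acquisition (16 views × 16 bins) and compare all four methods:

```r
library(annealtomo)

truth <- make_phantom("tree", 16, levels = 2, seed = 1)
geom  <- tomo_geometry(16, n_views = 16)
M     <- build_system_matrix(geom)
sino  <- project(truth, geom)

qa <- reconstruct_qa(M, sino, levels = 2, reads = 10, sweeps = 300, seed = 1)
cat("QA  energy:", qa$energy, " RMSE:", rmse(qa$image, truth),
    " SSIM:", ssim(qa$image, truth), "\n")
#> QA  energy: 0  RMSE: 0  SSIM: 1

fbp <- discretize(reconstruct_fbp(sino), 2)
cat("FBP RMSE:", round(rmse(fbp, truth), 4), " SSIM:", round(ssim(fbp, truth), 4), "\n")
#> FBP RMSE: 0.0625  SSIM: 0.8297

dart <- reconstruct_dart(sino, M, levels = 2)
cat("DART RMSE:", rmse(dart, truth), "\n")
#> DART RMSE: 0

pinv <- discretize(reconstruct_pinv(M, sino, cutoff = 0), 2)
cat("PI  RMSE:", rmse(pinv, truth), "\n")
#> PI  RMSE: 0
```

The annealed reconstruction reaches energy 0 — its sinogram reproduces
the measurement exactly — and recovers the phantom perfectly, as do the
algebraic baselines on this fully determined noiseless problem; filtered
backprojection pays a small discretization penalty at this image size.
`qa$uncertainty` holds the occurrence-weighted per-pixel variance of all
returned samples, an interpretability by-product of stochastic solving.

Five packaged study designs (image-size sweep, integer Shepp–Logan sweep,
noisy digits, few-view underdetermination, inverse-crime avoidance) run
through `run_experiment()`; see the vignette in `vignettes/` for the
science, conventions, and limitations. A thin command-line front end for
simulate/reconstruct/evaluate/experiment lives in `inst/scripts/annealtomo`.

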