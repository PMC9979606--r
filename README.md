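# hcnopes

Neural-network potential energy surfaces for the tetra-atomic [H,C,N,O]
isomer family, in R.

## The problem

The singlet potential energy surface (PES) of the four-atom [H,C,N,O]
system hosts a family of isomers — HNCO, HOCN, HONC, HCNO, HNOC and several
ring structures — connected by isomerization pathways through transition
states. A *unified* surface that describes all basins at once is what
nuclear-dynamics studies need, but high-level reference energies (coupled
cluster) are far too expensive to evaluate on demand, so the surface is
*fitted*: reference energies are computed on structured samples of
configuration space and a regression model is trained to interpolate them.

All isomers share six internal coordinates: the N–H, C–N and C–O
distances R₁, R₂, R₃ (Å), the H–N–C and N–C–O angles θ₁, θ₂ (degrees) and
the dihedral φ between the HNC and NCO planes. `hcnopes` implements the
whole fitting workflow over these coordinates:

- **geometry** — internal ↔ Cartesian conversion in a body-fixed frame,
  XYZ (and extended-XYZ `energy=`) file I/O;
- **sampling** — regular mesh grids (RMGs) around reference geometries,
  chemistry-aware preprocessing filters (energy ceiling −167.85 Hartree,
  repulsive-wall minima R₁ ≥ 0.8 Å and R₂, R₃ ≥ 0.9 Å, dissociation cap at
  3.5 Å, dihedral window [0°, 180°]), min–max scaling to [−1, 1],
  train/validation/test splits, and unified / improved-unified training-set
  construction with transition-path and dihedral-scan augmentation;
- **surrogate_pes** — an analytic eight-basin surrogate surface (Morse
  radial walls, cosine angular wells, smooth-min basin blending, global
  offset −168.5 Hartree) standing in for ab initio labels, plus a
  distance-based connectivity screen and a plug-in contract
  (`reference_backend`) for real electronic-structure callbacks;
- **three energy models**, each a classed fit object with
  `predict`/`print`/`summary`/`coef`/`residuals`/`plot` methods:
  - `slnn()` — molecular single-layer network with exponential activation,
    `E(x) = c₀ + Σₖ cₖ exp(bₖ + Wₖ·x)` (a sum of products of 1-D
    exponentials), trained by Levenberg–Marquardt with multi-restart split
    selection;
  - `bpnn()` — Behler–Parrinello atom-decomposed network `E = Σᵢ Eᵢ` over
    per-element feed-forward nets reading atom-centered symmetry functions
    G² (radial) and G³/G⁴ (angular) with the standard η, r_s, ζ, γ grids
    (≈70 functions per structure);
  - `gcnn()` — graph-convolutional atomic network: per-element embeddings,
    `depth` pairwise-interaction / interaction-pooling blocks over a radial
    basis with smooth cutoff, atomic output networks;
- **evaluation** — RMSE/MAE in kcal/mol (1 Hartree = 627.5095 kcal/mol),
  contour slices, the cross-basin transfer experiment, and the end-to-end
  `run_unified_workflow()`.

## Worked example

Fit the single-layer network to a 2-D angular slice through the deepest
basin of the built-in surrogate surface:

```r
library(hcnopes)
spec <- default_surrogate()
ctr  <- spec$basins[[1]]$center          # the deep "S1" basin
grid <- mesh_spec(ctr, vary = list(theta1 = c(84, 164, 4),
                                   theta2 = c(136, 180, 5)))
ds   <- sample_labeled_dataset(grid, spec, source = "S1")
fit  <- slnn(ds, neurons = 20, epochs = 500, restarts = 3, seed = 11)
summary(fit)
#> Single-layer sum-of-products potential energy surface
#> neurons: 20   parameters: 161
#> points:  train 153  validation 18  test 18
#> RMSE (kcal/mol):
#>      train validation       test
#>    0.00051    0.00068    0.00068
predict(fit, ctr)
#> [1] -168.75
surrogate_energy(ctr, spec)
#> [1] -168.75
```

The held-out RMSE of well under 0.5 kcal/mol says the 20-neuron network
interpolates this basin slice to far better than chemical accuracy; the
basin-center prediction reproduces the reference minimum at
offset − depth = −168.5 − 0.25 Hartree.

The same dataset objects feed `bpnn()` and `gcnn()` unchanged, and
`run_unified_workflow()` chains grid generation, labeling, filtering,
merging, splitting, training and evaluation with one master seed. A thin
command-line front end over these functions ships in
`inst/cli/hcnopes.R`.

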