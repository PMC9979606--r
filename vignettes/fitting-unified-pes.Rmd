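---
title: "Fitting a unified six-dimensional potential energy surface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting a unified six-dimensional potential energy surface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcnopes)
```

## The model problem

The four-atom [H,C,N,O] system supports several bound isomers — chain
structures such as HNCO, HOCN, HONC and HCNO, and a handful of rings —
living as basins on one six-dimensional singlet potential energy surface
(PES), connected by isomerization paths through transition states. A
regression model of that surface has to serve two masters: quantitative
accuracy inside each basin, and qualitative correctness in the saddle and
repulsive regions between basins where far fewer reference points exist.
`hcnopes` packages the whole fitting workflow: coordinates, structured
sampling, preprocessing, three neural-network energy models of increasing
sophistication, and the construction of *unified* multi-basin training
sets.

All structures are described by six shared internal coordinates: the N–H,
C–N and C–O distances $R_1, R_2, R_3$ (Å), the H–N–C and N–C–O angles
$\theta_1, \theta_2$ (degrees), and the dihedral $\varphi$ between the HNC
and NCO planes. Cartesian positions, when needed (file output, descriptor
evaluation), are built in a body-fixed frame — N at the origin, C on $+z$,
H in the $xz$ half-plane, O placed by $\theta_2$ and $\varphi$ with a
right-hand dihedral convention about N$\to$C, $\varphi$ stored modulo
360°. Any self-consistent frame would do: every feature consumed by the
models is a function of the internal coordinates alone, which the test
suite verifies by round-tripping and by checking invariance under random
rigid motions. Angles of exactly 0° or 180° make the dihedral undefined;
the conversion flags this explicitly instead of emitting `NaN`.

## The surrogate reference surface

High-level ab initio labels are replaced by an analytic surrogate with
controllable ground truth. Each basin $k$ contributes

$$E_k(q) = E_0 - D_k + \sum_{i=1}^{3} d_{ki}\,
  \bigl(1 - e^{-a_{ki}(r_i - r^0_{ki})}\bigr)^2
  + \sum_{j=1}^{2} \kappa_{kj}\,(1 - \cos(\theta_j - \theta^0_{kj}))
  + A_k\,(1 - \cos(\varphi - \varphi^0_k)),$$

and basins are blended with a smooth minimum (log-sum-exp with smoothness
$s$, in Hartree), which tends to the pointwise basin minimum as $s \to 0$.
Defaults: global offset $E_0 = -168.5$ Hartree, Morse well depths
$d_{ki} = D_k/3$ so the surface rises to the $E_0$ plateau as any distance
dissociates, ranges $a = 2$ Å$^{-1}$, angular amplitudes
$\kappa = 0.1$ Hartree, dihedral amplitude $A = 0.02$ Hartree,
$s = 0.005$ Hartree. The default layout has eight basins labelled S1..S8
at distinct internal-coordinate centers, with one deep global basin (S1,
$D = 0.25$ Hartree) and one shallow basin (S5, $D = 0.10$ Hartree) in a
remote angular region; that pair drives the transfer experiment below.
These values were chosen once so that well depths (tens to a couple of
hundred kcal/mol), wall steepness and the absolute energy scale are in the
range familiar from the real isomer family, and so that the default
preprocessing thresholds are meaningful; they are not calibrated to any
measured outcome.

What the surrogate emulates: multiple labelled minima at distinct centers,
Morse-like repulsive walls and dissociation plateaus, angular wells,
saddle-like regions where basin terms cross, and an absolute offset near
−168 Hartree. What it does not emulate: cusps and conical intersections,
long-range electrostatics, the precise anharmonicity of coupled-cluster
surfaces, and basin-dependent coupling between coordinates. Passing tests
therefore certify the *machinery* — sampling, filtering, training,
evaluation — at realistic scales and shapes, not the physics of any real
isomer.

A distance-based connectivity screen (bond declared when
$r_{ij} \le 1.3\,(\rho_i + \rho_j)$ with single-bond covalent radii, pass
iff the bond graph is connected) plays the preprocessing role that a
wavefunction-based bond-order analysis plays in production use; real
backends plug in through the `reference_backend` contract, a deterministic
callable from internal coordinates to Hartree energies.

## Sampling and preprocessing

Datasets are regular mesh grids (Cartesian products over 1–6 chosen
coordinates around a center), with the dihedral axis treated as periodic —
a full-circle scan at step 20° yields 18 points, not 19. The
preprocessing filters mirror the construction of a unified training set:
drop points above an energy ceiling of −167.85 Hartree (repulsive branch),
below $R_1 = 0.8$ Å or $R_2, R_3 = 0.9$ Å (inside the walls), beyond
3.5 Å in any channel (dissociation), or outside the [0°, 180°] dihedral
window. The distance thresholds are read as *lower* bounds excluding the
repulsive wall, consistent with their stated purpose of truncating
repulsion and dissociation branches. Rules are applied in a fixed order
and each removed point is attributed to the first rule it violates, so the
removal report sums exactly to the number of dropped points — a property
the suite checks against brute-force oracles on randomized fixtures.

Merging per-isomer sets deduplicates geometries identical to within
$10^{-9}$ (coordinates can only coincide by construction, not numerically
by accident), keeps the lower energy when duplicates disagree by more than
$10^{-8}$ Hartree (and reports the conflict), then filters. The improved
unified (IU) variant appends 2-D dihedral scans — full circle, step 20°,
excluding a ±30° window around each equilibrium dihedral — crossed with
one other coordinate; these augmentation points deliberately bypass the
dihedral filter, which exists to remove the very redundancy the
augmentation reinstates in a controlled way. Straight-line interpolations
between basin centers stand in for relaxed isomerization paths; their
resolution is a parameter because the composition of real transition-path
scans is system-specific.

Scaling is min–max to $[-1, 1]$ per channel,
$X_\mathrm{scaled} = -1 + 2(X - x_\min)/(x_\max - x_\min)$, fitted on the
training split only and applied to validation and test — the leakage-safe
choice. Coordinates held constant in a scan (degenerate channels) are
padded to a unit interval so they scale to 0; the exported
`scale_minmax()` keeps the strict behavior of rejecting degenerate
channels. Splits default to 80/10/10 with the rounding remainder assigned
to the training split, optionally stratified by provenance tag.

## The three energy models

**Single-layer network (`slnn`).** The scaled energy is
$c_0 + \sum_k c_k \exp(b_k + W_k \cdot x)$; the exponential activation
makes the surface a sum of products of one-dimensional exponentials, the
form quantum-dynamics codes like. Fitting is Levenberg–Marquardt on the
analytic Jacobian: classic damping (multiply by 10 on a rejected step,
divide by 10 on an accepted one, stop when damping exceeds $10^{10}$, the
gradient norm drops below $10^{-10}$, or the epoch budget runs out), with
the best-validation parameter vector checkpointed each epoch. Two
implementation details proved load-bearing. First, parameters whose
Jacobian column vanishes — the weights of a coordinate held constant in a
scan — are frozen and excluded from the normal equations; leaving them in
makes the damped system so ill-conditioned that convergence stalls.
Second, each restart draws random $(b, W)$ uniform in $[-0.5, 0.5]$ but
sets the output layer $(c_0, c)$ by linear least squares, which roughly
doubles the fraction of restarts that escape the fit-the-mean plateau of
exponential regression. Multi-restart fitting (fresh random splits and
fresh initialization per restart, child seeds derived from the master
seed) returns the best-validation model with the full per-restart report;
`optimize_neurons()` wraps this in a grid search over neuron counts.
Early stopping is off by default (`patience = Inf`): on these problem
sizes the full epoch budget is cheap, and patience-based stopping was
observed to kill slow-converging restarts that end at machine precision.

**Atom-decomposed symmetry-function network (`bpnn`).** The energy
decomposes as $E = \sum_i E_i$ with equal weight, one feed-forward network
per element, shared across atoms of that element. Inputs are atom-centered
symmetry functions with a smooth cosine cutoff
$f_c(r) = \tfrac12(\cos(\pi r/R_c) + 1)$ for $r \le R_c$:
radial $G^2_i = \sum_j e^{-\eta (r_{ij}-r_s)^2} f_c(r_{ij})$ and angular
$G^{3,4}_i = 2^{1-\zeta} \sum_{j<k} (1+\gamma\cos\theta_{ijk})^\zeta\,
e^{-\eta(r_{ij}^2 + r_{ik}^2 [+ r_{jk}^2])}\,
f_c(r_{ij}) f_c(r_{ik}) [f_c(r_{jk})]$, where $G^3$ carries the bracketed
$r_{jk}$ factors and $G^4$ omits them — both standard variants are
implemented since the assignment between the two conventions differs
across the literature. The default enumeration uses the customary grids:
$\eta \in \{0.0005, 0.005, 0.0015, 0.003, 0.01\}$ at $r_s = 0$;
$\eta \in \{0.07, 0.015, 0.03, 0.75, 1.5\}$ at $r_s = \min r_{ij}$; a
shifted-center family with 25 centers uniformly spanning $(0, R_c]$ and
widths set so adjacent Gaussians cross at half maximum (the center count
and width rule are configuration parameters, as no single convention
exists); and angular grids $\zeta \in \{1,4\}$, $\gamma \in \{-1,+1\}$
over $\eta \in \{0.01, 0.03, 0.07, 0.20, 0.4\}$ ($G^3$) and
$\{6.0613, 12.1227, 18.1840, 24.2454\}$ ($G^4$). That yields 35 radial and
36 angular functions — 71 per atom, in the "around 70" budget with 35–45
radial, which the suite asserts. $\gamma$ is the angular parity elsewhere
often written $\lambda$. Features are standardized on the training split;
energies are min–max scaled. Hidden layers are `tanh` (a `linear` option
collapses the network to a linear model for diagnostics); training is
full-batch Adam with a step decay at one half and three quarters of the
budget, validation-checkpointed. Classic momentum is retained as an
option, but adaptive per-parameter steps proved necessary to reach the
stated accuracies within reduced step budgets on one CPU, so Adam is the
default.

**Graph-convolutional atomic network (`gcnn`).** Atoms start from a
learned per-element embedding (H, C, N, O). Each of `depth` interaction
blocks forms pair representations from the concatenated endpoint node
features (the pairwise-interaction network), contracts them with a radial
basis expansion of the pair distance — Gaussians spanning $(0, R_c]$ times
the smooth cutoff — sum-pools over neighbors back onto atoms
(interaction pooling), and updates node features through the pooling and
interaction-to-interaction networks with a residual connection. Per-atom
output networks are summed into the molecular energy. The precise block
algebra of published graph PES codes varies; this variant was chosen for
being easy to reason about and is certified by the invariance suite:
permutation equivariance of node features, invariance of the energy under
rigid motions and relabeling of identical elements, continuity across the
cutoff, independence from neighbor enumeration order, and a compositional
check that a depth-1 model equals one manually composed block.

Both deep models end with an exact ridge least-squares refit of the linear
readout (all output-layer weights and biases jointly — the energy is
linear in them), accepted only if it does not hurt validation RMSE. This
costs one small linear solve and reliably removes the slow tail of
first-order training on near-linear targets.

## Numerical choices

- Energies are Hartree everywhere inside; kcal/mol appears only at
  reporting boundaries, always via the fixed factor 627.5095 kcal/mol per
  Hartree, recorded in every report. (Printed conversions in the
  literature occasionally round inconsistently; fixing the factor makes
  every reported number traceable.)
- Degrees outside, radians inside for trigonometry.
- All randomness flows from one master seed through a deterministic child
  seed derivation (kept within 32-bit range); two runs of the unified
  workflow with the same seed produce bit-identical datasets, manifests
  and model containers, which the suite asserts on the written files.
- Model containers are JSON with doubles printed at 17 significant
  digits, which round-trips IEEE values bit-exactly; containers are
  self-describing (architecture tag, format version, master seed, dataset
  hash).
- Duplicate tolerance $10^{-9}$; duplicate energy conflicts beyond
  $10^{-8}$ Hartree are reported and resolved toward the lower energy.
- Degenerate dihedrals are flagged, never silently `NaN`; filters warn on
  an empty result instead of succeeding silently; prediction outside the
  training range warns (extrapolation) but never fails.

## Problem sizes used by the tests and the acceptance script

The shipped experiments are sized for a single CPU: a 189-point 2-D basin
slice for the single-layer capacity check (held-out RMSE well under
0.5 kcal/mol with 20 neurons); an 832-point two-basin 3-D set for the deep
models (64×4 heavy-atom networks for the symmetry-function model, width
32 / depth 2 for the graph model, held-out RMSE under 1.5 kcal/mol at
reduced step budgets); and 2-D angular sets around the deep and shallow
basins for the transfer experiment. In the transfer experiment a model
trained only on basin A is evaluated on the union of both basins'
points — its RMSE exceeds 10 kcal/mol for all three architectures, the
extrapolation failure that motivates unified training — while the same
architecture trained on the merged set stays below 1 kcal/mol. These
sizes are scaled-down analogues of production fits (thousands of points
per isomer, $10^5$ training steps); the behaviors they certify are the
ones that survive scaling: bookkeeping exactness, invariances,
determinism, and the basin-transfer ordering.

## Known limitations

- The straight-line transition-path generator ignores the true
  minimum-energy path; it exists to populate the saddle regions, not to
  locate saddles.
- No analytic gradients of the fitted surfaces are exposed, and no force
  training is implemented.
- The symmetry-function shifted-center family and the radial-basis widths
  follow one documented convention; other codes make different choices,
  so descriptor sets are serialized alongside any trained model.
- Equilibrium geometries of the real isomers are not hard-coded anywhere;
  users supply their own reference geometries (XYZ) and mesh
  specifications to mimic production studies.
- The eight default surrogate basins share one angular force constant and
  dihedral amplitude; users wanting stiffer or softer basins override the
  per-basin parameters in `surrogate_spec()`.
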