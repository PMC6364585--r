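---
title: "Model and methods: subcellular element simulation of doublet mechanics and cell sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`scemsort` implements a three-dimensional, force-based simulation of small
multicellular aggregates in the subcellular element tradition: each cell is a
cloud of point elements, all dynamics derive from local pairwise forces, and
no global Hamiltonian is assumed. The state advances by overdamped Langevin
dynamics,

$$\gamma \dot{\mathbf{x}} = -\nabla U(\mathbf{x}) + \boldsymbol\zeta,$$

integrated with an explicit Euler–Maruyama step. Element pairs interact
through Morse potentials

$$V(r) = D_e\left(e^{-2a(r - r_e)} - 2e^{-a(r - r_e)} + 1\right),$$

whose force $-dV/dr$ is repulsive below the equilibrium separation $r_e$ and
attractive up to a truncation radius. Reduced units are used throughout:
$r_e = 1$ sets the length scale and the drag coefficient $\gamma = 1$ sets
the time/force normalisation, so the cortical tension `gamma_m`, the
adhesion magnitude `A_M`, and their ratio $\alpha = A_M/\gamma_m$ are
directly comparable across parameter sets.

Each cell carries a contractile cortex:

1. **Cortex allocation.** The sphere of directions about the cell's centre
   of mass is divided into 32 sectors of equal solid angle (4 equal-area
   polar bands by Archimedes' theorem, each cut into 8 azimuthal slices).
   Every element whose radius exceeds 80% of its sector's maximum radius is
   cortex; the rest are cytoplasm. Allocation is refreshed as elements move,
   so an escaping cytoplasm element is immediately re-labelled cortex and
   pulled back by the tension network.
2. **Tension network.** The cortex surface is triangulated by the convex
   hull of the cortex element positions — for the near-convex cells
   simulated here this coincides with a spherical Delaunay triangulation —
   and every triangulation edge carries an *attractive force of constant
   magnitude* `gamma_m` that does not depend on element separation. Using
   the hull of real positions (rather than a triangulation over all cortex
   elements projected to a sphere) keeps the network tangential to the cell
   surface; we found that meshes connecting different radial layers of the
   80%-band act as an internal scaffold that artificially rigidifies the
   cell.
3. **Interfaces.** Cortex elements within the adhesive interaction distance
   of another cell's cortex are labelled by the type of that cell
   (same-type / other-type, possibly both at triple contacts). Tension on an
   edge whose two endpoints share a label is scaled by the interfacial
   tension factor $\beta_{t,t'} \le 1$ of the cell-type pair at the
   interface, the same factor on both sides of the interface; the smaller
   applicable factor wins where labels overlap.
4. **Adhesion.** Only cortex elements of different cells adhere. The
   adhesive branch is a Morse attraction whose well depth $2 A_M / a$ is
   chosen so that its *maximum* attractive force equals `A_M`, the model's
   adhesion magnitude. Inter-cell pairs involving cytoplasm are
   repulsive-only, which keeps cells from interpenetrating. Each element's
   adhesive force is multiplied by its local surface-area share (one third
   of its incident facet areas, normalised by the cell mean), so adhesion
   per unit area does not depend on how crowded the cortex locally is.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `gamma_m` | 1.2 | cortical tension per edge; 1.2 = high-tension regime, 0.01 = low-tension |
| `A_M` | 0.2 | peak adhesive force between cortex elements of different cells |
| `beta` | 1 | interfacial tension factor(s), per cell-type pair |
| `De_core`, `a_core` | 0.2, 4 | intra-cell Morse well depth and range |
| `De_rep`, `a_rep` | 0.2, 4 | inter-cell repulsive core |
| `a_adh` | 4 | adhesive Morse range; well depth derived from `A_M` |
| `cutoff_core` | 1.5 | truncation of core interactions (nearest-neighbour shell) |
| `cutoff_adh` | 2.0 | reach of the adhesive force |
| `label_cutoff` | 1.4 | contact distance that defines "shares an adhesive interaction" |
| `measure_cutoff` | 1.2 | bound-pair distance used when measuring interface area |
| `noise_amp` | 0.3 | s.d. of the Gaussian random force per component |
| `dt` | 0.005 | Euler–Maruyama step; guarded so no element moves more than $r_e/2$ |

The Morse constants are the package's own calibration (the doublet
validation below is the benchmark): the core must be *stiff against
compression but shallow-welled*, i.e. nearly volume-preserving yet fluid
enough for elements to rearrange. Soft cores (`a_core = 2`) let cells at a
low-tension interface swell to roughly twice their high-tension volume,
which injects a spurious size-segregation into sorting runs; steep cores
with deep wells freeze rearrangement entirely. Repulsive branches are
capped at `rep_cap = 20` so that transient overlaps created by division or
element insertion relax smoothly instead of tripping the step-size guard;
the cap is far above any equilibrium force, so statics are unaffected.

Separating the adhesive *force reach* (`cutoff_adh`) from the *contact
distance* (`label_cutoff`, `measure_cutoff`) matters at the coarse test
resolution: the long-range tail of the adhesive Morse force is what lets a
growing interface recruit new element pairs, while interface labelling and
area measurement should only count pairs actually sitting in the adhesive
well. A single cutoff either starves interface growth (if short) or counts
merely-proximal elements as interface (if long). Both contact distances sit
just above the adhesive well minimum $r_e + \ln 2 / a_{adh} \approx 1.17$.

## Doublet experiments

`make_doublet()` follows the divide-then-relax protocol: one parent cell is
relaxed, split by a random plane through its centre of mass into two
identical-type daughters, and the doublet relaxes without growth or
division. The interface proportion

$$I_P = \frac{\text{summed area of facets whose three vertices all hold
bound inter-cell contacts}}{\text{total facet area of both cells}}$$

is recorded over time; the reported value is a trailing-window mean, with
an optional convergence rule (windowed mean changing by less than `tol`).
The analytic benchmark is the linear force balance (LFB) model, which
neglects adhesion and balances cortical against interfacial tension at the
contact line: $\beta = \cos(\theta/2)$ and $I_P = (1 - \beta)/(3 - \beta)$,
i.e. 1/3 for two hemispheres at $\beta = 0$ and 0 at $\beta = 1$.

At test scale (60 elements per cell, about 30–40 of them cortex) the
simulated high-tension doublet reproduces the LFB *ordering* in $\beta$ and
the small positive adhesion offset at $\beta = 1$, but the discrete
interface responds more weakly than the continuum prediction: the interface
is one element layer thick (a sizeable fraction of the whole cell at this
resolution), and contact-line advance requires collective rearrangement of
a handful of elements, so the measured $|I_P - I_{P,\mathrm{LFB}}|$ can
reach ~0.1 at intermediate $\beta$. In the low-tension regime
(`gamma_m = 0.01`) the model matches the expected phenomenology well:
no interface without adhesion, a sharp rise of interface with adhesion, a
plateau beyond `A_M` ≈ 0.1, and a plateau value near the two-hemisphere
limit of 1/3.

## Growth, division, sorting

Aggregates grow from 10 to 30 cells (`run_to_cell_count()`): cytoplasm
elements are inserted near the centre of mass at a stochastic rate
calibrated so a cell's element count doubles over one cell-cycle time
`tau_C`; a cell that reaches `target_elements` divides by a uniformly
random plane through its centre of mass (redrawn if a daughter would get
fewer than 4 elements). Symmetric division copies the parent type;
asymmetric division produces, with probability 0.5, one daughter of each
type. The initial aggregate is constructed directly as a relaxed packing of
10 equal cells with shuffled 5:5 type labels rather than grown from a
single founder — equivalent for the sorting analyses and considerably
cheaper.

Sorting is quantified by three measures over the final (or any) snapshot:
the mean radius of type-1 cells about their own centre of mass ($X_r$), the
number of like–like neighbour pairs of type 1 in the cell contact graph
($X_n$), and the share of the aggregate's free surface contributed by type
2 ($X_s$). Each is standardised against a randomised-control null: the
cell-type labels are re-assigned uniformly at random (fixed counts, fixed
geometry) $10^4$ times (Appendix-scale default; tests use $10^3$), giving
$E(X_i)$ and $\sigma(X_i)$, and

$$S_i = \pm\frac{X_i - E(X_i)}{3\,\sigma(X_i)},$$

with the sign chosen (negative for the radius measure) so that $S_i \to 1$
means sorted for every measure; $\sigma$ rather than the null range is used
so single extreme shuffles cannot deflate the index.

## Scale choices

All shipped tests and the acceptance script run at reduced scale chosen to
keep a complete run on one CPU within minutes: doublets use 60 elements per
cell and relaxation horizons of 100–150 time units; sorting runs use 10–20
cells at ~24–32 elements per cell, `tau_C = 150`, and 2–3 seeds per
condition; permutation nulls use $10^3$ shuffles in tests. The
`scale_preset("production")` settings (128 elements per cell, $10^4$
shuffles) reproduce the same pipelines at full resolution. At reduced scale
the sorting indices are strongly seed-dependent (a 20–30 cell aggregate has
only ~10–15 cells of each type), so sorting criteria are assessed on means
over seeds and with qualitative (ordering) checks, not point values.

## What the fixture generator does and does not emulate

`generate_labelled_aggregate()` builds packed-sphere aggregates with
controllable label arrangements (`shuffled`, `sorted`, `shell`) plus a
geometric proxy for free surface (each contact occludes 1/12 of a cell's
surface). It exercises the entire sorting-analysis stack without dynamics,
which makes null-calibration tests fast and exact; it does not emulate
element-resolution features (interface thickness, cortex density
variation), so passing fixture tests validates the *analysis*, not the
*mechanics*. The dynamical criteria are tested on simulated aggregates.

## Numerical choices and degenerate inputs

* Explicit Euler–Maruyama with a hard per-step displacement guard of
  $r_e/2$; violations abort with a step-size error rather than silently
  capping motion.
* Neighbour search uses a uniform-grid cell list at the largest interaction
  cutoff; it is exact (tested against an all-pairs oracle and a kd-tree
  library).
* The convex hull is an incremental algorithm with a relative tolerance of
  $10^{-10}$ on the visibility predicate; a deterministic, index-keyed
  jitter of $10^{-9}$ breaks exact degeneracies (co-spherical or coplanar
  points) without affecting reproducibility.
* Cells with fewer than 4 cortex elements carry no tension network that
  step (they still interact through Morse forces); zero-length edges are
  skipped.
* Division planes leaving a daughter with fewer than 4 elements are
  redrawn (up to 50 attempts).
* With a single cell type present, `surface_measure()` returns 0 or 1 by
  convention; the permutation null requires both types and at least two
  cells, otherwise it errors.
* All randomness flows through R's RNG (including the C++ noise terms via
  R's `norm_rand`), so a single `set.seed()` makes any pipeline
  reproducible bit-for-bit.

## Known limitations

* At test resolution the high-tension doublet under-responds to
  intermediate $\beta$ relative to the continuum force-balance line; the
  ordering and the zero-adhesion/zero-interface limits are robust. The
  deficit is an equilibrium property of the coarse discretisation, not
  under-relaxation: extending runs tenfold makes the bound contact decay
  toward an adhesion-controlled size rather than grow toward the
  force-balance value. The contact line is one element wide, so its
  advance requires collective hops over adhesive and packing barriers that
  are large compared with any workable noise amplitude.
* For the same reason a tightly bound aggregate at this resolution is
  kinetically arrested: a six-cell probe shows no contact-graph
  rearrangement over hundreds of time units. Sorting signals in growth
  runs are therefore carried largely by division placement under fast
  growth, are strongly seed-dependent, and are assessed as orderings of
  means over seeds. Sorting by a large adhesion ratio (R = 10), which only
  requires weakly bound cells to be expelled rather than bound cells to
  exchange neighbours, is robust.
* The model is calibrated for near-convex cells; strongly non-convex shapes
  would need a restricted surface reconstruction instead of the convex
  hull.
* No hydrodynamics, inertia, volume constraint, nucleus or membrane
  bending; cell–substrate mechanics are out of scope.
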