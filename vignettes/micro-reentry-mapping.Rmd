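---
title: "Mapping structural susceptibility to micro-anatomical reentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structural susceptibility to micro-anatomical reentry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrenet)
```

## The model

Micro-anatomical reentry is continuous electrical activation circulating a
fibre tract that interstitial fibrosis has insulated from its
surroundings. A circuit is sustained only if its loop length reaches the
refractory wavelength: by the time the wavefront returns, the tissue it
re-enters must have recovered. `fibrenet` treats this as a purely
structural problem on a spatial network:

* **Nodes** are points placed every voxel length along fibre tracts
  reconstructed from a per-voxel axial orientation field (or placed at
  random in the fibre-less null model).
* **Longitudinal edges** connect consecutive nodes of a tract with
  probability 1 — conduction along an intact fibre is never interrupted in
  this model.
* **Transverse edges** connect nodes of different tracts at distance $x$
  with probability
  $$p(x; r, c) = \frac{1}{e^{r(x - c)} + 1},$$
  a logistic attachment law with steepness $r = 7$ and characteristic
  distance $c$ (both distances in voxel units; only pairs with $x < 2$ are
  candidates). Removing transverse edges is the network analogue of
  depositing interstitial fibrosis, so $c$ acts as an inverse fibrosis
  grade: $c \approx 1$ is well-coupled tissue, $c \to 0$ fully insulated
  fibres. This places the model in the family of distance-dependent
  spatial networks studied in percolation theory.
* **Reentry criterion.** A unidirectional conduction block at the directed
  pair $(b \to a)$ induces reentry iff the shortest alternative path from
  $b$ back to $a$, plus the blocked edge, forms a loop of length
  $\ell \ge \tau$, with $\ell$ finite. $\tau$ is the refractory wavelength
  in node steps; since nodes sit one voxel apart, $\tau$ is approximately
  the physical wavelength divided by the voxel edge.

All distances in the package are voxel units (1.0 = one voxel edge); the
physical scale enters only through the `spacing` field of a geometry
(e.g. clustering range `eps = 10` ≈ 3 mm at 300 µm resolution).

### The discrete diffusion model and its oracle

`simulate_block()` implements the dynamics as a two-phase discrete
diffusion model. Phase 1 verifies that a paced wavefront (by default from
one boundary face of the occupied bounding box) reaches the block site at
all — blocks in unreachable components are not evaluated. Phase 2 models
the induction event itself in the slow-pacing limit: by the time the next
beat arrives, all tissue has recovered, so the re-initiation dynamics are
simulated from the block site on quiescent tissue. The automaton is
synchronous: an excited node excites all resting neighbours in the next
step and is then refractory for $\tau$ steps; the unidirectional block
suppresses transmission across $(b \to a)$ on its first arrival only.

For $\tau \ge 3$ this automaton is *provably equivalent* to the graph
criterion. In a single-source wave every neighbour pair differs in
activation time by at most one step — except across the blocked edge,
where the delay equals the alternative-path length. The only possible
re-excitation is therefore the wave re-entering the blocked site through
the loop, which succeeds exactly when $\ell \ge \tau$, and then
perpetuates with period $\ell$. `find_substrate()` exposes both engines:
`"ddm"` runs the automaton per block; `"oracle"` applies the criterion
directly with a bridge pre-pass (bridge edges can never host a loop) and
truncated breadth-first searches, and is the default for ensemble sweeps.
The test suite asserts exact agreement of the two engines on hundreds of
random networks; at $\tau = 2$ the automaton can sustain spurious
re-excitations and the equivalence is not guaranteed, which is why
defaults use $\tau \ge 3$.

### Risk measures

With uniform block susceptibility, the global risk is the per-block
induction probability
$\lambda = N / (\text{block opportunities evaluated}) \in [0, 1]$,
directly proportional to the substrate count $N$ at fixed network size.
The exact normalisation is a convention; any fixed constant rescales
$\lambda$ without affecting local-risk ratios or any qualitative result.
Sampling a fixed number of identified circuits per network gives
per-voxel counts $N_v$ (number of sampled circuits intersecting voxel
$v$), and the local risk
$$\tilde R_v = \lambda \frac{N_v}{\sum_v N_v}, \qquad \sum_v \tilde R_v = \lambda$$
apportions the global risk spatially. Maps are displayed after isotropic
3-d Gaussian smoothing (σ = 5 voxels, kernel truncated at 4σ with
normalized boundary handling and an exact total-preserving rescale);
smoothing is never applied before computing $\lambda$ or cluster
statistics.

Ensemble risk maps additionally record **anchor counts**: the voxel
containing the blocked node of each sampled circuit. At full scale a
micro-reentrant circuit is small relative to the atria and the two notions
coincide; on desk-scale fixtures a loop of $\ell \gtrsim \tau$ voxels
spans a large fraction of the geometry, so loop-extent counts dilute
spatial signal that the anchors retain. Structural analyses (substrate
OVF, clustering, regional densities) therefore use anchors; the local
risk map $\tilde R_v$ keeps the loop-extent definition of $N_v$.

### Structural metrics

* **Occupied voxel fraction (OVF)** — for each tissue voxel, the fraction
  of the lattice sphere of radius $\tilde r = 5$ voxels that is occupied.
  The denominator is the full 515-point lattice ball regardless of
  position, and voxels beyond the grid edge count as unoccupied, so thin
  or convex walls genuinely read low: bulk ≈ 1, flat surface ≈ 0.5,
  isolated structures lower still. This makes OVF a wall-thickness proxy
  that, unlike surface-normal thickness, is defined in the bulk.
* **Longitudinal connection fraction (LCF)** — per node, the fraction of
  its edges that are longitudinal, averaged per voxel. High LCF marks
  well-aligned fibre bundles. It is undefined for the null model (an
  error); fibre/null comparisons label null voxels with the paired fibre
  model's LCF. Note the denominator: LCF rises either with more
  longitudinal edges or with fewer transverse ones, so a sweep towards
  lower $c$ raises LCF without adding alignment.
* **Cluster counts** — substrate voxels are sampled (with replacement,
  which keeps the sample size fixed even for tiny substrates) and
  clustered with `eps = 10`, minimum cluster size 1. At minimum size 1,
  density clustering degenerates to the connected components of the
  eps-neighbourhood graph, which is what `count_eps_clusters()` computes
  via single-linkage at cut height `eps`; a brute-force union-find oracle
  in the tests confirms the equivalence. Bootstrap resampling supplies
  error bars.

## Synthetic fixtures: what they emulate, and what they do not

`fixture_suite()` generates seeded geometries emulating the structural
features that drive risk in real atria: thin and thick plates, a wedge
with a linear thickness ramp (for wall-thickness bias analyses), a ridge
on a plate (pectinate-muscle analogue, fibres along the ridge), a hollow
tube on a plate with circumferential fibres (pulmonary-vein sleeve
analogue), a slab with a fibre-disarray patch, and a slab with spherical
holes. Disarray is a von Mises–Fisher perturbation of the base direction
with concentration κ, drawn once per 3-voxel block: real fibre disarray is
spatially coherent over short ranges, and fully independent per-voxel
directions would terminate every streamline immediately. In one-voxel-thin
plates the perturbed vectors are projected back into the plate plane, so
fields remain tangent to the tissue.

These fixtures are homogeneous and small. Passing tests on them shows the
machinery is correct and that the method's directional claims reproduce;
it does not show anatomical realism — there is no trabeculated endocardium,
no transmural fibre rotation, no individual-specific fibrosis
distribution. Two desk-scale consequences matter for interpretation.
First, circuits span a visible fraction of a fixture (hence the anchor
convention above). Second, the informativeness of the cluster count
depends on the ratio of geometry size to `eps` times the sample size: at
full scale, 1000 samples spread over millions of voxels resolve
concentration versus dispersion, while 1000 samples in a 19000-voxel
wedge always form one eps-connected blob. `calibration_sweep()` therefore
defaults its per-member cluster sample to the full-scale sampling density
(about one sample per 1500 tissue voxels, minimum 8).

## Tractography choices

The tracer is a modified evenly-spaced-streamlines method: candidate
streamlines are traced from seeds at least $d_{sep} = 0.7$ voxels from all
accepted streamlines, and accepted longest-first within each round, which
favours long coherent fibres while the spacing rule keeps streamline
density approximately uniform. Termination follows standard streamline
practice: mask exit or missing orientation, a per-step turning cap
(default 60°), proximity $< d_{sep}$ to an accepted tract, and a length
cap. Orientation lookup is nearest-voxel with axial sign continuity
(choose $\pm v$ to minimise the turn), matching the discrete resolution of
the data; the integration step is 0.5 voxels. Node points are placed at
unit arc-length intervals from a random phase per tract. Seeding is
density-aware — seeds are drawn only from voxels still below the target
density of 1 node per voxel — so that regions of short, disordered tracts
(which the longest-first schedule would otherwise fill last) are not
starved when the global node budget runs out. The achieved density on
uniform fixtures is 1.00–1.01 nodes per voxel; incoherent regions fill to
a somewhat lower density because very short candidate tracts are
discarded, a genuine property of streamline coverage on disordered
fields.

Coarse-graining of orientation data averages the structure tensor
$\langle v v^\top \rangle$ over child voxels and takes its principal
eigenvector — the standard sign-invariant average for axial data
(antiparallel fibres reinforce rather than cancel); occupancy aggregates
by the "at least half the children, ties occupied" rule, chosen to
preserve thin walls conservatively. Degenerate tensors resolve to the
lexicographically smallest unit eigenvector, with a warning.

## Coupling and ensemble choices

One uniform variate is drawn per candidate pair in a fixed pair order, so
edge sets are exactly nested in $c$ for a fixed seed — sweeps over $c$
compare the *same* realisation at increasing fibrosis, making
monotonicity properties exact rather than statistical. Non-adjacent nodes
of the same tract get no transverse edge by default (the conservative
reading of "longitudinal coupling is certain along a fibre"); a flag
allows them to compete for transverse edges. In ensembles, the fibre
model fixes the tract set and redraws only the coupling (regeneration per
member is available and, per the tests, shifts $\lambda$ by no more than
ensemble noise); the calibration sweep likewise fixes the null model's
node placement per sweep and redraws edges per member.

Default parameters, with units and provenance in this package:

| parameter | default | unit | role |
|---|---|---|---|
| `d_sep` | 0.7 | voxels | seed/streamline separation |
| `step` | 0.5 | voxels | integration step |
| `max_angle` | π/3 | rad | per-step turning cap |
| node spacing | 1 | voxels | along-fibre node interval |
| `r` | 7 | — | attachment steepness |
| `cutoff` | 2 | voxels | candidate-pair bound |
| `c` | swept | voxels | inverse fibrosis grade |
| `tau` | 10 | node steps | refractory wavelength (≈ 3 mm at 300 µm) |
| `sigma` | 5 | voxels | display smoothing |
| `r_tilde` | 5 | voxels | OVF sphere radius |
| `eps` | 10 | voxels | cluster linking distance |
| samples | 1000 | voxels | cluster sample size |

No published value of $\tau$ is asserted; 10 node steps was chosen once as
a physiologically plausible desk-scale wavelength on the same 3 mm scale
as `eps`, and is configurable everywhere.

## The acceptance analyses

The ensemble tests reproduce the method's directional claims on the
fixture suite, at sizes chosen for a desk run (a 60×40×16 wedge of
19200 tissue voxels ≈ 2×10⁴ nodes; 50-network ensembles; 200 sampled
circuits per member):

* **Risk band.** $\lambda(c)$ vanishes at both ends of the coupling grid
  with an interior maximum, for the fibre and the null model — each
  region is susceptible only within a characteristic fibrosis-density
  band. The null model needs distinctly larger $c$ (its grid runs to 1.2)
  because it lacks permanent longitudinal edges.
* **Thin-tissue bias.** On the low-fibrosis branch of the sweep (grid
  points with $c$ strictly above the $\lambda$-maximising coupling — the
  régime corresponding to low/medium/high-risk labels before compact
  insulation sets in), the substrate's mean OVF lies below the
  geometry-wide mean at the smallest $\lambda$ and rises monotonically
  with $\lambda$. At and beyond the peak the substrate migrates into the
  bulk as thin regions fragment first, which is the same
  characteristic-band physics viewed from the other side; the branch
  restriction states where the monotone relation applies.
* **Clustering.** The per-member cluster count grows from the smallest to
  the largest $\lambda$ on that branch for both models: rare substrate is
  spatially confined, abundant substrate is dispersed.
* **Disarray.** On a slab with a fibre-disarray patch (κ = 2, correlation
  3 voxels) and a mirror-symmetric aligned control box — congruent boxes
  placed symmetrically so boundary effects cancel — the fibre model's
  anchor density is markedly higher inside the patch than in the control
  at the chosen coupling, while the null model, blind to orientation,
  shows no such contrast. The coupling is fixed by a pre-declared rule:
  the largest grid value at which reentry is clearly inducible
  ($\lambda \ge 0.005$ in a small calibration), i.e. the onset-of-reentry
  coupling, where aligned tissue is still protected by its longitudinal
  order.

## Numerical and degenerate-input conventions

Positions live in voxel units with voxel $(i,j,k)$ spanning
$[i-1,i)\times[j-1,j)\times[k-1,k)$; a point maps to the voxel containing
it. Zero-length orientation vectors at occupied voxels are an error that
reports the offending voxels; vectors at unoccupied voxels are discarded;
missing orientation terminates a streamline and is never fabricated.
Geometry containers are NIfTI (mask as uint8, vectors as a 4-d double
volume — double precision makes round trips bit-exact) or a native RDS
archive. Empty substrates give $\lambda = 0$ and an all-zero risk map;
$\lambda > 0$ with all-zero counts is an error. `smooth_map(σ = 0)` is the
identity. Every stochastic stage takes a seed, and ensemble members
derive theirs from one master seed, so all pipeline outputs are
bit-reproducible.

## Known limitations

The model is structural only: no action potentials, conduction
velocities, source–sink mismatch or functional block — it cannot study the
dynamics of fibrillation, only where anatomy permits micro-reentry. The
coupling grade $c$ is uniform across the tissue (region-dependent
coupling would need fibrosis imaging) and macroscopic/compact fibrosis is
not modelled. Streamline tractography cannot be validated against
histology here, and the uniform block susceptibility is a simplifying
assumption; $\lambda$ should be read as a relative, not an absolute, rate.
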