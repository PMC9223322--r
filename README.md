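# fibrenet

Spatial fibre networks for mapping where cardiac tissue is structurally
susceptible to micro-anatomical reentry.

Micro-anatomical reentry is a proposed driver of atrial fibrillation:
electrical activation circulating around a fibre tract that interstitial
fibrosis has electrically insulated from its neighbours. Such a circuit is
sustained only if its path length `ℓ` is at least one refractory wavelength
`τ`. `fibrenet` asks a purely structural question: given a tissue geometry
and its fibre-orientation field, *where* can insulated loops with
`ℓ ≥ τ` exist, and at which fibrosis grade?

The pipeline, for users working with voxel fibre-orientation data
(micro-CT, DTI, or synthetic):

1. **Tractography** — a modified evenly-spaced-streamlines tracer converts
   the per-voxel axial orientation field into global fibre tracts with node
   points every voxel length (seed/streamline separation `d_sep = 0.7`
   voxels, density ≈ 1 node per voxel).
2. **Network coupling** — consecutive nodes of a tract are connected with
   probability 1 (longitudinal edges); nodes on different tracts closer
   than `x < 2` voxels connect with probability

   `p(x; r, c) = 1 / (exp(r (x − c)) + 1)`,  `r = 7`,

   where the characteristic distance `c` is the (inverse) grade of
   interstitial fibrosis: reducing `c` removes transverse edges, exactly
   as fibrosis insulates fibres. A fibre-less null model (random nodes,
   distance-only coupling) isolates the contribution of fibre structure.
3. **Substrate detection** — a discrete diffusion model (synchronous
   excitation with a `τ`-step refractory period and a transient
   unidirectional block) finds every block that induces a self-sustaining
   loop; it provably agrees with the graph criterion "finite shortest
   return loop `≥ τ`", which doubles as an exact fast engine.
4. **Risk and structure metrics** — the global risk `λ` (reentry inductions
   per block opportunity), the local risk `R̃_v = λ N_v / Σ_v N_v` summing
   back to `λ`, Gaussian-smoothed risk maps, occupied voxel fraction (OVF,
   a bulk proxy for wall thickness/convexity), longitudinal connection
   fraction (LCF, a proxy for fibre alignment), DBSCAN-style substrate
   cluster counts with bootstrap error bars, and risk-weighted OVF × LCF
   distributions.

No imaging data is required: a seeded fixture generator provides slabs,
thickness wedges, pectinate-muscle-like ridges, pulmonary-vein-like
sleeves, fibre-disarray patches and structural holes.

## Worked example

```r
library(fibrenet)

# synthetic tissue: a thin atrial-wall-like slab
fx <- make_fixture(fixture_spec("slab", dims = c(40, 30, 4), thickness = 4))
tracts <- generate_tract_set(fx$geometry, fx$field, tractography_params(seed = 1))
net <- build_fibre_network(tracts, coupling_config(c = 0.55, seed = 1))
sub <- find_substrate(net, ddm_config(tau = 10))
glance(sub)
```

```
<tract_set> 122 tracts, 4823 nodes over 4800 occupied voxels (1.00/voxel)
<spatial_network:fibre> 4823 nodes, 5298 edges (4701 longitudinal, 597 transverse), c = 0.55
# A tibble: 1 x 5
  n_substrates n_evaluated n_substrate_nodes   tau lambda
         6040       10444              3069    10  0.578
```

At this coupling, 6040 of the 10444 evaluated unidirectional blocks sit on
an insulated loop of at least 10 node steps (`λ ≈ 0.58` — a heavily
fibrotic, high-risk substrate). Ensembles average over the coupling
randomness and localize the risk:

```r
risk <- ensemble_risk(fx$geometry, fx$field, "fibre", coupling_config(0.55),
                      ddm_config(tau = 10), n_networks = 20, n_circuits = 500,
                      tracts = tracts, seed = 1)
ovf  <- occupied_voxel_fraction(fx$geometry)
lcf  <- longitudinal_connection_fraction(net)
risk_weighted_distribution(risk, ovf, lcf)
```

```
<risk_map> lambda = 0.56100 over 20 network(s); 4234 voxels at risk
<risk_distribution> mean OVF: substrate 0.502 vs geometry 0.479
```

The risk-weighted mean OVF (0.502) against the geometry-wide mean (0.479)
says circuits in this slab show little wall-thickness bias at such a high
`λ`; sweeping `c` with `calibration_sweep()` reveals the full picture —
`λ(c)` vanishes at both strong and absent coupling with an interior
maximum, and at low `λ` the substrate concentrates in thin, low-OVF,
poorly aligned tissue. `autoplot()` methods display risk-map slices and
distributions; `plot_sweep()` shows `λ(c)` per model.

A thin CLI over the same functions is installed at
`inst/scripts/fibrenet` (subcommands `synth`, `trace`, `build`, `detect`,
`risk`, `metrics`, `sweep`, `run`), driven by YAML configs; `run` executes
the whole pipeline reproducibly and writes a manifest.

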