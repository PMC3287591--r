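# aquaperm

Single-channel water permeability analysis for membrane-channel molecular
dynamics trajectories, in R.

Aquaporins conduct water in single file, and the standard way to
characterize their transport from an equilibrium simulation is a pair of
single-channel permeability constants. **aquaperm** computes both, plus the
descriptive quantities usually reported next to them:

* **Diffusive permeability** `p_d = v_w * k0`, from counting complete
  permeation events: `k0 = N± / (2 * nm * t_sim)` with `N±` the completed
  boundary-to-boundary traversals pooled over `nm` monomers in `t_sim`, and
  `v_w = V_w / N_A ≈ 2.99e-23 cm^3` the volume of one water molecule.
* **Osmotic permeability** `p_f = v_w * D_n`, from the collective diffusion
  model: the collective coordinate `n(t)` accumulates the axial water
  displacements inside the constriction region in units of the channel
  length `L`, and `D_n` is fitted from its multi-origin mean-square
  displacement `<n^2(tau)> = 2 * D_n * tau`.
* **Single-fileness** `p_f / p_d`, which equals `N + 1` for a perfect single
  file of `N` waters (CTRW model) and falls toward 1 as water–water
  interchange increases.
* Channel occupancy histograms, HOLE-style pore radius profiles, water
  dipole order parameters `P1(z)`, `P2(z)`, and RMSD/RMSF/average-structure
  metrics.

It also ships an event-driven single-file channel simulator with exact,
closed-form ground truth (`simulate_single_file()`), so every estimator in
the package is validated end to end without any MD engine, plus geometric
fixtures with analytic answers for the pore-radius and orientation stages.

Trajectories are read from multi-MODEL PDB or multi-frame XYZ files
(`read_pdb()`, `read_xyz_multiframe()`); all analysis functions return
tibbles, results have `plot_*()`/`autoplot()` methods, and the `D_n` fit
supports `tidy()`/`glance()`.

## Worked example

Simulate a four-channel single-file system (7 waters per file, 50 ns per
channel at 2 ps frames) and run the full permeability pipeline:

```r
library(aquaperm)

sim <- simulate_single_file(n_monomers = 4, n_frames = 25000, seed = 1)
sim
#> <aq_sfsim> 7 site(s) x 4 monomer(s), 25000 frames; 168 logged traversals, k0 = 0.42 ns^-1

rep <- run_pipeline(sim$trajectory, sim$channel_def)
rep
#> <aq_report>
#>            quantity    M1    M2     M3    M4  mean    sd
#>                   L 19.60 19.60 19.600 19.60 19.60 0.000
#>                  k0  0.36  0.60  0.320  0.40  0.42 0.124
#>  p_d (1e-14 cm^3/s)  1.08  1.79  0.957  1.20  1.26 0.372
#>                 D_n  2.86  3.77  3.530  3.87  3.51 0.455
#>  p_f (1e-14 cm^3/s)  8.56 11.28 10.553 11.58 10.49 1.361
#>               pf_pd  7.95  6.29 11.029  9.68  8.74 2.062
#>           occupancy  7.00  7.00  7.000  7.00  7.00 0.000
```

Reading the table: each file holds exactly 7 waters (`occupancy`), the
channel length is `7 * 2.8 = 19.6 Å`, and the recovered single-fileness
ratio averages 8.7 ± 2.1 across monomers — consistent with the CTRW
prediction `N + 1 = 8` for a strict single file, with per-monomer scatter
coming from the finite event counts (168 traversals). The permeability
columns are in `1e-14 cm^3 s^-1`, the conventional scale for aquaporins.

`write_report(rep, "out/")` writes `report.json` (full precision),
`table1.tsv` (presentation rounding) and per-stage TSV series;
`plot_msd(rep$dn_fit)`, `plot_occupancy(rep$occupancy)` and friends draw
the standard figures.

For real trajectories, supply the channel definition yourself — the two
boundary atoms per monomer, e.g. carbonyl oxygens delimiting the
constriction region — either in code via `channel_definition()` or from a
YAML file via `read_channel_config()`:

```yaml
lateral_cutoff: 8
monomers:
  - id: M1
    top: name O & resno 195 & chain A
    bottom: name O & resno 79 & chain A
```

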