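# memglyco

Analysis of funnel-restrained simulations of glycopeptide–membrane
binding, in R.

Glycosylated helical peptides — such as CSF114(Glc), a designed
beta-turn antigenic probe carrying an N-glucosylated asparagine — can
associate with phospholipid bilayers with a preferred face: the
glycosylated side of the helix contacts the lipid head groups while the
opposite face stays solvent-exposed. Funnel-restrained molecular
dynamics is the standard way to sample such binding/unbinding
equilibria: a cone + cylinder boundary confines the unbound peptide to
a small solvent volume above the membrane so that binding events recur
on simulation timescales. memglyco implements the analysis side of that
experiment:

- **Funnel restraint** (`funnel_geometry()`, `bias_energy()`,
  `bias_force()`, `frame_bias_flags()`): cone half-angle 0.8 rad
  switching to a 1 Å cylinder at z = 35 Å, harmonic one-sided wall;
  frames biased by the wall are excluded from statistics.
- **Contact collective variable** (`switching_params()`,
  `contact_value()`, `per_side_series()`, `classify_bound()`): rational
  switching function with r0 = 5 Å, n = 8, m = 16, summed over
  peptide-Cα/phosphate pairs and normalised per tracked atom; bound
  when s > 0.5.
- **Pose clustering** (`rmsd_matrix()`, `average_linkage()`,
  `representatives()`): Kabsch-superposed core-Cα RMSD (residues 5–12),
  UPGMA agglomeration, population-ranked families with representative
  frames.
- **Chain order parameters** (`scd_profile()`, `profile_compare()`):
  per-carbon S_CD profiles with block-averaged errors and perturbation
  flagging between two systems.
- **Synthetic data with ground truth** (`build_ideal_helix()`,
  `simulate_funnel_langevin()`, `gen_bilayer_frames()`,
  `make_cluster_fixture()`): a rigid-helix Langevin simulator in an
  implicit membrane whose binding face and bound fraction are known by
  construction, used to validate every analysis stage.
- **Pipeline + CLI** (`run_binding_analysis()`,
  `run_order_analysis()`, `inst/cli/memglyco.R`): YAML-configured,
  hash-stamped, deterministic outputs.

The model, all parameter choices with units and rationale, and the
scope of the synthetic generators are documented in the methods
vignette, `vignettes/membrane-binding-analysis.Rmd`.

## Worked example

Simulate a glycosylated 21-residue helix binding an implicit membrane
inside the funnel, then analyse it. All numbers below are the actual
output of this code (seed 1).

```r
library(memglyco)

hx  <- build_ideal_helix()                          # 21 residues + glycan bead
sim <- simulate_funnel_langevin(hx, sim_config(seed = 1))

report <- run_binding_analysis(
  list(selections = list(), funnel = list(), contact = list(),
       clustering = list()),
  trajectory = sim$trajectory)
print(report)
#> mg_report: 2000 frames ( 1902 retained )
#>   mean s: Side1 3.152, Side2 1.793
#>   bound fractions: Side1 0.981, Side2 0.976, any 0.981
#>  cluster population fraction representative_frame
#>        1        382   0.9550                  693
#>        2          5   0.0125                  748
#>        3          3   0.0075                  272
#>        ...
```

The simulator's constructed ground truth for this run is a bound
fraction of 0.982 — the pipeline reports 0.981 — and the dominant pose
family (382 of 400 clustered frames, 95.5%) is the glycan-down
("Side1") orientation, matching the mean per-side contact values
(Side1 3.152 vs Side2 1.793). 98 of the 2000 frames touched the funnel
wall and were excluded.

Smaller building blocks behave as documented:

```r
p <- switching_params()
switch_value(c(0, 5, 10), p)
#> [1] 1.0000000 0.5000000 0.0038911

g <- funnel_geometry()
boundary_radius(c(0, 35, 40), g)    # cone mouth ... cylinder
#> [1] 37.0373  1.0000  1.0000
```

## Command line

```sh
Rscript inst/cli/memglyco.R validate --config analysis.yaml
Rscript inst/cli/memglyco.R synth --kind helix --out helix.pdb
Rscript inst/cli/memglyco.R run --config analysis.yaml
```

Verbs: `validate`, `funnel-check`, `contacts`, `cluster`, `scd`, `run`,
`synth`. Exit codes: 0 success, 1 usage error, 2 config/data error. Output CSVs
carry a `# config_hash:` header (md5 of the canonical parameter set) so
results are traceable to their configuration.

## License

MIT (see `LICENSE`).
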