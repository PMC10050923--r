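# billmech

Comparative biomechanics of cavity-excavating bird bills: does bill shape
trade impact resistance against torsion resistance, and does the natural
two-layer build (keratinous rhamphotheca over a bony core) beat a
homogeneous bill?

`billmech` is an R package for researchers in evolutionary morphology and
comparative biomechanics. It provides, end to end:

- a **parametric generator** for two-layer maxilla geometries (tapering
  superelliptic solids, keratin shell over bone core) and for synthetic
  clades whose bill dimensions evolve by correlated Brownian motion on a
  two-family phylogeny;
- a built-in **linear-elastic Tet4 finite-element solver** implementing
  the two excavation loading regimes — *impact* (10 N tip force, base
  fixed) and *torsion* (1.75 mrad base rotation, tip fixed) — with peak
  von Mises stress read off an outer-surface measurement zone at
  two-thirds of the bill length;
- the **closed-form elliptical-beam metrics**: critical buckling stress
  `σ_cr = π²Eb²/(16L²)` (impact performance, depth-controlled, from
  Euler's critical load with K = 2) and maximum torsional surface shear
  `τ_max = 2Gθa²b/((a²+b²)L)` (torsion performance);
- **phylogenetic comparative statistics**: Spearman correlations, PGLS
  under Pagel's λ (ML estimate plus fixed λ = 0 and λ = 1, with
  likelihood-ratio bound tests), Wilcoxon signed-rank tests, a
  REML-calibrated phylogenetic paired t-test, and Brownian-motion
  simulation;
- mesh I/O (ASCII PLY surfaces in/out, legacy VTK heat-map export) and a
  mesh-convergence harness with the 5% stress criterion.

## Worked example

```r
library(billmech)

report <- run_full_analysis(default_config(tier = "test", seed = 1))
print(report)
```

```
run_report: 15 species, 90 FE solves (test tier), 14.0 s total
Spearman correlations:
  peak_vm_torsion  vs peak_vm_impact   rho = -0.943  p = 1.425e-07
  sigma_cr         vs peak_vm_impact   rho = -0.986  p = 1.929e-11
  tau_max          vs peak_vm_torsion  rho =  0.854  p = 5.173e-05
  body_length      vs peak_vm_impact   rho = -0.950  p = 6.086e-08
  body_length      vs peak_vm_torsion  rho =  0.971  p = 1.687e-09
composite vs homogeneous (median % difference, + favours composite):
  impact  vs bone     +31.53 %  (Wilcoxon p = 6.104e-05)
  torsion vs bone    +110.22 %  (Wilcoxon p = 6.104e-05)
  impact  vs keratin  +31.53 %  (Wilcoxon p = 6.104e-05)
  torsion vs keratin   +7.59 %  (Wilcoxon p = 0.0004272)
```

Reading the output: species whose bills dissipate impact stress well
(deep, wide bills — low `peak_vm_impact`) are the ones that fare worst
under torsion, so the two peak stresses are negatively correlated
(rho = −0.94): the geometric tradeoff. Each regime's FE stress is
predicted by its beam metric — higher critical buckling stress goes with
lower impact stress (rho = −0.99), higher maximum shear with higher
torsion stress (rho = +0.85). And the composite keratin-over-bone build
has lower peak stress than a homogeneous bill in three of the four
comparisons (the two impact columns are identical because a homogeneous
bill's stress under a prescribed force is independent of its modulus).
The full per-species tables, PGLS fits at λ ∈ {ML, 0, 1}, paired tests
and VTK stress fields are in the returned `run_report` and, with
`out_dir` set, on disk; `make_fig_tables()` exports the performance-space
grid and scatter tables.

Individual stages are exported too:

```r
spec <- bill_spec(base_width = 0.016, base_depth = 0.020)
mesh <- make_bill_mesh(spec, n_axial = 24, n_circumferential = 16)
field <- solve_impact(mesh, material_assignment("composite"))
peak_vm_in_zone(field, mesh)           # Pa
beam_metrics(width = 0.016, depth = 0.020)
convergence_study(spec, material_assignment("composite"),
                  load_case("impact"), c(8, 12, 16, 24))
```

A thin command-line front end lives at `inst/scripts/billmech.R`
(`run`, `grid`, `converge` subcommands).

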