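# aquaflux

Stopped-flow osmotic permeability analysis and aquaporin conformer
selection, in R.

## What this is for

Aquaporins are membrane channels for passive water transport;
aquaglyceroporins such as AQP3 also conduct glycerol, and AQP3 is an
emerging anticancer drug target. The standard functional readout is
stopped-flow spectroscopy: cells are rapid-mixed with a hyperosmotic shock
solution and the resulting volume change is followed through scattered
light or self-quenching fluorescence. With an impermeant osmolyte the
cell simply shrinks (water efflux); with a glycerol shock the fast
shrinkage is followed by glycerol influx and reswelling, giving a
biphasic trace.

`aquaflux` is for researchers who need to turn such traces — or simulate
them — into permeability coefficients and inhibition statistics, and to
post-process molecular-dynamics sampling of the channel into
docking-ready conformations. It implements:

* a mechanistic two-flux cell-volume ODE
  (dV/dt = P_f·A·V_w·((N_i+N_g)/V − osm_out),
  dN_g/dt = P_gly·A·(c_out − N_g/V)) and its analytic equilibria;
* single-exponential rate extraction with phase detection and fluorophore
  bleach correction, then the standard inverse formulas
  P_f = k·(V_o/A)/(V_w·(osm_out)∞) and P_gly = k·(V_o/A), with percent
  inhibition and fold change;
* Hill dose–response fitting, y = 100/(1 + 10^((LogIC50 − X)·HillSlope)),
  with profile-likelihood and bootstrap confidence intervals for the IC50;
* 2D free-energy landscapes over inter-loop distance collective
  variables (ΔG = −k_B·T·ln(n/n_max)), basin detection, selection of
  binding-ready conformers (d1 > 1.9 nm, d2 > 1.19 nm), and per-residue
  ligand contact profiles from multi-model PDB files;
* a fully seeded synthetic-data generator (traces, dose–response sets,
  collective-variable samples, toy complexes) with ground truth recorded
  in every object, so the entire inverse chain is validated closed-loop.

## Worked example

```r
library(aquaflux)
presets <- aqpPresets()

# fit one synthetic hAQP3-yeast glycerol trace back to a permeability
baseline <- generateBaselineTrace(presets$yeast_aqp3, 300, 1000, seed = 1)
trace <- generateGlycerolTrace(presets$yeast_aqp3, 300, 1000, seed = 2)
tracePermeability(trace, "glycerol", baseline)
#> permeabilityResult (glycerol): P = 4.527e-06 +/- 9.7e-08 cm/s (k = 0.06787 s^-1)
```

The fitted reswelling rate (0.068 s⁻¹) times V_o/A returns the glycerol
permeability; the preset's true value is 4.54e-06 cm/s, so the single
noisy trace lands within 0.3%.

```r
# closed-loop yeast panel: 7 replicate traces per condition
panel <- runYeastAssays(seed = 7)
round(panel$fold_gly)
#> [1] 28        # hAQP3 vs empty-vector glycerol permeability
panel$inhibition_gly
#> [1] 73.19     # % inhibition of P_gly under Rottlerin treatment

# end-to-end dose-response: traces -> rates -> P -> inhibition -> IC50
conc <- 10^seq(log10(0.1), log10(150), length.out = 8)
dr <- doseResponsePipeline(presets$rbc, conc, replicates = 5, seed = 42,
                           kind = "glycerol", duration = 90, n_points = 600)
dr$fit
#> doseResponseFit: IC50 = 6.663 uM (95% CI 6.146-7.235), HillSlope = 3.25
```

The generator's true IC50 here is 6.7 µM with Hill slope 3.5: the
pipeline recovers the potency to ~0.6% from 80 noisy traces. A YAML-driven
runner (`runPipeline()`) and a thin CLI
(`inst/scripts/aquaflux-cli.R`, subcommands `simulate`, `fit-trace`,
`permeability`, `dose-response`, `landscape`, `contacts`, `run`) wire the
same stages into reproducible end-to-end runs with a manifest.

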