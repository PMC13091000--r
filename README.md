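# dtialps

Computation and statistical modelling of the DTI-ALPS index — "diffusion
along the perivascular space" — a diffusion-MRI proxy for glymphatic
(perivascular fluid) function, for researchers studying its development and
its clinical correlates in longitudinal cohorts.

At the level of the lateral ventricles, medullary veins and their
perivascular spaces run right–left (x), perpendicular both to projection
fibers (inferior–superior, z) and to association fibers
(anterior–posterior, y).  Per hemisphere the index is the ratio

```
ALPS = mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)
```

of x-axis diffusivity in projection/association-fiber ROIs to the
fiber-orthogonal diffusivities, where Dxx/Dyy/Dzz are diagonal
diffusion-tensor components extracted in native anatomical axes.  An index
of 1 means no excess mobility along the perivascular direction; values
above 1 index perivascular water mobility.

The package provides, end to end:

* **Tensor estimation** — log-linear least-squares fit from 4-D DWI +
  FSL-style bval/bvec (`fitTensorLogLinear`), canonical axis reorientation
  (`reorientToCanonical`), component/FA/principal-direction maps;
* **Automated ROI placement** — principal-direction classification inside a
  periventricular slab with an x-fiber exclusion rule (`placeRoisAuto`),
  plus the ALPS ratio (`computeAlps`) and a corpus-callosum Dxx negative
  control (`computeCcControl`);
* **QC** — group-wise IQR (±1.5) outlier fences and the bilateral-validity
  rule (`iqrFilter`, `bilateralValidity`, `filterAlpsTable`);
* **Statistics** — developmental-trajectory linear mixed models with
  participant random intercept+slope and a documented fallback ladder
  (`fitTrajectoryLmm`, `fitTrajectoryLmmFamily`), the ALPS → Glx/GABA
  regression (`fitEiOls`), deterministic χ²/Fisher 2×2 tests
  (`contingencyTest`), and BH-FDR (`bhFdr`);
* **Synthetic data** — tensor phantoms with known ground-truth ALPS
  (`buildTensorPhantom`, `phantomToDwi`) and simulated longitudinal
  cohorts with an MRS subset (`simulateCohort`, `simulateMrs`), so every
  stage is testable without clinical data;
* **Orchestration** — `runPipeline()` over a YAML config, and a thin CLI at
  `inst/cli/dtialps` (`run`, `simulate`, `table1`).

See `vignettes/dtialps-methods.Rmd` for the model, the design decisions and
their rationale, and known limitations.

## Worked example

Recover a known perivascular gain through the full imaging path — phantom
with ground truth ALPS = 1.5, 30-direction b = 1000 s/mm² acquisition at
SNR 30, tensor fit, automated ROI placement, index:

```r
library(dtialps)

spec <- phantomSpec(perivascular_gain = 1.5)
ph   <- buildTensorPhantom(spec)
dwi  <- phantomToDwi(ph$tensor, s0 = 1, noise_sd = 1/30, seed = 7)
tv   <- reorientToCanonical(fitTensorLogLinear(dwi))
comp <- tensorComponents(tv)
rois <- placeRoisAuto(faMap(tv), principalDirection(tv, mask = ph$masks$slab),
                      autoPlacementParams(slab_z = spec@slab_z))
computeAlps(comp$Dxx, comp$Dyy, comp$Dzz, rois)
#> AlpsMeasurement
#>   left: 1.526  right: 1.52  bilateral: 1.523
#>   qc: ok
```

The bilateral estimate 1.523 recovers the constructed gain 1.5 to within
the SNR-30 tolerance; noiseless runs return it to machine precision.

Fit the developmental trajectory model on a simulated cohort (83 controls,
85 deletion carriers, 1–3 scans each, group effect −0.05) after QC:

```r
co  <- simulateCohort(cohortSpec(), seed = 1)
qc  <- filterAlpsTable(co)
fitTrajectoryLmm(qc$table, keep_mask = "keep_bilateral")
#> Linear mixed-effects fit (full model): 282 obs, 163 participants
#>    alps_bilateral ~ .grp * .age_c + sex + (1 + .age_c | participant)
#>            term estimate      se     z        p     ci_lo    ci_hi
#>     (Intercept)  1.34290 0.01805 74.41 0.000000  1.307530  1.37828
#>        groupDEL -0.02499 0.02106 -1.19 0.235377 -0.066273  0.01629
#>           age_c  0.00375 0.00158  2.38 0.017379  0.000659  0.00684
#>            sexM  0.04877 0.02094  2.33 0.019878  0.007720  0.08981
#>  groupDEL:age_c -0.00746 0.00226 -3.30 0.000978 -0.011897 -0.00303
```

`groupDEL` is the group difference at the sample's mean age (here −0.025
with SE 0.021 for this single draw; across replicates the estimator is
centred on the generative −0.05 and its 95% CI covers it ~96% of the
time).  The carrier-only psychotic-symptom age interaction in the
generator (−0.01/yr) surfaces in `groupDEL:age_c`.

A demographic-table style 2×2 comparison (counts 41/27 vs 25/43):

```r
contingencyTest(41, 27, 25, 43)
#> 2x2 contingency test: yates_chi2, p = 0.01006
```

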