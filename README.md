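# bmdrank

Benchmark-dose (BMD) modelling and cross-tissue sensitivity ranking for
multi-endpoint genetic toxicology studies.

Studies of genotoxic carcinogens in transgenic rodent models measure several
mechanistically linked endpoints in the same animals — DNA adduct frequency
(per 10⁸ nucleotides), lacZ transgene and *Pig-a* mutant frequencies, and
micronucleated reticulocyte/erythrocyte frequencies — across many tissues
and an extended dose range. `bmdrank` implements the quantitative analysis
such studies need, for toxicologists and biostatisticians who want the whole
chain in one tested, scriptable package:

* **Dose-response modelling** with the nested exponential family for
  continuous data (m1: `y = a`; m2: `y = a·exp(bx)`; m3: `y = a·exp(bx^d)`;
  m4: `y = a·(c − (c−1)·exp(−bx))`; m5: `y = a·(c − (c−1)·exp(−bx^d))`)
  under log-normal errors, with analytic profiling of `log a` and `σ`.
* **Model selection** by the nested likelihood-ratio ladder
  (m2 → {m3, m4} → m5, each step accepted when 2·ΔLL exceeds the χ²
  critical value at α = 0.05), with a full audit trace.
* **BMD estimation**: closed-form inversion of the fitted curve at the
  benchmark response (CES = 1, i.e. BMD₁₀₀ = the dose doubling the
  background response) and two-sided 90% **profile-likelihood confidence
  intervals** (BMDL, BMDU) solving 2·(LLmax − LLprofile) = χ²₁,₀.₉₀ = 2.7055.
* **Trend testing** by Poisson regression: an overall likelihood-ratio
  chi-square (categorical dose, log-denominator offset) plus per-dose
  contrasts against control with the significance tiers *a* (p < 0.0001),
  *b* (< 0.001), *c* (< 0.01), *d* (< 0.05), and the LOGEL.
* **Sensitivity ranking** of tissues by the geometric midpoint
  √(BMDL·BMDU), with non-overlapping CIs declaring tissues distinguishable,
  and forest plots of the intervals.
* **Cross-endpoint comparison** (BMD progression and the fitted
  maximum-response parameter `c`) and **unity-slope proportionality
  analysis** between two endpoints' BMDs on the double-log scale, including
  a Ki-67 proliferation-index correlation helper.
* A seeded **synthetic-data generator** emulating the study design (11 dose
  groups at 0–50 mg/kg BW/day, 7 animals per group, 14 vehicle controls)
  with endpoint-appropriate noise, plus presets anchored to the published
  fold-change structure of a large benzo[a]pyrene MutaMouse study.

## Worked example

```r
library(bmdrank)

ds <- generate_preset("lacz_bone_marrow", seed = 1)  # synthetic study data
ds
#> <dr_dataset> bone_marrow / lacz_mf (count)
#>   84 animals, 11 dose levels (mg/kg BW/day): 0, 0.1, 0.2, 0.39, 0.78, 1.56, 3.13, 6.25, 12.5, 25, 50
#>   response units: mutants per 10^5 pfu

sel <- select_model(ds)
sel
#> <exp_selection> selected: m5 (alpha = 0.05, n = 84)
#>  comparison      stat df     crit accepted
#>    m2 vs m1 139.33143  1 3.841459     TRUE
#>    m3 vs m2   0.00000  1 3.841459    FALSE
#>    m4 vs m2  41.87523  1 3.841459     TRUE
#>    m5 vs m4  49.24129  1 3.841459     TRUE

estimate_bmd(sel, ds)
#> <bmd_estimate> bone_marrow / lacz_mf (m5, CES = 1)
#>   BMD = 2.764  [2.142, 3.454] 90% CI  (BMDU/BMDL = 1.61)
```

The ladder trace reads: a dose effect exists (m2 ≫ m1), the saturating m4
beats the plain exponential, and the extra shape parameter of m5 is still
worth one more degree of freedom. The selected curve doubles the background
lacZ mutant frequency at 2.76 mg/kg BW/day, with the 90% profile CI
[2.14, 3.45] — a BMDU/BMDL ratio of 1.6, i.e. a usefully precise estimate
(the preset's true doubling dose is 3.3, inside the interval).

Whole-study analyses go through the pipeline:

```r
rep <- run_pipeline(
  c(grep("^lacz_", preset_names(), value = TRUE),
    grep("^adducts_", preset_names(), value = TRUE)),
  run_config(seed = 1, out_dir = "results")
)
rep$rankings$lacz_mf        # CI-overlap sensitivity ranking
rep$proportionality[[1]]    # adduct vs lacZ unity-slope analysis
plot_bmd_forest(rep$rankings$lacz_mf)
```

A thin command-line wrapper with `simulate` and `run` subcommands lives at
`inst/cli/bmdrank.R`.

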