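# polkin

Transient-state kinetic analysis of RNA polymerase multi-nucleotide
addition, for enzymologists studying transcription elongation with chemical
quench-flow data — in particular the selective inhibition of RNA
polymerase I by the DNA intercalator BMH-21.

In the underlying assay, elongation complexes carrying a radiolabeled
10-mer RNA are rapidly mixed with saturating NTPs, quenched at times from
5 ms to 10 s, and resolved on sequencing gels; the fraction of lane signal
in each RNA-length band (10-mer through 19-mer) versus time is the
observable. `polkin` provides:

* **Kinetic schemes** (`build_scheme`): linear first-order networks for the
  four mechanisms — an irreversible Pol I chain with intrinsic nuclease
  cleavage (`S1`, rates `k1..k9`, `k10`), its extension with off-pathway
  paused states at the 11-/12-mer for Pol I + BMH-21 (`S2`,
  `kon1/koff1`, `kon2/koff2`), a reversible pyrophosphorolysis-competent
  Pol II chain (`S3`, `kF_i/kR_i`), and a Pol III chain with activation of
  an inactive subpopulation (`S4`, `kact`, `f_inactive`). Schemes
  serialize to JSON so custom mechanisms need no code changes.
* **An exact solver** (`solve_timecourse`): eigendecomposition of the rate
  generator (matrix-exponential and stiff-ODE fallbacks), projected onto
  gel bands by `project_observables` (same-length species co-migrate).
  `bateman_chain` supplies the closed-form oracle for irreversible chains.
* **Synthetic data** (`default_scenarios`, `generate_dataset`): noisy
  replicate datasets with the statistical structure of the assay, standing
  in for the study's undeposited raw data.
* **Global fitting** (`fit_global`, `hybrid_optimize`): a hybrid genetic
  algorithm + Levenberg–Marquardt search fitting one shared parameter set
  to all nine product bands simultaneously, with per-replicate fits
  aggregated as mean ± SD (`aggregate_replicates`).
* **Model comparison and summaries** (`compare_schemes`,
  `summarize_kinetics`): AICc selection between candidate schemes plus the
  tabulated conventions (mean addition-step rate, fold changes,
  forward/reverse ratios).
* **EC stability analysis** (`analyze_stability`, `collapse_fraction`):
  RNase-protection collapse fractions, condition contrasts, and an
  optional exponential collapse fit.

## Worked example

Simulate the Pol I + BMH-21 arm, fit both candidate schemes, and ask which
mechanism the data support:

```r
library(polkin)

sc  <- default_scenarios()
ds  <- generate_dataset(sc$pol1_bmh21, seed = 42)

fits <- fit_replicates(ds, config = fit_config(seed = 1))
agg  <- aggregate_replicates(fits)
agg
#> <aggregated_fit S2: 3 replicate fits>
#>           mean     sd
#> k1    38.70000 0.3230
#> k2    34.06000 1.1900
#> k3    27.17000 1.9300
#> k4    27.41000 1.1000
#> k5    30.94000 5.7600
#> k6    32.32000 4.5700
#> k7    32.09000 2.5100
#> k8    26.83000 3.7100
#> k9    22.42000 4.6900
#> kon1  18.97000 0.5840
#> koff1  0.49900 0.0413
#> kon2  12.17000 0.5170
#> koff2  0.48540 0.0331
#> k10    0.03149 0.0528

cmp <- compare_schemes(ds$replicates[[1]],
                       list(build_scheme("S1"), build_scheme("S2")),
                       fit_config(seed = 1))
cmp
#> <model_comparison>
#>  scheme        ssr       aicc    delta
#>      S1 0.81923720  -949.3191 511.8547
#>      S2 0.04530342 -1461.1739   0.0000
#> preferred: S2
```

The replicate-averaged rate constants recover the generating values (pause
entry ~20 s^-1, exit ~0.5 s^-1), and AICc decisively prefers the
paused-state scheme on data generated with pausing — the formalized version
of "the simple chain fails to describe the drug-treated time courses".

Condition summaries follow the tabulated conventions:

```r
summarize_kinetics(sc$pol3_bmh21$true_params,
                   reference = sc$pol3_vehicle$true_params)
#> <kinetic_summary>
#>   mean k_obs (addition steps): 39 s^-1
#>   reduction vs reference: 20.4%
```

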