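# noisenet

Condition-dependent gene expression noise and its propagation through a
transcription-factor regulatory network.

## The scientific problem

Genome-wide reporter studies in bacteria measure, by flow cytometry, the
distribution of expression of each promoter across single cells, in each
of several growth conditions. Two robust observations organize such data:

1. The variance of log-expression across promoters has a hard lower
   envelope as a function of mean expression — a condition-specific
   **noise floor** that decreases with growth rate.
2. Above the floor, the **relative noise levels** of promoters are highly
   condition-dependent, and much of that structure is explained by
   **noise propagation**: fluctuations in the activity of transcription
   factors (TFs) transmit to the expression variance of their target
   promoters.

`noisenet` is an R package for this analysis chain, aimed at researchers
working with promoter-reporter cytometry libraries and regulatory-network
annotations. It covers:

- robust per-promoter/per-condition mean and variance of
  log-fluorescence via an EM-fitted **Gaussian + uniform outlier
  mixture** (C++ core; ~3 ms per 5,000-event fit);
- the per-condition **minimal-variance envelope**
  `v_min(m) = a_c + b_c exp(-m)` (binned lower-quantile fit under
  positivity constraints), **noise levels** `N_pc = v_pc - v_min(m_pc)`,
  and the regression of the floor `a_c` on growth rate;
- **TF activity inference** from the centered linear model

  ```
  N_pc - N̄_c = ε + Σ_r (S_pr - S̄_r) A_rc
  ```

  by ridge regression (Gaussian prior, cross-validated strength), with
  posterior error bars `δA_rc`, explained variance (FOV), a row-shuffle
  permutation null, condition-specific propagator calling
  (`A_rc > δA_rc` in exactly one condition), and condition-averaged
  ranking by `|Ā_r/δĀ_r|`;
- **enrichment statistics** linking noise to regulatory inputs (cutoff
  curves, Welch tests, plasticity by input-count groups);
- **PCA of the 10-gene-feature correlation matrix** (expression levels,
  codon bias, evolutionary rates, regulation/noise features);
- a **synthetic-data generator** reproducing the statistical structure of
  such a study (log-normal fluorescence, uniform outliers,
  condition-dependent floor, sparse binary network, planted global and
  condition-specific propagators) so the whole pipeline is testable
  end-to-end against ground truth.

## Worked example

Simulate a small study (400 promoters, 12 TFs, 4 conditions, 1,000
events per promoter x condition), push it through the full chain, and
compare with the planted truth:

```r
library(noisenet)

truth <- simulate_noise_study(P = 400, R = 12, C = 4,
                              n_condition_specific = 2, n_global = 3,
                              n_events = 1000, seed = 1)
summaries <- summarize_replicates(summarize_study(truth))
nl <- noise_level_matrix(summaries)
nl$fits[["cond1"]]
#> Noise floor [cond1]: a = 0.02034, b = 0.8262 (q = 0.05, 400 promoters)

fit <- floor_vs_growth_rate(nl$fits, truth$metadata$growth_rate)
#> slope = -0.0191, intercept = 0.0528, R^2 = 1.000

est <- infer_activities(nl$noise, truth$network, lambda = "auto", seed = 1)
est
#> Activity estimates: 12 regulators x 4 conditions (400 promoters, lambda = 1)
#>   in-sample FOV: 54.6%, 48.7%, 51.4%, 53.0%

average_activities(est, top_k = 3)$table[1:3, ]
#>   regulator   A_bar delta_A_bar significance
#> 1      TF05 0.00957    0.000407         23.5
#> 2      TF03 0.01029    0.000453         22.7
#> 3      TF01 0.00940    0.000453         20.8
attr(truth$activities, "global_regulators")
#> [1] "TF03" "TF01" "TF05"

sh <- randomized_fov(nl$noise, truth$network, lambda = est$lambda,
                     n_shuffles = 100, seed = 1)
#> shuffled-null FOV: 2.9% +/- 1.0%  (observed 52.0%)
```

Reading the numbers: the fitted floor (`a = 0.020`) and Poissonian term
(`b = 0.83`) recover the generator's `0.021` and `0.8`; the floor
declines linearly with growth rate at the planted slope; the three
planted condition-independent propagators are exactly the top three by
significance, each inferred at its planted activity `0.01` (variance of
log-fluorescence per target, ~23 error bars above zero); and the model
explains ~52% of centered noise variance versus ~3% after shuffling the
association between promoters and their regulatory inputs.

`run_noise_pipeline(noise_pipeline_config(...))` orchestrates the same
stages from TSV inputs (events, network edge list, growth rates) and
writes one TSV per artifact plus a JSON run manifest; reruns with the
same config and seed are bit-identical.

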