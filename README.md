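# wormmem

Analysis of associative-memory coding in the compact neural network of
*C. elegans*.

Worms trained to associate the odorant butanone (the conditioned stimulus,
CS) with food or starvation shift their preference for butanone against an
alternative attractant (diacetyl). `wormmem` implements the computational
side of studying how those memories are encoded: processing calcium-imaging
traces recorded during butanone/diacetyl exchange protocols, testing
group differences across training paradigms, decoding the training
condition from population activity, explaining interneuron activity as a
linear combination of sensory inputs, isolating experience components by
PCA filtering, quantifying chemotaxis locomotion, and simulating the
two-choice assay from measured locomotion parameters. Synthetic-data
generators with planted ground truth make every stage verifiable.

## Core quantities

- **Choice Index** for endpoint counts:
  `CI = (n_cs − n_alt) / (n_cs + n_alt) ∈ [−1, +1]`, −1 complete aversion
  to the CS, +1 full attraction. **Learning Indices** are CI differences:
  `LI_stimulus = CI_trained − CI_mock`, `LI_training = CI_trained −
  CI_naive`, `LI_treatment = CI_mock − CI_naive`.
- **Ground-state normalization** `F/F_G`, with `F_G` the mean of smoothed
  intensities below the 10% quantile (20-frame kernel), or the mean of the
  last 10 frames for short recordings.
- **Comparison design**: 18 pairwise group contrasts (8 for the exchange
  dataset), normality-gated t/Wilcoxon tests on 95%-CI-filtered summed
  activities, Storey pFDR q-values (λ = 0.5).
- **Decoding**: per-trial binned + z-normalized multi-neuron features,
  stratified 60/40 splits × 10 rounds, macro F1, with kNN (k = 2,
  distance-weighted), 500-tree random forest, and a (50, 100) MLP.
- **Linear combination**: OLS of interneuron activity on trial-averaged
  sensory activities in 15 s post-switch windows, with incremental fits and
  50/50 cross-validation.
- **Component PCA**: a 36-row (component × trial) delta matrix,
  reconstruction from selected principal components, amplitude-normalized
  signed change maps, k-means significance thresholding.
- **Locomotion / simulation**: per-24-frame-segment deviation angle, speed
  and reversal rate; agent-based two-choice simulation with hybrid cohorts
  attributing the behavioural gap to single parameters.

## Worked example

```r
library(wormmem)

# a synthetic exchange-protocol dataset with a planted effect:
# AWA loses its butanone response in STAP-trained animals
neurons <- tibble::tibble(neuron_id = c("AWA", "AWCON"),
                          responder_type = c("ON", "OFF"),
                          base_amplitude = c(1.5, 2))
eff <- effect_matrix(c("AWA", "AWCON"))
eff["AWA", "CSap"] <- -1
cfg <- trace_gen_config(neurons, n_animals = 8, noise_sd = 0.05, seed = 7)
ds <- gen_trace_dataset(cfg, eff)

summed <- summed_activities(ds, switch_type = "but_on")
res <- run_comparisons(summed)
dplyr::filter(res, q < 0.05) |>
  dplyr::count(neuron_id, group_a, group_b)
#> # A tibble: 3 × 4
#>   neuron_id group_a group_b     n
#>   <chr>     <chr>   <chr>   <int>
#> 1 AWA       STAP-T  STAP-M      6
#> 2 AWA       STAP-T  STAV-T      6
#> 3 AWA       STAP-T  naive       6

behavior_indices(endpoint_counts(90, 10), endpoint_counts(60, 40),
                 endpoint_counts(50, 50))[c("CI_trained", "LI_stimulus")]
#> $CI_trained
#> [1] 0.8
#> $LI_stimulus
#> [1] 0.6
```

Of the 96 comparisons run (2 neurons × 6 switches × 8 contrasts), the
significant ones single out AWA in exactly the three contrasts that involve
the STAP-trained group — the planted stimulus-specific response loss —
across all six exchange trials, with no false positives at q < 0.05.

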