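# pavlophys

Statistical analysis of head-fixed Pavlovian reward/punishment
discrimination sessions with simultaneous extracellular single-unit
recordings — written for experiments in which auditory thalamus (MGN) and
basolateral amygdala (BLA) are recorded while mice learn that one tone
(CS-E) predicts a reward and another (CS-A) predicts an airpuff.

The package implements the full pipeline as reusable functions plus a set
of numbered analysis drivers, and ships a ground-truth-labelled session
simulator so everything can be run and validated without recorded data:

* **behavior** — lick detection from an IR beam-break voltage trace;
  bootstrap power analysis of anticipatory-vs-ITI licking (paired *t*,
  1000 resamples per trial count); acquisition and discrimination learning
  criteria (*p* < 0.01 on first/last/random 20-trial subsets plus a >50%
  anticipatory-licking rate check); hit / miss / false-alarm /
  correct-rejection trial labels.
* **phototag** — photoidentification of MGN→BLA projectors (signed-rank
  *p* < 0.001 and peak *z* > 3.5 within 10 ms of the 5 ms 1 Hz light
  pulses) and of in-network BLA units (rank-sum *p* < 0.001 within 50 ms).
* **ensemble** — PSTHs, baseline *z*-scoring with causal Gaussian
  smoothing, 0–100 ms signed-rank responsiveness calls, and the nine-way
  valence/arousal category (E±A±, E±, A±, none) with χ²/Fisher and
  leave-one-subject-out Kruskal–Wallis statistics.
* **trajectories** — shared-basis PCA state-space trajectories per region
  and condition; leave-one-subject-out polyline lengths and per-bin
  inter-trajectory distances with rank-sum / Kruskal–Wallis comparisons.
* **phasic clustering** — Ward (Euclidean) hierarchical clustering of
  concatenated per-condition *z*-PSTHs, dendrogram cut at 23% of the
  maximum merge height, clusters under 3 members discarded, with
  leave-one-out prevalence statistics and composition tables.
* **tonic** — per-trial counts in ITI baseline [−3,−2), pre-cue [−1,0) and
  response [0,1) windows, baseline *z*-scoring and across-trial smoothing,
  Ward clustering of the concatenated E/A × pre/response series at the 20%
  cutoff, and a tonic-change test: OLS of count on trial index, flagged
  when the 95% CI on the slope excludes zero.

The methods, parameter choices and calibration caveats are documented in
`vignettes/pavlophys-methods.Rmd`.

## Worked example

```r
library(pavlophys)

study <- simulate_study(sim_config(seed = 1))
s <- study$sessions[[1]]

# behavioural learning criterion
counts <- per_trial_lick_counts(s$licks, s$trials)
assess_learning(counts[counts$cs_type == "E", ],
                counts[counts$cs_type == "A", ], "discrimination", seed = 1)
#> <learning_outcome: discrimination, learned = TRUE (anticipatory rate 1.00)>
#>     subset            p effect_ok pass
#>   first_20 1.511122e-08      TRUE TRUE
#>    last_20 3.801202e-09      TRUE TRUE
#>  random_20 2.937361e-12      TRUE TRUE

# photoidentification
head(tag_session(s), 3)
#>       unit_id region   p_value    z_peak latency_ms        class
#> 1 subj01_u001    MGN 0.3995171 1.7119574   5.852072 MGN_untagged
#> 2 subj01_u002    MGN 1.0000000 0.7086652   3.391776 MGN_untagged
#> 3 subj01_u003    MGN 0.3740628 0.9703446   7.794366 MGN_untagged
```

Each subject "learned" because all three 20-trial subset tests reject at
*p* < 0.01 with more reward-trial than punishment-trial licking, and every
reward trial had anticipatory licks. Untagged MGN units show chance-level
light responses (p ≫ 0.001, peak z < 3.5), so they keep the unidentified
label.

The numbered drivers run the same stages over a session directory and
write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1      # sessions + ground truth
Rscript analysis/02_behavior.R 1      # learning table, power curve, outcomes
Rscript analysis/03_phototag.R        # unit classification vs ground truth
Rscript analysis/04_categorize.R      # valence categories + statistics
Rscript analysis/05_trajectories.R    # PCA trajectories + geometry
Rscript analysis/06_cluster_phasic.R  # Ward clustering of phasic profiles
Rscript analysis/07_cluster_tonic.R   # tonic clustering + slope test
```

`run_pipeline(sim_config(seed = 1), out_dir = "results/run")` chains all
stages in one call and writes a machine-readable `summary.json`.

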