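---
title: "Methods: analysing Pavlovian reward/punishment electrophysiology with pavlophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing Pavlovian reward/punishment electrophysiology with pavlophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`pavlophys` implements the statistical pipeline for a head-fixed Pavlovian
discrimination experiment with simultaneous extracellular recordings in two
connected regions (auditory thalamus, MGN, and basolateral amygdala, BLA).
Each discrimination session presents 75 reward-predicting (CS-E) and 35
punishment-predicting (CS-A) tone trials (4 s tone, US onset jittered
1–1.5 s after cue onset, cue onsets separated by the tone plus a uniform
16–24 s inter-trial interval). The package covers:

1. behavioural analysis — lick detection, a bootstrap power analysis that
   justifies 20-trial subsets, and the acquisition/discrimination learning
   criteria;
2. optogenetic photoidentification of MGN→BLA projectors and in-network BLA
   units;
3. peri-stimulus time histograms, baseline z-normalisation, and a-priori
   valence/arousal response categories;
4. population state-space trajectories by PCA with leave-one-subject-out
   geometry statistics;
5. Ward hierarchical clustering of phasic response profiles; and
6. a between-trial tonic-change analysis based on the confidence interval
   of a regression slope.

Because no recordings ship with the package, a first-class synthetic-data
module generates complete sessions with ground-truth labels; every analysis
stage is validated against that ground truth in the test suite.

# The synthetic study

`sim_config()` fixes the study conditions; `simulate_study()` draws from
them. Spike trains are inhomogeneous Poisson processes: each unit's
instantaneous rate is

$$\lambda(t) = \big[\,\lambda_0 + s\,(k(t)-1) + \textstyle\sum_{\text{trials}} a_c\,
e^{-(t - t_{\text{cue}} - \ell)/\tau}\,\mathbf{1}[t \ge t_{\text{cue}}+\ell]\,\big]_+$$

with baseline $\lambda_0$ (default 5 Hz), tonic drift $s$ per trial index
$k(t)$, and a per-cue phasic kernel with signed amplitude $a_c$, onset
latency $\ell$ and exponential decay $\tau$. The rate is evaluated on a
10 ms grid, rectified at zero, and spikes are placed uniformly within grid
steps (exact for a piecewise-constant rate).

Defaults and the reasoning behind them:

* **Trial structure** (75 E / 35 A, 1–1.5 s US jitter, 20 ± 4 s ITI read as
  uniform on [16, 24] s, unconstrained seeded shuffle for trial order) is
  the discrimination-session design the analyses assume. The US onset is
  drawn relative to cue onset so the anticipatory window is the jittered
  first 1–1.5 s of the tone.
* **Response templates.** Five archetypes (excited to E, to A, to both,
  inhibited by both, flat) with 15 Hz phasic amplitudes, 15 ms onset
  latency and ~0.3 s decay. These are typical magnitudes for auditory
  thalamus/amygdala cue responses; the latency matters because the
  responsiveness tests use a 0–100 ms window, and a realistic short latency
  leaves most of the evoked response inside it.
* **Tonic drift**: 20% of units drift at 0.05 spikes/trial (in a 1 s
  window), applied linearly in trial index across each trial's whole epoch,
  matching the linear-regression detection model downstream.
* **Licking**: Poisson, 1 Hz during the ITI and 6 Hz in reward anticipatory
  windows for learners; punishment-trial anticipatory rate defaults to the
  ITI rate. The paper-scale effect (learners lick throughout the
  anticipatory period) is what the learning criteria are designed to
  detect; the exact rates are tuning knobs, not claims about real animals.
* **Phototagging**: a post-task laser epoch (1 s pulses, then 100 pulses
  each of 5 ms at 1/10/20 Hz). Tagged MGN→BLA units spike once per 5 ms
  pulse with probability 0.9 at a uniform 3–8 ms latency. In-network BLA
  units — polysynaptic followers — respond with probability 0.6 at
  12–35 ms. The BLA parameters are generator plumbing chosen so that the
  four subpopulations are recoverable; only their qualitative structure
  (longer latency, lower reliability, inside 50 ms) matters downstream.

What the generator does **not** emulate: refractoriness, bursting,
adaptation, non-Poisson count dispersion, correlated noise across units,
electrode drift, or sorting errors. Passing tests therefore demonstrate
that the statistical machinery is correct and calibrated under its own
model assumptions — not that those assumptions hold in any particular
recording.

# Behavioural criteria

Licks are downward threshold crossings of the IR beam-break voltage,
merged within a 30 ms refractory period (rhythmic licking tops out near
10 Hz, so 30 ms only removes sensor chatter). Each trial contributes an
anticipatory count (cue onset to US onset, half-open) and a count from a
duration-matched window immediately preceding cue onset.

`bootstrap_power()` resamples n trials with replacement 1000 times per
candidate n and reports the fraction of resamples whose paired t test on
anticipatory-vs-ITI counts is significant at α = 0.05. Resampling is with
replacement; zero-variance resamples count as not significant.

`assess_learning()` implements both criteria at α = 0.01 on 20-trial
subsets. Acquisition uses paired t tests on the first and last 20 reward
trials, passing on either subset (mirroring the discrimination rule's "any
of the three"); discrimination uses two-sample t tests on per-trial
difference scores (anticipatory − ITI) between CS-E and CS-A over the
first 20, last 20, and a seeded random 20 trials, with the additional
requirement that raw CS-E licks exceed raw CS-A licks. A subject must also
emit at least one anticipatory lick on more than half of the reward
trials; `learned` is the conjunction of any-subset-pass and this rate
check, in both modes. The acquisition t test is paired because the
windows are matched per trial; the discrimination test is two-sample
because E and A trials are different trials.

# Photoidentification

For each unit, per-pulse spike counts in [0, w) after light onset are
compared against a duration-matched pre-pulse window across the 100 pulses
of the 5 ms 1 Hz block — paired Wilcoxon signed-rank for MGN (w = 10 ms),
unpaired rank-sum for BLA (w = 50 ms), thresholds p < 0.001. MGN units
must additionally reach a peak z > 3.5 in the 1 ms-binned pulse-aligned
response, z-scored against the mean/SD of the pre-pulse bins (50 ms span).
Peak-bin z (rather than window-mean z) is used because a 10 ms window at
1 ms resolution is exactly where a reliable evoked spike concentrates; the
choice is exposed through the returned statistics. The 10 ms latency
threshold is a fixed constant justified by ex vivo evidence against
recurrent excitation among the projectors. Units with no evoked spikes get
an undefined latency and are never tagged.

# Responsiveness and valence categories

Task responsiveness uses per-trial counts in [0, 100 ms) after stimulus
onset against a 3 s baseline ending at cue onset, rescaled to the 100 ms
equivalent, in a paired signed-rank test at α = 0.01; the response sign
(excited/inhibited) is the sign of the mean baseline-referenced z. The
nine-way valence/arousal category combines the per-CS significance and
sign: E±A± when both CS tests are significant, single letters for one, and
"none" otherwise. Same-sign categories (E+A+, E−A−) indicate
arousal/salience coding; mixed signs indicate valence coding.

A calibration caveat worth knowing: comparing an integer 100 ms count with
a 1/30-scaled 3 s count gives a null difference distribution that is
mean-zero but not symmetric, so the signed-rank test rejects slightly
above nominal (about 2% per stimulus at α = 0.01 with 30 trials in our
simulations, drifting up with trial count). The test suite freezes the
simulated null calibration (~96% of unmodulated units labelled "none")
rather than the nominal value. The US window is taken symmetrically as
0–100 ms after US onset.

Category proportions are compared with chi-squared tests, switching to
Fisher's exact test whenever a cell count is below 5. Prevalence across
categories (and later, clusters) uses leave-one-subject-out count
distributions: the count vector is recomputed k times leaving out each
subject, a Kruskal–Wallis test runs across groups, and on significance the
largest-mean group is compared to each other group by rank-sum at a
Bonferroni-adjusted α = 0.05/(number of pairwise tests actually run).

# Trajectories

Per region, 50 ms-bin PSTHs per condition are z-scored against the −2 s
baseline, smoothed with a causal Gaussian (25 previous bins for the
2-condition CS analysis, 10 for the 4-condition outcome analysis), and
concatenated along time; PCA is fit once on the concatenated bins × units
matrix (features centred), so all conditions share one basis. Fitting is
per region because the two regions are analysed in separate state spaces.
Trajectory length is the polyline length of the first 3 PCs; distance is
the per-bin Euclidean distance between two condition trajectories, with
means over the 1 s pre-cue and 1 s post-cue windows. Leave-one-subject-out
statistics refit the basis without the held-out subject's units, which
keeps every statistic a function of a self-contained population. Each PC
is oriented so its largest-magnitude loading is positive — PCA signs are
otherwise arbitrary and this makes outputs reproducible; lengths and
distances are invariant to the convention. With k = 3 subjects the
rank-sum comparisons bottom out at p = 0.10, so geometry statistics only
become informative at larger k; the test suite uses k = 4–7 where
significance matters.

# Phasic clustering

Features are the concatenated per-condition smoothed z-PSTHs (100 ms bins,
−2 s baseline, 10-bin causal smoothing); units with zero baseline SD or
non-finite z-scores are removed and reported, mirroring NaN handling.
Clustering is agglomerative with Ward linkage on the Euclidean metric
(`stats::hclust(method = "ward.D2")`), the tree is cut at a fraction of
the maximum merge height — 0.23 for the phasic analyses (0.30 is the
documented alternative for the 4-condition outcome variant, passed through
`cutoff_fraction`), 0.20 for the tonic variant — and clusters under 3
members are discarded with their units
flagged rather than reassigned. "Fraction of the max value in the set" is
read as the standard dendrogram cutoff: fraction × maximum linkage height.
Retained labels are canonicalised by decreasing size with ties broken by
smallest member index, so unit order never changes memberships, only
numbering. The suite verifies the linkage against a from-scratch O(n³)
Ward implementation (merge sequences and heights, exactly) and recovers
four generating templates with adjusted Rand index ≥ 0.9.

# Tonic analysis

Per unit and CS condition, spikes are counted per trial in three half-open
windows around cue onset: ITI baseline [−3, −2), pre-cue [−1, 0) and
response [0, 1) s — all inside the ITI by construction, validated against
the previous trial's tone epoch. Pre-cue and response series are z-scored
against the across-trial mean/SD of the baseline series ("subtract the
mean and SD of the baseline" is read as standard z-scoring; subtracting an
SD is not a defined normalisation), smoothed across trials with a causal
Gaussian, and the four series (E-pre, E-response, A-pre, A-response) are
concatenated for clustering at the 0.20 cutoff.

The smoothing-factor parametrisation (0.85) maps to a trailing window of
`max(3, ceil(f·n/2))` trials with σ = span/5 — a qualitative stand-in for
an otherwise unpublished kernel mapping, exposed in the configuration.

The change test fits ordinary least squares of count against trial index
on each cluster's mean series and flags a tonic change when the t-based
95% CI on the slope excludes zero (no level is prescribed; 95% is the
conventional default). The regression is fit to the **raw** mean counts by
default: smoothing induces serial correlation that inflates the false-flag
rate well above nominal, and the suite records calibration (3–7% false
flags at 95% CI on flat Poisson clusters; ~95% CI coverage of a true
0.05 spikes/trial drift over 75 trials) for the unsmoothed fit. Fitting
the smoothed series is available as an option for visual consistency with
smoothed plots. All four series are fit and reported per cluster.
Normalisation against the within-trial baseline window is the default; a
first-k-trials ("habituation") reference exists as a configuration choice.

# Numerical conventions and degenerate inputs

* All event windows are half-open [a, b); times are seconds from session
  start.
* The causal Gaussian kernel spans the current and k previous bins with
  σ = k/5, renormalised over available samples, so constants are preserved
  exactly and no mass leaks backwards in time.
* Zero-variance inputs never crash: degenerate paired tests count as not
  significant, zero-baseline-SD units are removed and reported, an
  all-zero contingency table and sub-minimum cluster sizes are explicit
  errors, and a significant response with mean z exactly 0 is reported as
  sign-indeterminate rather than forced into a category.
* Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; `simulate_study()` derives per-unit seeds from the
  master seed so identical configurations serialise byte-identically.

# Problem sizes

The bundled study uses 3 subjects × 40 units (14 untagged MGN, 6 MGN→BLA,
12 out-of-network BLA, 8 in-network BLA) — about 120 units — which keeps a
full pipeline run under a minute while leaving every stage's statistics
well-posed. Calibration properties (tonic CI coverage and false-flag rate,
behavioural null pass rates, phototag null rate) are measured over 1000
simulated seeds; recovery properties (templates, valence categories,
learner/non-learner separation) over 50–100 seeds or 40–120 units.

# Known limitations

* The Poisson generator understates real count dispersion; calibration
  bands verified here can shift on overdispersed data.
* The scaled-baseline signed-rank comparison is mildly anticonservative
  (see above); on real data a duration-matched baseline subwindow is the
  conservative alternative.
* Leave-one-subject-out statistics with k = 3 subjects cannot reach
  conventional significance in two-group rank-sum comparisons.
* The tonic regression attributes any monotone trend in the pre-cue rate
  to a tonic change; it cannot distinguish biological drift from slow
  recording instabilities, which the simulator does not model.
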