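# pacdev

Phase-amplitude coupling (PAC) analysis for developmental scalp EEG, from
segmented multichannel recordings to comodulograms, significant-coupling
(PAC+) clusters, phase-preference maps, and age-trend statistics — with a
synthetic-data module that makes every stage verifiable without clinical
recordings.

## What it computes

For each recording, channel, and valid low/high frequency pair, the package
extracts low-frequency phase φ(t) and high-frequency amplitude A(t) with a
zero-phase complex FIR filter bank (LF centers 2–20 Hz in 2-Hz steps, 2-Hz
bandwidth; HF centers 40–100 Hz in 4-Hz steps, 20-Hz bandwidth; pairs with
overlapping filter responses are excluded). Amplitude is averaged in 18
20° phase bins over 30 randomly selected 2-s segments, giving a distribution
P(b) whose Kullback–Leibler divergence from uniformity defines the raw
modulation index

    MI_raw = D_KL(P ‖ U) / log 18 = [log 18 − H(P)] / log 18 ∈ [0, 1],

and the bin of maximal amplitude defines the *phase max* (preferred phase).
200 surrogates, built by circularly time-shifting each segment's amplitude by
0.1–1.9 s, yield the normalized index

    MI_norm = (MI_raw − μ(MI_surr)) / σ(MI_surr).

Group inference compares MI_raw with μ(MI_surr) by paired t tests at every
cell, clusters p < 0.05 cells per channel under 4-connectivity, and screens
cluster masses Σ(|t| − t_crit) against a flip-half permutation null (95th
percentile, 200 permutations). Within the surviving PAC+ cells, the package
correlates age with mean MI_norm, tests per-bin age trends of phase-max
proportions (Bonferroni, 18 tests), and summarizes regional phase preference
by circular means.

## Worked example

Simulate a 12-subject cohort whose coupling depth grows with age and whose
anterior/posterior channels prefer −110°/+70°, then run the analysis:

```r
library(pacdev)
spec   <- build_filterbank(250, lf_centers = c(6, 8, 10),
                           hf_centers = c(56, 64, 72))
cohort <- simulate_cohort(12, channel_labels = c("Fz", "F3", "Pz", "O1"),
                          duration_s = 60, base_depth = 0.2,
                          depth_slope_per_month = 0.6 / 33, seed = 7)
maps <- lapply(cohort, function(r) pac_map(segment_recording(r), spec, seed = 11))
cl <- pac_cluster(maps, seed = 5)
tr <- pac_trends(cl)
tr
#> <pac_trends> MI_norm ~ age: r = 0.9057, p = 5.01e-05 (n = 12)
#>   overall: circular mean phase max 169.7 deg (R = 0.01); 0 significant trend bin(s)
#>   anterior: circular mean phase max -111.1 deg (R = 0.98); 0 significant trend bin(s)
#>   posterior: circular mean phase max 69.6 deg (R = 0.98); 0 significant trend bin(s)
```

Coupling strength rises with age (r = 0.91, p = 5×10⁻⁵ against the injected
positive depth slope), and the regional circular means recover the simulated
−110°/+70° preferences within one 20° bin. The near-zero overall resultant
(R = 0.01) is expected: the two regions' preferences are antipodal, so pooled
phase maxima cancel.

File-based workflows go through `write_cohort()` / `read_manifest()` /
`run_pipeline()`, which apply segmentation, joint-probability rejection,
30-segment selection (recordings with fewer are excluded and logged), and
write all result tables as TSV together with a seed-complete run log.
`validate_filters()` reruns the simulated phase-preference harness (−90°, 0°,
90°, 180° at LF 2/4/8/16 Hz) that certifies the filters do not distort phase.

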