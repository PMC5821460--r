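# l1cycle

Quantitative analysis of LINE-1 (L1) retrotransposon dynamics across the
cell cycle, for researchers studying when L1 proteins reach the nucleus
and when retrotransposition happens.

LINE-1 is the only autonomous human retrotransposon. Its ORF1p protein
is mostly cytoplasmic, but a minority of cells — typically pairs of
recently divided daughters — show nuclear ORF1p, consistent with L1
ribonucleoproteins entering the nucleus during mitotic nuclear-envelope
breakdown; retrotransposition itself peaks in S phase. Turning those
observations into numbers takes several separate statistical tools, and
`l1cycle` packages all of them, each exercised end-to-end on seeded
synthetic data with full ground truth:

- **Proximity analysis** (`proximity_test`): nearest-neighbour distances
  of nuclear-ORF1p cells against a resampled null (1000 draws of equal
  size from the non-nuclear population), per-cell permutation p-values
  `p_i = (1 + #{d_null <= d_i}) / (1 + N_null)` with Benjamini–Hochberg
  FDR, selection at p <= 0.1, and a two-sided rank-sum comparison against
  a random non-nuclear sample — reported both in its classical Wilcoxon
  form and permutation-calibrated against the resampled null.
- **High-content compartmental quantification** (`segment_nuclei`,
  `build_compartments`, `quantify_localization`): isodata nucleus
  segmentation, circle (nucleus − 4 px) and ring (1–8 px outside the
  nuclear edge) compartments, negative-control positivity limits, and
  `% nuclear = 100 · n_circle+ / n_ring+`.
- **Cell-cycle quantitation** (`phase_fractions_from_durations`,
  `deconvolve_dna`, `slope_analysis`): the exponential-growth age density
  `f(a) = (2 ln2 / T) 2^(−a/T)`, maximum-likelihood deconvolution of
  DNA-content histograms (2N and 4N Gaussians plus an 8-step S bridge),
  and finite-difference slope analysis of reporter time courses with
  phase annotation and a no-peak flag.
- **Fluorescent-timer event timing** (`estimate_conversion_time`,
  `onset_quantiles`, `gate_ft`): first-order blue→red maturation
  (`red(t) = B0 (1 − e^(−k t))`, conversion time `ln2/k`), expression
  onset quantiles, and blue/red flow gating that orders
  retrotransposition events in time.
- **IP-MS interactor classification** (`classify_confidence`,
  `exclusive_interactors`): the ≥ 2-unique-peptide filter, per-experiment
  V5/IgG exclusivity, and the red / orange / yellow / gray confidence
  classes.

Synthetic inputs come from `gen_cell_field`, `gen_image`,
`gen_facs_snapshot`, `gen_timecourse`, `gen_ft_traces` and
`gen_peptide_table`; every generator is deterministic given a seed and
carries its ground truth with it. `run_config()` (and the thin wrapper
script in `inst/scripts/l1cycle`) exposes every step as a configurable,
reproducible pipeline stage.

## Worked example

Simulate a field in which 80% of nuclear-ORF1p cells sit as daughter
pairs ~10 µm apart, test for clustering, then recover a planted
cell-cycle mixture and the timer kinetics:

```r
library(l1cycle)

field <- gen_cell_field(200, frac_nuclear = 0.15, frac_paired = 0.8,
                        pair_sep_mean = 10, pair_sep_sd = 1, seed = 2)
proximity_test(field, seed = 1)
#> proximity_report: k = 29 nuclear cells, 22 selected at p <= 0.1
#>   rank-sum p (selected vs random sample): 1.36e-09
#>   rank-sum p (all nuclear vs random sample): 1.64e-05
#>   rank-sum p (permutation-calibrated): 0.000999

m <- hela_cycle_model()
m
#> cell_cycle_model: T = 24.000 h (G1 9.973, S 9.077, G2/M 4.950)

facs <- gen_facs_snapshot(m, n = 100000, event_rule = "fixed_phase_mixture",
                          mixture = phase_fractions(9.38, 78.1, 12.5,
                                                    normalize = TRUE),
                          seed = 3)
deconvolve_dna(facs$events$dna)
#> dna_fit: G1 9.5% | S 77.4% | G2/M 13.1%  (2N at 99.8, CV 5.2%, n = 100000)

est <- estimate_conversion_time(gen_ft_traces(500, seed = 4))
round(c(mean = est$mean, sd = est$sd), 2)
#>  mean    sd
#>  2.35  0.53

onset_quantiles(onset_curve(gen_onset_times(10000, seed = 5)))
#>  t50  t90
#>  2.7  8.0
```

Reading the output: 22 of 29 nuclear cells are significantly closer to
another nuclear cell than resampled cells are to each other, and the
rank-sum comparison rejects random localization (the calibrated p is
floored at 1/(n_perm + 1)). The deconvolution recovers the planted
9.4/78.1/12.5 phase mixture to within a fraction of a percentage point,
and the timer estimators return the calibrated 2.35 h maturation time
and the 2.71 h / 8.01 h onset quantiles they were built around.

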