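---
title: "Methods: quantifying LINE-1 dynamics across the cell cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying LINE-1 dynamics across the cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1cycle)
```

LINE-1 (L1) is the only autonomous human retrotransposon. Its ORF1p
RNA-chaperone is mostly cytoplasmic, but a minority of cells show nuclear
ORF1p — typically pairs of recently divided daughter cells, suggesting
that L1 ribonucleoproteins enter the nucleus when the nuclear envelope
breaks down in mitosis — and retrotransposition itself is biased toward S
phase. Testing those claims quantitatively requires several distinct
pieces of statistical machinery: a spatial test for daughter-pair
clustering, high-content image quantification of nuclear versus
cytoplasmic signal, cell-cycle phase estimation from DNA content, timing
models for fluorescent reporters, and rule-based scoring of
co-immunoprecipitation mass spectrometry. `l1cycle` implements each of
these as a reusable, seeded, fully testable operation, together with
synthetic-data generators that emulate the corresponding measurements
with known ground truth.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic benchmarks do and do not
demonstrate.

## The exponential-growth age structure

Every cell-cycle computation rests on one model: in an asynchronous,
exponentially growing culture with doubling time $T$, cell age $a$ (time
since the last division) has density

$$f(a) = \frac{2\ln 2}{T}\, 2^{-a/T}, \qquad 0 \le a \le T,$$

because each division creates two age-zero cells, so young cells are
over-represented. A phase occupying ages $[a_1, a_2]$ then contains the
fraction $2(2^{-a_1/T} - 2^{-a_2/T})$ of the population
(`phase_fractions_from_durations()`), and the inverse map
$a = -T\log_2(1 - F/2)$ converts cumulative phase fractions into phase
durations (`durations_from_fractions()`); the two are exact inverses and
the round trip is tested to $10^{-9}$.

The package default, `hela_cycle_model()`, anchors $T = 24$ h (typical
HeLa doubling) and inverts the measured asynchronous propidium-iodide
distribution — G1 49.5%, S 34.2%, G2/M 15.2% — into durations of roughly
10.0, 9.1 and 5.0 h. Flow gates rarely close exactly (those percentages
sum to 98.9), so `phase_fractions(..., normalize = TRUE)` rescales them;
the G1 fraction the model reproduces is therefore 50.05% rather than
49.5%, a 0.55-point difference inherent to renormalization, not a fitting
error.

## Proximity analysis of nuclear-ORF1p cells

`proximity_test()` asks whether the $k$ nuclear-positive cells in a field
sit closer to one another than randomly chosen cells would:

1. each nuclear cell's nearest-neighbour (NN) distance to another nuclear
   cell;
2. a resampled null — `n_perm = 1000` draws of $k$ cells without
   replacement (by default from the non-nuclear population, since the
   null hypothesis is "random localization of non-nuclear cells"; an
   all-cells mode exists because either reading is defensible);
3. per-cell p-values from the pooled null,
   $p_i = (1 + \#\{d_{null} \le d_i\})/(1 + N_{null})$, with the add-one
   correction so p-values are valid and never zero, and
   Benjamini–Hochberg q-values alongside;
4. selection of cells at raw $p \le 0.1$ (selection on raw p, with q
   reported, mirrors how such screens are usually read);
5. a two-sided rank-sum comparison of the selected cells' NN distances
   against the within-sample NN distances of one random sample of $k$
   non-nuclear cells.

Step 5 is reported three ways, and the distinction matters. `ranksum_p`
is the classical Wilcoxon on the *selected* cells — the screen's
headline number, maximally sensitive but conditioned on small distances.
`ranksum_p_all` is the same test without selection. Neither holds its
nominal level under random labelling: NN distances within a sample are
dependent (mutual nearest neighbours contribute identical values twice),
which inflates the analytic Wilcoxon reference; we measure its rejection
rate at $\alpha = 0.05$ near 0.11. `ranksum_p_calibrated` therefore
refers the identical rank-sum statistic to its permutation distribution
across the resampled null rows, two-sided via distance from the null
centre $\mu = k(2k+1)/2$ with the add-one correction. This version is
exactly valid by construction (measured rejection 0.048 over 500 random
fields in the acceptance suite) and is the recommended inferential
output; its resolution floor is $1/(n_{perm}+1)$, so detection claims
far below that (such as the classical test's very small p on strongly
paired fields) are only expressible through `ranksum_p`. Ties in the
Wilcoxon are unavoidable for the same mutual-neighbour reason, so the
analytic version always uses the tie-corrected normal approximation
rather than switching to an exact method that ties would invalidate.

The synthetic fields (`gen_cell_field()`) place most cells uniformly and
a chosen fraction of nuclear-positive cells as daughter pairs separated
by a truncated-normal distance, defaulting to $15 \pm 5$ µm — a
post-mitotic spacing on the order of one cell diameter; the real
experiments report only that paired cells lie "in close proximity", so
this is a modelling choice, not a measured value. Planted-pair fields
(80% paired at $10 \pm 1$ µm among 200 cells in a 1 mm² field) yield
classical p-values far below $10^{-3}$; fields with randomly assigned
labels calibrate the type-I rate. What passing these tests shows is that
the statistical chain is correct and powered at realistic densities — it
does not reproduce the actual micrograph coordinates behind the original
observation, which were never released.

## High-content compartmental quantification

`segment_nuclei()` reproduces the standard high-content pipeline:
grayscale-opening background subtraction (structuring disc radius 15 px
by default, comfortably larger than a nucleus), isodata (iterative
intermeans) thresholding, connected-component labelling, and an area
floor equal to a disk of radius 3 px to reject specks; the floor is far
below any plausible nucleus, so it only removes noise. The isodata
threshold is written in-package and verified against a brute-force
intermeans iteration; on a two-value histogram it converges to the
midpoint, as it must.

`build_compartments()` makes the two measurement regions per nucleus: a
**circle** (nucleus eroded by 4 px, avoiding the rim) and a **ring** (the
annulus 1–8 px outside the nuclear edge, sampling perinuclear
cytoplasm). Two geometric decisions needed making. First, pixels within
the inner band (1 px) of *any* nucleus are excluded from every ring:
such rim pixels are contaminated regardless of which cell they would be
credited to, and without this rule a pixel hugging one nucleus could be
absorbed by a neighbour's ring. Second, pixels reachable by several
rings go to the nucleus nearest in exact Euclidean distance (distance
transforms), ties to the lower label id; a brute-force per-pixel scan
verifies the partition in the tests.

Positivity limits come from a negative control
(`calibrate_limits()`): the circle and ring limits are the *maxima* of
the corresponding per-cell means among cells that express no marker, so
no negative cell scores positive by construction. Because a maximum is
an order statistic, the false-positive rate on a fresh field scales as
$1/(n_{negatives}+1)$: calibrating on a single 50-cell field leaves
roughly one false call per field, while pooling a few negative fields
(the tests use three, mirroring multi-field control acquisitions) makes
it negligible. Per-cell statistics are compartment means by default
(totals are also computed, since the commercial software's choice is not
documented), and the summary applies the screen's convention
$$\%\,\mathrm{nuclear} = 100 \cdot
\frac{\#\,\mathrm{circle\ positive}}{\#\,\mathrm{ring\ positive}},$$
with the ring-positive count doubling as "total expressing cells"
because every expressing cell shows cytoplasmic signal. Scoring is
covariant under a constant intensity shift applied to both the image and
the limits.

The synthetic images (`gen_image()`) are bright nuclear disks plus a
cytoplasmic annulus per cell (marker also filling the nucleus only for
nuclear-positive cells), additive Gaussian read noise, and a push-apart
placement that keeps every annulus clear of every other nucleus. They
deliberately omit optics — no point-spread function, vignetting, focus
variation or spectral spillover — so recovery of planted nuclear
fractions (mean absolute error under 2 percentage points across 20
fields spanning 0–50%) validates the measurement chain, not robustness
to real microscope artefacts.

## DNA-content deconvolution

`deconvolve_dna()` fits a DNA-stain histogram with a three-part mixture:
a Gaussian at the 2N position (free mean $\mu$ and CV), a Gaussian at 4N
constrained to mean $2\mu$ with the same CV (stain fluorescence is
proportional to DNA content), and S phase as eight equal-weight
broadened steps spanning 2N→4N — the classic step-decomposition approach
to S-phase modelling. Fitting maximizes the multinomial likelihood of a
256-bin histogram (binning makes the cost independent of event count)
with bounded quasi-Newton optimization; weights go through a softmax,
$\mu$ and CV through logs, and four restarts over data-quantile-derived
2N starting positions guard against the G1-depleted case where the 2N
peak is nearly absent. A single-valued input short-circuits to pure G1.
Planted mixtures of $10^5$ events at 5% CV — including the measured
blue⁻ (49.5/34.2/15.2), blue⁺red-low (9.38/78.1/12.5) and blue⁺red-high
(0/10.9/89.1) populations — are recovered within 2 percentage points per
fraction; residual bias of a few tenths of a point comes from
approximating a uniform S bridge with eight steps and is well inside
that band.

The 5% CV default is a typical width for a propidium-iodide histogram on
a well-tuned cytometer; the source experiments do not report one.

## Retrotransposition time courses and slope analysis

`gen_timecourse()` emulates the synchronization experiment: cells
released from mitosis start at age zero, a fraction `event_prob`
(default 5%, matching the few-percent GFP⁺ frequencies such reporters
give) acquires one retrotransposition event at a uniformly random
position within its S phase, and a cell scores GFP⁺ once event time plus
detection delay has passed. `slope_analysis()` then computes forward
finite-difference slopes of the percent-positive curve: a cell-cycle
burst appears as a slope peak, annotated with the phase whose window
majority-overlaps the peak interval, while an unbiased process rises
linearly. The no-peak flag fires when the maximum slope is below 1.5×
the median slope — on an exactly linear rise max equals median, so the
flag is robustly raised, while a synchronized S-burst concentrates most
of the rise in 1–2 of eight intervals and clears the threshold easily.

The non-synchronized control deserves a note. A fixed, non-dividing
cohort with exponential-age initial conditions would *not* produce a
linear rise: the flux of cells entering S would oscillate two-fold over
one period. In a real culture, division continuously replenishes every
age class, and the per-unit-time probability that some cell enters S is
flat. The generator models this steady-state renewal directly — S-entry
wall-times uniform over one doubling time — which reproduces the
near-linear control without simulating lineages. Acceptance checks run
20 seeds of each condition at 50 000 cells and 3-h sampling over 24 h:
synchronized cohorts place the slope peak in an S-annotated interval,
asynchronous cohorts raise the no-peak flag.

Those acceptance cohorts use zero detection delay, isolating the slope
machinery. With a realistic onset delay (median ≈ 2.7 h) the detected
peak shifts right by the delay's mode and can smear across the S/G2-M
boundary; that is a property of the measurement, not of the analysis,
and is why the event-timing reporter below exists.

## Fluorescent-timer kinetics

The fast fluorescent timer translates blue and matures to red by a
first-order process. For a burst of $B_0$ molecules,
$\mathrm{red}(t) = B_0(1 - e^{-k_{mat}t})$, so the half-rise time of red
is $\ln 2 / k_{mat}$. `ft_kinetics()` calibrates
$k_{mat} = \ln 2 / 2.35\ \mathrm{h}^{-1}$ so the mean conversion time is
2.35 h, and sets the expression-onset delay lognormal with median 2.71 h
and 90th percentile 8.01 h — exactly the measured onset quantiles — by
$\mu = \ln 2.71$, $\sigma = \ln(8.01/2.71)/z_{0.9}$.

`estimate_conversion_time()` scores each trace by the first
linearly-interpolated crossing of half the red plateau, after a 3-sample
moving average that suppresses spurious early crossings in noisy traces.
The plateau itself is estimated by conservation: for a constant burst
the total pool blue + red is constant in time, so its trace-mean is an
unbiased plateau estimate even when sampling stops before red fully
saturates (a tail-mean fallback handles traces without a usable blue
channel, and traces still rising at the end are excluded rather than
mis-scored). On noiseless traces the estimator matches $\ln 2 / k_{mat}$
to better than 0.01 h (the residual is linear-interpolation error on a
concave curve); across maturation rates 0.1–1.0 h⁻¹ with 5% noise the
bias stays below 5%. Simulated populations draw per-cell conversion
times as Normal(2.35, 0.52) h truncated above 0.2 h, reproducing both
the measured mean and its cell-to-cell spread.

`gate_ft()` splits flow events into blue⁻, blue⁺red-low and
blue⁺red-high. The automatic blue threshold is the maximum blue signal
among no-event cells — the same negative-control-maximum rule used for
imaging limits, applied to cytometry for consistency — and the red
low/high split defaults to the median red of blue⁺ events, since no
threshold was reported for that gate. On snapshots with S-restricted
events, blue⁺red-low events are majority S (recent events) and
blue⁺red-high majority G2/M (aged events), reproducing the qualitative
pattern that motivates the timer: red accumulation orders events in
time.

## FUCCI counts and western normalization

`fucci_contingency()` is a checked 2×2 cross-tabulation of nuclear
marker status against the two-colour cell-cycle indicator (red nucleus =
G1, green = S/G2/M). Simulating 3 309 cells with 80 nuclear-marker cells
under the model "nuclear localization only in G1" yields exactly 0
green-nucleus/nuclear cells and 80 red-nucleus/nuclear cells — a
consistency check of the bookkeeping, not an inference.
`normalize_westerns()` divides target band intensities by the histone-H3
loading control and anchors the first timepoint at 1.

## IP-MS interactor classification

`classify_confidence()` applies, in order: the ≥ 2-unique-peptide floor
(a protein qualifies when any bait channel reaches it — whether the
floor applies per experiment or overall is not specified, so overall is
the default with a strict per-experiment flag), then the colour rules:
**red** = bait peptides in both experiments and no IgG peptides in
either; **orange** = both experiments but some IgG signal; **yellow** =
exactly one experiment, IgG-clean; **gray** = everything else, which
covers both sub-floor proteins and the legend's undefined cell
(single-experiment with IgG contamination). `exclusive_interactors()`
implements the per-experiment exclusivity rule (bait-positive,
IgG-zero). Classification partitions any input table, is invariant to
row order, and — for tables past the floor — depends only on
zero/non-zero channel presence. The generator plants each class by
construction, so recovery is exact by design and tests the rules, not a
statistical procedure; the published supplementary protein table that
the exclusivity counts were originally derived from is not redistributed
with the package, so those counts are not re-derived here.

## Problem sizes, determinism and limitations

All randomness flows through per-call integer seeds
(`withr::with_seed`), so every generator and every report is
reproducible bit-for-bit; stochastic claims in the test suite are made
over fixed seed families. The default benchmark sizes — 500 proximity
fields of 120 cells with 1 000-permutation nulls, 20 imaging fields of
50 cells, $10^5$-event DNA histograms, 500 timer traces, 10⁴ onset
delays, 50 000-cell time courses — were chosen so each acceptance
property is measured with Monte-Carlo error several times smaller than
its tolerance band; at 10⁴ onset delays the t90 estimate has a standard
error near 0.12 h against its ±0.2 h band, the loosest of these.

Known limitations: the image model omits optics and 3-D structure; the
DNA model assumes a single diploid population (no aneuploidy, debris or
aggregates, and no sub-G1 compartment); the snapshot reporter model
tracks at most one event per cell within the current cycle; nuclear
positivity is a static label per field rather than a kinetic state, as
no quantitative export model was available to emulate; and the FACS
generators do not model spectral spillover or compensation.
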