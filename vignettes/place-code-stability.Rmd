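---
title: "Methods: place-code stability analysis for virtual-corridor calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place-code stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placecode)
```

# The experiment this package models

A head-fixed mouse runs on a treadmill through a 400-cm virtual linear
corridor containing four 40-cm reward zones centered at 30, 137, 243 and
350 cm, licking a spout to collect water when inside a zone. Hippocampal
CA1 pyramidal neurons expressing GCaMP6f are imaged at 30 Hz across weeks:
a daily baseline block before an injection of microspheres (which produces
disseminated microinfarcts) or a sham operation, then sessions every third
day for four weeks. Sessions are grouped into three phases relative to the
injection day: *healthy* (day ≤ 0), *early post* (days 1–7) and *late
post* (beyond day 7).

The package implements the full analysis chain for such data — behavioral
scoring, spatial activity maps, place-cell detection and stability
classification, functional-class transition statistics, Bayesian position
decoding, population-vector correlation, pairwise-synchrony structure, and
cross-session ROI tracking — together with a seeded synthetic generator so
every stage can be verified against ground truth at desk scale.

# Coordinate conventions

Positions are in cm from the corridor start. Spatial bins are half-open
`[k·w, (k+1)·w)`; neural maps use 80 bins of 5 cm, lick histograms 120
finer bins. Inside R, frames and bins are 1-based (the idiomatic choice);
the HDF5 session container written by `write_session()` stores 0-based
frame indices and half-open trial bounds so the on-disk layout is
language-neutral. Frames outside every trial (the 1-s screen blackout
while the corridor resets) carry no meaningful position and are excluded
from every analysis.

# Behavioral performance

Licks are binned into 120 spatial bins; the lick probability
$\lambda_i$ is the fraction of trials with at least one lick in bin $i$,
and occupancy $t_i$ is the time spent there (no velocity filter is applied
to the behavioral occupancy; the 5 cm/s filter below concerns neural maps
only — a stationary licking mouse is behaviorally informative). The
spatial information of the histogram is

$$SI = \sum_i p_i \frac{\lambda_i}{\bar\lambda}
  \log_2 \frac{\lambda_i}{\bar\lambda}, \qquad
  p_i = \frac{t_i}{\sum_i t_i}, \qquad
  \bar\lambda = \sum_i p_i \lambda_i .$$

Never-visited bins have $p_i = 0$ and drop out of the sums; bins with
$\lambda_i = 0$ contribute nothing (the $x \log x \to 0$ limit). A session
without licks has no defined concentration and is scored 0 bits with a
warning rather than an error, because severely impaired mice produce such
sessions mid-pipeline. Performance is expressed per session as a
percentage of the mean healthy-phase SI. Outcome classification uses an
inclusive 75% boundary (a tie counts as impaired) in both post phases:
below in both phases is *No-Recovery*, below only early is *Recovery*,
above in both pools the mouse with the shams — a pooling that in the
original design additionally requires sham-like histology, exposed here as
the `sphere_override` flag.

# From fluorescence to spatial maps

Traces are detrended as $\Delta F/F = (F - F_0)/(B_0 + F_0)$, with the
baselines set at the percentile where the mode of the trace distribution
sits. `rolling_mode_percentile()` estimates that percentile per 1000-frame
sliding window (stride half a window) with a Gaussian KDE using
Silverman's bandwidth, and returns the median across windows; for sparse
positive calcium transients it lands below the 50th percentile. A
constant window is assigned the 50th percentile by convention.

`bin_activity()` excludes frames below 5 cm/s running velocity (strictly
below; frames at exactly 5 cm/s are kept) and averages each neuron's
$\Delta F/F$ per trial and 5-cm bin. Bins a trial never visits at running
speed are *missing*, never zero. Smoothing (`smooth_map()`, Gaussian
kernel, σ = 5 cm) uses reflective boundaries — corridor ends are walls,
not wraparound — which conserve total map mass; missing bins are linearly
interpolated before smoothing and re-flagged afterwards, so their absence
does not smear zeros into visited bins. The decoder and the
population-vector analyses use the interpolated (un-reflagged) maps, which
must be complete. Per-trial maps and the trial-mean map are smoothed
independently; within-session stability works on the per-trial maps.

# Place-cell detection

Detection screens each neuron's smoothed trial-mean map for candidate
fields: maximal runs of bins strictly above
`baseline + 0.25 (max − baseline)`, where the baseline is the mean of the
lowest quartile of bin values. A candidate becomes a place field if

1. it is at least 15 cm wide (3 bins),
2. its mean in-field activity is at least 6× the out-of-field mean, and
3. significant transients cover at least 20% of the velocity-filtered
   frames spent inside the field.

Significant transients are runs of at least 0.5 s above 3σ, with σ
estimated from the FWHM of the trace's value distribution
(σ = FWHM / 2√(2 ln 2)) — robust to the sparse positive transients that
inflate an ordinary SD. When the out-of-field mean is not positive the 6×
ratio is undefined; the criterion is then satisfied exactly when the
in-field mean is positive, preserving the intended strong-contrast
reading. The whole detection is invariant to positive rescaling of a
trace, since every threshold scales with the data.

Significance: the trace is cut into 50-frame chunks (the final partial
chunk kept as its own piece, preserving all data), the chunk order is
permuted against the fixed behavior, and the full detection is re-run;
`p_pf` is the fraction of 1000 shuffles in which some field passes all
three criteria. A cell is a place cell when a passing field exists and
`p_pf ≤ 0.05`.

Stability: within-session stability Fisher-averages the Pearson
correlations of first-half vs second-half and odd vs even trial-mean maps
(correlations clipped at 1 − 10⁻⁶ before `atanh`); cross-session scores
Fisher-average map correlations over all session pairs exactly 3 days
apart within a phase and are reported back on the correlation scale. The
network baseline is the median healthy score across all neurons; place
cells strictly above it are `stable_pc`, at or below it (`higher` is read
strictly, so ties fall to the impaired side) `unstable_pc`, non-place
cells `noncoding`.

# Class transitions

`transition_probabilities()` is the row-normalized class-conditional count
matrix between two time points; `shuffled_delta_p()` permutes the *second*
time point's labels across cells (permuting the first is equivalent for
this statistic) and reports `ΔP = P_true − mean(P_shuffle)` with the
per-entry shuffle SD. Row sums of `ΔP` are identically zero. The default
of 1000 shuffles is a package choice. Both phase-level and
session-pair-level labels can be compared; cells absent at either time
point are dropped pairwise.

# Bayesian position decoder

For each of the top 100 neurons by within-session stability, training
trials give per-bin cross-trial means $\mu_i(x)$ and SDs $\sigma_i(x)$ of
the smoothed per-trial maps; per-bin SDs below the neuron's mean per-bin
SD are floored to that mean, and everything to ε = 10⁻⁶ ΔF/F, so every
density is proper. Decoding scores the windowed activity
$S_i(t)$ (mean ΔF/F over $t \pm 0.5$ s, truncated at the record edges)
under each bin's Gaussian, normalizes each neuron's likelihood row by its
maximum over bins, and takes

$$\hat x(t) = \arg\max_x \; occ(x) \prod_i
  \frac{p_i(x,t)}{\max_x p_i(x,t)},$$

computed entirely in log space (ties resolve to the lowest bin index).
All trial frames are decoded, including sub-threshold-velocity frames.
Accuracy is the exact-bin hit rate; sensitivity the fraction of
truly-in-reward-zone frames decoded into any reward zone. Within-session
evaluation is leave-one-trial-out with the neuron ranking computed once
per session; cross-session evaluation trains on the whole training
session restricted to tracked neurons.

The empirical chance level relabels the spatial bins of the *entire*
training set — tuning means, SDs, and the occupancy prior together — by
one random permutation per shuffle, decodes, and averages over 500
shuffles. Relabelling everything makes the prediction uniform over bins
regardless of occupancy structure, so chance accuracy converges to
`1/80 = 1.25%` on the standard corridor and chance reward-zone
sensitivity to the 40% of the corridor that reward zones cover. Because a
bin relabelling only permutes the posterior's columns, each shuffle is
evaluated by remapping the unshuffled argmax through the inverse
permutation — mathematically identical to refitting on relabelled maps,
at a fraction of the cost.

# Population structure

The population-vector correlation between positions $x, y$ of two
sessions is the cosine of the across-neuron activity vectors of the
smoothed maps. The PVC curve averages the matrix over position pairs at
each offset from 0 to 275 cm (56 values); its y-intercept measures
cross-session stability and its maximum absolute discrete slope over
0–100 cm, reported per 100 cm (a unit choice; the scale factor is
explicit in the code), measures spatial precision. Relative peak
prominence — (peak − mean of flanking valleys) / peak for each interior
local maximum — quantifies the periodicity that reward-zone-locked coding
imprints on the curve; with the standard geometry the first peak falls
near the ~107-cm zone spacing.

Pairwise structure uses Pearson correlations of ΔF/F traces over whole
sessions ("pairwise firing activity"; the velocity filter is not applied
here) or of spatial maps ("spatial synchronicity"). The synchronous pool
takes the strict upper triangle, thresholds at the 95th percentile
(midpoint interpolation), and keeps pairs strictly above. Composition is
reported two ways, because "the percentage of place-cell pairs in the
pool" is ambiguous: the default is, for each unordered class pair, the
fraction of that class pair's cell pairs that land in the pool (which is
5% for every class under class-independent correlations, matching a 5%
chance line); the pool-share reading is returned alongside. Correlation
structure persistence across days is the cosine similarity of the strict
upper triangles; phase-averaged pairwise coefficients are matched across
phase pairs and summarized by Pearson r, p and regression slope, with
non-significant (p > 0.05) distributions flagged excluded rather than
silently dropped.

Place-field geometry measures each field's distance to the nearest
reward-zone *edge* (zero inside). The `close`/`far` boundary defaults to
25 cm — half a zone width beyond the edge; the threshold is explicit and
configurable since no canonical value exists.

# ROI tracking

Cross-session alignment splits both mean-intensity images into a 2×2
patch grid, estimates each patch's translation by FFT phase
cross-correlation with parabolic sub-pixel refinement, and bilinearly
interpolates patch shifts to a per-pixel displacement field (featureless
patches inherit the mean of the others). Matching displaces session-A
centroids by the field and accepts mutual nearest neighbors within 12 px
(≈ 20 µm at 830 µm / 512 px). The original workflow confirms matches by
eye; the mutual-NN acceptance radius is this package's automatic stand-in
and is labelled as such, not a fidelity claim.

# The synthetic generator

`generate_trajectory()` emulates expert behavior — running at ~18 cm/s
with speed fluctuations, pausing 0.5–1.2 s inside each reward zone,
licking at ~8 Hz while stopped plus anticipatory licks in the 10 cm
before a zone and occasional stray licks — or a naive agent that runs
steadily and licks uniformly. Expert sessions place well over 60% of
licks inside zones and score high lick-SI; naive sessions score near
zero.

`generate_population()` draws stable place cells, unstable place cells
(field centers independently resampled every session) and non-coding
cells. Defaults, chosen once as realistic study conditions: Gaussian
tuning with 15–30 cm FWHM; 2 transients/s at the field center while
running (a burst-firing rate typical of CA1 cells crossing their field —
at much lower rates no cell can satisfy the 20% transient-coverage
criterion, because isolated transients barely exceed the 0.5-s duration
minimum); 0.02/s baseline events; 0.08/s for non-coding cells (active but
not spatial); additive noise SD 0.15 ΔF/F. `generate_dff()` convolves
Poisson events with a GCaMP6f-like kernel (one-frame rise, exponential
decay τ = 0.7 s, ~1 ΔF/F amplitude). One consequence worth knowing: the
indicator's decay drags a field's apparent map peak 2–3 bins in the
running direction — real calcium maps do the same.

`perturbation_spec()` defines stroke-like effects for sessions after an
onset day: a one-time class turnover, a multiplicative rate reduction,
session-to-session remapping of formerly stable cells, and an optional
recovery half-life relaxing the rate/stability effects toward baseline.
Post-lesion effect sizes are free generator parameters, not measured
quantities. The generator does *not* emulate several properties of real
recordings — correlated neuropil contamination, motion artifacts, slow
photobleaching, uneven cross-session ROI visibility, running-direction
selectivity — so green tests demonstrate that the estimators recover the
structure the generator encodes, not that they are robust to every
real-data nuisance.

# Numerical choices and problem sizes

Degenerate inputs resolve conservatively: constant traces give σ = 0 (with
a warning) and percentile 50; zero-variance map rows give missing
correlations; empty from-classes give missing transition rows; argmax
ties take the lowest bin. Bootstrap chunk shuffles permute the trace and
its 3σ mask identically (the σ estimate is permutation-invariant), which
is what makes 1000-shuffle detection affordable.

The test-suite and acceptance computations run on deliberately desk-sized
problems — sessions of 60–150 neurons, 12–20 trials, bootstrap counts of
100–200 and the full 500-shuffle chance estimate — sizes at which every
Monte-Carlo tolerance in the tests (3 SE bands) is meaningful. The same
code scales to full-size recordings by raising the counts in
`run_config()`.

# Known limitations

Single-corridor, single-running-direction analysis; no directional map
splitting; no multi-field statistics beyond "at least one passing field";
the ROI tracker handles translation-type deformation only; and the
healthy-phase "stable place cell" definition uses the median-split rule
(the 5-consecutive-day persistence reading is available as an option but
not the default).
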