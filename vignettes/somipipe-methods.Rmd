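---
title: "Methods: reward-coding analysis of dentate gyrus interneuron recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward-coding analysis of dentate gyrus interneuron recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

Head-fixed mice run laps on a 4 m circular virtual track with two fixed
reward sites while hilar units are recorded extracellularly and
somatostatin-expressing interneurons (SOMIs) are identified optogenetically.
The scientific questions this package operationalizes are: which animals
have learned the task (expert vs non-expert), which units are SOMIs,
principal cells or fast-spiking interneurons, which principal cells drive
which SOMIs monosynaptically, how single cells respond around reward
delivery and running-state transitions, how much of SOMI activity is
explained by behavior (licking, speed, acceleration, reward), and how well
reward expectation can be decoded from SOMI spiking.

`somipipe` implements this analysis chain as composable, tested functions
plus `run_pipeline()`, and ships a synthetic-session generator with full
ground truth so every stage can be validated end to end without recordings.

# Session model

A `somipipe_session` holds: a unit table (sorted spike times and a mean
site-by-sample waveform per unit), uniformly sampled behavior traces
(position in cm on the 400 cm track, speed in cm/s), an event table
(rewards, licks, light pulses at the dentate gyrus and fimbria sites,
sensory stimuli), and a lap table. All timestamps are seconds on one clock;
bins are half-open `[t, t + dt)`; event-aligned frames put the event onset
at `t = 0`. Bundles on disk are directories of CSV tables plus a JSON
manifest — inspectable and language-agnostic.

# Behavioral analysis

Speed below 0.5 cm/s is immobility; above 3 cm/s is steady-state
locomotion; the band in between is deliberately left as "intermediate"
because the two conventional thresholds leave a gap. A running onset requires
at least 3 s of immobility followed by the speed reaching 3 cm/s within
3 s; the onset time is the first sample at or above 0.5 cm/s of the
qualifying ramp, and the offset rule is the mirror image. These rules are
validated against an exhaustive per-sample scan in the test suite.

Per reward delivery, lick rates and mean speeds are computed in three
windows: baseline (−6 to −4 s), pre (−2 to 0 s) and post (0 to +2 s).
A session is called *expert* when, across trials, the pre-window lick rate
is significantly above baseline **and** the pre-window speed is
significantly below baseline. The field's convention states only that the differences be significant; we
use paired two-sided Wilcoxon signed-rank tests at
alpha 0.05 with the direction read from the median difference, because
per-trial lick counts are small, skewed integers for which a t test's
normality assumption is doubtful. The *performance score* is the fraction
of trials whose pre-window lick rate exceeds its baseline, and
`lick_lap_trend()` fits the per-lap lick rate against lap index by ordinary
least squares with a Pearson correlation.

# Unit classification

The bursting index is the mean autocorrelogram count in the 3–5 ms bins
divided by the mean count in the 200–300 ms bins; we bin at 1 ms up to
300 ms so both windows are expressed exactly, reading "3–5 ms" as the bins
covering lags in (3, 5]. Trough-to-peak duration is measured on the
recording site with the largest amplitude, from the global trough to the
following maximum. Units with bursting index above 3 and trough-to-peak
above 0.45 ms are putative principal cells; both below, fast-spiking
interneurons; wide but non-bursting, wide-spike interneurons. Values
exactly at a threshold are "unclassified" (the defining criteria use
strict inequalities on both sides), as is the bursty-narrow quadrant.

For separating granule-like from mossy-like principal cells, k = 2 k-means
(50 restarts, fixed seed) runs on z-scored features: the first two
principal components of the second derivative (central differences) of the
mean waveform over 0–0.8 ms from the trough (PCA fit across the session's
units), the externally supplied dentate-spike amplitude, and spatial
information. Whether to z-score the features is an open choice; we do,
because the four features have incommensurable units. Spatial information is Skaggs' bits/spike,
$\sum_i p_i (\lambda_i/\bar\lambda)\log_2(\lambda_i/\bar\lambda)$ — the
usual choice where the original citation does not print a formula. The
cluster with the higher mean spatial information is labeled `putative_GC`.

# Optogenetic tagging

Per light pulse, spikes during `[onset, onset + dur)` are compared with the
same-length pre-stimulation interval (paired Wilcoxon, alpha 0.05 — the
test and level are not pinned down by the tagging convention, so both are
config defaults). A unit is a **SOMI** if its rate increases significantly and its
first light-evoked spikes arrive within 5 ms; we operationalize "first
spikes within 5 ms" as the *median over pulses* of the first-spike latency,
which is robust to occasional spontaneous spikes just after onset.
Significant increases with later first spikes are SOM-disinhibited units;
significant decreases, SOM-inhibited units. The 50 ms and 250 ms pulse sets
are tested separately and combined by a union rule (significant in either,
with a consistent direction). SOMIs that also respond to fimbria
stimulation (antidromic activation of long-range axons) are projection
SOMIs; SOMIs without a significant fimbria change are local. A unit whose
count rises in the first 5 ms of the pulse but falls afterwards is flagged
as a candidate SOMI-inhibited-by-SOMI rather than given a fifth class.

# Monosynaptic connection detection

Cross-correlograms use 0.5 ms bins over ±50 ms: the two-consecutive-bin
rule inside the 2.8 ms causal window needs sub-millisecond bins, and ±50 ms
comfortably supports the 10 ms smoothing kernel (both values are declared
defaults of this implementation). The baseline is the convolution
of the observed CCG with a partially hollow Gaussian kernel (SD 10 ms,
hollow fraction 60%, kernel renormalized to unit mass; mass falling outside
the window is redistributed by renormalizing over in-window support). A bin
is significant when its count exceeds the 99.9th percentile of the Poisson
distribution with the baseline as mean. A pair is connected when (a) at
least two consecutive significant bins lie in the +1.2 to +4 ms window and
(b) the causal peak exceeds the same Poisson quantile evaluated at the
largest anti-causal peak, taken over the mirrored window −4 to −1.2 ms
(the anti-causal window and the form of the causal-vs-anticausal comparison
are not standardized; we mirror the causal window and reuse the 99.9%
Poisson rule for symmetry). Analyses of this kind often add manual inspection of detected pairs; here
the automatic criteria stand alone and the pair table reports peak counts and
minimal tail probabilities so borderline pairs can be reviewed.

# Event-aligned responses

Activity is aligned to events in 100 ms bins over −5 to +5 s (the pre/post
zones plus 3 s margins), smoothed with a Gaussian of SD 1 bin along time
only, and z-scored over the full trial-by-bin matrix to remove the
between-unit rate bias. Reward modulation is tested on raw counts: per
trial, mean rates in the pre and post zones are each compared with the
baseline window by paired Wilcoxon tests; a cell is *anticipatory* when its
pre-zone rate is up-modulated. Two baseline conventions coexist for this analysis
(4–6 s before reward, or the 3 s immediately prior for the delay
reference); we default
to −6 to −4 s computed from raw spike times, clipping to the aligned window
where needed, and keep the window a config key. The delay to maximal change
is the argmax over −2 to +2 s of the absolute difference between the
smoothed, z-scored trial-averaged trace and its baseline level; ties break
to the earliest bin for reproducibility. The ±2 s search window is an
inference from the reported delay ranges, again kept as a config default.
Locomotion ON/OFF classification compares −3 to −1 s against +1 to +3 s
around onsets and offsets (windows chosen to avoid the transition ramp
itself): OFF units drop at onsets and
rise at offsets; ON units do the reverse; at least 8 transitions of each
kind are required. Speed regression bins rate and speed at 100 ms and fits
OLS, optionally restricted to steady-state locomotion (speed above
3 cm/s). Sensory responses compare counts during each stimulus epoch with
the same-length pre-stimulus interval, per modality, requiring 15 events.

# The encoding model

Per trial, the −3 to +3 s window around reward is divided into 24 bins of
0.25 s (the bin width follows from the bin count); the response
is the binned firing rate and the predictors are binned lick rate, speed,
acceleration (first difference of binned speed, leading bin padded with 0)
and a binary reward signal that switches on at the bin containing reward
onset. Fits are ordinary least squares with intercept under five-fold
cross-validation with folds split **by trial** — a five-fold split could
also run by row, but splitting by trial
prevents within-trial autocorrelation from leaking into held-out rows.
Explained variance EV = 1 − Var(residual)/Var(response) is pooled over
held-out rows.

Significance uses a 500-iteration permutation null. Each permutation
shuffles whole-trial predictor blocks across trials *and* applies an
independent random circular bin shift within every trial. Block shuffling
alone preserves each predictor's within-trial temporal structure, but it
cannot disturb a predictor that is identical on every trial — and the
reward step is identical on every trial by construction, so a pure block
null would leave the reward variable's explanatory power fully intact and
its importance identically zero. The added circular rotation breaks the
alignment of all predictors with the response while preserving their
within-trial structure up to rotation. The model is significant when the
actual EV exceeds the null's 95th percentile; per-variable importance is
EV_full minus the mean EV with only that variable permuted. The
anticipatory variant applies the same machinery to the 12 bins before
reward onset without the reward column.

# The maximum-likelihood decoder

Two class windows are defined around each reward: the *expectation* period
from −1.5 to +1.5 s, and a *baseline* period ending at −1.5 s. Only the
baseline's end is pinned by the definition; we take the 2.75 s
immediately preceding it so that every decoding-window length up to 2.75 s
fits both classes, and we anchor test windows at each class-window start.
Per cell and class, the firing rate is estimated by Gaussian kernel density
(bandwidth 200 ms) of spike times pooled over training trials, normalized
to Hz, with reflected-boundary edge correction and a 0.1 Hz floor that
keeps log-likelihoods finite (a standard regularization for Poisson
decoding). Likelihoods are time-resolved Poisson on 0.25 s count bins (the
KDE grid is 0.05 s; both are declared defaults with bins well below the
bandwidth). Each held-out trial contributes one test pattern per class (test windows
could alternatively tile each class period; one window per trial per class
is the default, recorded in the configuration), classified by the larger summed log-likelihood under the two rate
models. Cross-validation is two-fold over even and odd trials, a split that
guards against slow non-stationarity; accuracy is the
fraction of correct patterns over both folds. Significance compares the
accuracy with the 99th percentile of 500 label-shuffled accuracies; we
shuffle the class labels of the held-out test patterns with the
predictions fixed, which is exchangeable with the true-null accuracy
distribution and calibrates the 1% rule exactly in simulation. Population
decoding sums log-likelihoods across cells before the argmax, averaging
over 50 random subsets per subset size. The residualized variant subtracts
each cell's GLM-predicted speed and acceleration contributions from its
binned counts (floored at 0) and re-estimates the class rate models as
per-bin means of the residualized training activity — the piecewise-
constant limit of the KDE estimate, since residualized activity no longer
consists of spike times.

# The synthetic-session generator

`generate_session()` emulates the study conditions the analyses assume:
30 laps on a 4 m track with reward sites at 100 and 300 cm; expert behavior
(lick rate stepping from 0.5 Hz baseline to 4 Hz in the 2 s pre-reward
window and 8 Hz post-reward; a linear deceleration over the final 2 s to a
5 cm/s reward-zone speed, echoing the reported reward-zone speeds) or
non-expert behavior (flat licking and speed until reward); an immobility
bout every lap (4 s at exactly 0 cm/s, flanked by 1–2 s ramps) so that
transition detection is exercised ~30 times per session. The lap layout
places the bout and ramps so that every reward's −6 to −4 s baseline window
falls on steady cruising and the transition windows avoid the reward
response — without that separation the baseline statistics conflate
locomotor state with reward anticipation. Speed carries smooth
multiplicative noise (CV 0.08) as trial-to-trial running variability;
position stays on the nominal profile, mimicking the cm-level mismatch of
real tracking. Spikes are inhomogeneous Poisson via thinning — matching the
Poisson assumptions of the decoder and the CCG null — with unit rate
functions composed of baseline rate, locomotion factor (ON/OFF cells span
0.75–1.25× across the speed range), place fields for principal cells,
Gaussian reward bumps (predictive peak −0.1 s or consumption peak +1.2 s,
SD 0.5 s, 3× gain) or boxcar steps, and an optional additive speed slope.
Principal cells fire doublets (4 ms partner with probability 0.25) so their
bursting index separates cleanly; waveforms are biphasic templates with
class-specific trough-to-peak times on four sites. Monosynapses add one
postsynaptic spike per presynaptic spike with the configured efficacy at
2 ms latency with 0.2 ms jitter. The default presynaptic mossy-like cells
are non-spatial so synaptic drive does not copy a place field into the
postsynaptic reward-window statistics. ChR2 units respond to light with a
deterministic first spike at their latency plus a 10× rate step for the
pulse duration — guaranteeing the 5 ms first-spike criterion is exercised
on both sides — while inhibited units lose 95% of in-pulse spikes and
disinhibited units gain rate only from 8 ms after onset.

What the generator deliberately does **not** emulate: biophysical dynamics
(conductances, spike-frequency adaptation, refractoriness beyond an
optional dead time), LFP of any kind (the dentate-spike amplitude enters
only as a supplied per-unit feature), theta-modulated firing, behavioral
idiosyncrasies such as mid-lap stops at variable places, and electrode
drift or sorting errors. Passing tests therefore demonstrate correctness of
the estimators under the stated statistical assumptions, not robustness to
every property of real recordings.

One consequence of position-locked rewards deserves note: any
place-modulated cell is genuinely reward-window-modulated, because the
pre-reward window always covers the same track segment. Ground-truth
recovery of reward-modulation labels is therefore scored on the units with
configured reward profiles (the SOMIs); for place cells a detected
modulation is correct behavior, not a false positive.

# Numerical choices and degenerate inputs

Bins are half-open everywhere; ties in the delay argmax resolve to the
earliest bin; boundary values at classification thresholds are
"unclassified"; flat traces, constant predictors, silent units, empty
windows and underpowered designs (fewer than 10 trials, 20 pulses, 8
transitions or 15 stimuli) are refused or flagged rather than silently
processed. Every stochastic stage draws from a named child stream of the
single config seed, so stages are independently reproducible and the full
pipeline is bit-identical under a fixed seed.

The test suite runs the heavier checks at sizes chosen to keep the full
suite in a few minutes on one core while retaining power: calibration
checks use 500 null simulations per test, detection power uses 200 synthetic
pairs at 2000 presynaptic spikes, and the decoding cohort uses 10 cells and
30 trials over 6 generator seeds (the acceptance script uses 20).

# Known limitations

The hollow-kernel baseline is mildly biased at the window edges by the
renormalization; detection uses the central ±4 ms where the effect is
negligible. The Wilcoxon-based tests are conservative for very low counts
(heavily tied data), so empirical false-positive rates can fall slightly
below alpha in sparse regimes. The GLM is identity-link least squares by
design and will under-fit strongly
nonlinear rate-behavior relationships. The decoder's one-pattern-per-trial
convention yields fewer test patterns (and noisier accuracies) than tiling
the class windows would; the choice is recorded in the configuration.
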