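---
title: "Spatial and contextual population codes in a virtual go/no-go task: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial and contextual population codes in a virtual go/no-go task: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorcode)
```

## The task and the data model

`corridorcode` analyzes calcium-imaging recordings of hippocampal CA1
populations in a head-fixed virtual go/no-go task. The animal runs down
106-cm virtual corridors of two kinds — rewarded (R) and unrewarded (U) —
presented in pseudorandom order and separated by gray timeout screens. An
uncued reward zone (RZ) occupies the last ~10 cm; the animal must lick there
in R corridors and withhold licking in U corridors. Behavior (position,
speed, licks, rewards) is aligned frame-by-frame (~30 Hz) to two
cells × frames matrices: raw fluorescence and deconvolved "inferred spike"
activity, the latter being the quantity all rate analyses use.

A `corridor_session` stores these aligned streams with the geometry
(corridor length 106 cm, 50 spatial bins of 2.12 cm). Conventions fixed
across all modules: positions are cm from corridor entry; bins are 0-based
and half-open with the last bin closed; lap indices are 0-based; gray-zone
frames carry corridor id `GRAY` and an undefined position that analyses must
never consult directly — every computation starts from an explicit frame
mask. Sessions round-trip losslessly through a directory of CSV tables plus
a YAML attribute file (doubles serialized at 17 significant digits), which
keeps the store human-readable and language-portable.

## Behavioral scoring

A lick *event* is the rising edge of the per-frame lick signal. An R lap is
correct iff at least one lick event falls in the RZ, a U lap iff none does.
Performance is a trailing (causal) 40-lap moving fraction of correct laps —
trailing so that the learning criterion (36 of 40 correct) is well defined
online — and epochs are labeled LOW (perf < 0.65), HIGH (perf > 0.84) or MED
(boundaries map to MED; strict inequalities), with epochs required to span
at least 30 laps.

Lick rate and speed are binned over the 50 spatial bins (rate = events per
occupancy second; speed = occupancy-weighted mean; empty bins are missing,
never zero). Behavioral zones are geometric: RZ bins 45–49, prezone (PZ)
bins 40–44, control zone (CZ) bins 15–19 (5 bins starting 25 bins before the
PZ). Two statistics summarize discrimination, both of the contrast form
$(a-b)/(a+b)$:

* intracorridor index: $(x_{PZ}-x_{CZ})/(x_{PZ}+x_{CZ})$ per corridor;
* intercorridor selectivity:
  $(x_{PZ}^{rew}-x_{PZ}^{unrew})/(x_{PZ}^{rew}+x_{PZ}^{unrew})$,

where $x$ is the lick rate or mean speed. Zone aggregates use occupancy-
weighted bin means (the simple-vs-weighted choice is not dictated by the
form of the statistic; weighted was chosen and is recorded here).

## Calcium events and activity filters

$\Delta F/F = (F - F_0)/F_0$ with $F_0$ the mode of the raw trace,
estimated as the center of the tallest histogram bin at Freedman–Diaconis
width — deterministic and robust to activity-induced skew. The trace is
smoothed with a 100-ms Gaussian kernel for detection (the 100 ms is taken
as the kernel SD; configurable). The cell-specific noise SD is the SD of
$\Delta F/F$ over maximal "resting" segments of ≥ 1 s whose inferred-spike
rate stays below 20 events/s; continuous deconvolved amplitudes are
converted to event weights by rounding with a minimum of 1 for any positive
sample — an explicit, overridable convention. Transients are local maxima of
the smoothed trace exceeding 3 noise SD; a maximum within 5 s of the
previously retained event is absorbed into it (the separation rule is
applied to peak times). Cells are *active* at ≥ 1 event/min and
*sufficiently active* (the stricter filter used for event-session analyses)
at a mean inferred rate strictly above 1 event/s.

## Rate maps and cell-level statistics

Analyses are restricted to running frames (speed strictly > 5 cm/s,
gray zones excluded). Inferred spikes are binned, averaged across the three
neighboring bins (edge bins average the existing neighbors; corridors are
linear, so no wraparound), summed across laps and divided by per-bin
occupancy time — separately per corridor, and separately for even/odd laps
where two independent estimates are needed. The three-bin average is applied
to the binned counts before occupancy division, following the order of
operations of the estimator's definition.

Per cell and corridor:

* **spatial reliability** — mean Pearson correlation between single-lap
  binned activity and the tuning curve (zero-variance laps skipped and
  counted);
* **tuning specificity** — corridor length divided by the activity-weighted
  SD of position. Activity in a bin is treated as uniform within the bin
  (adding $w^2/12$ to the weighted variance), so a uniform curve gives
  exactly $\sqrt{12}$ and a single-bin curve the finite maximum
  $50\sqrt{12}$ — no ad-hoc cap is needed;
* **spatial information** — Skaggs information
  $\sum_i p_i (\lambda_i/\bar\lambda)\log_2(\lambda_i/\bar\lambda)$ in
  bits/event ($p_i$ = occupancy share); bits/s is also exposed.

**Corridor selectivity** is $(r_{rew}-r_{unrew})/(r_{rew}+r_{unrew})$ with
$r$ = total spikes over total running time per corridor, computed for the
whole corridor and in four zones (P1 bins 0–13, P2 14–27, P3 28–41, RZ —
a corridor-dependent window, bins 42–45 in U and 45–48 in R; which corridor
gets which window is configurable since the zone list admits either
assignment).

### Shuffle null and classification

Significance uses a circular-shift surrogate: each of the (default) 1000
shuffles shifts the cell's full spike train relative to position by a
uniform random offset of at least 10 s (preventing near-identity
surrogates), then splits the shifted train into 5 contiguous chunks of at
least 500 frames (chunk boundaries redrawn per shuffle) and permutes the
chunk order; all metrics are recomputed with the original masks and
binning. P-values are $(1+\#\{null \ge obs\})/(1+n)$, one-sided high for
the spatial metrics and one-sided on $|selectivity|$ (cells can be
selective for either corridor).

Each cell's 11 tests (3 spatial metrics × 2 corridors + 5 selectivities)
form one Holm–Bonferroni family at family-wise α = 0.05; the family is
per-cell because the classification is per-cell. A cell is *spatially
tuned* in a corridor if any corrected spatial test there is significant,
*corridor-selective* if any corrected selectivity test is, yielding the
categories inactive / active-untuned / spatial-only / selective-only /
dual. Note a discreteness constraint that matters when reducing the
surrogate count: with $n$ shuffles the smallest attainable p is $1/(n+1)$,
and Holm's most stringent step requires $p \le \alpha/11$, so $n$ must
exceed 219 for any detection to be possible. The bundled validation runs
use 300 surrogates on these grounds; the package default remains 1000.

On the synthetic task the shuffle null has one quirk worth knowing: laps
have similar durations, so a pure circular shift relocates a field
semi-coherently across laps, and occasional surrogates retain high spatial
metrics until the chunk permutation and pseudorandom schedule break the
alignment. Detection and type-I calibration are unaffected; single-cell
p-values just need not reach the $1/(n+1)$ floor.

## Population analyses

* **PV correlation**: $M_{ij} = \mathrm{corr}(PV_i^A, PV_j^B)$ with $PV_i$
  the vector of all cells' rates in bin $i$; the diagonal summarizes the
  similarity of two spatial codes. Zero-variance vectors give missing
  entries, never imputed; summary means skip and count them.
* **Lap-to-lap correlation**: $C_{ij} = \mathrm{corr}(AV_i, AV_j)$ with
  $AV_i$ the flattened cells × bins activity of lap $i$, over 20 laps of a
  corridor on each side of a Switch/Reversal event; the per-lap summary
  $C_i$ is the mean of row $i$ excluding the diagonal (reading the
  event-centered average as the mean over the 40-lap window).
* **Template correlation**: $B_i = \mathrm{corr}(AV_i, TV)$ against a
  template concatenating all cells' tuning curves estimated from the laps
  before (or after) the event, excluding 20 laps around it; laps carry
  correctness flags so error laps can be compared with correct laps.
  Template tuning curves reuse the same rate-map estimator (same smoothing
  and masks) for consistency.
* **Normalized activity difference**: per-cell difference of two maps
  divided by the SD of that cell's difference across positions (zero-SD
  rows flagged undefined).
* **Category transitions**: cells co-registered across a LOW and a HIGH
  epoch are cross-tabulated by category; the random-transition expectation
  distributes the cells entering each target category in proportion to
  source-group sizes (algebraically the classical independence expectation
  row × col / N), tested with $\sum (O-E)^2/E$. A permutation alternative is
  available by shuffling the HIGH labels.
* **ROI matching**: two epochs' ROIs are the same cell iff both traces
  correlate above 0.958 with the corresponding segments of a
  concatenated-recording reference trace; any ROI in more than one
  surviving pair has all its pairs removed.

## Bayesian decoding

Frames from gray zones, laps shorter than 40 frames, frames below 3 cm/s
and the first 2% of the track (the first bin, where corridor identity is
not yet observable) are removed. Spikes are smoothed with an 11-frame
uniform kernel applied as a moving *sum* and binarized at 0.5 — with sparse
deconvolved events a moving average almost never crosses 0.5, while the
moving sum marks a frame as spiking iff any event falls within the window,
which is the intended "fraction of frames with spikes" Bernoulli statistic.
The decoder is naive Bayes over 98 states (49 bins × 2 corridors):
$P(s_i \mid x_j, c_k)$ is the fraction of training frames with a spike,
regularized by a Jeffreys-style pseudocount of 0.5 (zero-probability states
would break the log-likelihood; the pseudocount is configurable, zero is
rejected). The posterior is accumulated in the log domain under a uniform
prior; predicted position is the median of the position marginal (smallest
bin whose cumulative marginal reaches 0.5), predicted corridor the argmax
of the corridor marginal (ties to the first corridor); the posterior mass
on the wrong corridor is also emitted as a *soft* error so the hard/soft
choice is visible in the outputs. Cross-validation uses 10 contiguous frame
blocks (contiguity limits temporal leakage; random-frame folds are an
option), with up to 400 neurons drawn without replacement per fold × repeat
and results averaged over 20 repeats (degenerate when all neurons are
used).

## The synthetic session generator

Every downstream stage is validated against `simulate_session()`, which
emulates the task geometry and a CA1-like population with full ground
truth: pseudorandom balanced U/R blocks of 4; ~20 cm/s running with jitter
and anticipatory slowing in the R corridor on HIGH-stage laps; gray
interludes of 0.5 s after correct laps and a ~2.5-s run-through after
errors; stage-dependent Bernoulli licking (elevated in the anticipation
zone of both corridors at LOW, only in R at HIGH); Gaussian place fields
(SD 8 cm) tiling the track with 20% reward-zone over-representation;
Poisson spiking with baseline 0.2 events/s and field amplitude 12 events/s
— the amplitude was set so that single-lap population vectors of a corridor
correlate at the ~0.6–0.7 level reported for CA1 event data, and fixed;
fluorescence as the exponential-kernel (τ = 0.8 s) convolution of spikes
plus Gaussian noise. Corridor selectivity is injected by a multiplicative
gain $g$ on the field amplitude in R only, making the whole-corridor
selectivity analytically $(g-1)/(g+1)$ in the zero-baseline limit — a
closed-form recovery target. Scripted events: a Switch resamples field
center and gain for a configured fraction of cells at the event lap; a
Reversal adds per-lap Gaussian drift to field centers from the event lap on
(the Reversal variant models representational drift, not behavioral
relearning — lick policy is left unchanged, so post-event error laps arise
from the unchanged policy).

Generation is two-pass so gray durations can depend on lap correctness:
trajectory → licks → lap scoring → trajectory regenerated from the same
seed with correctness-conditioned gray durations (lap frames are identical
across passes because gray frames consume no random numbers). Everything is
deterministic given (config, seed).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: slow drift of tuning outside scripted events,
theta-related temporal structure, interneurons, deconvolution artifacts
(ground-truth spikes stand in for inferred spikes), stopping/disengagement
bouts, and visually evoked non-spatial responses. Conclusions about
estimator correctness transfer; conclusions about effect sizes in real
recordings do not.

## Validation problem sizes and numerical choices

The bundled validation (tests and `scripts/acceptance.R`) uses: null
calibration on 3 × 200 homogeneous Poisson cells (1 event/s, 60 laps);
recovery on 100 planted-field cells (60 laps); selectivity recovery at
$g \in \{1,2,3\}$ on 50 cells each with matched occupancy (no R-corridor
slowing, since occupancy asymmetries induce genuine time-weighted
selectivity); decoder checks against brute-force enumeration on ≤ 5-neuron
instances plus chance-level (shared tuning) and high-SNR (disjoint fields)
regimes; Switch/Reversal analyses on 100-cell sessions of 90 and 140 laps.
These sizes give stable statistics at interactive run times.

Other fixed numerical choices: permutation p-values use the add-one
estimator; Pearson correlations on vectors with missing bins use pairwise
complete observations and return missing below 3 points or at zero
variance; the specificity variance includes the within-bin term $w^2/12$;
Holm correction is `stats::p.adjust(method = "holm")`; chi-square p-values
come from the asymptotic distribution with $(r-1)(c-1)$ degrees of freedom.

## Known limitations

Disengagement detection is not implemented (no formula is available for
it); the behavioral-stage schedule is scripted rather than learned; the
session store holds one imaging epoch per file (laps partially imaged are
out of scope); and the ROI matcher operates on traces, not on spatial
footprints — it validates the correlation-threshold logic, not image
registration.
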