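---
title: "Methods: phase-locking functional networks and their synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-locking functional networks and their synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`plvnet` implements a dynamic functional-connectivity analysis for
multichannel thalamocortical recordings — instantaneous LFP phase,
windowed phase-locking values, percentile-thresholded binary graphs,
small-world statistics, spike-rate analysis, and rank-sum comparisons
across a group x condition design — together with a synthetic generator
that produces recordings with exactly the statistical structure the
analysis assumes. This vignette is the package's account of the model, its
parameters, the numerical conventions, and the design decisions taken
where more than one reasonable choice existed.

## 1. The analysis model

### Phase and PLV

A band-limited signal $x(t)$ is paired with its Hilbert transform to form
the analytic signal $x(t) + i\,H(x)(t)$, whose argument is the
instantaneous phase $\varphi(t)$, wrapped to $(-\pi, \pi]$. The transform
is computed by the FFT quadrature filter (`analytic_phase()`): positive
frequencies doubled, negative zeroed. Segments shorter than 64 samples or
with zero variance are rejected — phase is undefined there.

Synchrony between channels $x$ and $y$ over a window of $T$ samples is

$$\mathrm{PLV} = \Big|\tfrac1T \sum_{t=1}^T e^{\,i(\varphi_x(t) - \varphi_y(t))}\Big|,$$

the modulus of the time-averaged unit phasor of the phase difference: 1
for locked signals at any constant lag, and for independent uniform phases
a sampling floor of $\sqrt{\pi}/(2\sqrt{T})$ (about 0.056 at $T = 250$,
i.e. 500 ms at 500 Hz). This floor is why windows below 25 samples are
refused: a "synchrony" estimate dominated by its own bias is not
interpretable.

Two conventions matter and are enforced by tests:

* **Phase is extracted once per epoch**, then sliced into windows. Per-
  window Hilbert transforms would put the transform's end effects inside
  every window; epoch-level extraction confines them to the epoch ends,
  which are then excluded by a 5% **edge guard** (`windowed_plv()`).
* **Windows are half-open** $[s, s+T)$, starts at
  $k \cdot \ell(1-\text{overlap})$, defaults $\ell = 500$ ms and 50%
  overlap. Window length is constrained to 50–1000 ms, the range in which
  the sliding-window analysis is defined.

### Graphs

Each window's symmetric PLV matrix is binarized at the **75th percentile
of its own upper-triangle weight distribution**, keeping strictly greater
weights. Three numerical choices here were genuinely open:

* *Percentile definition.* Linear interpolation between order statistics
  with plotting positions $p_k = k/(n+1)$ (R's `quantile` type 6). Under
  this convention the 75th percentile of $\{0.1, \dots, 0.6\}$ is 0.525 —
  the worked reference case frozen in the tests. R's default (type 7)
  would give 0.475 and one extra edge.
* *Tie rule.* Strictly-greater-than. A constant matrix then yields an
  explicitly flagged empty graph rather than an arbitrary subset of tied
  edges; determinism is worth more than edge count here.
* *Per-matrix thresholding*, not pooled across windows: "the weight
  distribution" of a window most naturally means that window's own
  weights, and per-matrix thresholds keep graph density comparable across
  windows by construction. (Pooled thresholding can be emulated by
  thresholding the stacked array yourself; the package does not hide it
  behind an option it does not test.)

Graphs are filtered by two **admissibility criteria**: (i) at least 99% of
nodes in the largest connected component — by ceiling, for $n \le 100$
this means *all* nodes connected; (ii) ensemble outlier removal, dropping
graphs outside the 5th–95th percentile of the node-count, edge-count or
density distribution. Ensembles smaller than 20 skip the outlier filter
with a warning, since 5% tails of fewer than 20 values are individual
points.

Statistics on kept graphs (binary undirected conventions): mean clustering
coefficient $C$ with degree-< 2 nodes contributing 0; characteristic path
length $L$ as the mean over reachable pairs, with unreachable pairs
excluded and counted (rare by construction, given criterion (i));
normalized Brandes betweenness. All three are computed through `igraph`
behind the package's interface and are verified exactly against
brute-force oracles — triangle enumeration, Floyd–Warshall, exhaustive
geodesic enumeration — in the test suite.

### Spikes

Units pass QC if the mean rate lies strictly inside 4–100 spikes/s
(exactly 4 or 100 is kept: the exclusion rule names rates *below* and
*above* the band) and if at most 1.5% of inter-spike intervals fall below
a 2 ms refractory bound. The ISI rule is this package's operationalisation
of "implausible ISI distribution" — no quantitative criterion is standard
— so both the threshold and the bound are exposed as arguments and the
violation fraction is reported per unit.

Firing rates are counts over half-open epochs. Evoked rates pool the
500 ms epochs after every pulse onset (total spikes over total evoked
time); with equal-length epochs pooling equals averaging per-epoch rates,
and pooling is numerically simpler. Couplet second pulses start before the
first pulse's epoch ends; both epochs are kept, flagged as overlapping,
and spikes in the overlap count toward each — merging them would silently
redefine "the response to a stimulus onset".

### Statistics

`ranksum()` uses midranks for ties; for pooled $n \le 12$ the two-sided p
is exact (doubled smaller tail over all $\binom{N}{n_a}$ rank
assignments, clamped at 1), otherwise a normal approximation with tie
correction and 0.5 continuity correction. The approximation's accuracy at
the crossover size is itself tested: below 0.01 where decisions are made
(exact $p \le 0.2$) and about 0.02 at mid-range p — an intrinsic property
of the continuity-corrected normal approximation, not improvable without
changing the method. Bonferroni correction multiplies p by the family
size; families default to the simultaneous contrasts of one results
paragraph (typically 2–4), and are configurable through
`comparison_spec()`.

**Sampling units** are stated explicitly per measure: firing rate — unit x
window; $C$, $L$ — graph (window); PLV — **window, averaged over channel
pairs**. The last deviates from the superficially natural pair x window
choice for a measured reason: all ~150 pairs of a window share one
oscillator-trajectory snapshot, so pair-level samples are strongly
clustered, and treating them as independent inflates evidence to the point
that identical-preset null runs reject in most seeds. With window-averaged
synchrony the null is calibrated (tested: ≥90% of null seeds show no
corrected rejection) while every injected contrast remains recovered.

## 2. The synthetic generator

The generator is **not** a biophysical model. It is a stochastic Kuramoto
system,

$$d\varphi_i = \omega_i\,dt + \sum_j K_{ij}\sin(\varphi_j - \varphi_i)\,dt + \sigma\,dW_i,$$

read out as $x_c(t) = A_c \cos\varphi_c(t) + \varepsilon_c(t)$ with white
observation noise — chosen precisely because pairwise phase coupling is
the statistic PLV measures, which makes parameter recovery a well-posed
test: coupling in, synchrony out, with ground truth retained
(`synth_recording()$ground_truth`).

Parameters, units and defaults (`synth_config()`):

| parameter | unit | default | why |
|---|---|---|---|
| `fs` | Hz | 500 | the analysis sampling rate after decimation |
| `duration` | s | 600 | 10-min rest sessions, trimmed to the central 8 min |
| `natural_freqs` | Hz | U(8, 30) | inside the 1–120 Hz band, far below Nyquist |
| `coupling` | rad/s | block matrix, 1.0 within / 0.5 between region | thalamocortical loop: tighter within-region coupling |
| `phase_noise_sd` | rad/√s | 2.5 | windows decorrelate within ~1 s; PLV well off its floor and off 1 |
| `amplitude`, `obs_noise_sd` | µV | 40, 15 | LFP-scale signal with realistic SNR after band-limiting |
| `base_rates` | spikes/s | U(8, 30) | strictly inside the 4–100 QC band |
| `stim_rate_gain` | — | 2 | evoked firing-rate boost during the 500 ms post-pulse epochs |

Integration uses Euler–Maruyama at $dt = 1/f_s$ (2 ms); phase dynamics at
these coupling strengths are slow relative to the step, and a smaller step
is refused only in the other direction ($dt > 1/f_s$ is an error). One
master seed spawns per-stream sub-seeds (phases, observation noise, spike
streams, schedule) so partial re-runs leave other streams untouched;
identical config + seed gives bit-identical recordings.

**Spikes** are inhomogeneous Poisson by thinning with a 2 ms absolute
refractory period enforced by deletion. Plain thinning + deletion loses
$\approx r\tau$ of spikes (4% at 20 spikes/s), which would break the
generator's contract that realised rates track requested rates within 5%;
the thinning intensity is therefore dead-time-compensated,
$\lambda^* = r/(1 - r\tau)$, which for constant rates makes the
post-deletion rate exactly $r$ (the kept process is a renewal process with
ISI $= \tau + \mathrm{Exp}(\lambda^*)$). Thinning requires
$r_{\max}\tau < 1$ and rejects otherwise.

**The stimulus schedule** is couplets: first pulses every 500 ms from
$t = 0$, each second pulse a uniform 150–250 ms later, 5 ms width as
metadata. Note a structural consequence: consecutive 500 ms evoked epochs
tile essentially the whole tactile session, so evoked coupling/rate boosts
are effectively tonic within tactile sessions; evoked-versus-rest
contrasts are therefore made against separate rest sessions.

### The study preset and its narrowband choice

`thalamocortical_config()` is the configuration the pipeline simulates: 9
channels per region (two 3 x 3 electrode matrices), one unit per channel,
and per-channel natural frequencies drawn from **U(9, 13) Hz** rather than
the generator-wide U(8, 30) default. This was chosen once, for a
structural reason: two oscillators detuned by $\Delta\omega$ only respond
to coupling when $K$ is comparable to $\Delta\omega$. With 8–30 Hz spreads,
typical detunings are $2\pi \cdot 10$ rad/s ≈ 60 rad/s, so couplings of a
few rad/s produce no synchrony gradient at all, and couplings large enough
to matter lock the whole array to PLV ≈ 1. A shared mu-like rhythm with
±2 Hz jitter places the system in the regime where the preset multipliers
express as graded, recoverable PLV differences — which is the property the
whole testbed exists to provide.

**Preset table** (`condition_presets()`; 8 cells = {CR, CCI} x {rest,
tactile, reac_rest, reac_tactile}): CCI scales coupling by 1.3 (chronic
pain raises resting synchrony); tactile conditions apply a 2.0 coupling
multiplier inside evoked epochs; REAC conditions scale coupling by 1.5 on
the group base and firing rates by 1.43 (CR rest), 1.93 (CCI rest), 1.09
(CR tactile), 1.41 (CCI tactile). The rate multipliers are the four
reported percent increments of the study design; the synchrony multipliers
are this package's calibration — the source reports directions and
significance for synchrony, not effect sizes — and they are deliberately
not tuned per analysis: they are fixed constants of the preset table.

### What the generator does and does not emulate

Emulated: the channel layout and region labels, session durations and
trimming, the couplet schedule, condition-dependent synchrony and rate
effects with ground truth, LFP-scale amplitudes and noise, spike trains
that pass the package's own QC.

Not emulated: 1/f LFP spectra and broadband transients, volume
conduction, spike–LFP coupling, anesthesia depth, electrode drift,
between-animal variability (a group is one draw of oscillators and rates,
not twelve animals), and any physics of the REAC device — REAC conditions
are multiplier presets, nothing more. Passing tests therefore demonstrate
that the *analysis chain* is correct and sensitive under its own model
assumptions; they say nothing about effect sizes in real tissue, and real
recordings additionally stress the QC and admissibility filters in ways
clean synthetic data cannot.

## 3. The recording container

A recording bundle is one directory: `lfp.bin` (flat little-endian
float64, channel-major) + `lfp.json` sidecar (shape, dtype, rate, units),
`spikes.tsv` and `stimuli.tsv` event tables, `meta.json` (session and
channel metadata, unit QC status). Event times are written with 17
significant digits, so text round-trips are bit-exact for doubles; the
round trip `read_recording(write_recording(rec))` is tested for identity.
Malformed bundles — missing files, sidecar/array shape mismatch,
non-monotone timestamps — fail with classed errors, never silently. All
times are seconds from recording start; all epochs half-open.

The analysis band is 1–120 Hz (order-4 Butterworth, forward–backward so
the filter is zero-phase — a hard requirement, since downstream phase
estimates must not inherit filter delay). Acquisition-side decimation
(e.g. 32 kHz to 500 Hz) uses a zero-phase anti-alias low-pass at 80% of
the target Nyquist followed by integer subsampling.

## 4. Problem sizes and known limitations

The test suite and acceptance script run the chain at reduced problem
sizes chosen to exercise every stage with comfortable statistical margins:
120 s sessions for the 8-condition study run (≈430 PLV windows and 2160
unit-window rates per cell), 60 s sessions for each of the 10–20
identical-preset null replicates, 20-second two-block simulations (20
seeds) for coupling recovery, and 200/100 random graphs for the
brute-force oracle comparisons. These sizes are the package's choice of
demonstration scale; nothing in the implementation depends on them, and
`run_full(duration = 600)` reproduces the full-length design.

Limitations worth knowing:

* Windows from one session are statistically dependent; the rank-sum
  layer treats its stated sampling units as independent. The window-level
  PLV unit keeps the identical-preset null calibrated in the tested
  regime, but dependence grows with slower dynamics, and a hierarchical
  (session-level) model would be the principled extension. Animal-level
  clustering is likewise not modelled.
* With per-matrix 75th-percentile thresholding, graph density is pinned
  near 25%, so $C$ and $L$ respond to the *arrangement* of strong pairs,
  not to overall synchrony level; strongly modular coupling can also push
  graphs toward two components and thus *out* of the admissible set. In
  the preset regime a minority of windows is admissible — the admissible
  count is reported per session in the run manifest, and every discarded
  graph is accounted for (`manifest`: inadmissible + outlier-removed +
  kept = windows).
* PLV matrices of even fully uncoupled narrowband oscillators are not
  structureless: frequency-adjacent channels lock more, and shared
  node-level phase excursions make threshold graphs cluster above the
  Erdős–Rényi baseline. Clustering comparisons between conditions are
  meaningful; absolute $C$ values are not interpretable against a naive
  random-graph null.
* Betweenness centrality is computed and exported but carries no
  acceptance-tested effect structure — the design injects no
  betweenness-specific signal.
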