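---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`stellate` re-implements, as a tested pipeline, the quantitative analyses
by which small local glycinergic interneurons (L-stellate cells) of the
ventral cochlear nucleus are distinguished from D-stellate projection
neurons: intrinsic-property extraction from current-clamp sweeps, K-means
classification, chopper-firing analysis, synaptic-event analysis, and
reconstruction morphometry. This vignette records the models behind each
stage, the parameters that matter, and the numerical decisions that a
reader would otherwise have to reverse-engineer from the code.

## Spike-feature extraction

**Threshold.** Spike threshold is the voltage at 5% of the peak of the
spike's first derivative, measured after subtracting the baseline dV/dt
generated by the cell's electrotonic charging. dV/dt is computed by
central differences on the raw grid; no smoothing is applied by default
because the acquisition chain is already band-limited, and any additional
filter would bias the rate-of-rise measurement. The baseline is estimated
by fitting a mono-exponential charging curve
$V(t) = V_0 + A\,(1 - e^{-(t-t_{on})/\tau})$ to the segment between the
step onset and 1 ms before the first spike's dV/dt surge, and subtracting
the fit's analytic derivative; a charging transient is exponential for a
passive membrane, which is why an exponential (rather than, say, a
sliding median) is the right model for this nuisance term. When the fit
window holds less than 2 ms, or the fit fails, a zero baseline is used
and flagged. The 5% crossing is located by walking backward from the
spike peak to the last upward crossing of $0.05\,d_{max}$ and linearly
interpolating both the crossing time and the voltage.

**Features.** Height is threshold to peak; halfwidth is the interpolated
width at threshold + height/2; overshoot is the peak relative to 0 mV;
undershoot is the most negative excursion relative to threshold within a
post-peak window (10 ms, truncated at the next spike's threshold crossing
and at the step offset — both defaults because the source definitions do
not state a window); AHP latency is peak to undershoot trough; and the
AHP metric is the voltage 1 ms after the trough minus the trough voltage,
reported positive for a repolarizing recovery so that published values
carry their printed signs. The AHP metric is marked undefined when the
next spike or the step end falls within 1 ms of the trough — without this
rule the last spike of a step contaminates the per-cell average with the
post-step decay.

**Detection defaults.** Spikes are local voltage maxima preceded (within
1 ms) by dV/dt above 20 V/s, with a 1 ms refractory gap. The 20 V/s value
is a convention of the field, not a published parameter, and both knobs
are exposed.

**Input resistance** is Ohm's law on a hyperpolarizing step:
$R_{in} = 10^3 \, \Delta V / \Delta I$ (mV, pA → MΩ), with the
steady-state voltage averaged over the last 20% of the step and the
baseline over the 50 ms before onset. The source describes the
measurement as performed "in voltage clamp mode" while computing Ohm's
law from an injected current; this package implements the current-clamp
reading, which is the one the formula describes. Sweeps containing
spikes are rejected as contaminated.

## The synthetic sweep generator

Spike *timing* and spike *waveform* are deliberately decoupled so each
has exact ground truth.

**Waveform.** `make_analytic_spike()` builds a piecewise-analytic
template from cosine-ease segments. On the half-cosine upstroke dV/dt is
proportional to $\sin(\pi u)$, so the 5% crossing sits at
$u_5 = \arcsin(0.05)/\pi$, and the upstroke's start voltage is chosen in
closed form so the voltage at $u_5$ equals the designed threshold. The
repolarization is split at the threshold voltage so the designed
halfwidth and the designed AHP latency can be satisfied simultaneously;
the post-trough recovery is linear with slope equal to the designed AHP
metric per millisecond. The template's pre-spike padding is nudged by
less than one sample so the trough lands exactly on the sampling grid,
which keeps the sampled AHP metric equal to its design value at 20 and
40 kHz alike.

**Timing.** A leaky integrate-and-fire recursion with exact exponential
updates: the membrane charges toward $V_\infty = V_{rest} + I R_{in}$
with $\tau_m = R_{in} C_m$, a spike is triggered at the closed-form
crossing of the initiation voltage (equal to the waveform threshold, so
splices join the subthreshold trajectory continuously), the waveform is
spliced from the crossing through its linear recovery, and charging
resumes from the recovery end-point. The recovery duration is calibrated
once per phenotype by root-finding so that the inter-spike interval at
+500 pA equals `1000 / rate_at_500pa_true` exactly; refractoriness is
emergent. Noise-free subthreshold steps therefore obey Ohm's law to
machine precision, and the +500 pA spike count is the calibration target
within one spike.

**Presets.** `"D_stellate"` and `"L_small"` carry the published
population means (input resistance 114.87 / 305.54 MΩ, halfwidth 0.31 /
0.55 ms, AHP 4.18 / 1.55 mV, AHP latency 0.87 / 1.81 ms, rate of rise
317.67 / 288.06 V/s, threshold −45.57 / −43.46 mV, overshoot 24.57 /
20.46 mV, undershoot −17.79 / −14.03 mV, +500 pA rate 213.52 / 225.72
sp/s). Capacitance is not published; the defaults (25 and 12 pF) give
membrane time constants of roughly 3–4 ms, typical for these cells. The
resting potential is −65 mV, inside the −60 to −70 mV range the
recordings were held at. With a linear integrate-and-fire membrane the
D-stellate preset's rheobase from −65 mV exceeds +100 pA (its Table
values imply ~170 pA), so D-stellate simulations fire from +200 pA; the
small-cell preset fires at +100 pA as the recordings describe.

**Chopper jitter.** The published description of the firing pattern —
well-timed onset spikes whose timing jitter accumulates through the step
with little rate adaptation — is qualitative; no jitter rate is printed,
so `jitter_growth` (default 0.004 ms of SD per ms of elapsed time) is a
free parameter. Jitter is implemented as a per-trial random walk on the
deterministic spike times whose variance budget makes the SD of the k-th
spike time exactly `jitter_growth × (t_k − onset)`. An earlier design
(Gaussian noise on the membrane current) was rejected because, with a
post-spike voltage reset, current noise yields spike-time SD growing as
√t and a flat ISI-CV profile, contradicting both the linear-growth target
and the observed increase in CV through the step; the random-walk form
delivers both directly while keeping spike order and mean rate intact.

## Classification

The feature matrix holds AP halfwidth (ms), AHP metric (mV) and input
resistance (MΩ). Features are z-scored by default: the source does not
say whether raw or standardized features entered its clustering, but raw
input resistance (hundreds of MΩ) would dominate the Euclidean metric,
so standardization is the defensible default; `standardize = FALSE`
provides the sensitivity check, and the transform is recorded so
centroids can be reported in original units.

K-means uses k-means++-style seeding (first centre uniform, later
centres proportional to squared distance from the nearest centre) with
Lloyd iterations, best of 50 restarts by WCSS; restarts and seed are part
of the result's provenance. The WCSS curve adds, at each K, a warm start
built from the K−1 solution plus the worst-fitting point, which makes the
curve non-increasing by construction rather than by post-hoc clamping.
The elbow is the interior K maximizing the discrete second difference
$W(K\!-\!1) - 2W(K) + W(K\!+\!1)$, ties broken toward smaller K.
Separation accuracy maps each cluster to its majority label (several
clusters may map to one label when K exceeds the label count) and scores
each label by the fraction of its cells in clusters mapped to it — the
score under which 11 of 12 visually identified D-stellate cells (91.7%)
were separated in the source analysis.

For synthetic populations the published SEMs are converted to SDs with
n = 12 — the stated count of visually identified D-stellate cells — for
both columns, since the per-column n is not printed. At those spreads the
two classes are ~4–5 within-class SDs apart in the standardized space and
K = 2 recovers the labels at ≥ 99% on average.

## Firing-pattern analysis

PSTHs use half-open bins $[t, t+\Delta)$ from stimulus onset (a spike on
an edge counts rightward), so counts are conserved for every bin width.
Rates are counts / (trials × bin). The chopper metrics are the SD across
trials of the first post-onset spike time, a CV-of-ISI profile (ISIs
assigned to 10-ms bins by their left spike — a stated convention, since
either end is defensible), and an adaptation ratio (mean rate over the
last quarter of the step / first quarter). The sustained-chopper label
(first-spike SD < 1 ms, early CV < 0.35, adaptation ratio > 0.7) encodes
the classical cochlear-nucleus criteria; all three thresholds are
configurable because the source classifies the pattern qualitatively.

## Synaptic-event analysis

**Kernel.** Events are modelled as
$k(t) = (e^{-t/\tau_d} - e^{-t/\tau_r})/k_{peak}$, normalized to unit
peak; the peak time
$t_p = \tau_r \tau_d / (\tau_d - \tau_r)\,\ln(\tau_d/\tau_r)$ is closed
form.

**Detection** is sliding template matching: at each lag the kernel is
least-squares fitted with free scale and offset, and the detection
criterion is the fitted scale divided by its standard error under the
recording's baseline noise SD, estimated robustly from first differences
(median absolute deviation / √2, floored at 10⁻⁴ of the signal range so
noise-free traces behave). Using the global baseline noise rather than
the per-window residual keeps the criterion intact when a second event
overlaps the template window. Candidates must be criterion > 4 (the
default, in noise-SD units), local maxima of the fitted amplitude, and
pass shape checks: the trace must rise from the onset level by at least
max(0.15 × scale, 2.5 noise SEs) into the predicted peak — a decaying
tail fails this, which matters because the criterion alone is scale-free
along an event's own decay — and low-significance candidates must stay
elevated over the first two decay constants, which rejects pure-noise
excursions. Up to three matching-pursuit passes subtract the fitted
templates (extended to 14 decay constants so no above-floor stump
remains) and re-detect on the residual, resolving event pairs close
enough to merge into one amplitude peak. Amplitude attribution for pairs
closer than about twice the kernel peak time remains approximate; times
are still recovered.

**Latencies.** Each event's latency is measured to its fitted onset (the
"synaptic delay" wording implies onset, though peak-referencing is
conceivable) against the nearest preceding stimulus within 20 ms;
< 1 ms is monosynaptic, > 2 ms is delayed/polysynaptic, the 1–2 ms gap is
left unassigned because the source's definitions do not cover it, and
events outside the window are spontaneous.

**Condition changes** are per-cell percentage changes in class-restricted
counts, averaged with their SEM across cells. With Poisson event counts
the per-cell percentage has an SD of roughly
$ (1+f)\sqrt{1/N_t + 1/N_c} \times 100 $ points, which is why the
calibration experiment (5 cells × ~63 s, ~175 control delayed events per
cell) is compared within three standard errors of its own cell-to-cell
spread.

**Decay kinetics.** Detected events are aligned on their refined peaks
and averaged; events whose window overlaps a neighbour are excluded. The
baseline is the mean of the last millisecond of the averaging window
(eight decay constants after the peak), where the kernel and any residual
background from neighbouring events have both decayed; referencing the
far tail rather than the pre-onset segment keeps the decay fit unbiased
when windows are conditioned on having no neighbouring event. A
mono-exponential is fitted by log-linear least squares from 90% of peak
down toward baseline (5% of peak), and the full width at half maximum of
the averaged event is reported alongside τ.

## Morphometry

SWC files are validated on read (seven numeric fields, unique ids, a
single root, parents preceding children), with errors naming the
offending line. The longest axis is the Feret diameter of the node set
and the shortest the minimal caliper width; the default `"projection"`
mode measures both in the x–y plane with rotating calipers, because
slice reconstructions are nearly planar, while `"3D"` mode searches
orientations orthogonal to the 3D Feret axis. The source does not define
its "longest/shortest axis" operationally; Feret/minimal-caliper is the
standard reading. Convex hulls are computed by an incremental 3D hull
written for these modest point counts (no computational-geometry package
is declared as a dependency); volume is the tetrahedron sum against an
interior point, area the facet sum, and coplanar node sets return zero
volume (flagged) with the planar hull polygon's area. Sholl profiles
count parent–child segments whose endpoint distances straddle each shell
radius (tangency ignored) on a 10 µm grid — the shell step is not
published. The two-group Sholl comparison treats each profile as
count-weighted radius samples and applies the two-sample
Kolmogorov–Smirnov test with asymptotic p.

The morphology generator places nodes in elliptical coordinates inside
the target ellipse, lands 16 boundary tips at near-uniform angles, and
rescales x/y against the same caliper measurements the morphometry module
uses, pinning both extents to their targets within 1%. Proximal-heavy
profiles place at least 60% of branch points within the inner third of
the radial extent, mirroring the small cells' soma-proximal branching;
distal-heavy mirrors the tufted T-stellate pattern. Segments are kept
radially monotone so the endpoint-straddling Sholl count coincides with
a dense-resampling count.

## Population statistics

Soma-volume tables get per-group mean ± SEM, adjusted Fisher–Pearson
skewness (`e1071::skewness`, type 2), and a Gaussian fitted by least
squares to histogram counts (Freedman–Diaconis bin width by default; the
source's bin width is unstated). Because the empirical distribution is
positively skewed, the Gaussian is descriptive — as it was in the source
figure — and a log-normal fit is reported alongside as a diagnostic.
Group comparisons are paired or Welch unpaired t tests.

## What the generators do and do not emulate

The generators reproduce: two intrinsic-property phenotypes at the
published means; sustained-chopper spiking with accumulating jitter;
evoked EPSC latency mixtures (monosynaptic < 1 ms, delayed > 2 ms) with
a carbachol condition as a rate/amplitude scaling; Poisson spontaneous
events with difference-of-exponentials currents; and reconstructions
with controllable caliper extents and branch placement. They do not
emulate: conductance-based spike generation (waveforms are stereotyped,
so spike-amplitude adaptation at strong steps is absent), series-
resistance and space-clamp artefacts, correlated or non-stationary
synaptic bombardment, electrode noise spectra, or tortuous neurite
paths. Passing the recovery suites therefore demonstrates that the
extraction operators are correct and well-calibrated, not that they are
robust to every pathology of real recordings.

## Problem sizes

The test and acceptance suites run at desk scale: single sweeps of 1.2–
1.3 s at 20–40 kHz, event recordings of 10–63 s at 10–40 kHz, populations
of 50 cells per class, reconstructions of ~100–200 nodes, and exhaustive
clustering oracles at n ≤ 10. The end-to-end pipeline defaults to six
cells per class at 20 kHz.
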