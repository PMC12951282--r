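---
title: "Methods: spike timing, level sensing and environment control for incubated MEAs"
author: "meaflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike timing, level sensing and environment control for incubated MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaflow)
```

meaflow models the computational core of an incubated multi-electrode-array
(MEA) electrophysiology platform: the spike-detection chain that turns raw
extracellular voltage into event tables, the spike-time-triggered raster
plot (STTRP) statistics that quantify how network spike timing responds to
temperature, osmolarity and pharmacology, the optical liquid-level sensor
that closes the volume-control loop, and deterministic simulators of the
fluidic and thermal control loops. A synthetic-data module generates
ground-truthed recordings so every stage is testable without hardware.

## Signal conditioning and spike detection

Raw traces (17 361 Hz per electrode, microvolts) are conditioned in two
steps: a causal third-order Butterworth high-pass at 300 Hz removes the
local-field and DC components, and a 5-point degree-2 Savitzky–Golay filter
suppresses high-frequency noise. Causal (forward-only) filtering is the
default because it is what a real-time detector sees; zero-phase filtering
is available (`zeroPhase = TRUE`) for offline work. The Savitzky–Golay
polynomial degree is fixed at 2, the standard choice for 5-point smoothing
(degrees 0–1 would over-smooth spikes; degree 3+ is underdetermined at this
window).

Detection is threshold-based. The threshold is `X` times the *raw* median
absolute deviation (MAD) of the electrode's detection trace — no Gaussian
consistency factor (1.4826) is applied, so for Gaussian noise of standard
deviation $\sigma$ the threshold is $0.6745\,X\sigma$. Two modes exist:

* **direct** — the absolute filtered value is compared against the
  threshold, with $X \in \{5, 6\}$ typical (spikes may be negative- or
  positive-going, hence the absolute value);
* **sneo** — the smoothed nonlinear energy operator
  $\psi[n] = x[n]^2 - x[n-k]\,x[n+k]$ (spacing $k \in \{3,4\}$), smoothed
  with a Bartlett window of length $4k+1$, is thresholded at $X = 12.5$,
  while amplitude and timestamp are still read from the filtered trace.
  The MAD is computed on the sneo trace itself (the quantity being
  thresholded); boundary samples where $\psi$ is undefined are excluded
  from threshold estimation.

At the first crossing a 1 ms peak-search window opens; the sample of the
maximum absolute filtered value is recorded (ties broken by the earliest
sample) and detection is suppressed for a further 2 ms measured from the
crossing, so crossings closer than 3 ms merge into one event. Windows are
converted to samples by rounding (17 and 35 samples at 17 361 Hz). The MAD
is estimated over the whole recording by default; `madRange` restricts it
(e.g. for chunked re-estimation). Two numerical choices matter in corner
cases: the Bartlett window is normalized to unit peak, so an impulse in
$\psi$ maps to the window itself (unit-area normalization, which makes a
sinusoid's sneo converge to exactly $A^2\sin^2(k\omega)$, differs only by
the constant $2k$ and is available via `normalize = "area"`); and if a
trace's MAD is degenerate — zero up to numerical dust, as in noise-free
synthetic data — the threshold falls back to 5 % of the trace's maximum
absolute value, which sits above the causal filter's ringing (~4 % of a
transient's peak) and far below any spike.

With Gaussian white noise the direct rule at $X = 6$ operates near a
4-sigma effective threshold, which puts the false-alarm rate close to
1 Hz per electrode; this is a property of the threshold rule itself, not
of the implementation, and the detection-recovery tests assert recall
$\ge 0.95$ at SNR 8 together with a false-positive ceiling of 1 Hz per
electrode at full scale (60 s × 4 electrodes).

## STTRP analysis

A **valid triggering spike** on the chosen trigger electrode is one with no
preceding spike inside an exclusion window (default 10 ms). Because
published analyses use several conventions — exclusion on the trigger
electrode only, or on all electrodes; 10 ms or 5 ms — both the window and
its scope are explicit `TriggerRule` parameters, never hard-coded. Each
valid trigger opens a half-open segment $[t, t + \mathrm{segment})$
(5 or 10 ms) and every network spike inside it is stored as (electrode,
latency); the trigger itself appears at latency 0. All interval logic is
half-open, and latencies are measured from the trigger's peak sample.

Latency bands (e.g. 3.25–4.5 ms on one observation electrode) summarize a
stripe in the raster. `bandMetrics` returns the in-band latency samples,
the **transmission fidelity** — the fraction of triggers followed by at
least one in-band spike — and the per-30-s-bin mean latency used for trend
views; the overall latency summary is the median, the per-bin summary the
mean. Trends are assessed with the classic non-seasonal two-sided
Mann–Kendall test (tie-corrected variance, continuity-corrected normal
approximation), and p-values from repeated runs combine with Fisher's
method ($-2\sum\ln p_i \sim \chi^2_{2k}$).

For pattern drift, segments are binned to 0.1 ms in latency and 2 min in
trigger time, per trigger electrode $i$ and observation electrode $j$. The
similarity of two latency profiles is the cosine
$S = \langle a, b\rangle / (\|a\|_2 \|b\|_2)$, which is 1 exactly when the
two profiles carry an identical normalized pattern and is invariant to
overall spiking frequency. If either profile is all-zero, $S = 0$: a
silent bin reads as maximally dissimilar rather than undefined. The
overall similarity $\bar S(t)$ averages, over all 16 $(i,j)$ pairs, the
similarity between bin $t$'s profile and a reference pooled (counts
summed) over the initial-phase bins $\Omega_{\mathrm{init}}$; a
per-bin-averaged reference is available via `pooled = FALSE`. Note that
bins inside $\Omega_{\mathrm{init}}$ are compared against a pool
containing themselves and are therefore slightly inflated; trend tests on
$\bar S$ should exclude them.

Stimulus-response analysis reuses the same machinery with stimulus times
as triggers and no exclusion rule. Spikes with post-stimulus latency of at
most 5 ms are excluded from response counts (direct, non-synaptic
activation); each spike is assigned to the most recent stimulus, and
overlapping windows are flagged.

## The optical level sensor

The liquid level is read from the row position of a laser reflection on an
800 × 600, 8-bit camera frame (4.5 µm pixels). Row intensities are
integrated; the maximal row integral marks the spot if it exceeds
10 × 255 and the brightest pixel exceeds 200 (both strictly), otherwise
the frame is invalid and the code 6000 is returned (one more than the
largest possible reading, 5990). The subpixel position is the
integral-weighted mean of the 0-based row indices over the 20-row window
$\{m-10, \dots, m+9\}$ (clipped at the borders, and used as-is near them),
times 10, rounded half-away-from-zero — so one row of motion is exactly
10 units. Weights are the raw row integrals with no background
subtraction, mirroring the embedded implementation.

Geometry: a height change $\Delta h$ moves the reflection by
$\Delta x = 2\sin(\beta)\,\Delta h$ on the sensor ($\beta = 60°$ incidence
by default). For a cylindrical 19 mm well this predicts
$2\sin\beta \cdot 1000 / (\pi r^2) \approx 6.11$ µm of sensor displacement
per µL. The synthetic frame renderer draws a bright Gaussian reflection
streak (peak 255, $\sigma$ = 4 rows × 20 columns) with shot-noise-like
pixel noise — standard deviation scaling with the square root of local
intensity, dark pixels black-level clamped at 0, as on a real 8-bit
sensor. That noise model matters: zero-mean additive noise on a dark frame
would be clipped at zero and bias the raw-sum centroid, which the physical
camera does not do. Round trips through render → detect → geometry recover
programmed heights within 0.5 µm for peak-referred noise up to 5 counts.

## Environment-control simulators

**Concentrations.** A partial medium exchange of fraction $f$ maps every
solute to $(1-f)c + f\,c_{\mathrm{fresh}}$ (replace semantics, volume
unchanged); $n$ half-exchanges therefore contract the offset from fresh by
$2^{-n}$. Stock addition uses the additive volume-fraction convention
$c' = c + \mathrm{vv}\times c_{\mathrm{stock}}$ (0.81 mM + 0.5 % of 1 M =
5.81 mM); the exact-dilution model $c' = (c + \mathrm{vv}\,
c_{\mathrm{stock}})/(1+\mathrm{vv})$, about 0.5 % lower here, is available
via `exact = TRUE`. Evaporation removes water only, concentrating solutes;
pure-water additions conserve solute mass.

**Level control.** An event-driven loop evaporates the well continuously
(default step 1 s) and adds one water increment (2 µL) whenever the sensor
reading falls to one increment below the starting level and the single
shared syringe pump is free; exchanges on other wells block the pump and
skipped additions are logged. With a noiseless sensor the volume ripples
within about one increment; with 1-unit sensor quantization at a slope of
at least 2 units/µL the worst-case ripple stays within 4 µL. Threshold
calibration mirrors the hardware routine: 3 cycles of remove-50 µL /
measure / add-50 µL / measure, the median of 30 readings per plateau, and
the final thresholds as the means over cycles.

**Thermal control.** The medium is a first-order lumped plant
$\tau\,\dot T = -(T - T_{\mathrm{env}}) + u$ under PI control with
conditional-integration anti-windup. Gains, time constant and ambient
coupling are not physically identified; the defaults
($K_p = 20$, $K_i = 1$, $\tau = 30$ s, $T_{\mathrm{env}} = 22$ °C,
clamp $[-15, 40]$ K) are tuned so the closed loop reproduces the
behavioral envelope of the modeled hardware — 2 K setpoint steps settle
well within 5 min without overshoot, and bolus disturbances recover within
about a minute — and all are configurable. Medium boluses mix
instantaneously, $T \leftarrow (V_0 T + V T_{\mathrm{in}}) / (V_0 + V)$
(a 100 µL bolus 1.43 K colder than a 1000 µL well drops it by 130 mK),
with the well volume restored afterwards as in a remove-then-add exchange.
The RTD readout is quantized to a 32 mK least significant bit, taken as a
given constant; the quantized output never deviates from the true
temperature by more than half an LSB. The integrator is initialized at the
steady-state actuation for the initial setpoint so an undisturbed
simulation holds its setpoint exactly. First-order dynamics are an
explicit modeling choice; the real plant's order is unknown.

**Perfusion scheduling.** Protocols are ordered step lists (stock
addition, half-exchange, hold) over up to 4 wells sharing one pump;
pumped steps occupy the pump for volume/rate seconds, explicit start times
that overlap a busy pump raise a scheduling error, and the full state
timeline is returned for audit.

## The synthetic-data generator

`generateEventStream` emulates one 4-electrode network: trigger spikes are
a homogeneous Poisson process with a 10 ms refractory floor (so exclusion
rules have a nontrivial effect), each band emits a follower with its
fidelity at latency $\mathrm{base} + \mathrm{slope}\,(T - 37) +
\mathcal N(0, \mathrm{jitter}^2)$, and uncorrelated background spikes
(default 10 % of the trigger rate per electrode) stress the exclusion
logic. The temperature–latency coupling is linear with a configurable
slope (negative by default in test scenarios, mimicking the physiological
speed-up of transmission with warming); since no numeric magnitude is
established for real cultures, recovery tests assert direction and
self-consistency, not a particular slope. Drift scenarios multiply band
fidelity and shift band latency along user profiles.
`generateRecording` renders events into voltage: a biphasic template
(0.3 ms negative phase, smaller positive rebound, peak amplitude
configurable) is added at each ground-truth sample on seeded Gaussian
noise; SNR means peak amplitude over noise standard deviation. Everything
is byte-for-byte reproducible under a seed.

What the generator does *not* emulate: bursting and other non-Poisson
point-process structure, spike-waveform diversity and overlap, electrode
drift, stimulation artifacts, and correlated (1/f or line) noise. Passing
recovery tests therefore demonstrates that the analysis chain is correct
and well calibrated on its own model assumptions — not that those
assumptions hold for any particular culture.

## Problem sizes used in the test suite

The packaged tests run the detection-recovery property on 60 s × 4
electrodes at 17 361 Hz; the latency-trend recovery on 100 seeds of a
35 min, 7-level temperature staircase (250 mK steps, 5 min holds, 2 Hz
triggers); the drift experiment on 5 seeds of a 74 min stream with a
22 min initial phase; and the Mann–Kendall null calibration on 10 000
replicates of length-20 series. These sizes give the relevant Monte-Carlo
estimates comfortable margins while keeping the suite quick to run; hold
durations per temperature level are shorter than a wet-lab experiment
would use because only estimator consistency, not culture physiology,
constrains them.

## Worked example

```{r example, eval = FALSE}
spec <- NetworkSpec(triggerRateHz = 2,
                    bands = list(BandSpec("E2", baseLatencyMs = 4,
                                          jitterSdMs = 0.1, fidelity = 0.9,
                                          tempSlopeMsPerK = -0.2)))
stair <- temperatureStaircase(seq(35.5, 37, 0.25), holdS = 300)
es   <- generateEventStream(spec, 2100, temperature = stair, seed = 1)
rule <- TriggerRule("E1", exclusionMs = 10, segmentMs = 5)
st   <- buildSttrp(es$events, findValidTriggers(es$events, rule), "E1", 5)
bm   <- bandMetrics(st, Band("E2", 3.25, 4.8), timeBinS = 30)
mannKendall(bm$byTime$meanLatency)
```

## Known limitations

* The false-alarm behavior of the direct $X = 6$ rule is tied to the noise
  spectrum; colored noise would change the crossing rate.
* The Eq.-style overall-similarity reference includes the initial-phase
  bins themselves; their similarity values are biased upward.
* The thermal plant is first order with unidentified gains: simulated
  transients match the target envelopes, not measured step responses.
* The level sensor model assumes a single bright reflection; multiple
  reflections or ambient light are not modeled.
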