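---
title: "Simulating and evaluating virtual epileptic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating virtual epileptic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vepsim)
```

# The problem

Methods that estimate the epileptogenic zone (EZ) from stereo-EEG (SEEG)
recordings are hard to validate: for real patients there is no ground
truth. A virtual epileptic cohort sidesteps this by simulating whole
patients — brain anatomy, structural connectome, SEEG implantation, and
three kinds of brain activity (spontaneous seizures, stimulation-induced
seizures, interictal spikes) — from a *known* per-region
epileptogenicity map. The simulated recordings then serve as benchmark
data with ground truth attached.

`vepsim` implements the full chain: synthetic anatomy fixtures, the
Epileptor neural mass network, a stimulation-extended Epileptor, a
distance-based SEEG forward model, an electric-field model of bipolar
SEEG stimulation, BIDS-iEEG-style BrainVision output, and the
evaluation suite (seizure masks, four headline similarity metrics,
interictal spike statistics, permutation tests).

# The neural mass model

Each brain region carries a 6-variable Epileptor. Two fast variables
(`x1`, `y1`) produce fast ictal discharges; two intermediate variables
(`x2`, `y2`) produce spike-wave activity; a slow permittivity variable
`z` moves the node in and out of seizures; `g` low-pass filters `x1`.
The excitability parameter `x0` sets the regime of an isolated node:

* `x0` below about -2.062: stable down-state fixed point (interictal);
* between about -2.062 and -1.025: only the seizure limit cycle exists
  (spontaneous seizure-like events);
* above -1.025: an up-state resting point exists.

The -2.062 edge is located by `find_regime_boundary()`, a bisection on
noise-free simulations classified by trailing peak-to-peak amplitude of
`x1`. The -1.025 edge is the *existence* boundary of the up-branch
equilibrium: setting the up-branch root condition at `x1 = 0` gives
`c + Iext1 + 4 x0 = 0`, i.e. `x0 = -4.1/4 = -1.025` with defaults.
Numerically this equilibrium is born weakly unstable (trajectories keep
cycling down to roughly `x0 = -0.95`), so `find_up_state_boundary()`
bisects on equilibrium existence computed from the model's right-hand
side rather than on trajectory amplitude; this is the quantity the
regime map refers to.

Regions are coupled by the linear permittivity approximation
`K * sum_j C_ij (x1_j - x1_i)` acting in the `z` equation, with `C` the
symmetric, zero-diagonal, max-normalized connectome and `K` a global
scalar.

## Numerical integration

Explicit Euler (Euler-Maruyama with noise) in compiled code. The fast
subsystem's Jacobian eigenvalue at the down-state fixed point is about
-17/ms, so explicit Euler is only stable below roughly `dt = 0.12` ms;
the package default is `dt = 0.05` ms (`0.02` ms for stimulated runs,
whose post-crossing ictal transients are stiffer). A property test
checks that halving `dt` moves the regime boundary by less than 0.005.

Default initial conditions sit on the down-state branch
(`x1 = -1.6, y1 = -11.8, x2 = -0.18, y2 = 0.42, z = 3, g = -0.16`);
mid-range states such as the origin are strongly repelling and explicit
Euler diverges from them. Runs discard a burn-in. Spontaneous runs
start healthy regions at their computed down-state equilibrium
(`down_state_z()`) and epileptogenic regions with an exaggerated
post-ictal `z` (12), so recordings open on interictal baseline and the
first seizure begins a few seconds in, EZ before PZ. With the printed
slow rate `r = 0.00035`/ms the slow timescale is about 3 s, so seizure
cycles last around 10 s — much shorter than clinical seizures; relative
timing (onset order, propagation) is the meaningful output, absolute
durations are not.

# From EZ hypothesis to parameters

An `ez_hypothesis()` holds one normalized epileptogenicity value per
region in [0, 1]. Three affine maps translate it into model parameters:

* spontaneous: `x0 = -2.2 + 1.0 ev` (range [-2.2, -1.2]); regions above
  the critical excitability seize autonomously;
* stimulated: `x0 = -2.2 + 0.13 ev` (sub-critical range
  [-2.2, -2.07]) and seizure threshold `mthresh = 10 - 9.5 ev`
  (decreasing: epileptogenic regions have lower thresholds);
* interictal: `x0 = -3 + 0.2 ev` with `Iext1 = 6.0` and additive noise.

# Stimulated seizures

The stimulation-extended Epileptor makes `m` a state variable:
`m' = r2 (k |Istim| - 0.3 m)` integrates the rectified stimulus, and
when `m` crosses `mthresh` a Heaviside term shifts the effective
excitability by one unit in the `z` equation, pushing the node into the
seizure state. Crossing at equality counts as crossed (configurable).

The stimulus is a symmetric biphasic pulse train (zero net charge) at
the clinical frequency/amplitude/pulse width/duration, distributed over
regions by the normalized magnitude of the electric field of two
opposite point charges at the anode and cathode contacts (permittivity
1), evaluated at region surface vertices with vertex-area weighting and
max-normalized.

Two scale choices matter:

* `istim_scale` (default 0.05 model units per mA) fixes the free
  amplitude scale between clinical current and the phenomenological
  input. It was chosen analytically from the `m` equilibrium: under a
  50 Hz, 1 ms-pulse train the duty cycle is 10%, so
  `m_eq = k * duty * istim_scale * A / 0.3 = 0.333 A`; a weight-1
  region with the lowest threshold (0.5) then crosses near `A = 1.5`
  mA, placing the clinical amplitudes 0.5-1 mA below and 2-4 mA above
  threshold.
* Train duration: the model is intended to be operated with the
  `m`-crossing near the end of the train. If the Heaviside shift stays
  engaged for several seconds, `z` dives far below its normal band and
  the fast subsystem enters very stiff deep relaxation spikes. The
  synthetic reference protocol therefore uses a 1 s, 50 Hz train (the
  `m` time constant is 0.55 s), which yields bounded, SLE-like induced
  seizures that outlast the stimulus.

The stimulus waveform is also added to the two stimulating monopolar
contacts so the artifact is visible on the SEEG, as in clinical traces.

# Interictal spikes

With `Iext1 = 6`, the interictal map places epileptogenic regions at
the fold of the fast subsystem (their down-state `z` equals the fold
value 5.815 at `ev = 1`), so interictal spikes are noise-triggered
escapes of the *fast* subsystem across its fold. Noise on the
intermediate subsystem alone cannot reach `x1` on the down branch (the
`x2` term of `f1` only acts on the up branch), so `run_interictal()`
applies noise to `x1, y1` (default amplitude 0.05; this controls spike
rate and its epileptogenicity grading) as well as to `x2, y2` (trace
texture). At the defaults, an `ev = 1` region spikes at roughly 1-2 Hz
while healthy regions stay silent.

# Forward model and SEEG

The gain from region `j` to sensor `k` is
`g_jk = sum_i a_i / d_ik^2` over the region's surface vertices, with
`a_i` the one-third-rule vertex area. No orientation, no
normalization; simulated SEEG amplitudes are arbitrary units (scaled by
100 for display). Source activity is the standard Epileptor field proxy
`x2 - x1`. Monopolar contact signals are formed first, then the
clinical bipolar montage (adjacent same-shaft contacts).

# Evaluation suite

The envelope feature drives seizure detection. With the printed
equations, the intermediate subsystem's fixed point is unstable at the
down-state `z` of the spontaneous regime, so every region radiates a
continuous ~33 Hz background; the measured seizure/background contrast
in any high-pass band is only ~1.2x. What does discriminate is the
large, channel-specific slow shift of `x2 - x1` (about 1.5 model units)
between interictal and ictal states. `seizure_envelope()` therefore
references each channel to its own initial-baseline level, rectifies,
and smooths (0.5 Hz low-pass on a 100 Hz grid, with reflection padding
against filter edge transients). `flag_and_mark()` then normalizes each
channel's envelope by its own baseline amplitude and applies one global
ratio threshold (default 3) to all channels — the "same threshold for
every electrode" rule expressed in ratio units, which is robust to the
orders-of-magnitude gain differences across synthetic channels. An
absolute-threshold mode is available (`relative = FALSE`). Onset and
offset walk outward from the threshold crossing to the
baseline-departure level (half the threshold by default).

Masks (channel x time, 1 on [onset, offset] of flagged channels) are
compared after equal-bin nearest-neighbour resampling to 512 bins:

* mask Pearson correlation over all entries;
* binary overlap `|E & S| / |E|` (the formula variant; the
  identical-entries reading is available as `variant = "agreement"`);
* Jaccard coefficients of the seizure-onset (SO) and
  seizure-propagation (SP) channel sets, SO being channels whose onset
  falls in the first 10% (configurable 5-15%) of the seizure span.
  Empty-versus-empty sets score 1 (perfect agreement on absence).

Runs without any detected seizure have constant masks; against a
seizing reference they score correlation 0, and two seizure-free
recordings score 1 (`compare_runs()`); `mask_correlation()` itself
treats constant masks as an error. For stimulated runs the envelope
baseline comes from the pre-stimulus segment and the comparison is
restricted to the post-stimulus window.

Interictal spikes: band-pass 1-70 Hz (zero-phase, demeaned first so
filter edge transients on a DC offset are not mistaken for spikes),
robust noise level `sigma = median(|x|)/0.6745`, peaks above
`4 sigma`, chained merging of peaks closer than 250 ms, and a 25 uV
amplitude floor for empirical recordings only. Channel spike counts are
normalized to the IIS fraction vector and compared by Pearson
correlation.

The permutation test for group comparisons (H0: mean(A) <= mean(B))
pools both groups, reshuffles labels (200,000 times by default), and
reports the fraction of permuted mean differences at least as extreme
as observed; with 10 or fewer observations all splits are enumerated
exactly, and the Monte-Carlo path is tested against that enumeration.

# Synthetic anatomy: what it emulates and what it does not

`generate_parcellation_geometry()` renders each region as a small
triangulated sphere (radius 8 mm, surface ~8 cm^2) at random
well-separated centers in a brain-sized box; only vertex positions,
areas and region assignment enter the forward model, so folded cortical
sheets are not needed. `generate_connectome()` draws log-normal
(heavy-tailed) weights on a random edge subset, symmetrizes, zeroes the
diagonal, then max-normalizes. `generate_electrode_implantation()`
plants straight shafts of 10-18 contacts at 1.5 or 5 mm spacing aimed
*near* (not exactly at) target region centers — an exactly central pass
would give adjacent contacts equal gain and cancel in the bipolar
montage. `synthetic_patient()` clusters the remaining shafts around the
EZ, as clinical implantations do.

Passing tests on these fixtures demonstrate that the simulation and
evaluation chain behaves correctly and that personalized parameters are
recoverable *within the model's own world*. They do not show that the
model reproduces any particular patient's recordings: real SEEG has
folded cortical geometry, dipole orientation effects, background
rhythms and artifacts that the fixtures deliberately omit.

# Scales used by the tests

The test-suite scenarios are sized for quick, repeatable runs: 6-12
region patients, 60 s spontaneous / 20 s stimulated recordings,
1000 Hz output sampling, a 5-patient cohort with 3 randomized draws per
patient (15 randomized runs), 3 stimulation pairs per distance group,
and 20,000 permutation shuffles inside the cohort test (200,000 where
the Monte-Carlo/enumeration agreement itself is the property under
test). Larger cohorts use the same code paths.

# Known limitations

* Seizure durations are ~10 s (set by the printed `r`); only relative
  spatio-temporal structure is comparable to clinical data.
* The intermediate-subsystem background oscillation is always on in
  the spontaneous regime; seizure detection rests on slow level shifts.
* Sustained supra-threshold stimulation (Heaviside engaged for several
  seconds) drives the model into a stiff, physiologically dubious
  regime; the provided protocols avoid it and the integrator reports
  divergence with a step index if it is entered.
* Dipole orientation is ignored by the forward model; amplitudes are
  arbitrary units.
* Afterdischarges, semiology and resting-state background dynamics are
  out of scope.
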