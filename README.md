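# vepsim

Virtual epileptic patient cohorts in R: whole-brain network simulation
of spontaneous seizures, stimulation-induced seizures and interictal
spikes with the Epileptor neural mass model, projected to stereo-EEG
(SEEG) sensors, plus the evaluation suite needed to compare simulated
against reference recordings.

## Who this is for

Researchers developing or validating methods that localize the
epileptogenic zone (EZ) from SEEG. Real recordings come without ground
truth; a virtual cohort provides recordings *generated from a known
per-region epileptogenicity map*, so localization and source-analysis
methods can be scored against the parameters that produced the data.
Everything runs from synthetic anatomy fixtures — no patient data
required.

## The model

Each brain region is a 6-variable Epileptor

    x1' = y1 - f1(x1, x2) - z + Iext1
    y1' = c - d x1^2 - y1
    x2' = -y2 + x2 - x2^3 + Iext2 + 0.002 g - 0.3 (z - 3.5)
    y2' = (-y2 + f2(x2)) / tau
    z'  = r (4 (x1 - x0) - z + f3(z) + K sum_j C_ij (x1_j - x1_i))
    g'  = -0.01 (g - 0.1 x1)

with the usual piecewise `f1`, `f2`, `f3` and defaults `r = 0.00035`,
`tau = 10`, `Iext1 = 3.1`, `Iext2 = 0.45`, `a = 1`, `a2 = 6`, `b = 3`,
`c = 1`, `d = 5`. The excitability `x0` sets the regime: a down-state
fixed point below about -2.062, autonomous seizure-like oscillations up
to -1.025, an up-state resting point above. Regions couple through the
connectome `C` (symmetric, zero diagonal, max-normalized) via the
linear permittivity term scaled by `K`.

For stimulation, `m` becomes a state that integrates the rectified
stimulus input, `m' = r2 (k |Istim| - 0.3 m)`; crossing the per-region
seizure threshold engages a Heaviside shift of the effective
excitability, provoking a seizure. The stimulus is a zero-net-charge
biphasic pulse train spatially weighted by the point-source electric
field of the anode/cathode pair.

An EZ hypothesis (per-region epileptogenicity in [0, 1]) is translated
to parameters by three affine maps: `x0` in [-2.2, -1.2] for
spontaneous seizures, `x0` in [-2.2, -2.07] with thresholds in
[10, 0.5] for stimulated seizures, and `x0` in [-3, -2.8] with
`Iext1 = 6` plus noise for interictal spiking.

Sensor signals are `t(G) %*% (x2 - x1)` with gain
`g_jk = sum_i a_i / d_ik^2` over region surface vertices (one-third-rule
areas), then formed into the clinical bipolar montage. Cohorts are
written as BIDS-iEEG style trees with BrainVision recordings, TSV
sidecars and a TVB-style connectome ZIP.

## Worked example

```r
library(vepsim)

# one virtual patient: anatomy, connectome, SEEG implantation, EZ hypothesis
patient <- synthetic_patient(R = 12, ez_regions = 1, pz_regions = 2,
                             K = 0.1, seed = 7)

# a pseudo-empirical seizure and a matched re-simulation
emp <- run_spontaneous(patient, duration_s = 60, seed = 101, noise = 0.05)
sim <- run_spontaneous(patient, duration_s = 60, seed = 202)
rep <- compare_runs(sim$seeg, emp$seeg)
cat(sprintf("mask correlation: %.3f\n", rep$correlation))
cat(sprintf("binary overlap:   %.3f\n", rep$overlap))
cat(sprintf("SO Jaccard:       %.3f\n", rep$so_jaccard))
cat(sprintf("SP Jaccard:       %.3f\n", rep$sp_jaccard))

# the same comparison with another patient's hypothesis (randomized control)
other <- ez_hypothesis(as.numeric(seq_len(12) == 7), tag = "Randomized")
rc <- run_spontaneous(patient, seed = 303, hypothesis = other)
cat(sprintf("randomized-hypothesis correlation: %.3f\n",
            compare_runs(rc$seeg, emp$seeg)$correlation))
```

prints

```
mask correlation: 0.997
binary overlap:   0.998
SO Jaccard:       1.000
SP Jaccard:       1.000
randomized-hypothesis correlation: -0.542
```

A re-simulation with the patient's own EZ hypothesis reproduces the
spatio-temporal seizure mask of the pseudo-empirical recording almost
perfectly (correlation 0.997, all seizure-onset and propagation
channels recovered), while the same network simulated with a *wrong*
(randomized) hypothesis produces seizures in the wrong place and time
(correlation -0.542). That gap is what makes the cohort useful as a
benchmark: the personalized parameters are the information.

`write_bids(list(emp, sim), "cohort", bundles = setNames(list(patient),
patient$id))` lays the runs out as a BIDS-iEEG tree
(`sub-001/ses-01/ieeg/...` BrainVision triplets plus
`derivatives/sub-001/{struct,parameters}` with the connectome ZIP, gain
TSV, hypothesis TSV and per-run JSON sidecars sufficient to re-simulate
each run bit-identically).

A thin command-line front end is installed at `exec/vepsim`
(subcommands `fixtures`, `simulate`, `sweep`, `evaluate`).

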