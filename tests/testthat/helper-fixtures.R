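# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_patient <- function() {
  cached("tiny_patient", function()
    synthetic_patient(R = 6, n_shafts = 2, vertices_per_region = 12,
                      K = 0.1, seed = 5))
}

# the 10-region patient used by the stimulation scenarios: one ev = 1
# region near the stimulating pair, 5 mm contact spacing so adjacent-pair
# midpoints span all four distance groups
stim_patient <- function() {
  cached("stim_patient", function()
    synthetic_patient(R = 10, n_shafts = 6, spacing = 5, K = 0.1,
                      seed = 11))
}

reference_stimulus <- function(bundle, amplitude_ma = 2) {
  pp <- pick_stim_pair(bundle)
  stimulus_spec(pp$anode, pp$cathode, frequency_hz = 50,
                amplitude_ma = amplitude_ma, pulse_width_ms = 1,
                duration_s = 1, onset_s = 5)
}

# two-channel toy recording: channel 1 carries a 20 Hz burst, channel 2 is
# background noise; used by the evaluation tests
burst_recording <- function(fs = 200, dur_s = 60, burst = c(20, 30),
                            seed = 42) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  ch1 <- 0.05 * rnorm(length(t))
  on <- t >= burst[1] & t < burst[2]
  ch1[on] <- ch1[on] + 5 * sin(2 * pi * 20 * t[on])
  ch2 <- 0.05 * rnorm(length(t))
  ts <- rbind(A = ch1, B = ch2)
  list(ts = ts, fs = fs)
}
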