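#' Clinical stimulation specification
#'
#' Parameters of a bipolar SEEG stimulation: anode and cathode contact
#' labels, pulse frequency, current amplitude, single-phase pulse width,
#' train duration and onset. Clinical practice uses 1 Hz or 50 Hz, 0.5-5
#' mA, 0.5-3 ms pulse widths, and durations of seconds to tens of
#' seconds.
#'
#' @param anode,cathode Contact labels (e.g. "B2", "B3"); must differ.
#' @param frequency_hz Pulse repetition rate (> 0).
#' @param amplitude_ma Current amplitude in mA (> 0).
#' @param pulse_width_ms Width of each phase in ms.
#' @param duration_s Train duration in s.
#' @param onset_s Onset time into the simulation in s (default 0).
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(anode, cathode, frequency_hz, amplitude_ma,
                          pulse_width_ms, duration_s, onset_s = 0) {
  stopifnot(frequency_hz > 0, amplitude_ma > 0, pulse_width_ms > 0,
            duration_s > 0, onset_s >= 0)
  if (identical(anode, cathode)) stop("anode and cathode must differ")
  if (2 * pulse_width_ms * frequency_hz > 1000)
    stop("biphasic pulses do not fit the stimulation period")
  structure(list(anode = anode, cathode = cathode,
                 frequency_hz = frequency_hz, amplitude_ma = amplitude_ma,
                 pulse_width_ms = pulse_width_ms, duration_s = duration_s,
                 onset_s = onset_s),
            class = "stimulus_spec")
}

#' Biphasic pulse train
#'
#' Builds the symmetric biphasic stimulus waveform: at each pulse, a
#' positive phase of `pulse_width_ms` immediately followed by an equal
#' negative phase, repeated at `frequency_hz` for `duration_s`, scaled by
#' `amplitude_ma`. The symmetric shape carries zero net charge, as used
#' clinically to limit tissue damage.
#'
#' @param spec A [stimulus_spec()].
#' @param dt Sample step in ms.
#' @return Numeric waveform (one value per `dt`), covering exactly the
#'   train duration (onset padding is left to the caller).
#' @export
build_pulse_train <- function(spec, dt) {
  phase_n <- round(spec$pulse_width_ms / dt)
  if (phase_n < 1)
    stop("pulse width ", spec$pulse_width_ms,
         " ms is shorter than one sample at dt = ", dt, " ms")
  period_n <- round(1000 / spec$frequency_hz / dt)
  n_pulses <- floor(spec$duration_s * spec$frequency_hz)
  total_n <- round(spec$duration_s * 1000 / dt)
  w <- numeric(total_n)
  one <- c(rep(spec$amplitude_ma, phase_n), rep(-spec$amplitude_ma, phase_n))
  for (p in seq_len(n_pulses)) {
    i0 <- (p - 1) * period_n
    idx <- i0 + seq_along(one)
    idx <- idx[idx <= total_n]
    w[idx] <- one[seq_along(idx)]
  }
  w
}

#' Electric-field magnitude of a bipolar point-source pair
#'
#' Evaluates the magnitude of the electric field of two opposite point
#' charges (anode `+q`, cathode `-q`) at given locations:
#' `|E(r)| = | q/(4 pi eps) * ((r-r+)/|r-r+|^3 - (r-r-)/|r-r-|^3) |`.
#'
#' @param points M x 3 matrix of evaluation points (mm).
#' @param r_anode,r_cathode 3-vectors, charge locations (mm).
#' @param q Charge magnitude; by convention equal to the stimulation
#'   amplitude in mA (the absolute scale is arbitrary for the
#'   phenomenological model and is fixed downstream).
#' @param eps Permittivity of the medium (default 1).
#' @return Numeric vector of field magnitudes at each point; `Inf` where
#'   a point coincides with a charge.
#' @export
efield_magnitude <- function(points, r_anode, r_cathode, q = 1, eps = 1) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  dp <- sweep(points, 2, r_anode)
  dm <- sweep(points, 2, r_cathode)
  np <- sqrt(rowSums(dp^2))
  nm <- sqrt(rowSums(dm^2))
  E <- dp / np^3 - dm / nm^3
  mag <- q / (4 * pi * eps) * sqrt(rowSums(E^2))
  mag[np == 0 | nm == 0] <- Inf
  mag
}

#' Per-region stimulation field weights
#'
#' Evaluates the bipolar electric-field magnitude at every surface vertex
#' of each region, averages with vertex-area weights (mirroring the gain
#' matrix aggregation), and normalizes so the maximum region weight is 1.
#' Vertices coinciding with a charge are excluded from the average.
#'
#' @param electrodes A `vep_electrodes` object.
#' @param spec A [stimulus_spec()]; its anode/cathode labels select the
#'   charge locations.
#' @param mesh A `vep_mesh`.
#' @param eps Permittivity (default 1).
#' @return A `field_weights` object: `weights` (per-region, max 1),
#'   `raw` (unnormalized area-weighted mean field per region), `eps`.
#' @export
field_weights <- function(electrodes, spec, mesh, eps = 1) {
  pos <- contact_positions(electrodes)
  for (lab in c(spec$anode, spec$cathode))
    if (!lab %in% rownames(pos)) stop("unknown contact label: ", lab)
  ra <- pos[spec$anode, ]
  rc <- pos[spec$cathode, ]
  mag <- efield_magnitude(mesh$vertices, ra, rc, q = spec$amplitude_ma,
                          eps = eps)
  a <- mesh$vertex_area
  reg <- mesh$region_of_vertex
  ok <- is.finite(mag)
  if (!any(ok)) stop("all evaluation points coincide with a charge")
  num <- tapply(a[ok] * mag[ok], reg[ok], sum)
  den <- tapply(a[ok], reg[ok], sum)
  R <- max(reg)
  raw <- numeric(R)
  raw[as.integer(names(num))] <- num / den
  w <- if (max(raw) > 0) raw / max(raw) else raw
  structure(list(weights = w, raw = raw, eps = eps), class = "field_weights")
}

#' Stimulus input time course
#'
#' Distributes the stimulus waveform over regions as the outer product of
#' the normalized field weights with the pulse train: region `i` receives
#' `weights[i] * waveform[t]`.
#'
#' @param fw A [field_weights()] object (or plain weight vector).
#' @param waveform Numeric waveform from [build_pulse_train()].
#' @return R x T stimulus matrix.
#' @export
istim_timecourse <- function(fw, waveform) {
  w <- if (inherits(fw, "field_weights")) fw$weights else fw
  outer(w, waveform)
}
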