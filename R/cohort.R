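# Virtual-patient construction and the three simulation types, plus the
# stimulation sweeps and BIDS-iEEG style output.

#' Assemble a virtual patient bundle
#'
#' A bundle holds everything needed to simulate one patient: anatomy
#' (parcellation, mesh, connectome), implantation, gain matrix, bipolar
#' montage, one or more EZ hypotheses, and the global coupling.
#'
#' @param id Patient identifier, e.g. "sub-001".
#' @param parcellation,mesh,connectome,electrodes Structural members.
#' @param hypotheses Named list of [ez_hypothesis()] objects, keyed by
#'   tag (e.g. `VEPhypothesis`).
#' @param K Global coupling scalar (default 1).
#' @param seed Base seed for runs derived from this bundle.
#' @return A `patient_bundle` object (gain and montage are computed).
#' @export
patient_bundle <- function(id, parcellation, mesh, connectome, electrodes,
                           hypotheses, K = 1, seed = 1) {
  stopifnot(parcellation$R == nrow(connectome$weights))
  for (h in hypotheses) stopifnot(length(h$ev) == parcellation$R)
  gain <- compute_gain(mesh, electrodes,
                       region_labels = parcellation$region_labels)
  structure(list(id = id, parcellation = parcellation, mesh = mesh,
                 connectome = connectome, electrodes = electrodes,
                 gain = gain, montage = bipolar_montage(electrodes),
                 hypotheses = hypotheses, K = K, seed = seed),
            class = "patient_bundle")
}

#' Generate a synthetic virtual patient
#'
#' Builds a complete patient bundle from the synthetic fixture
#' generators: geometry, connectome, implantation with one shaft aimed
#' at each epileptogenic region (so that the implantation samples the EZ,
#' as clinical implantations are designed to), and a sparse EZ/PZ/HZ
#' hypothesis.
#'
#' @param id Patient identifier.
#' @param R Number of regions (default 12).
#' @param ez_regions Indices of epileptogenic regions (ev = 1);
#'   default region 1.
#' @param pz_regions Indices of propagation regions (ev = 0.5); default
#'   region 2.
#' @param n_shafts Number of shafts (default 4); the first shafts target
#'   the EZ and PZ regions, remaining shafts random regions.
#' @param density Connectome density (default 0.4).
#' @param K Global coupling (default 0.5).
#' @param vertices_per_region Mesh resolution (default 20).
#' @param spacing Optional fixed contact spacing in mm (see
#'   [generate_electrode_implantation()]).
#' @param seed Integer seed.
#' @return A `patient_bundle`.
#' @export
synthetic_patient <- function(id = "sub-001", R = 12, ez_regions = 1,
                              pz_regions = 2, n_shafts = 4, density = 0.4,
                              K = 0.5, vertices_per_region = 20,
                              spacing = NULL, seed = 1) {
  geo <- generate_parcellation_geometry(R, vertices_per_region, seed = seed)
  con <- generate_connectome(R, density, seed = seed + 1)
  targets <- c(ez_regions, pz_regions)
  if (n_shafts > length(targets)) {
    # remaining shafts sample the neighbourhood of the EZ, as clinical
    # implantations cluster around the suspected focus
    d <- sqrt(colSums((t(geo$parcellation$centers) -
                       geo$parcellation$centers[ez_regions[1], ])^2))
    near <- setdiff(order(d), targets)
    targets <- c(targets, near[seq_len(n_shafts - length(targets))])
  }
  elec <- generate_electrode_implantation(geo$parcellation, n_shafts,
                                          seed = seed + 3,
                                          target_regions = targets,
                                          spacing = spacing)
  ev <- numeric(R)
  ev[pz_regions] <- 0.5
  ev[ez_regions] <- 1
  hyp <- ez_hypothesis(ev, region_labels = geo$parcellation$region_labels,
                       tag = "VEPhypothesis")
  patient_bundle(id, geo$parcellation, geo$mesh, con, elec,
                 hypotheses = list(VEPhypothesis = hyp), K = K, seed = seed)
}

#' Generate a synthetic cohort
#'
#' A list of synthetic patients with distinct seeds and distinct
#' epileptogenic regions, mimicking a cohort in which each patient's EZ
#' hypothesis is informative about their own seizures but not about
#' other patients'.
#'
#' @param n_patients Number of patients (default 5).
#' @param seed Master seed; per-patient seeds are derived as
#'   `seed * 100 + patient`.
#' @param R Regions per patient (default 12).
#' @param ... Passed to [synthetic_patient()].
#' @return List of `patient_bundle`s.
#' @export
synthetic_cohort <- function(n_patients = 5, seed = 1, R = 12, ...) {
  lapply(seq_len(n_patients), function(i) {
    ez <- ((i - 1) %% R) + 1
    pz <- (ez %% R) + 1
    synthetic_patient(id = sprintf("sub-%03d", i), R = R,
                      ez_regions = ez, pz_regions = pz,
                      seed = seed * 100 + i, ...)
  })
}

source_to_seeg <- function(bundle, out, scale = 100) {
  src <- scale * (out$x2 - out$x1)   # standard Epileptor field proxy
  mono <- project_to_sensors(bundle$gain, src)
  rownames(mono) <- colnames(bundle$gain)
  list(mono = mono, bip = apply_montage(mono, bundle$montage))
}

run_record <- function(bundle, session, tag, out, seeg, fs, seed, extra = list()) {
  rec <- c(list(patient = bundle$id, session = session,
                hypothesis_tag = tag,
                seeg = list(ts = seeg$bip, fs = fs),
                mono = seeg$mono,
                source = list(x1 = out$x1, x2 = out$x2, z = out$z,
                              time = out$time, dt = out$dt),
                seed = seed),
           extra)
  class(rec) <- "run_record"
  rec
}

#' Simulate a spontaneous seizure run
#'
#' Maps the chosen EZ hypothesis to excitabilities in `[-2.2, -1.2]`,
#' integrates the Epileptor network (discarding a burn-in), projects the
#' source proxy `x2 - x1` through the gain matrix and forms bipolar SEEG
#' channels.
#'
#' @param bundle A `patient_bundle`.
#' @param hypothesis_tag Which hypothesis to use (default first).
#' @param duration_s Recorded duration in s (default 60).
#' @param seed Run seed (default derived from the bundle seed).
#' @param noise Noise amplitude on the intermediate population (default
#'   0.01, a light roughening of the traces).
#' @param dt Integration step in ms (default 0.05).
#' @param fs Output sampling rate in Hz (default 1000; must divide
#'   1000/dt).
#' @param hypothesis Optional explicit [ez_hypothesis()] overriding the
#'   tagged one (used for randomized-cohort runs).
#' @return A `run_record` with `seeg` (bipolar ts + fs), `mono`, `source`
#'   and parameter metadata.
#' @export
run_spontaneous <- function(bundle, hypothesis_tag = NULL, duration_s = 60,
                            seed = NULL, noise = 0.01, dt = 0.05, fs = 1000,
                            hypothesis = NULL) {
  if (is.null(hypothesis_tag)) hypothesis_tag <- names(bundle$hypotheses)[1]
  hyp <- if (!is.null(hypothesis)) hypothesis
         else bundle$hypotheses[[hypothesis_tag]]
  if (is.null(hyp)) stop("unknown hypothesis tag: ", hypothesis_tag)
  if (is.null(seed)) seed <- bundle$seed * 10L + 1L
  params <- epileptor_params(x0 = map_spontaneous(hyp))
  spec <- network_spec(bundle$connectome, K = bundle$K, params = params,
                       noise = noise, dt = dt)
  rec_every <- as.integer(round(1000 / (fs * dt)))
  # healthy regions start at their down-state equilibrium (steady
  # background from the first sample); regions in the oscillatory regime
  # start with an elevated (post-ictal) slow variable, so their first
  # seizure begins a few seconds into the recording, as in per-seizure
  # clinical recordings that open on interictal baseline
  y0 <- initial_state(spec)
  z0 <- vapply(params$x0, function(x0i) {
    if (x0i <= -2.07) down_state_z(x0i, params) else 12
  }, numeric(1))
  y0[, 5] <- z0
  out <- integrate_network(spec, duration_s * 1000, y0 = y0,
                           burn_in_ms = 500,
                           record_every = rec_every, seed = seed)
  seeg <- source_to_seeg(bundle, out)
  run_record(bundle, "ses-01", if (!is.null(hypothesis)) hyp$tag
                               else hypothesis_tag,
             out, seeg, out$fs, seed,
             extra = list(parameters = list(
               mode = "spontaneous", x0 = params$x0, K = bundle$K,
               noise = noise, dt = dt, duration_s = duration_s)))
}

#' Simulate a stimulated run
#'
#' Maps the hypothesis to the sub-critical excitability range and the
#' seizure-threshold range, builds the biphasic pulse train and its
#' spatial field weights, and integrates the stimulation-extended
#' Epileptor. The stimulus waveform is also added to the two stimulating
#' contacts so the artifact is visible on the SEEG, as in clinical
#' recordings.
#'
#' @param bundle A `patient_bundle`.
#' @param stimulus A [stimulus_spec()].
#' @param hypothesis_tag,hypothesis As in [run_spontaneous()].
#' @param duration_s Recorded duration (default stimulus onset + stimulus
#'   duration + 20 s of follow-up).
#' @param seed Run seed.
#' @param istim_scale Stimulus input scale in model units per mA
#'   (default 0.05); fixes the free amplitude scale between the clinical
#'   current and the phenomenological model input. With the default,
#'   a weight-1 region under 50 Hz / 1 ms pulses reaches the
#'   lowest seizure threshold (0.5) at about 1.5 mA.
#' @param artifact_gain Amplitude of the stimulus artifact added to the
#'   stimulating contacts (default 50).
#' @param noise,dt,fs As in [run_spontaneous()] (noise default 0; dt
#'   default 0.02 ms: the post-crossing ictal regime drives the fast
#'   subsystem into deep relaxation spikes whose local Jacobian exceeds
#'   the Euler stability bound at 0.05 ms).
#' @return A `run_record`; `induced` flags a post-stimulus seizure, and
#'   `m_crossed` whether any region crossed its threshold.
#' @export
run_stimulated <- function(bundle, stimulus, hypothesis_tag = NULL,
                           duration_s = NULL, seed = NULL,
                           istim_scale = 0.05, artifact_gain = 50,
                           noise = 0, dt = 0.02, fs = 1000,
                           hypothesis = NULL) {
  if (is.null(hypothesis_tag)) hypothesis_tag <- names(bundle$hypotheses)[1]
  hyp <- if (!is.null(hypothesis)) hypothesis
         else bundle$hypotheses[[hypothesis_tag]]
  if (is.null(hyp)) stop("unknown hypothesis tag: ", hypothesis_tag)
  if (is.null(seed)) seed <- bundle$seed * 10L + 2L
  if (is.null(duration_s))
    duration_s <- stimulus$onset_s + stimulus$duration_s + 20
  maps <- map_stimulated(hyp)
  params <- epileptor_params(x0 = maps$x0)
  stim <- stim_params(mthresh = maps$mthresh)
  spec <- network_spec(bundle$connectome, K = bundle$K, params = params,
                       stim = stim, noise = noise, dt = dt)
  fw <- field_weights(bundle$electrodes, stimulus, bundle$mesh)
  wave <- build_pulse_train(stimulus, dt) * istim_scale
  n_steps <- as.integer(round(duration_s * 1000 / dt))
  onset_n <- as.integer(round(stimulus$onset_s * 1000 / dt))
  full_wave <- numeric(n_steps)
  idx <- onset_n + seq_along(wave)
  idx <- idx[idx <= n_steps]
  full_wave[idx] <- wave[seq_along(idx)]
  istim <- istim_timecourse(fw, full_wave)
  rec_every <- as.integer(round(1000 / (fs * dt)))
  out <- integrate_network(spec, duration_s * 1000, istim = istim,
                           burn_in_ms = 10e3, record_every = rec_every,
                           seed = seed)
  seeg <- source_to_seeg(bundle, out)
  # stimulus artifact on the stimulating contacts (monopolar), then re-montage
  art_idx <- pmin(n_steps, (seq_len(ncol(seeg$mono)) - 1L) * rec_every + 1L)
  art <- full_wave[art_idx] / istim_scale
  seeg$mono[stimulus$anode, ] <- seeg$mono[stimulus$anode, ] +
    artifact_gain * art
  seeg$mono[stimulus$cathode, ] <- seeg$mono[stimulus$cathode, ] -
    artifact_gain * art
  seeg$bip <- apply_montage(seeg$mono, bundle$montage)
  offset_s <- stimulus$onset_s + stimulus$duration_s
  post <- out$time > offset_s * 1000
  induced <- any(out$x1[, post] > 0)
  m_crossed <- any(out$m > matrix(stim$mthresh, nrow(out$m), ncol(out$m)))
  run_record(bundle, "ses-02", if (!is.null(hypothesis)) hyp$tag
                               else hypothesis_tag,
             out, seeg, out$fs, seed,
             extra = list(stimulus = stimulus, field_weights = fw,
                          induced = induced, m_crossed = m_crossed,
                          parameters = list(
                            mode = "stimulated", x0 = maps$x0,
                            mthresh = maps$mthresh, K = bundle$K,
                            istim_scale = istim_scale, noise = noise,
                            dt = dt, duration_s = duration_s)))
}

#' Simulate an interictal run
#'
#' Maps the hypothesis to the interictal excitability range `[-3, -2.8]`
#' with raised drive `Iext1 = 6` and additive noise, so regions close to
#' the seizure threshold emit irregular interictal spikes. Per-channel
#' spike counts are detected on the bipolar SEEG.
#'
#' @param bundle A `patient_bundle`.
#' @param hypothesis_tag,hypothesis As in [run_spontaneous()].
#' @param duration_s Recorded duration (default 60).
#' @param seed Run seed.
#' @param noise Noise amplitude on the intermediate population (default
#'   0.05).
#' @param noise_x1 Noise amplitude on the fast population (default 0.05).
#'   Interictal spikes are noise-triggered escapes of the fast subsystem
#'   across its fold, so this is the amplitude that controls spike rate.
#' @param dt,fs As in [run_spontaneous()].
#' @return A `run_record` with `spike_counts` (per channel) and
#'   `iis` (normalized, `NULL` when no spikes were detected).
#' @export
run_interictal <- function(bundle, hypothesis_tag = NULL, duration_s = 60,
                           seed = NULL, noise = 0.05, noise_x1 = 0.05,
                           dt = 0.05, fs = 1000, hypothesis = NULL) {
  if (is.null(hypothesis_tag)) hypothesis_tag <- names(bundle$hypotheses)[1]
  hyp <- if (!is.null(hypothesis)) hypothesis
         else bundle$hypotheses[[hypothesis_tag]]
  if (is.null(hyp)) stop("unknown hypothesis tag: ", hypothesis_tag)
  if (is.null(seed)) seed <- bundle$seed * 10L + 3L
  maps <- map_interictal(hyp, noise = noise)
  params <- epileptor_params(x0 = maps$x0, Iext1 = maps$Iext1)
  spec <- network_spec(bundle$connectome, K = bundle$K, params = params,
                       noise = c(noise_x1, noise_x1, maps$noise, maps$noise,
                                 0, 0), dt = dt)
  rec_every <- as.integer(round(1000 / (fs * dt)))
  # start every region at its interictal equilibrium: the recording opens
  # in a steady interictal state and all activity is noise-driven
  y0 <- initial_state(spec)
  y0[, 5] <- vapply(params$x0, down_state_z, numeric(1), params = params)
  out <- integrate_network(spec, duration_s * 1000, y0 = y0,
                           burn_in_ms = 10e3,
                           record_every = rec_every, seed = seed)
  seeg <- source_to_seeg(bundle, out)
  counts <- vapply(rownames(seeg$bip), function(ch)
    length(detect_spikes(seeg$bip[ch, ], out$fs)), integer(1))
  iis <- if (sum(counts) > 0) iis_count(counts) else NULL
  run_record(bundle, "ses-03", if (!is.null(hypothesis)) hyp$tag
                               else hypothesis_tag,
             out, seeg, out$fs, seed,
             extra = list(spike_counts = counts, iis = iis,
                          parameters = list(
                            mode = "interictal", x0 = maps$x0,
                            Iext1 = maps$Iext1, K = bundle$K,
                            noise = maps$noise, dt = dt,
                            duration_s = duration_s)))
}

#' Pick the adjacent contact pair closest to a region
#'
#' Returns the adjacent same-shaft contact pair whose midpoint is
#' nearest the given region's center — the natural choice of
#' stimulating pair for targeting that region.
#'
#' @param bundle A `patient_bundle`.
#' @param region Region index (default: the region with maximal
#'   epileptogenicity in the first hypothesis).
#' @return List with `anode`, `cathode`, `channel`, `distance_mm`.
#' @export
pick_stim_pair <- function(bundle, region = NULL) {
  if (is.null(region))
    region <- which.max(bundle$hypotheses[[1]]$ev)
  pairs <- adjacent_pairs(bundle)
  cen <- bundle$parcellation$centers[region, ]
  d <- sqrt((pairs$mid_x - cen[1])^2 + (pairs$mid_y - cen[2])^2 +
            (pairs$mid_z - cen[3])^2)
  i <- which.min(d)
  list(anode = pairs$positive[i], cathode = pairs$negative[i],
       channel = pairs$channel[i], distance_mm = d[i])
}

adjacent_pairs <- function(bundle) {
  mon <- bundle$montage
  pos <- contact_positions(bundle$electrodes)
  mid <- (pos[mon$positive, , drop = FALSE] +
          pos[mon$negative, , drop = FALSE]) / 2
  data.frame(mon, mid_x = mid[, 1], mid_y = mid[, 2], mid_z = mid[, 3],
             stringsAsFactors = FALSE)
}

#' Stimulation-location sweep
#'
#' Re-runs the reference stimulation from electrode pairs at increasing
#' distance from the reference pair. Adjacent same-shaft contact pairs
#' are grouped by the distance (cm) of their midpoint from the reference
#' pair's midpoint: Dist1 (<= 1 cm), Dist2 ((1, 2]), Dist3 ((2, 3]),
#' Dist4 (> 3 cm); the reference pair itself is excluded. Up to
#' `n_per_group` pairs are sampled per group; all other parameters stay
#' fixed.
#'
#' @param bundle A `patient_bundle`.
#' @param reference A [stimulus_spec()] (the empirical-like stimulation).
#' @param n_per_group Pairs sampled per group (default 10).
#' @param seed Sampling/run seed.
#' @param ... Passed to [run_stimulated()].
#' @return List of `run_record`s, each with `dist_group` and
#'   `distance_cm`; empty groups produce a warning and contribute none.
#' @export
sweep_stimulation_location <- function(bundle, reference, n_per_group = 10,
                                       seed = 1, ...) {
  pairs <- adjacent_pairs(bundle)
  ref_idx <- which(pairs$positive == reference$anode &
                   pairs$negative == reference$cathode)
  if (length(ref_idx) == 0)
    stop("reference pair not found among adjacent same-shaft pairs")
  ref_mid <- as.numeric(pairs[ref_idx, c("mid_x", "mid_y", "mid_z")])
  d_cm <- sqrt((pairs$mid_x - ref_mid[1])^2 + (pairs$mid_y - ref_mid[2])^2 +
               (pairs$mid_z - ref_mid[3])^2) / 10
  grp <- cut(d_cm, c(-Inf, 1, 2, 3, Inf),
             labels = c("Dist1", "Dist2", "Dist3", "Dist4"))
  keep <- setdiff(seq_len(nrow(pairs)), ref_idx)
  set.seed(seed)
  records <- list()
  for (g in levels(grp)) {
    cand <- keep[grp[keep] == g]
    if (length(cand) == 0) {
      warning("no candidate pairs in group ", g)
      next
    }
    take <- if (length(cand) > n_per_group)
      sample(cand, n_per_group) else cand
    for (i in take) {
      sp <- reference
      sp$anode <- pairs$positive[i]
      sp$cathode <- pairs$negative[i]
      rec <- run_stimulated(bundle, sp, seed = seed, ...)
      rec$dist_group <- g
      rec$distance_cm <- d_cm[i]
      records[[length(records) + 1]] <- rec
    }
  }
  records
}

#' Stimulation-amplitude sweep
#'
#' Re-runs the reference stimulation at each amplitude (default the
#' clinically common set 0.5, 1, 3 and 4 mA around the empirical
#' 1.8-2.2 mA), all other parameters fixed.
#'
#' @param bundle A `patient_bundle`.
#' @param reference A [stimulus_spec()].
#' @param amplitudes Amplitudes in mA (default `c(0.5, 1, 3, 4)`).
#' @param seed Run seed (same for every amplitude).
#' @param ... Passed to [run_stimulated()].
#' @return List of `run_record`s with `$stimulus$amplitude_ma` set.
#' @export
sweep_stimulation_amplitude <- function(bundle, reference,
                                        amplitudes = c(0.5, 1, 3, 4),
                                        seed = 1, ...) {
  stopifnot(all(amplitudes > 0))
  lapply(amplitudes, function(a) {
    sp <- reference
    sp$amplitude_ma <- a
    run_stimulated(bundle, sp, seed = seed, ...)
  })
}

#' Write run records as a BIDS-iEEG style cohort tree
#'
#' Lays out `sub-XXX/ses-0N/ieeg/` BrainVision triplets with channel and
#' electrode TSVs, and `derivatives/sub-XXX/{struct,parameters}` with the
#' connectome bundle, gain matrix, hypothesis TSV, a JSON parameter
#' sidecar per run (sufficient to re-simulate the run bit-identically)
#' and the source-level time series (float32 + JSON sidecar). Seizure
#' onset/offset from the envelope detector and the stimulus window are
#' stored as BrainVision markers.
#'
#' @param records List of `run_record`s (may span patients/sessions).
#' @param root Output directory.
#' @param bundles Named list of `patient_bundle`s keyed by patient id
#'   (for the derivatives tree); optional.
#' @return Data frame listing the written runs (patient, session, tag,
#'   run, vhdr path), invisibly.
#' @export
write_bids <- function(records, root, bundles = NULL) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counter <- new.env(parent = emptyenv())
  written <- NULL
  for (rec in records) {
    key <- paste(rec$patient, rec$session, rec$hypothesis_tag, sep = "|")
    n <- (if (is.null(counter[[key]])) 0L else counter[[key]]) + 1L
    counter[[key]] <- n
    run <- sprintf("run-%02d", n)
    ieeg_dir <- file.path(root, rec$patient, rec$session, "ieeg")
    dir.create(ieeg_dir, recursive = TRUE, showWarnings = FALSE)
    base <- sprintf("%s_%s_task-simulation_acq-%s_%s_ieeg",
                    rec$patient, rec$session, rec$hypothesis_tag, run)
    basepath <- file.path(ieeg_dir, base)
    if (file.exists(paste0(basepath, ".vhdr")))
      stop("run index collision at ", basepath)
    markers <- seizure_markers(rec)
    write_brainvision(rec$seeg$ts, rec$seeg$fs, basepath, markers)
    chan <- data.frame(name = rownames(rec$seeg$ts), type = "SEEG",
                       units = "arbitrary", sampling_frequency = rec$seeg$fs)
    write.table(chan, file.path(ieeg_dir, paste0(base, "_channels.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    der <- file.path(root, "derivatives", rec$patient)
    par_dir <- file.path(der, "parameters")
    dir.create(par_dir, recursive = TRUE, showWarnings = FALSE)
    side <- rec$parameters
    side$seed <- rec$seed
    side$patient <- rec$patient
    side$hypothesis_tag <- rec$hypothesis_tag
    if (!is.null(rec$stimulus)) side$stimulus <- unclass(rec$stimulus)
    jsonlite::write_json(side,
                         file.path(par_dir, paste0(base, "_parameters.json")),
                         auto_unbox = TRUE, digits = NA)
    write_source_series(rec, file.path(par_dir, paste0(base, "_source")))
    if (!is.null(bundles) && rec$patient %in% names(bundles)) {
      b <- bundles[[rec$patient]]
      struct_dir <- file.path(der, "struct")
      dir.create(struct_dir, recursive = TRUE, showWarnings = FALSE)
      wzip <- file.path(struct_dir, paste0(rec$patient, "_connectome.zip"))
      if (!file.exists(wzip))
        write_connectome_bundle(b$connectome, b$parcellation, wzip)
      write_gain_tsv(b$gain, file.path(struct_dir,
                                       paste0(rec$patient, "_gain.tsv")))
      write_electrodes_tsv(b$electrodes,
                           file.path(ieeg_dir,
                                     paste0(rec$patient, "_electrodes.tsv")))
      hyp <- b$hypotheses[[rec$hypothesis_tag]]
      if (!is.null(hyp))
        write_hypothesis_tsv(hyp,
                             file.path(par_dir,
                                       paste0(rec$patient, "_",
                                              rec$hypothesis_tag, ".tsv")),
                             region_labels = b$parcellation$region_labels)
    }
    written <- rbind(written,
                     data.frame(patient = rec$patient, session = rec$session,
                                tag = rec$hypothesis_tag, run = run,
                                vhdr = paste0(basepath, ".vhdr"),
                                stringsAsFactors = FALSE))
  }
  invisible(written)
}

seizure_markers <- function(rec) {
  markers <- NULL
  env <- try(seizure_envelope(rec$seeg$ts, rec$seeg$fs), silent = TRUE)
  if (!inherits(env, "try-error")) {
    marks <- flag_and_mark(env)
    if (any(marks$flag)) {
      on <- min(marks$onset, na.rm = TRUE)
      off <- max(marks$offset, na.rm = TRUE)
      markers <- rbind(markers, data.frame(
        type = "Seizure",
        description = c("onset", "offset"),
        position = pmax(1L, as.integer(round(c(on, off) * rec$seeg$fs)) + 1L),
        length = 1L))
    }
  }
  if (!is.null(rec$stimulus)) {
    s <- rec$stimulus
    markers <- rbind(markers, data.frame(
      type = "Stimulus",
      description = c("on", "off"),
      position = as.integer(round(c(s$onset_s, s$onset_s + s$duration_s) *
                                  rec$seeg$fs)) + 1L,
      length = 1L))
  }
  markers
}

write_source_series <- function(rec, basepath) {
  vars <- intersect(c("x1", "x2", "z"), names(rec$source))
  con <- file(paste0(basepath, ".f32"), "wb")
  for (v in vars) writeBin(as.vector(rec$source[[v]]), con, size = 4,
                           endian = "little")
  close(con)
  jsonlite::write_json(
    list(variables = vars, regions = nrow(rec$source$x1),
         samples = ncol(rec$source$x1), dt_ms = rec$source$dt,
         layout = "region-major per variable, float32 little-endian"),
    paste0(basepath, ".json"), auto_unbox = TRUE)
  invisible(basepath)
}
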