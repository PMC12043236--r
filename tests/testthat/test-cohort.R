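test_that("spontaneous runs are reproducible and shaped by the montage", {
  b <- tiny_patient()
  r1 <- run_spontaneous(b, duration_s = 10, seed = 21)
  r2 <- run_spontaneous(b, duration_s = 10, seed = 21)
  expect_identical(r1$seeg$ts, r2$seeg$ts)
  r3 <- run_spontaneous(b, duration_s = 10, seed = 22)
  expect_false(identical(r1$seeg$ts, r3$seeg$ts))

  expect_equal(nrow(r1$seeg$ts), nrow(b$montage))
  expect_equal(r1$seeg$fs, 1000)
  expect_equal(ncol(r1$seeg$ts), 10 * 1000 + 1)
  expect_equal(r1$session, "ses-01")
})

test_that("an all-healthy hypothesis produces no seizure channels", {
  b <- tiny_patient()
  hz <- ez_hypothesis(rep(0, b$parcellation$R))
  rec <- run_spontaneous(b, duration_s = 20, seed = 31, hypothesis = hz,
                         noise = 0)
  env <- seizure_envelope(rec$seeg$ts, rec$seeg$fs)
  expect_false(any(flag_and_mark(env)$flag))

  # whereas the patient's own (EZ-bearing) hypothesis does seize
  rec2 <- run_spontaneous(b, duration_s = 20, seed = 31)
  env2 <- seizure_envelope(rec2$seeg$ts, rec2$seeg$fs)
  expect_true(any(flag_and_mark(env2)$flag))
})

test_that("stimulated runs confine the stimulus input to its window", {
  b <- stim_patient()
  sp <- reference_stimulus(b)
  rec <- run_stimulated(b, sp, seed = 72, duration_s = 10)
  expect_equal(rec$session, "ses-02")
  expect_true(rec$m_crossed)
  expect_true(rec$induced)
  # before stimulus onset (5 s) the sub-critical network sits at rest
  pre <- rec$source$time < 4900
  expect_true(all(abs(rec$source$x1[, pre] - rec$source$x1[, 1]) < 0.2))
  # the stimulus artifact (difference against an artifact-free run) is
  # confined to the stimulation window and to the stimulating contacts
  rec0 <- run_stimulated(b, sp, seed = 72, duration_s = 10,
                         artifact_gain = 0)
  dart <- rec$seeg$ts - rec0$seeg$ts
  t_s <- rec$source$time / 1000
  during <- t_s >= sp$onset_s & t_s <= sp$onset_s + sp$duration_s
  expect_gt(max(abs(dart[, during])), 0)
  expect_equal(max(abs(dart[, !during])), 0)
  touched <- rownames(dart)[rowSums(abs(dart)) > 0]
  pair_chans <- b$montage$channel[b$montage$positive %in% c(sp$anode, sp$cathode) |
                                  b$montage$negative %in% c(sp$anode, sp$cathode)]
  expect_true(all(touched %in% pair_chans))
})

test_that("interictal spikes concentrate on epileptogenic-zone channels", {
  b <- tiny_patient()
  rec <- run_interictal(b, duration_s = 30, seed = 33)
  expect_equal(rec$session, "ses-03")
  expect_gt(sum(rec$spike_counts), 0)
  expect_equal(sum(rec$iis), 1)

  # spike profile correlates better with the patient's own ev-weighted
  # gain profile than with a shuffled one
  ev <- b$hypotheses[[1]]$ev
  mon <- b$montage
  bg <- sapply(seq_len(b$parcellation$R), function(r)
    abs(b$gain[r, mon$positive] - b$gain[r, mon$negative]))
  prof <- as.vector(bg %*% ev)
  own <- cor(rec$spike_counts, prof)
  set.seed(1)
  shuffled <- cor(rec$spike_counts, sample(prof))
  expect_gt(own, shuffled)

  # a zero-excitability, noise-free network emits no spikes
  hz <- ez_hypothesis(rep(0, b$parcellation$R))
  rec0 <- run_interictal(b, duration_s = 10, seed = 34, hypothesis = hz,
                         noise = 0, noise_x1 = 0)
  expect_equal(sum(rec0$spike_counts), 0)
  expect_null(rec0$iis)
})

test_that("amplitude sweeps reuse every parameter except the amplitude", {
  b <- stim_patient()
  sp <- reference_stimulus(b)
  recs <- sweep_stimulation_amplitude(b, sp, amplitudes = c(2, sp$amplitude_ma),
                                      seed = 72, duration_s = 10)
  expect_length(recs, 2)
  # the reference amplitude reproduces the reference run bit-identically
  direct <- run_stimulated(b, sp, seed = 72, duration_s = 10)
  expect_identical(recs[[2]]$seeg$ts, direct$seeg$ts)
  expect_identical(recs[[1]]$seeg$ts, recs[[2]]$seeg$ts)  # same amplitude twice
})

test_that("location sweeps group pairs by distance and exclude the reference", {
  b <- stim_patient()
  sp <- reference_stimulus(b)
  recs <- suppressWarnings(
    sweep_stimulation_location(b, sp, n_per_group = 2, seed = 5,
                               duration_s = 8))
  expect_true(length(recs) >= 4)
  for (rec in recs) {
    expect_false(rec$stimulus$anode == sp$anode &&
                 rec$stimulus$cathode == sp$cathode)
    d <- rec$distance_cm
    g <- rec$dist_group
    expect_equal(as.character(cut(d, c(-Inf, 1, 2, 3, Inf),
                                  labels = paste0("Dist", 1:4))), g)
  }
  expect_error(sweep_stimulation_location(
    b, stimulus_spec("A1", "B1", 50, 1, 1, 1), 2),
    "reference pair")
})

test_that("the BIDS tree holds round-trippable runs with unique indices", {
  b <- tiny_patient()
  rec <- run_spontaneous(b, duration_s = 5, seed = 21)
  rec2 <- run_interictal(b, duration_s = 5, seed = 22)
  root <- file.path(tempdir(), paste0("cohort-", as.integer(runif(1, 1e6, 9e6))))
  written <- write_bids(list(rec, rec2, rec), root,
                        bundles = stats::setNames(list(b), b$id))
  expect_equal(written$run, c("run-01", "run-01", "run-02"))
  expect_equal(written$session, c("ses-01", "ses-03", "ses-01"))

  rb <- read_brainvision(written$vhdr[1])
  f32 <- matrix(readBin(writeBin(as.vector(rec$seeg$ts), raw(), size = 4,
                                 endian = "little"),
                        "numeric", n = length(rec$seeg$ts), size = 4,
                        endian = "little"),
                nrow(rec$seeg$ts))
  expect_true(all(rb$ts == f32))   # float32-exact sample recovery
  expect_equal(rb$fs, rec$seeg$fs)
  expect_identical(rownames(rb$ts), rownames(rec$seeg$ts))

  # derivatives: connectome bundle, gain, hypothesis, parameter sidecar
  der <- file.path(root, "derivatives", b$id)
  expect_true(file.exists(file.path(der, "struct",
                                    paste0(b$id, "_connectome.zip"))))
  expect_true(file.exists(file.path(der, "struct", paste0(b$id, "_gain.tsv"))))
  side_files <- list.files(file.path(der, "parameters"),
                           pattern = "_parameters\\.json$")
  expect_length(side_files, 3)
  side <- jsonlite::read_json(file.path(der, "parameters", side_files[1]))
  expect_equal(side$seed, rec$seed)
  expect_equal(side$mode, "spontaneous")
})

test_that("full-cohort runs are deterministic from the master seed", {
  a <- synthetic_cohort(2, seed = 9, R = 6, n_shafts = 2,
                        vertices_per_region = 12)
  b <- synthetic_cohort(2, seed = 9, R = 6, n_shafts = 2,
                        vertices_per_region = 12)
  expect_identical(a[[1]]$connectome$weights, b[[1]]$connectome$weights)
  expect_identical(a[[2]]$gain, b[[2]]$gain)
  r1 <- run_spontaneous(a[[1]], duration_s = 5)
  r2 <- run_spontaneous(b[[1]], duration_s = 5)
  expect_identical(r1$seeg$ts, r2$seeg$ts)
})
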