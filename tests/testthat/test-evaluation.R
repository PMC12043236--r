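test_that("the envelope tracks departures from baseline", {
  fs <- 200
  zero <- matrix(0, 2, fs * 30, dimnames = list(c("a", "b"), NULL))
  ez <- seizure_envelope(zero, fs)
  expect_equal(max(ez$env), 0)

  dc <- zero + 5
  expect_lt(max(seizure_envelope(dc, fs)$env), 1e-9)

  br <- burst_recording()
  env <- seizure_envelope(br$ts, br$fs)
  inside <- env$env["A", env$fs * 20:30]
  outside <- env$env["A", seq_len(env$fs * 15)]
  expect_gt(min(inside[-1]), 10 * max(outside))

  expect_error(seizure_envelope(zero[, 1:5, drop = FALSE], fs), "short")
})

test_that("flagging, onsets and the seizure mask locate the burst", {
  br <- burst_recording()
  env <- seizure_envelope(br$ts, br$fs)
  mk <- flag_and_mark(env)
  expect_true(mk$flag["A"])
  expect_false(mk$flag["B"])
  expect_equal(unname(mk$onset["A"]), 20, tolerance = 0.1)
  expect_equal(unname(mk$offset["A"]), 30, tolerance = 0.1)
  # mask is one contiguous interval on the flagged channel only
  runs <- rle(as.vector(mk$mask$mask["A", ]))
  expect_equal(sum(runs$values == 1), 1)
  expect_equal(sum(mk$mask$mask["B", ]), 0)

  # absolute mode with an unreachable threshold flags nothing
  mk2 <- flag_and_mark(env, threshold = max(env$env) * 2, relative = FALSE)
  expect_false(any(mk2$flag))
  expect_equal(sum(mk2$mask$mask), 0)
})

test_that("mask correlation follows hand-computed Pearson values", {
  expect_equal(mask_correlation(rbind(c(1, 1, 0, 0)), rbind(c(1, 1, 0, 0))), 1)
  expect_equal(mask_correlation(rbind(c(1, 1, 0, 0)), rbind(c(0, 0, 1, 1))), -1)
  expect_equal(mask_correlation(rbind(c(1, 1, 0, 0)), rbind(c(1, 0, 0, 0))),
               1 / sqrt(3), tolerance = 1e-12)
  expect_error(mask_correlation(rbind(c(0, 0)), rbind(c(1, 0))), "variance")
  # resampling an already-common grid is the identity
  m <- matrix(rbinom(512, 1, 0.3), 1)
  expect_identical(resample_masks(m, m, 512)$a, m)
})

test_that("binary overlap is the reference-normalized intersection", {
  e <- rbind(c(1, 1, 0, 0)); s <- rbind(c(1, 0, 0, 0))
  expect_equal(binary_overlap(e, s), 0.5)
  expect_equal(binary_overlap(e, e), 1)
  expect_equal(binary_overlap(e, rbind(c(0, 0, 1, 1))), 0)
  expect_error(binary_overlap(rbind(c(0, 0, 0, 0)), s), "empty")
  # prose variant: identical entries over all entries
  expect_equal(binary_overlap(e, s, variant = "agreement"), 0.75)
})

test_that("SO/SP classification splits by onset within the seizure", {
  marks <- list(flag = c(a = TRUE, b = TRUE, c = FALSE),
                onset = c(0, 5, NA), offset = c(10, 10, NA))
  cls <- classify_so_sp(marks, window_fraction = 0.10)
  expect_equal(unname(cls), c("SO", "SP", "none"))
  # all simultaneous onsets are all SO
  marks2 <- list(flag = c(a = TRUE, b = TRUE), onset = c(3, 3),
                 offset = c(9, 12))
  expect_equal(unname(classify_so_sp(marks2)), c("SO", "SO"))
  # single flagged channel defines the start, hence SO
  marks3 <- list(flag = c(a = TRUE), onset = 4, offset = 8)
  expect_equal(unname(classify_so_sp(marks3)), "SO")
  # percent-based window is invariant to rescaling the time axis
  marks4 <- lapply(marks, function(x) if (is.numeric(x)) x * 7 else x)
  expect_equal(classify_so_sp(marks4), cls)
})

test_that("jaccard handles overlap, identity, disjoint and empty sets", {
  expect_equal(jaccard(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A"), c("B")), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
})

test_that("signal power is the normalized mean square", {
  expect_equal(signal_power(matrix(2, 1, 10), normalize = FALSE)[1], 4)
  expect_equal(signal_power(matrix(c(1, 2, 3), 1), normalize = FALSE)[1],
               14 / 3)
  p <- signal_power(rbind(c(1, 1), c(3, 3)))
  expect_equal(unname(p), c(1 / 9, 1))
  expect_error(signal_power(matrix(0, 2, 5)), "all-zero")
})

test_that("the robust sigma estimator recovers the noise level within 2%", {
  set.seed(99)
  x <- rnorm(1e5, sd = 1.7)
  sigma_hat <- median(abs(x)) / 0.6745
  expect_equal(sigma_hat, 1.7, tolerance = 0.02)
})

test_that("spike detection finds injected transients and merges poly-spikes", {
  fs <- 1000
  set.seed(1)
  n <- 20 * fs
  spike <- 20 * sin(pi * seq_len(0.025 * fs) / (0.025 * fs))
  x <- rnorm(n)
  expect_length(detect_spikes(x, fs), 0)   # clean background premise
  for (t0 in c(5, 8, 11)) {
    idx <- t0 * fs + seq_along(spike)
    x[idx] <- x[idx] + spike
  }
  expect_length(detect_spikes(x, fs), 3)

  set.seed(4)
  y <- rnorm(n)
  for (t0 in c(5, 5.1)) {          # 100 ms apart: one spike
    idx <- round(t0 * fs) + seq_along(spike)
    y[idx] <- y[idx] + spike
  }
  expect_length(detect_spikes(y, fs), 1)

  expect_length(detect_spikes(numeric(5000), fs), 0)
  # the empirical amplitude floor suppresses small-signal spikes
  expect_length(detect_spikes(x / 100, fs, empirical = TRUE), 0)
  expect_error(detect_spikes(x, fs = 100), "sampling rate")
})

test_that("IIS counts normalize to fractions summing to one", {
  expect_equal(iis_count(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  expect_equal(iis_count(c(0, 4, 0)), c(0, 1, 0))
  set.seed(2)
  v <- rpois(20, 3)
  expect_equal(sum(iis_count(v + 1)), 1)
  expect_error(iis_count(c(0, 0)), "no spikes")
})

test_that("IIS correlation is plain Pearson with variance guards", {
  expect_equal(iis_correlation(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1)
  # hand Pearson: deviations give r = -39/42
  expect_equal(iis_correlation(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2)),
               -39 / 42, tolerance = 1e-12)
  expect_lt(iis_correlation(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(iis_correlation(c(1, 1), c(1, 2)), "variance")
  expect_error(iis_correlation(c(1, 2, 3), c(1, 2)), "length")
})

test_that("the permutation test matches exhaustive enumeration", {
  # identical constant groups: every permutation is as extreme
  expect_equal(permutation_test(c(2, 2), c(2, 2))$p, 1)
  # maximal separation: only the observed split among C(6,3) = 20
  r <- permutation_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$method, "exact")
  expect_equal(r$p, 1 / 20)
  # property: Monte-Carlo agrees with the exact path on small inputs
  set.seed(11)
  for (k in 1:4) {
    a <- rnorm(4); b <- rnorm(4)
    pe <- permutation_test(a, b, exact = TRUE)$p
    pm <- permutation_test(a, b, n_perm = 20000, seed = k, exact = FALSE)$p
    se <- sqrt(pe * (1 - pe) / 20000)
    expect_lt(abs(pm - pe), 3 * se + 1e-9)
  }
})

test_that("a recording compared against itself scores perfectly", {
  br <- burst_recording()
  rep <- compare_runs(br, br)
  expect_equal(rep$correlation, 1)
  expect_equal(rep$overlap, 1)
  expect_equal(rep$so_jaccard, 1)
  expect_equal(rep$sp_jaccard, 1)

  # disjoint channel sets cannot be compared
  other <- br
  rownames(other$ts) <- c("X", "Y")
  expect_error(compare_runs(br, other), "common channels")
})
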