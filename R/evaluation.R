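# Comparison suite: envelope features, seizure masks, headline metrics,
# interictal spike statistics and the permutation test.

#' Seizure envelope of SEEG channels
#'
#' Tracks each channel's departure from its own pre-ictal baseline:
#' the channel is (optionally) high-pass filtered against drift,
#' referenced to its initial-baseline level, rectified, decimated and
#' smoothed with a low-pass filter. The result is a non-negative
#' envelope per channel that is low at baseline and elevated during
#' seizure activity, whichever polarity the seizure shift has on that
#' channel.
#'
#' Rectification is taken around the initial baseline rather than the
#' recording mean because seizure activity in this model shifts the
#' signal's slow level strongly in a channel-specific direction; see the
#' methods vignette.
#'
#' @param ts C x T matrix (channels in rows).
#' @param fs Sampling rate in Hz.
#' @param hp_cutoff Optional drift-removal high-pass cutoff in Hz
#'   (default 0: baseline referencing alone).
#' @param lp_cutoff Envelope smoothing cutoff in Hz (default 0.5).
#' @param fs_env Envelope sampling rate after decimation (default 100 Hz;
#'   the low-pass is applied at this rate, where its normalized cutoff is
#'   numerically comfortable).
#' @param baseline_fraction Initial fraction of samples defining each
#'   channel's baseline level (default 0.05).
#' @return An `envelope_feature` list: `env` (C x T' matrix), `fs`,
#'   `baseline_level` (per channel: mean envelope over the baseline
#'   window), channel labels.
#' @export
seizure_envelope <- function(ts, fs, hp_cutoff = 0, lp_cutoff = 0.5,
                             fs_env = 100, baseline_fraction = 0.025) {
  stopifnot(is.matrix(ts), fs > 2 * hp_cutoff)
  if (ncol(ts) < 12) stop("signal too short for envelope filtering")
  bf <- if (hp_cutoff > 0)
    signal::butter(2, hp_cutoff / (fs / 2), type = "high") else NULL
  dec <- max(1L, floor(fs / fs_env))
  fs2 <- fs / dec
  lf <- signal::butter(2, min(0.99, lp_cutoff / (fs2 / 2)), type = "low")
  n0 <- max(1L, floor(ncol(ts) * baseline_fraction))
  env <- t(apply(ts, 1, function(x) {
    if (!is.null(bf)) x <- signal::filtfilt(bf, x)
    rect <- abs(x - median(x[seq_len(n0)]))
    rect <- rect[seq(1, length(rect), by = dec)]
    # reflection padding tames filtfilt's edge transients, which would
    # otherwise distort the initial-baseline window
    np <- min(length(rect) - 1L, ceiling(2 * fs2 / lp_cutoff))
    padded <- c(rev(rect[seq_len(np)]), rect,
                rev(rect[(length(rect) - np + 1L):length(rect)]))
    sm <- signal::filtfilt(lf, padded)[(np + 1L):(np + length(rect))]
    pmax(sm, 0)
  }))
  rownames(env) <- rownames(ts)
  nb <- max(1L, floor(ncol(env) * baseline_fraction))
  structure(list(env = env, fs = fs2,
                 baseline_level = rowMeans(env[, seq_len(nb), drop = FALSE]),
                 channels = rownames(ts)),
            class = "envelope_feature")
}

#' Flag seizure channels and build the binary seizure mask
#'
#' A channel is flagged as a seizure channel when its envelope peak
#' exceeds `threshold`. For flagged channels, onset and offset are the
#' first and last crossings of the baseline-departure level (a fraction
#' of the threshold). The mask is 1 on `[onset, offset]` of flagged
#' channels and 0 elsewhere.
#'
#' In the default relative mode each channel's envelope is first
#' normalized by its own baseline amplitude, so the same (ratio)
#' threshold applies to every channel regardless of its gain; the
#' default threshold of 3 flags channels whose envelope peak exceeds
#' three times their baseline level. With `relative = FALSE` the
#' threshold is in absolute envelope units.
#'
#' @param envf An [seizure_envelope()] result.
#' @param threshold Peak threshold (> 0); default 3 (relative mode) or,
#'   in absolute mode with `threshold = NULL`, baseline mean + 3
#'   baseline SD pooled over channels.
#' @param relative Normalize each channel by its baseline amplitude
#'   before thresholding (default TRUE).
#' @param departure_fraction Baseline-departure level as a fraction of
#'   threshold (default 0.5).
#' @return List with `flag`, `onset`, `offset` (per channel, seconds and
#'   NA for unflagged), `mask` (`seizure_mask`: binary C x T' matrix plus
#'   `fs` and `time`), `threshold`.
#' @export
flag_and_mark <- function(envf, threshold = NULL, relative = TRUE,
                          departure_fraction = 0.5) {
  env <- envf$env
  if (relative) {
    # floor the per-channel baseline so silent channels (baseline ~ 0)
    # do not blow up the ratio
    floor_lvl <- pmax(envf$baseline_level, 1e-3 * max(env), 1e-300)
    env <- env / floor_lvl
    if (is.null(threshold)) threshold <- 3
  }
  if (is.null(threshold)) {
    nb <- max(1L, floor(ncol(env) * 0.1))
    base <- env[, seq_len(nb), drop = FALSE]
    threshold <- mean(base) + 3 * sd(as.vector(base))
  }
  stopifnot(threshold > 0)
  C <- nrow(env)
  flag <- apply(env, 1, max) > threshold
  onset <- offset <- stats::setNames(rep(NA_real_, C), rownames(env))
  mask <- matrix(0L, C, ncol(env), dimnames = dimnames(env))
  dep <- departure_fraction * threshold
  for (i in which(flag)) {
    hit <- which(env[i, ] > threshold)
    # walk out from the threshold crossings to the baseline-departure level
    below_pre <- which(env[i, seq_len(hit[1])] <= dep)
    i_on <- if (length(below_pre) == 0) 1L else max(below_pre) + 1L
    after <- seq(hit[length(hit)], ncol(env))
    below_post <- after[env[i, after] <= dep]
    i_off <- if (length(below_post) == 0) ncol(env) else min(below_post) - 1L
    onset[i] <- (i_on - 1) / envf$fs
    offset[i] <- (i_off - 1) / envf$fs
    mask[i, i_on:i_off] <- 1L
  }
  msk <- structure(list(mask = mask, fs = envf$fs,
                        time = (seq_len(ncol(env)) - 1) / envf$fs,
                        channels = envf$channels),
                   class = "seizure_mask")
  list(flag = flag, onset = onset, offset = offset, mask = msk,
       threshold = threshold)
}

mask_matrix <- function(m) if (inherits(m, "seizure_mask")) m$mask else m

# restrict a flag_and_mark() result to times >= t0 (seconds), recomputing
# flags and per-channel onsets/offsets from the cropped mask
crop_marks <- function(marks, t0) {
  msk <- marks$mask
  keep <- which(msk$time >= t0)
  m <- msk$mask[, keep, drop = FALSE]
  flag <- stats::setNames(rowSums(m) > 0, rownames(m))
  onset <- offset <- stats::setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (i in which(flag)) {
    w <- which(m[i, ] == 1)
    onset[i] <- (w[1] - 1) / msk$fs
    offset[i] <- (w[length(w)] - 1) / msk$fs
  }
  msk$mask <- m
  msk$time <- msk$time[keep] - t0
  list(flag = flag, onset = onset, offset = offset, mask = msk,
       threshold = marks$threshold)
}

#' Resample two seizure masks to a common time grid
#'
#' Nearest-neighbour resampling of both masks to `n_bins` time bins so
#' that element-wise comparisons are defined for recordings of unequal
#' duration. Resampling a mask already on the target grid is the
#' identity.
#'
#' @param a,b Seizure masks (objects or binary matrices).
#' @param n_bins Number of common time bins (default 512).
#' @return List of two binary matrices with `n_bins` columns.
#' @export
resample_masks <- function(a, b, n_bins = 512) {
  rs <- function(m) {
    m <- mask_matrix(m)
    if (ncol(m) == n_bins) return(m)
    # equal-width bins: bin k maps to the source column covering the same
    # relative time, so every source column receives (near-)equal weight
    idx <- floor((seq_len(n_bins) - 1) * ncol(m) / n_bins) + 1L
    m[, idx, drop = FALSE]
  }
  list(a = rs(a), b = rs(b))
}

#' Pearson correlation of two binary seizure masks
#'
#' Flattens both channel x time masks (resampled to a common grid) and
#' computes the Pearson correlation over all entries.
#'
#' @param mask_a,mask_b Seizure masks of matching channel count.
#' @param n_bins Common time grid (default 512).
#' @return Correlation in `[-1, 1]`.
#' @export
mask_correlation <- function(mask_a, mask_b, n_bins = 512) {
  m <- resample_masks(mask_a, mask_b, n_bins)
  if (nrow(m$a) != nrow(m$b)) stop("masks have different channel counts")
  x <- as.vector(m$a); y <- as.vector(m$b)
  if (sd(x) == 0 || sd(y) == 0)
    stop("mask correlation undefined: a mask has zero variance")
  cor(x, y)
}

#' Binary overlap of seizure masks
#'
#' Fraction of the reference (empirical) mask's active entries that are
#' also active in the simulated mask, `|E & S| / |E|`. The alternative
#' reading (identical entries over all entries) is available via
#' `variant = "agreement"`.
#'
#' @param mask_emp,mask_sim Seizure masks (empirical first).
#' @param n_bins Common time grid (default 512).
#' @param variant `"reference"` (default) or `"agreement"`.
#' @return Fraction in `[0, 1]`.
#' @export
binary_overlap <- function(mask_emp, mask_sim, n_bins = 512,
                           variant = c("reference", "agreement")) {
  variant <- match.arg(variant)
  m <- resample_masks(mask_emp, mask_sim, n_bins)
  if (nrow(m$a) != nrow(m$b)) stop("masks have different channel counts")
  if (variant == "agreement") return(mean(m$a == m$b))
  ne <- sum(m$a == 1)
  if (ne == 0) stop("empirical mask is empty; overlap undefined")
  sum(m$a == 1 & m$b == 1) / ne
}

#' Classify seizure channels as onset (SO) or propagation (SP)
#'
#' Among flagged channels, those whose onset falls within the first
#' `window_fraction` of the global seizure duration (earliest onset to
#' latest offset) are seizure-onset channels; the rest are propagation
#' channels.
#'
#' @param marks A [flag_and_mark()] result.
#' @param window_fraction Fraction of the seizure duration defining the
#'   onset window, in `[0.05, 0.15]` (default 0.10).
#' @return Character vector per channel: `"SO"`, `"SP"` or `"none"`.
#' @export
classify_so_sp <- function(marks, window_fraction = 0.10) {
  stopifnot(window_fraction >= 0.05, window_fraction <= 0.15)
  out <- rep("none", length(marks$flag))
  names(out) <- names(marks$flag)
  if (!any(marks$flag)) return(out)
  t0 <- min(marks$onset, na.rm = TRUE)
  t1 <- max(marks$offset, na.rm = TRUE)
  cutoff <- t0 + window_fraction * (t1 - t0)
  out[which(marks$flag)] <- ifelse(marks$onset[marks$flag] <= cutoff,
                                   "SO", "SP")
  out
}

#' Jaccard similarity coefficient
#'
#' `|A intersect B| / |A union B|`; two empty sets agree perfectly on
#' absence and score 1.
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return Coefficient in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  u <- union(set_a, set_b)
  if (length(u) == 0) return(1)
  length(intersect(set_a, set_b)) / length(u)
}

#' Normalized per-channel signal power
#'
#' Mean square amplitude per channel, `P = mean(s_t^2)`, normalized by
#' the maximum across channels so values lie in `[0, 1]`.
#'
#' @param ts C x T matrix.
#' @param normalize Divide by the channel maximum (default TRUE).
#' @return Per-channel power vector.
#' @export
signal_power <- function(ts, normalize = TRUE) {
  stopifnot(is.matrix(ts), ncol(ts) >= 1)
  p <- rowMeans(ts^2)
  if (!normalize) return(p)
  if (max(p) == 0) stop("all-zero recording; normalized power undefined")
  p / max(p)
}

#' Detect interictal spikes on one channel
#'
#' Band-pass filters the signal (Butterworth order 2, zero-phase,
#' 1-70 Hz), estimates the background noise level robustly as
#' `sigma = median(|x|) / 0.6745`, and detects peaks exceeding
#' `4 * sigma`. Peaks closer than 250 ms are merged into a single spike
#' (poly-spike rule). For empirical recordings an additional 25 uV
#' amplitude floor applies.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz (> 140).
#' @param empirical Apply the 25 uV amplitude floor (default FALSE).
#' @param lowcut,highcut Band edges in Hz (defaults 1 and 70).
#' @param merge_ms Merge window in ms (default 250).
#' @return Integer vector of spike sample indices (possibly empty).
#' @export
detect_spikes <- function(x, fs, empirical = FALSE, lowcut = 1,
                          highcut = 70, merge_ms = 250) {
  if (fs <= 2 * highcut) stop("sampling rate too low for the 1-70 Hz band")
  if (length(x) < 24) stop("signal too short for spike detection")
  bf <- signal::butter(2, c(lowcut, highcut) / (fs / 2), type = "pass")
  # demean first: filtfilt's edge transients on a large DC offset would
  # otherwise masquerade as spikes
  xf <- signal::filtfilt(bf, x - mean(x))
  sigma <- median(abs(xf)) / 0.6745
  thr <- 4 * sigma
  if (empirical) thr <- max(thr, 25)
  if (thr == 0) return(integer(0))
  # a channel whose in-band content is negligible against its overall
  # amplitude is silent: the relative threshold alone would otherwise
  # flag numerical residue on noise-free simulations
  if (max(abs(xf)) < 1e-6 * max(abs(x))) return(integer(0))
  above <- abs(xf) > thr
  if (!any(above)) return(integer(0))
  # local maxima of |xf| above threshold
  ax <- abs(xf)
  n <- length(ax)
  peaks <- which(above &
                 ax >= c(-Inf, ax[-n]) &
                 ax > c(ax[-1], -Inf))
  if (length(peaks) == 0) return(integer(0))
  # chained merge: a peak closer than the merge window to the previous
  # peak joins its group (poly-spikes count once)
  merge_n <- merge_ms / 1000 * fs
  keep <- peaks[1]
  last <- peaks[1]
  for (p in peaks[-1]) {
    if (p - last > merge_n) keep <- c(keep, p)
    last <- p
  }
  keep
}

#' Interictal spike count vector
#'
#' Per-channel fraction of detected spikes relative to all detected
#' spikes, `IIS_i = S_i / sum(S)`; sums to 1.
#'
#' @param spike_totals Non-negative per-channel spike counts.
#' @return Normalized vector.
#' @export
iis_count <- function(spike_totals) {
  s <- sum(spike_totals)
  if (s == 0) stop("no spikes detected; IIS count undefined")
  spike_totals / s
}

#' Pearson correlation of two IIS count vectors
#'
#' @param vec_sim,vec_emp Equal-length numeric vectors with variance.
#' @return Pearson correlation.
#' @export
iis_correlation <- function(vec_sim, vec_emp) {
  if (length(vec_sim) != length(vec_emp)) stop("vectors differ in length")
  if (sd(vec_sim) == 0 || sd(vec_emp) == 0)
    stop("IIS correlation undefined: zero variance")
  cor(vec_sim, vec_emp)
}

#' One-sided permutation test on a difference of means
#'
#' Tests H0: mean(a) <= mean(b) against H1: mean(a) > mean(b) by pooling
#' both groups, reshuffling group membership, and reporting the
#' proportion of permuted mean differences at least as extreme as the
#' observed one (the observed assignment counts once when enumerating
#' exactly). With 10 or fewer observations in total, all distinct splits
#' are enumerated exactly; otherwise `n_perm` random shuffles are drawn.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param n_perm Number of random shuffles (default 200000).
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto: exact when
#'   `length(a) + length(b) <= 10`).
#' @return List with `p`, `observed` (mean difference), `n_perm` used,
#'   and `method`.
#' @export
permutation_test <- function(group_a, group_b, n_perm = 200000,
                             seed = NULL, exact = NULL) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  na <- length(group_a)
  pool <- c(group_a, group_b)
  obs <- mean(group_a) - mean(group_b)
  if (is.null(exact)) exact <- length(pool) <= 10
  if (exact) {
    idx <- combn(length(pool), na)
    diffs <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(diffs >= obs - 1e-12)
    return(list(p = p, observed = obs, n_perm = ncol(idx),
                method = "exact"))
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- 0L
  block <- 10000L
  done <- 0L
  while (done < n_perm) {
    nb <- min(block, n_perm - done)
    for (k in seq_len(nb)) {
      i <- sample.int(length(pool), na)
      d <- mean(pool[i]) - mean(pool[-i])
      if (d >= obs - 1e-12) cnt <- cnt + 1L
    }
    done <- done + nb
  }
  list(p = cnt / n_perm, observed = obs, n_perm = n_perm,
       method = "monte-carlo")
}

#' Compare a simulated against a reference SEEG recording
#'
#' Restricts both recordings to their common channels (and, for
#' stimulated runs, to the post-stimulus window), computes envelopes and
#' seizure masks, and reports the four headline metrics: mask Pearson
#' correlation, binary overlap, and Jaccard coefficients of the
#' seizure-onset and seizure-propagation channel sets.
#'
#' @param sim,ref Lists with `ts` (labelled C x T matrix) and `fs`
#'   (e.g. from [read_brainvision()] or a run record's `seeg`).
#' @param post_stimulus_s Optional time (s) before which samples are
#'   discarded from both recordings (stimulus window removal).
#' @param threshold_sim,threshold_ref Envelope thresholds; `NULL` for the
#'   baseline-derived default.
#' @param window_fraction SO window fraction (default 0.10).
#' @param ... Passed to [seizure_envelope()].
#' @return A `metric_report` list: `correlation`, `overlap`,
#'   `so_jaccard`, `sp_jaccard`, plus channel classes.
#' @export
compare_runs <- function(sim, ref, post_stimulus_s = NULL,
                         threshold_sim = NULL, threshold_ref = NULL,
                         window_fraction = 0.10, ...) {
  common <- intersect(rownames(sim$ts), rownames(ref$ts))
  if (length(common) == 0) stop("no common channels to compare")
  sts <- sim$ts[common, , drop = FALSE]
  rts <- ref$ts[common, , drop = FALSE]
  es <- seizure_envelope(sts, sim$fs, ...)
  er <- seizure_envelope(rts, ref$fs, ...)
  ms <- flag_and_mark(es, threshold_sim)
  mr <- flag_and_mark(er, threshold_ref)
  if (!is.null(post_stimulus_s)) {
    # the envelope baseline comes from the pre-stimulus segment; the
    # comparison itself covers only the post-stimulus window
    ms <- crop_marks(ms, post_stimulus_s)
    mr <- crop_marks(mr, post_stimulus_s)
    if (ncol(ms$mask$mask) == 0 || ncol(mr$mask$mask) == 0)
      stop("post-stimulus window empty")
  }
  cls_s <- classify_so_sp(ms, window_fraction)
  cls_r <- classify_so_sp(mr, window_fraction)
  so_s <- common[cls_s == "SO"]; so_r <- common[cls_r == "SO"]
  sp_s <- common[cls_s == "SP"]; sp_r <- common[cls_r == "SP"]
  # a run without any detected seizure yields a constant (all-zero) mask;
  # score it as no agreement (0) against a seizing reference, and perfect
  # agreement (1) if the reference is also seizure-free
  empty_s <- !any(ms$mask$mask == 1)
  empty_r <- !any(mr$mask$mask == 1)
  corr <- if (empty_s && empty_r) 1
          else if (empty_s || empty_r) 0
          else mask_correlation(mr$mask, ms$mask)
  ovl <- if (empty_r) NA_real_ else binary_overlap(mr$mask, ms$mask)
  structure(list(
    correlation = corr,
    overlap = ovl,
    so_jaccard = jaccard(so_r, so_s),
    sp_jaccard = jaccard(sp_r, sp_s),
    channels = common,
    classes_sim = cls_s, classes_ref = cls_r),
    class = "metric_report")
}
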