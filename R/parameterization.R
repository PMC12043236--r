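#' EZ hypothesis
#'
#' Per-region normalized epileptogenicity values in `[0, 1]`, the
#' ground-truth parameter object of every simulation. Values near 1 mark
#' the epileptogenic zone (EZ), intermediate values the propagation zone
#' (PZ), values near 0 healthy regions (HZ).
#'
#' @param ev Numeric vector of epileptogenicity values in `[0, 1]`.
#' @param region_labels Optional region labels (recycled check only).
#' @param zones Optional per-region class in `{"EZ", "PZ", "HZ"}`.
#' @param tag Provenance tag: `"VEPhypothesis"`, `"ClinicalHypothesis"` or
#'   `"Randomized"`.
#' @return An `ez_hypothesis` object.
#' @export
ez_hypothesis <- function(ev, region_labels = NULL, zones = NULL,
                          tag = c("VEPhypothesis", "ClinicalHypothesis",
                                  "Randomized")) {
  tag <- match.arg(tag)
  if (length(ev) == 0) stop("ev must be non-empty")
  if (any(ev < 0 | ev > 1)) stop("epileptogenicity values must lie in [0, 1]")
  if (!is.null(region_labels) && length(region_labels) != length(ev))
    stop("region_labels length must match ev")
  if (is.null(zones))
    zones <- ifelse(ev >= 0.7, "EZ", ifelse(ev >= 0.3, "PZ", "HZ"))
  structure(list(ev = as.numeric(ev), region_labels = region_labels,
                 zones = zones, tag = tag),
            class = "ez_hypothesis")
}

ev_of <- function(hypothesis) {
  ev <- if (inherits(hypothesis, "ez_hypothesis")) hypothesis$ev
        else as.numeric(hypothesis)
  if (any(ev < 0 | ev > 1)) stop("epileptogenicity values must lie in [0, 1]")
  ev
}

#' Excitability map for spontaneous seizures
#'
#' Linearly maps epileptogenicity `[0, 1]` onto the excitability range
#' `[-2.2, -1.2]`: `x0_i = -2.2 + 1.0 * ev_i`. Regions mapped above the
#' critical excitability (about -2.06 in isolation) seize autonomously.
#'
#' @param hypothesis An [ez_hypothesis()] or numeric ev vector.
#' @return Per-region `x0` vector.
#' @export
map_spontaneous <- function(hypothesis) {
  -2.2 + 1.0 * ev_of(hypothesis)
}

#' Excitability and seizure-threshold map for stimulated seizures
#'
#' Maps epileptogenicity onto a sub-critical excitability range
#' `[-2.2, -2.07]` (`x0_i = -2.2 + 0.13 * ev_i`), so no region seizes
#' spontaneously, and onto the seizure threshold range `[0.5, 10]` with
#' decreasing orientation (`mthresh_i = 10 - 9.5 * ev_i`): epileptogenic
#' regions have lower thresholds than healthy regions.
#'
#' @param hypothesis An [ez_hypothesis()] or numeric ev vector.
#' @return List with `x0` and `mthresh` vectors.
#' @export
map_stimulated <- function(hypothesis) {
  ev <- ev_of(hypothesis)
  list(x0 = -2.2 + 0.13 * ev, mthresh = 10 - 9.5 * ev)
}

#' Excitability map for interictal activity
#'
#' Maps epileptogenicity onto `[-3, -2.8]` (`x0_i = -3 + 0.2 * ev_i`),
#' raises the fast-subsystem drive to `Iext1 = 6.0`, and turns on
#' additive stochastic noise so that regions near the seizure threshold
#' produce irregular interictal spikes.
#'
#' @param hypothesis An [ez_hypothesis()] or numeric ev vector.
#' @param noise Noise amplitude on the intermediate population variables
#'   (default 0.05).
#' @return List with `x0`, `Iext1` and `noise`.
#' @export
map_interictal <- function(hypothesis, noise = 0.05) {
  list(x0 = -3 + 0.2 * ev_of(hypothesis), Iext1 = 6.0, noise = noise)
}

#' Randomized-cohort hypotheses
#'
#' For a given patient, draws EZ hypotheses from the *other* patients of
#' a cohort (never the patient's own), the construction behind the
#' randomized control cohort: re-simulating a patient with someone
#' else's hypothesis shows how much the personalized parameters matter.
#'
#' @param cohort List of patient bundles or of `ez_hypothesis` objects
#'   (>= 2 entries).
#' @param patient_index Index of the patient being re-simulated.
#' @param n_draws Number of draws (default 3, with replacement across
#'   draws but never the patient's own).
#' @param seed Integer seed.
#' @return List of `ez_hypothesis` objects tagged `"Randomized"`.
#' @export
make_randomized_hypothesis <- function(cohort, patient_index, n_draws = 3,
                                       seed = 1) {
  if (length(cohort) < 2) stop("cohort must contain at least 2 patients")
  if (patient_index < 1 || patient_index > length(cohort))
    stop("patient_index out of range")
  set.seed(seed)
  others <- setdiff(seq_along(cohort), patient_index)
  picks <- others[sample.int(length(others), n_draws, replace = TRUE)]
  lapply(picks, function(i) {
    h <- cohort[[i]]
    if (!inherits(h, "ez_hypothesis")) h <- h$hypotheses[[1]]
    out <- ez_hypothesis(h$ev, h$region_labels, h$zones, tag = "Randomized")
    attr(out, "source_patient") <- i
    out
  })
}
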