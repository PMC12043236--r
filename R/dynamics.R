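#' Epileptor model parameters
#'
#' Parameter set for the 6-variable Epileptor neural mass model. Each brain
#' region carries one Epileptor; the excitability parameter `x0` controls the
#' dynamical regime of the isolated node: a stable down-state fixed point
#' (interictal) at low `x0`, a sustained up-state oscillation (seizure-like
#' event) at intermediate `x0`, and a stable up-state fixed point at high
#' `x0`.
#'
#' @param x0 Excitability, scalar or one value per region (model units).
#' @param r Inverse time scale of the slow permittivity variable `z`
#'   (1/ms; default 0.00035).
#' @param tau Time scale of the intermediate population (default 10).
#' @param Iext1,Iext2 External drives of the fast and intermediate
#'   populations (defaults 3.1 and 0.45).
#' @param a,a2,b,c,d,m Remaining Epileptor constants (defaults 1, 6, 3, 1,
#'   5, 0).
#' @return An object of class `epileptor_params` (a list).
#' @export
epileptor_params <- function(x0 = -2.2, r = 0.00035, tau = 10,
                             Iext1 = 3.1, Iext2 = 0.45,
                             a = 1, a2 = 6, b = 3, c = 1, d = 5, m = 0) {
  stopifnot(r > 0, tau > 0)
  structure(list(x0 = x0, r = r, tau = tau, Iext1 = Iext1, Iext2 = Iext2,
                 a = a, a2 = a2, b = b, c = c, d = d, m = m),
            class = "epileptor_params")
}

#' Stimulation-extension parameters
#'
#' Extra parameters of the stimulation-extended Epileptor, in which the
#' constant `m` becomes a state variable that integrates the rectified
#' stimulation input and, on crossing the seizure threshold `mthresh`,
#' shifts the effective excitability by one model unit (Heaviside term in
#' the slow equation), pushing the node into the seizure state.
#'
#' @param mthresh Seizure threshold on `m`, scalar or per region
#'   (default 1.5).
#' @param k Gain of the rectified stimulus into `m` (default 20).
#' @param r2 Time scale of `m` (1/ms; default 0.006).
#' @param n Direct stimulus gain into the fast variable `x1` (default 3).
#' @param heaviside_at_equality If `TRUE` (default) the threshold crossing
#'   counts exactly at `m == mthresh` (H(0) = 1).
#' @return An object of class `stim_params` (a list).
#' @export
stim_params <- function(mthresh = 1.5, k = 20, r2 = 0.006, n = 3,
                        heaviside_at_equality = TRUE) {
  stopifnot(all(mthresh > 0), r2 > 0)
  structure(list(mthresh = mthresh, k = k, r2 = r2, n = n,
                 heaviside_at_equality = heaviside_at_equality),
            class = "stim_params")
}

f1_epileptor <- function(x1, x2, z, m, a, b) {
  ifelse(x1 < 0, a * x1^3 - b * x1^2,
         -(m - x2 + 0.6 * (z - 4)^2) * x1)
}

f2_epileptor <- function(x2, a2) ifelse(x2 < -0.25, 0, a2 * (x2 + 0.25))

f3_epileptor <- function(z) ifelse(z < 0, -0.1 * z^7, 0)

#' Time derivative of the Epileptor
#'
#' Evaluates the right-hand side of the 6-variable Epileptor for one region.
#' Used as the reference implementation for the compiled network integrator.
#'
#' @param state Numeric vector `(x1, y1, x2, y2, z, g)`.
#' @param params An [epileptor_params()] object with scalar `x0`.
#' @param coupling Scalar network coupling term entering the slow equation.
#' @return Numeric vector of the six derivatives.
#' @export
epileptor_deriv <- function(state, params, coupling = 0) {
  stopifnot(length(state) == 6, all(is.finite(state)))
  p <- params
  x1 <- state[1]; y1 <- state[2]; x2 <- state[3]
  y2 <- state[4]; z <- state[5]; g <- state[6]
  c(y1 - f1_epileptor(x1, x2, z, p$m, p$a, p$b) - z + p$Iext1,
    p$c - p$d * x1^2 - y1,
    -y2 + x2 - x2^3 + p$Iext2 + 0.002 * g - 0.3 * (z - 3.5),
    (-y2 + f2_epileptor(x2, p$a2)) / p$tau,
    p$r * (4 * (x1 - p$x0) - z + f3_epileptor(z) + coupling),
    -0.01 * (g - 0.1 * x1))
}

#' Time derivative of the stimulation-extended Epileptor
#'
#' Evaluates the right-hand side of the 7-variable stimulation variant for
#' one region: `x1` gains `n * Istim`, the slow equation gains a Heaviside
#' shift `H(m - mthresh)` of one model unit on the excitability, and
#' `m' = r2 * (k * |Istim| - 0.3 * m)`.
#'
#' @param state Numeric vector `(x1, y1, x2, y2, z, g, m)`.
#' @param params An [epileptor_params()] object with scalar `x0`.
#' @param stim An [stim_params()] object with scalar `mthresh`.
#' @param coupling Scalar network coupling term.
#' @param Istim Stimulus input value at this instant (model units).
#' @return Numeric vector of the seven derivatives.
#' @export
stim_epileptor_deriv <- function(state, params, stim, coupling = 0,
                                 Istim = 0) {
  stopifnot(length(state) == 7, all(is.finite(state)), is.finite(Istim))
  p <- params; s <- stim
  x1 <- state[1]; y1 <- state[2]; x2 <- state[3]
  y2 <- state[4]; z <- state[5]; g <- state[6]; m <- state[7]
  H <- if (s$heaviside_at_equality) as.numeric(m >= s$mthresh)
       else as.numeric(m > s$mthresh)
  c(y1 - f1_epileptor(x1, x2, z, m, p$a, p$b) - z + p$Iext1 + s$n * Istim,
    p$c - p$d * x1^2 - y1,
    -y2 + x2 - x2^3 + p$Iext2 + 0.002 * g - 0.3 * (z - 3.5),
    (-y2 + f2_epileptor(x2, p$a2)) / p$tau,
    p$r * (4 * (x1 - p$x0 - H) - z + f3_epileptor(z) + coupling),
    -0.01 * (g - 0.1 * x1),
    s$r2 * (s$k * abs(Istim) - 0.3 * m))
}

#' Permittivity coupling term
#'
#' Linear difference coupling on the fast variable,
#' `K * sum_j C_ij * (x1_j - x1_i)` for each region `i`; it enters the slow
#' `z` equation of each Epileptor.
#'
#' @param x1 Numeric vector of fast-variable values, one per region.
#' @param connectome `vep_connectome` object or plain R x R weight matrix.
#' @param K Global coupling scalar (>= 0).
#' @return Numeric vector of per-region coupling terms.
#' @export
coupling_term <- function(x1, connectome, K) {
  W <- if (inherits(connectome, "vep_connectome")) connectome$weights
       else connectome
  stopifnot(is.matrix(W), nrow(W) == ncol(W), K >= 0)
  if (length(x1) != nrow(W)) stop("x1 length does not match connectome size")
  K * (as.vector(W %*% x1) - x1 * rowSums(W))
}

#' Network model specification
#'
#' Bundles everything the integrator needs: connectome, global coupling,
#' per-region parameters, per-variable noise amplitudes, and the time step.
#'
#' @param connectome `vep_connectome` or R x R weight matrix.
#' @param K Global coupling scalar (default 1).
#' @param params [epileptor_params()]; `x0` may be per region.
#' @param stim Optional [stim_params()] to select the 7-variable
#'   stimulation variant; `mthresh` may be per region.
#' @param noise Per-variable noise amplitudes. Either a full vector (length
#'   6 or 7) or a single scalar applied to `x2` and `y2` only (the usual
#'   choice for irregular interictal spiking). Default 0 (deterministic).
#' @param dt Integration step in ms (default 0.05). Explicit Euler is only
#'   stable for this model below roughly 0.1 ms: the fast subsystem's
#'   Jacobian eigenvalue at the down-state fixed point is about -17/ms.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(connectome, K = 1, params = epileptor_params(),
                         stim = NULL, noise = 0, dt = 0.05) {
  W <- if (inherits(connectome, "vep_connectome")) connectome$weights
       else connectome
  stopifnot(is.matrix(W), nrow(W) == ncol(W), dt > 0, K >= 0)
  nv <- if (is.null(stim)) 6L else 7L
  if (length(noise) == 1) {
    nz <- numeric(nv); nz[3:4] <- noise; noise <- nz
  }
  stopifnot(length(noise) == nv, all(noise >= 0))
  structure(list(W = W, R = nrow(W), K = K, params = params, stim = stim,
                 noise = noise, dt = dt, nv = nv),
            class = "network_spec")
}

#' Default initial state
#'
#' Every region starts near the interictal down-state fixed point,
#' `(x1, y1, x2, y2, z, g) = (-1.6, -11.8, -0.18, 0.42, 3, -0.16)` (plus
#' `m = 0` for the stimulation variant); a burn-in then relaxes the network
#' onto its attractor before the recorded run. Starting on the down-state
#' branch keeps the explicit Euler scheme stable at the default 0.5 ms
#' step, which the strongly repelling mid-range states do not.
#'
#' @param spec A [network_spec()].
#' @return R x nv state matrix.
#' @export
initial_state <- function(spec) {
  base <- c(-1.6, -11.8, -0.18, 0.42, 3, -0.16, 0)
  matrix(rep(base[seq_len(spec$nv)], each = spec$R), spec$R, spec$nv)
}

expand_region <- function(v, R, what) {
  if (length(v) == 1) rep(v, R)
  else if (length(v) == R) as.numeric(v)
  else stop(what, " must be scalar or length R")
}

#' Integrate an Epileptor network
#'
#' Explicit Euler (Euler-Maruyama when any noise amplitude is positive)
#' integration of the coupled Epileptor network, with an optional discarded
#' burn-in and an optional per-region stimulus time course for the
#' stimulation variant.
#'
#' @param spec A [network_spec()].
#' @param duration_ms Recorded duration in ms (>= dt).
#' @param y0 Initial R x nv state matrix; default [initial_state()].
#' @param istim Optional R x n_steps stimulus matrix (model units); only
#'   allowed with the stimulation variant. Columns beyond the stimulus
#'   duration may be zero-padded by the caller; if the matrix is shorter
#'   than the run it is zero-padded here.
#' @param burn_in_ms Discarded noise-free relaxation before recording
#'   (default 0).
#' @param record_every Keep every k-th sample (default 1).
#' @param seed Optional integer seed applied just before the recorded
#'   (stochastic) phase.
#' @return A list with `time` (ms, relative to recording start), one R x T
#'   matrix per state variable (`x1`, ..., `g`, and `m` for the stimulation
#'   variant), `dt`, `fs` (effective sampling rate in Hz) and the
#'   network specification.
#' @export
integrate_network <- function(spec, duration_ms, y0 = initial_state(spec),
                              istim = NULL, burn_in_ms = 0,
                              record_every = 1L, seed = NULL) {
  stopifnot(inherits(spec, "network_spec"), duration_ms >= spec$dt)
  p <- spec$params
  stim_variant <- !is.null(spec$stim)
  if (!stim_variant && !is.null(istim))
    stop("istim requires the stimulation variant (supply stim_params)")
  x0 <- expand_region(p$x0, spec$R, "x0")
  iext1 <- expand_region(p$Iext1, spec$R, "Iext1")
  mthresh <- if (stim_variant)
    expand_region(spec$stim$mthresh, spec$R, "mthresh") else numeric(0)
  k_gain <- if (stim_variant) spec$stim$k else 0
  r2 <- if (stim_variant) spec$stim$r2 else 1
  n_gain <- if (stim_variant) spec$stim$n else 0
  hge <- if (stim_variant) spec$stim$heaviside_at_equality else TRUE

  run <- function(y, n_steps, noise, istim_mat, rec_every) {
    integrate_epileptor_cpp(y, spec$W, spec$K, x0, iext1, mthresh,
                            p$r, p$tau, p$Iext2, p$a, p$a2, p$b, p$c, p$d,
                            p$m, k_gain, r2, n_gain, spec$dt,
                            as.integer(n_steps), noise, istim_mat,
                            as.integer(rec_every), stim_variant, hge)
  }

  if (burn_in_ms > 0) {
    nb <- as.integer(round(burn_in_ms / spec$dt))
    bo <- run(y0, nb, numeric(spec$nv), NULL, nb)
    y0 <- do.call(cbind, lapply(bo, function(mm) mm[, ncol(mm)]))
  }
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(duration_ms / spec$dt))
  if (!is.null(istim)) {
    if (!is.matrix(istim) || nrow(istim) != spec$R)
      stop("istim must be an R x T matrix")
    if (ncol(istim) < n_steps)
      istim <- cbind(istim, matrix(0, spec$R, n_steps - ncol(istim)))
  }
  out <- run(y0, n_steps, spec$noise, istim, record_every)
  out$time <- seq(0, by = spec$dt * record_every,
                  length.out = ncol(out$x1))
  out$dt <- spec$dt * record_every
  out$fs <- 1000 / out$dt
  out$spec <- spec
  class(out) <- "network_run"
  out
}

#' Classify the regime of an isolated Epileptor
#'
#' Simulates a single noise-free Epileptor at the given excitability and
#' reports whether it settles into a fixed point or sustains an oscillation
#' (seizure-like activity). Oscillation is declared when the peak-to-peak
#' amplitude of `x1` in any trailing window exceeds `amplitude_threshold`
#' model units; windows cover the trailing half of the run so that
#' seizure-like events with long quiescent phases near the regime boundary
#' are still caught.
#'
#' @param x0 Excitability value.
#' @param duration_ms Simulated duration after burn-in (default 200e3).
#' @param dt Integration step in ms (default 0.05).
#' @param amplitude_threshold Peak-to-peak threshold (default 0.5).
#' @param params Base parameters (x0 is overridden).
#' @return `"fixed_point"` or `"oscillation"`.
#' @export
classify_regime <- function(x0, duration_ms = 200e3, dt = 0.05,
                            amplitude_threshold = 0.5,
                            params = epileptor_params()) {
  params$x0 <- x0
  spec <- network_spec(matrix(0, 1, 1), K = 0, params = params,
                       noise = 0, dt = dt)
  out <- integrate_network(spec, duration_ms, burn_in_ms = 10e3,
                           record_every = max(1L, as.integer(2 / dt)))
  x1 <- out$x1[1, ]
  n <- length(x1)
  half <- x1[(n %/% 2 + 1):n]
  wlen <- max(2L, as.integer(20e3 / out$dt))     # 20-s windows
  nw <- max(1L, length(half) %/% wlen)
  p2p <- vapply(seq_len(nw), function(w) {
    seg <- half[((w - 1) * wlen + 1):min(w * wlen, length(half))]
    diff(range(seg))
  }, numeric(1))
  if (max(p2p) > amplitude_threshold) "oscillation" else "fixed_point"
}

#' Down-state slow-variable equilibrium
#'
#' Solves for the slow variable's value at the down-state (interictal)
#' fixed point of an isolated Epileptor: on the down branch,
#' `z = -x1^3 - 2 x1^2 + c + Iext1` with `z = 4 (x1 - x0)`. Only defined
#' below the fold (roughly `x0 < -2.06` with defaults).
#'
#' @param x0 Excitability value.
#' @param params Base parameters.
#' @return The equilibrium `z` value.
#' @export
down_state_z <- function(x0, params = epileptor_params()) {
  p <- params
  g <- function(x1) -x1^3 - 2 * x1^2 + p$c + p$Iext1 - 4 * (x1 - x0)
  x1 <- stats::uniroot(g, c(-3, -1.2), tol = 1e-10)$root
  4 * (x1 - x0)
}

#' Up-state equilibrium of the isolated Epileptor
#'
#' Solves for an equilibrium on the seizure (up-state) branch of the fast
#' subsystem (`x1 >= 0`). At an equilibrium, `y1 = c - d*x1^2`,
#' `g = 0.1*x1`, `z = 4*(x1 - x0)`, and `x2` solves its own scalar
#' equilibrium equation given `z` and `g`; substituting these into the
#' `x1` equation leaves a one-dimensional root problem. The equilibrium is
#' born at `x1 = 0` when `c + Iext1 + 4*x0 = 0`, i.e. at `x0 = -1.025`
#' with default parameters: this is the regime edge above which the model
#' possesses an up-state resting point rather than only the seizure limit
#' cycle.
#'
#' @param x0 Excitability value.
#' @param params Base parameters (x0 is overridden).
#' @return The equilibrium state vector `(x1, y1, x2, y2, z, g)`, or
#'   `NULL` when no up-branch equilibrium exists.
#' @export
up_state_equilibrium <- function(x0, params = epileptor_params()) {
  p <- params
  p$x0 <- x0
  x2_at <- function(z, g) {
    fx2 <- function(x2) -f2_epileptor(x2, p$a2) + x2 - x2^3 + p$Iext2 +
      0.002 * g - 0.3 * (z - 3.5)
    stats::uniroot(fx2, c(-3, 3), tol = 1e-12)$root
  }
  # up-branch x1 equation: y1 - f1 - z + Iext1 with
  # f1 = -(m - x2 + 0.6 (z-4)^2) x1
  Fx1 <- function(x1) {
    z <- 4 * (x1 - p$x0)
    x2 <- x2_at(z, 0.1 * x1)
    y1 <- p$c - p$d * x1^2
    y1 + (p$m - x2 + 0.6 * (z - 4)^2) * x1 - z + p$Iext1
  }
  if (Fx1(0) < 0) return(NULL)         # root would need x1 < 0: down branch
  # F turns negative quickly on the up branch (the -d*x1^2 term); find the
  # first sign change rather than assuming monotonicity
  hi <- NULL
  for (cand in seq(0.05, 1, by = 0.05)) {
    if (Fx1(cand) < 0) { hi <- cand; break }
  }
  if (is.null(hi)) return(NULL)
  x1 <- stats::uniroot(Fx1, c(0, hi), tol = 1e-12)$root
  z <- 4 * (x1 - p$x0)
  x2 <- x2_at(z, 0.1 * x1)
  c(x1 = x1, y1 = p$c - p$d * x1^2, x2 = x2,
    y2 = f2_epileptor(x2, p$a2), z = z, g = 0.1 * x1)
}

#' Locate the oscillation/up-state regime boundary
#'
#' Bisects the excitability at which the isolated Epileptor first
#' possesses an up-state equilibrium (the edge of the seizure-only
#' oscillatory regime), using [up_state_equilibrium()]. With default
#' parameters the boundary sits at -1.025: below it only the seizure
#' limit cycle exists; above it the up-state resting point exists. The
#' equilibrium is created weakly unstable and trajectories can keep
#' cycling slightly above the edge, so the boundary is located from the
#' equilibrium structure of the model rather than trajectory amplitude.
#'
#' @param lower,upper Bracketing excitabilities (no equilibrium at
#'   `lower`, equilibrium at `upper`).
#' @param resolution Bisection stops below this bracket width
#'   (default 0.005).
#' @param params Base parameters.
#' @return Midpoint of the final bracket.
#' @export
find_up_state_boundary <- function(lower = -1.2, upper = -0.8,
                                   resolution = 0.005,
                                   params = epileptor_params()) {
  has <- function(x0) !is.null(up_state_equilibrium(x0, params))
  if (has(lower) || !has(upper))
    stop("bracket does not straddle the equilibrium-existence edge")
  while (upper - lower > resolution) {
    mid <- (lower + upper) / 2
    if (has(mid)) upper <- mid else lower <- mid
  }
  (lower + upper) / 2
}

#' Locate a regime boundary of the isolated Epileptor by bisection
#'
#' Bisects the excitability `x0` between two values known to lie in
#' different regimes, using [classify_regime()] on noise-free simulations.
#' With default parameters the down-state/oscillation boundary sits near
#' -2.062 and the oscillation/up-state boundary near -1.025.
#'
#' @param lower,upper Bracketing excitabilities (different regimes).
#' @param resolution Bisection stops when the bracket is narrower than
#'   this (default 0.005).
#' @param ... Passed to [classify_regime()].
#' @return Midpoint of the final bracket.
#' @export
find_regime_boundary <- function(lower, upper, resolution = 0.005, ...) {
  cl <- classify_regime(lower, ...)
  cu <- classify_regime(upper, ...)
  if (cl == cu)
    stop("lower and upper excitability are in the same regime (", cl, ")")
  while (upper - lower > resolution) {
    mid <- (lower + upper) / 2
    if (classify_regime(mid, ...) == cl) lower <- mid else upper <- mid
  }
  (lower + upper) / 2
}
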