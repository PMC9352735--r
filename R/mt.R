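# Model area MT: speed- and direction-tuned motion filters with
# leaky-integrator dynamics and synaptic depression.

#' Sample the MT population parameters
#'
#' Builds the tuning parameters of the MT unit array: `resolution^2` retinal
#' positions x `n_dirs` preferred directions x `n_speeds` preferred-speed
#' channels. Preferred speeds are drawn uniformly within octave-spaced bins
#' (one bin per channel), the log-speed tuning bandwidth from a positive-
#' truncated normal, and the speed offset (which keeps the log finite at
#' zero speed) from an exponential distribution. Speed parameters are drawn
#' per (position, speed channel) and shared across the direction channels at
#' that site; direction preferences are evenly spaced.
#'
#' @param resolution Pixels per side of the flow grid.
#' @param n_speeds,n_dirs Number of speed and direction channels.
#' @param speed_bins Matrix (`n_speeds` x 2) of preferred-speed bin bounds,
#'   deg/s.
#' @param sigma_mean,sigma_sd Mean and SD of the bandwidth distribution, deg.
#' @param s0_mean Mean of the exponential speed-offset distribution, deg/s.
#' @param eta Von Mises direction-tuning shape parameter.
#' @param alpha Passive decay rate of MT activation.
#' @param tau Synaptic depression time-constant scale.
#' @param kappa Synaptic depression rate.
#' @param seed Integer seed; sampling is a pure function of it.
#'
#' @return An object of class `mt_params`.
#' @export
mt_params <- function(resolution = 64, n_speeds = 5, n_dirs = 24,
                      speed_bins = matrix(c(0.5, 2.0,
                                            2.0, 4.3,
                                            4.3, 7.6,
                                            7.6, 12.7,
                                            12.7, 32.0),
                                          ncol = 2, byrow = TRUE),
                      sigma_mean = 1.16, sigma_sd = 0.5, s0_mean = 0.25,
                      eta = 3, alpha = 1, tau = 0.1, kappa = 10,
                      seed = 1L) {
  stopifnot(nrow(speed_bins) == n_speeds, all(speed_bins[, 2] > speed_bins[, 1]))
  set.seed(seed)
  npos <- resolution^2
  v_pref <- vapply(seq_len(n_speeds), function(k) {
    stats::runif(npos, speed_bins[k, 1], speed_bins[k, 2])
  }, numeric(npos))
  sigma_v <- matrix(stats::rnorm(npos * n_speeds, sigma_mean, sigma_sd),
                    npos, n_speeds)
  while (any(bad <- sigma_v <= 0))    # bandwidth must be positive: redraw
    sigma_v[bad] <- stats::rnorm(sum(bad), sigma_mean, sigma_sd)
  s0 <- matrix(stats::rexp(npos * n_speeds, rate = 1 / s0_mean),
               npos, n_speeds)
  structure(
    list(resolution = as.integer(resolution),
         n_speeds = as.integer(n_speeds), n_dirs = as.integer(n_dirs),
         v_pref = v_pref, sigma_v = sigma_v, s0 = s0,
         preferred_dirs = (seq_len(n_dirs) - 1) * 360 / n_dirs,
         eta = eta, alpha = alpha, tau = tau, kappa = kappa,
         seed = as.integer(seed)),
    class = "mt_params")
}

#' Log-normal speed tuning curve
#'
#' `exp(-log((s + s0) / (v_pref + s0))^2 / (2 sigma_v^2))`: peaks at 1 when
#' the stimulus speed equals the preferred speed and falls off symmetrically
#' in log-speed.
#'
#' @param s Stimulus speed, deg/s (non-negative).
#' @param v_pref Preferred speed, deg/s.
#' @param s0 Non-negative offset preventing the log singularity at 0.
#' @param sigma_v Log-speed bandwidth.
#' @return Response in (0, 1].
#' @export
speed_tuning <- function(s, v_pref, s0, sigma_v) {
  exp(-log((s + s0) / (v_pref + s0))^2 / (2 * sigma_v^2))
}

#' Von Mises direction tuning curve
#'
#' `exp(eta * cos(theta - mu)) / exp(eta)`: peaks at 1 at the preferred
#' direction; `eta` sets the bandwidth.
#'
#' @param theta Stimulus direction, degrees (wraps).
#' @param mu Preferred direction, degrees.
#' @param eta Shape parameter.
#' @return Response in (0, 1].
#' @export
direction_tuning <- function(theta, mu, eta) {
  exp(eta * (cos((theta - mu) * pi / 180) - 1))
}

#' Net input to the MT population for one flow frame
#'
#' The drive to the unit tuned to speed channel `k` and direction `d` at
#' pixel (x, y) is the product of its speed and direction tuning curves
#' evaluated on the local flow vector. Pixels without a dot contribute zero
#' drive to every unit at that site.
#'
#' @param u,v Matrices (`resolution` x `resolution`) of flow components,
#'   deg/s.
#' @param mask Logical matrix of dot occupancy.
#' @param params An [mt_params()] object.
#' @return Array `resolution x resolution x n_dirs x n_speeds`.
#' @export
mt_net_input <- function(u, v, mask, params) {
  res <- params$resolution
  nd <- params$n_dirs
  ns <- params$n_speeds
  s <- sqrt(u^2 + v^2)
  theta <- atan2(v, u) * 180 / pi
  V <- array(0, c(res, res, nd))
  for (d in seq_len(nd))
    V[, , d] <- direction_tuning(theta, params$preferred_dirs[d], params$eta)
  m <- as.numeric(mask)
  I <- array(0, c(res, res, nd, ns))
  for (k in seq_len(ns)) {
    S <- speed_tuning(as.vector(s), params$v_pref[, k], params$s0[, k],
                      params$sigma_v[, k]) * m
    I[, , , k] <- V * as.vector(S)  # S recycles over the direction dimension
  }
  I
}

#' Initial MT dynamic state
#'
#' Activation starts at zero. Synaptic efficacy starts at 1 and, because its
#' dynamics are autonomous and every synapse starts fresh, remains identical
#' across units; it is therefore tracked as a single scalar.
#'
#' @param params An [mt_params()] object.
#' @return List with `m` (activation array) and `h` (scalar efficacy).
#' @export
mt_init_state <- function(params) {
  res <- params$resolution
  list(m = array(0, c(res, res, params$n_dirs, params$n_speeds)), h = 1)
}

#' One forward-Euler step of the MT dynamics
#'
#' Activation follows the shunting leaky integrator
#' `dm/dt = -alpha m + (1 - m) I`, which confines `m` to \[0, 1\] for
#' non-negative input. Synaptic efficacy follows
#' `dh/dt = tau (1 - h (1 + kappa h))`, decaying from 1 toward its
#' equilibrium `(sqrt(1 + 4 kappa) - 1) / (2 kappa)`.
#'
#' @param state State list from [mt_init_state()] or a previous step.
#' @param I Net input array from [mt_net_input()].
#' @param params An [mt_params()] object.
#' @param dt Euler step, model time units.
#' @return Updated state list.
#' @export
step_mt <- function(state, I, params, dt = 0.1) {
  m <- state$m + dt * (-params$alpha * state$m + (1 - state$m) * I)
  h <- state$h + dt * params$tau *
    (1 - state$h * (1 + params$kappa * state$h))
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("MT activation left [0, 1]: reduce the integration step")
  list(m = m, h = h)
}

# Advance the MT state by n Euler steps under constant input. The Euler
# recurrence for m is affine with fixed point I/(alpha + I) and contraction
# factor 1 - dt (alpha + I) per step, so the n-step iterate has a closed
# form; h is a scalar and is stepped directly.
mt_advance <- function(state, I, params, dt, n) {
  g <- 1 - dt * (params$alpha + I)
  mstar <- I / (params$alpha + I)
  m <- mstar + (state$m - mstar) * g^n
  h <- state$h
  for (s in seq_len(n))
    h <- h + dt * params$tau * (1 - h * (1 + params$kappa * h))
  list(m = m, h = h)
}

#' MT output signal
#'
#' The signal transmitted to MSTd is the activation scaled by the synaptic
#' efficacy, `O = h m`, implementing a compressive nonlinearity through
#' synaptic depression.
#'
#' @param state MT state list.
#' @return Array of the same shape as the activation.
#' @export
mt_output <- function(state) {
  state$h * state$m
}
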