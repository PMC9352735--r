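# The assembled encoder: MT population + MSTd template bank + dynamics.

#' Build the MT-MSTd encoder
#'
#' Samples the MT tuning parameters and the sparse MT-to-MSTd connectivity
#' and packages them with the template bank, smoothing kernels, and
#' integration settings. Construction is a pure function of `seed`.
#'
#' @param config A [camera_config()]; sets the flow grid resolution.
#' @param n_connections MT connections sampled per MSTd template.
#' @param com_n CoM grid side for the template bank.
#' @param n_spirality Spirality levels per ring arm.
#' @param b_mstd CoM distance falloff of connection weights.
#' @param dt Euler integration step, model time units.
#' @param steps_per_frame Integration steps taken per video frame.
#' @param seed Integer seed for all parameter sampling.
#'
#' @return An object of class `spiral_model`.
#' @export
spiral_model <- function(config = camera_config(), n_connections = 200,
                         com_n = 16, n_spirality = 21, b_mstd = 1e-3,
                         dt = 0.1, steps_per_frame = 10, seed = 1L) {
  mt <- mt_params(resolution = config$resolution, seed = derive_seed(seed, 1))
  bank <- spiral_bank(com_n = com_n, resolution = config$resolution,
                      n_spirality = n_spirality)
  conn <- sample_connections(bank, n_connections = n_connections,
                             n_dirs = mt$n_dirs, b_mstd = b_mstd,
                             seed = derive_seed(seed, 2))
  structure(
    list(config = config, mt = mt, bank = bank, conn = conn,
         kernels = mstd_kernels(bank),
         dt = dt, steps_per_frame = as.integer(steps_per_frame),
         alpha_1a = 1, alpha_1b = 1, alpha_c = 1, alpha_2 = 10, beta_2 = 3,
         seed = as.integer(seed)),
    class = "spiral_model")
}

#' @export
print.spiral_model <- function(x, ...) {
  cat(sprintf(
    "<spiral_model> %d MSTd units (%d patterns x %d CoM), %d connections/template, seed %d\n",
    x$bank$n_units, x$bank$n_patterns, x$bank$com_n^2,
    x$conn$n_connections, x$seed))
  invisible(x)
}

#' Encode a flow sequence into MSTd population activity
#'
#' Runs the MT and MSTd dynamics over the frames of a flow sequence and
#' returns the Layer-2 activation of every MSTd unit at the end of the final
#' frame -- the population vector the decoders consume. For each frame the
#' MT net input is held fixed while the MT state takes `steps_per_frame`
#' Euler steps; the resulting MT output drives the MSTd net input, which is
#' held fixed while the MSTd layers take `steps_per_frame` Euler steps.
#'
#' @param model A [spiral_model()].
#' @param flow A [simulate_flow()] result on the same grid.
#'
#' @return Numeric vector of length `model$bank$n_units`, in the unit order
#'   of `model$bank$units`.
#' @export
encode <- function(model, flow) {
  stopifnot(inherits(model, "spiral_model"), inherits(flow, "flow_sequence"))
  if (flow$config$resolution != model$config$resolution)
    stop("flow resolution does not match the model")
  mt_state <- mt_init_state(model$mt)
  ncom2 <- model$bank$com_n^2
  npat <- model$bank$n_patterns
  a <- matrix(0, ncom2, npat)
  b <- matrix(0, ncom2, npat)
  c_thr <- numeric(npat)
  z <- matrix(0, ncom2, npat)
  n_frames <- dim(flow$frames)[1]
  for (f in seq_len(n_frames)) {
    I <- mt_net_input(flow$frames[f, , , 1], flow$frames[f, , , 2],
                      flow$mask[f, , ], model$mt)
    mt_state <- mt_advance(mt_state, I, model$mt, model$dt,
                           model$steps_per_frame)
    R <- mstd_net_input(mt_output(mt_state), model$conn, model$bank)
    for (s in seq_len(model$steps_per_frame)) {
      a <- step_layer1a(a, R, model$dt, model$alpha_1a)
      J <- smooth_layer1b(a, model$kernels)
      b <- step_layer1b(b, J, model$dt, model$alpha_1b)
      c_thr <- step_threshold(c_thr, b, model$dt, model$alpha_c)
      z <- step_layer2(z, layer2_input(b, c_thr), model$dt,
                       model$alpha_2, model$beta_2)
    }
  }
  as.vector(z)
}

#' Encode every trial of a dataset specification
#'
#' Generates each trial's dot scene and flow sequence, encodes it, and
#' stacks the population vectors into a trials x units activation matrix.
#' Flow sequences are discarded after encoding, so memory stays flat in the
#' number of trials.
#'
#' @param model A [spiral_model()].
#' @param spec A `dataset_spec`.
#' @param verbose Print a progress line every 25 trials.
#'
#' @return Matrix `length(spec$trials) x n_units` of Layer-2 activations.
#' @export
encode_spec <- function(model, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- length(spec$trials)
  X <- matrix(0, n, model$bank$n_units)
  for (i in seq_len(n)) {
    trial <- spec$trials[[i]]
    flow <- simulate_flow(make_scene(trial, model$config), trial, model$config)
    X[i, ] <- encode(model, flow)
    if (verbose && i %% 25 == 0)
      message(sprintf("encoded %d/%d trials (%s)", i, n, spec$split))
  }
  X
}
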