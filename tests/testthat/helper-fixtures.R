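# Shared fixtures, built in code. Heavy objects are memoized so several
# test files can reuse one computation.

.fixtures <- new.env(parent = emptyenv())

memoize <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Small camera for cheap flow tests: quarter resolution, few dots.
small_camera <- function(n_dots = 300, n_frames = 4) {
  camera_config(resolution = 32, n_dots = n_dots, n_frames = n_frames)
}

# Finite-difference oracle for the flow equations: project a world-frame
# dot through the camera at t +/- delta and centrally difference the
# angular image position. Uses only the pose/projection geometry, not the
# analytic flow formula.
fd_flow_oracle <- function(trial, config, world_dot, delta) {
  proj <- function(t) {
    pose <- spiralpath:::camera_pose(trial, config, t)
    cam <- drop(t(spiralpath:::yaw_matrix(pose$psi)) %*% (world_dot - pose$pos))
    c(atan(cam[1] / cam[3]), atan(cam[2] / cam[3])) * 180 / pi
  }
  (proj(delta) - proj(-delta)) / (2 * delta)
}

# The default-scale encoder with a reduced connection count, reused by the
# MSTd and encode tests.
default_model <- function() {
  memoize("default_model", spiral_model(camera_config(), seed = 11L))
}

# The reduced-scale end-to-end experiment shared by the pipeline and
# acceptance tests: 90 training / 50 test trials, 50 connections per
# template, fixed master seed.
scaled_run <- function() {
  memoize("scaled_run",
          run_full_experiment(n_train = 90, n_test = 50, n_connections = 50,
                              master_seed = 101L, bootstrap_reps = 0))
}
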