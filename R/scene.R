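#' Random dot scene for a self-motion trial
#'
#' Places `config$n_dots` dots uniformly in the region of space visible to the
#' camera at the start of the trial. Ground scenes place dots on the plane one
#' camera-height below the eye, uniformly over the viewing-frustum footprint
#' between the valid depths; cloud scenes fill the frustum volume uniformly.
#' Positions are expressed in the camera frame at time zero (x right, y up,
#' z along the optical axis) and are reproducible from `trial$seed`.
#'
#' @param trial A [trial_params()] object.
#' @param config A [camera_config()] object.
#'
#' @return An object of class `dot_scene`: list with `dots` (n x 3 matrix of
#'   camera-frame coordinates, meters) and `kind`.
#' @export
make_scene <- function(trial, config = camera_config()) {
  stopifnot(inherits(trial, "trial_params"), inherits(config, "camera_config"))
  set.seed(trial$seed)
  dots <- draw_dots(config$n_dots, trial$scene_kind, config)
  structure(list(dots = dots, kind = trial$scene_kind), class = "dot_scene")
}

# Uniform draws from the visible region, in the current camera frame.
# Ground dots lie on y = -height; their depth lower bound is raised to
# height / tan(fov_v/2) so every dot starts inside the vertical FOV.
draw_dots <- function(n, kind, config) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  th <- tan(config$fov_h / 2 * pi / 180)
  tv <- tan(config$fov_v / 2 * pi / 180)
  if (kind == "ground") {
    zmin <- max(config$depth_min, config$height / tv)
    # footprint width grows linearly with depth: area-uniform => Z ~ sqrt law
    z <- sqrt(stats::runif(n, zmin^2, config$depth_max^2))
    x <- stats::runif(n, -1, 1) * z * th
    y <- rep(-config$height, n)
  } else {
    # frustum cross-section area grows as Z^2 => cube-root law
    z <- (stats::runif(n, config$depth_min^3, config$depth_max^3))^(1 / 3)
    x <- stats::runif(n, -1, 1) * z * th
    y <- stats::runif(n, -1, 1) * z * tv
  }
  cbind(x, y, z, deparse.level = 0)
}
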