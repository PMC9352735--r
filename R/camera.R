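#' Camera and simulation configuration
#'
#' Describes the simulated pinhole camera and the self-motion simulation it
#' records. Defaults correspond to the reference configuration used throughout
#' the package: a 90 x 90 degree field of view rendered on a 64 x 64 pixel
#' grid, eye height 1.61 m above the ground, forward speed 3 m/s, 2000 visible
#' dots kept within a 1-50 m depth range, and 10-frame sequences.
#'
#' @param fov_h,fov_v Horizontal and vertical field of view, degrees.
#' @param resolution Pixels per side of the square sampling grid.
#' @param height Camera height above the ground plane, meters.
#' @param speed Observer translation speed, m/s.
#' @param depth_min,depth_max Valid relative depth range for dots, meters.
#' @param n_dots Number of dots kept visible in every frame.
#' @param n_frames Number of frames per sequence.
#' @param frame_dt Time between frames, seconds.
#'
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(fov_h = 90, fov_v = 90, resolution = 64,
                          height = 1.61, speed = 3,
                          depth_min = 1, depth_max = 50,
                          n_dots = 2000, n_frames = 10,
                          frame_dt = 1 / 30) {
  stopifnot(fov_h > 0, fov_h < 180, fov_v > 0, fov_v < 180,
            resolution >= 2, height > 0, speed >= 0,
            depth_min > 0, depth_min < depth_max,
            n_dots > 0, n_frames >= 1, frame_dt > 0)
  structure(
    list(fov_h = fov_h, fov_v = fov_v, resolution = as.integer(resolution),
         height = height, speed = speed,
         depth_min = depth_min, depth_max = depth_max,
         n_dots = as.integer(n_dots), n_frames = as.integer(n_frames),
         frame_dt = frame_dt),
    class = "camera_config")
}

#' Parameters of a single self-motion trial
#'
#' A trial is a constant-speed traversal of a circular path. `path_sign = +1`
#' denotes clockwise travel seen from above (the observer turns rightward),
#' `-1` counterclockwise. The gaze offset is a fixed yaw of the camera
#' relative to the instantaneous path tangent; positive offsets rotate gaze
#' rightward. Straight paths are represented by `radius = Inf`.
#'
#' @param radius Path radius in meters (`Inf` for a straight path).
#' @param path_sign `+1` (CW) or `-1` (CCW).
#' @param gaze_offset Gaze yaw relative to the path tangent, degrees.
#' @param scene_kind `"ground"` (dots on the ground plane) or `"cloud"`
#'   (dots throughout the viewing frustum).
#' @param seed Integer seed controlling dot placement for this trial.
#'
#' @return An object of class `trial_params`. The derived path curvature
#'   `1/radius` (1/m, zero for straight paths) is stored in `$curvature`.
#' @export
trial_params <- function(radius, path_sign = 1, gaze_offset = 0,
                         scene_kind = c("ground", "cloud"), seed = 1L) {
  scene_kind <- match.arg(scene_kind)
  if (!is.numeric(radius) || length(radius) != 1 || is.na(radius) || radius <= 0)
    stop("`radius` must be a positive number or Inf")
  if (!path_sign %in% c(-1, 1)) stop("`path_sign` must be +1 or -1")
  if (abs(gaze_offset) > 90) stop("`gaze_offset` outside a plausible range")
  structure(
    list(radius = radius, path_sign = path_sign, gaze_offset = gaze_offset,
         curvature = if (is.finite(radius)) 1 / radius else 0,
         scene_kind = scene_kind, seed = as.integer(seed)),
    class = "trial_params")
}

#' Geometric sequence of path radii
#'
#' Generates the training radii by repeated multiplication: starting from
#' `r0`, each radius is `factor` times the previous one, keeping every value
#' not exceeding `r_max`. With the defaults (5 m start, factor 1.078, 200 m
#' cap) this yields 50 radii, concentrating samples at small radii where a
#' fixed radius step produces the largest change in path curvature.
#'
#' @param r0 Starting radius, meters.
#' @param factor Multiplicative growth factor (> 1).
#' @param r_max Upper bound on the generated radii, meters.
#'
#' @return Numeric vector of strictly increasing radii in `[r0, r_max]`.
#' @export
generate_radii <- function(r0 = 5, factor = 1.078, r_max = 200) {
  if (!is.numeric(r0) || r0 <= 0) stop("`r0` must be positive")
  if (!is.numeric(factor) || factor <= 1) stop("`factor` must exceed 1")
  if (r_max <= r0) stop("`r_max` must exceed `r0`")
  n <- floor(log(r_max / r0) / log(factor)) + 1
  r0 * factor^(seq_len(n) - 1)
}

#' Yaw rotation rate implied by a circular path
#'
#' An observer translating at `speed` along a circle of radius `radius`
#' rotates at `speed / radius` radians per second. Straight paths
#' (`radius = Inf`) rotate at 0.
#'
#' @param speed Translation speed, m/s.
#' @param radius Path radius, meters (`Inf` allowed).
#'
#' @return Rotation rate in degrees per second (unsigned).
#' @export
path_rotation_rate <- function(speed, radius) {
  if (!is.numeric(radius) || any(radius <= 0)) stop("`radius` must be positive or Inf")
  ifelse(is.finite(radius), speed / radius * 180 / pi, 0)
}

# Deterministic per-trial seed derived from a master seed and trial index.
# Linear congruential mix; kept strictly below 2^31 so it is a valid R integer.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}
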