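# Optic-flow simulation for circular self-motion with a yawed pinhole camera.
#
# Conventions (documented once, used everywhere):
#   * Camera frame: x right, y up, z along the optical axis.
#   * Image position is expressed through the tangent mapping: a dot at
#     camera coordinates (X, Y, Z) projects to tangent coordinates
#     (a, b) = (X/Z, Y/Z) and angular position (atan(a), atan(b)) in degrees.
#   * Flow components (u, v) are the time derivatives of the angular
#     position, deg/s; positive u is rightward, positive v upward.
#   * Yaw is positive rightward (seen from above). In this right-handed
#     frame a rightward yaw is a positive rotation about +y, so a CW path
#     (path_sign +1) has angular velocity +speed/radius about the up axis.

# Rotation taking camera-frame coordinates to world-frame for a camera at
# rightward yaw psi (radians).
yaw_matrix <- function(psi) {
  matrix(c(cos(psi), 0, -sin(psi),
           0, 1, 0,
           sin(psi), 0, cos(psi)), 3, 3, byrow = FALSE)
}

# Camera world position (x east, y up, z north) and yaw at time t for a trial.
# At t = 0 the camera sits at the origin with the path tangent along +z and
# gaze yawed by the gaze offset.
camera_pose <- function(trial, config, t) {
  gamma <- trial$gaze_offset * pi / 180
  if (is.finite(trial$radius)) {
    omega <- config$speed / trial$radius
    phi <- omega * t
    pos <- c(trial$path_sign * trial$radius * (1 - cos(phi)), 0,
             trial$radius * sin(phi))
    psi <- trial$path_sign * phi + gamma
  } else {
    pos <- c(0, 0, config$speed * t)
    psi <- gamma
  }
  list(pos = pos, psi = psi)
}

# Instantaneous rigid-motion flow for dots given in the camera frame.
# Returns per-dot (u, v) in deg/s. `omega_y` is the world/camera angular
# velocity about the +y axis (rad/s); `t_cam` the camera translational
# velocity in its own frame (m/s).
rigid_flow <- function(dots_cam, t_cam, omega_y) {
  X <- dots_cam[, 1]; Y <- dots_cam[, 2]; Z <- dots_cam[, 3]
  # relative dot velocity: V = -T - Omega x X, Omega = (0, omega_y, 0)
  Vx <- -t_cam[1] - omega_y * Z
  Vy <- -t_cam[2]
  Vz <- -t_cam[3] + omega_y * X
  a <- X / Z
  b <- Y / Z
  adot <- (Vx - a * Vz) / Z
  bdot <- (Vy - b * Vz) / Z
  cbind(u = adot / (1 + a^2) * 180 / pi,
        v = bdot / (1 + b^2) * 180 / pi)
}

# Map tangent coordinates to pixel indices on the square grid (1..res,
# increasing rightward/upward). Values outside the FOV return NA.
tangent_to_pixel <- function(a, tan_half, res) {
  p <- ceiling((a / tan_half + 1) * res / 2)
  p[p == 0] <- 1L            # exactly on the lower edge
  p[a < -tan_half | a > tan_half] <- NA
  p
}

#' Simulate an optic-flow sequence for one trial
#'
#' Moves the camera along the trial's circular path at the configured speed,
#' holding the gaze offset constant relative to the path tangent, and renders
#' the instantaneous angular motion of every visible dot on each frame. Dots
#' that leave the field of view or the valid depth range are replaced by
#' fresh uniform draws from the visible region so the visible count stays
#' constant. Each dot's flow vector is written to the nearest pixel of the
#' sampling grid; when two dots fall on one pixel the nearer dot wins.
#'
#' @param scene A [make_scene()] result consistent with `trial`.
#' @param trial A [trial_params()] object.
#' @param config A [camera_config()] object.
#'
#' @return An object of class `flow_sequence`: list with
#'   `frames` (`n_frames x resolution x resolution x 2` array of (u, v) in
#'   deg/s, indexed `[frame, x, y, component]` with x rightward, y upward),
#'   `mask` (logical array, `TRUE` where a dot occupies the pixel), and the
#'   `trial` and `config` used. Pixels without a dot carry zero flow.
#' @export
simulate_flow <- function(scene, trial, config = camera_config()) {
  stopifnot(inherits(scene, "dot_scene"), inherits(trial, "trial_params"),
            inherits(config, "camera_config"))
  if (scene$kind != trial$scene_kind)
    stop("scene kind does not match trial")
  res <- config$resolution
  th <- tan(config$fov_h / 2 * pi / 180)
  tv <- tan(config$fov_v / 2 * pi / 180)
  gamma <- trial$gaze_offset * pi / 180
  omega <- if (is.finite(trial$radius)) config$speed / trial$radius else 0
  t_cam <- config$speed * c(-sin(gamma), 0, cos(gamma))
  omega_y <- trial$path_sign * omega

  # dots tracked in the world frame; scene is given in the t=0 camera frame
  pose0 <- camera_pose(trial, config, 0)
  world <- scene$dots %*% t(yaw_matrix(pose0$psi))
  world <- sweep(world, 2, pose0$pos, "+")

  frames <- array(0, c(config$n_frames, res, res, 2))
  mask <- array(FALSE, c(config$n_frames, res, res))

  for (f in seq_len(config$n_frames)) {
    pose <- camera_pose(trial, config, (f - 1) * config$frame_dt)
    R <- yaw_matrix(pose$psi)
    cam <- sweep(world, 2, pose$pos, "-") %*% R   # R^T applied to rows

    bad <- which(cam[, 3] < config$depth_min | cam[, 3] > config$depth_max |
                   abs(cam[, 1]) > cam[, 3] * th |
                   abs(cam[, 2]) > cam[, 3] * tv)
    if (length(bad) > 0) {
      set.seed(derive_seed(trial$seed, f))
      fresh <- draw_dots(length(bad), trial$scene_kind, config)
      cam[bad, ] <- fresh
      world[bad, ] <- sweep(fresh %*% t(R), 2, pose$pos, "+")
    }

    uv <- rigid_flow(cam, t_cam, omega_y)
    px <- tangent_to_pixel(cam[, 1] / cam[, 3], th, res)
    py <- tangent_to_pixel(cam[, 2] / cam[, 3], tv, res)
    ok <- which(!is.na(px) & !is.na(py))
    # write far dots first so the nearest dot claims contested pixels
    ok <- ok[order(cam[ok, 3], decreasing = TRUE)]
    idx <- cbind(px[ok], py[ok])
    u_img <- matrix(0, res, res); v_img <- matrix(0, res, res)
    m_img <- matrix(FALSE, res, res)
    u_img[idx] <- uv[ok, 1]
    v_img[idx] <- uv[ok, 2]
    m_img[idx] <- TRUE
    frames[f, , , 1] <- u_img
    frames[f, , , 2] <- v_img
    mask[f, , ] <- m_img
  }
  structure(list(frames = frames, mask = mask, trial = trial, config = config),
            class = "flow_sequence")
}

#' Polar decomposition of a flow vector
#'
#' @param u,v Horizontal and vertical flow components, deg/s.
#' @return List with `speed` (deg/s) and `direction` (degrees in (-180, 180],
#'   from the two-argument arctangent; 0 for a zero vector by convention).
#' @export
flow_polar <- function(u, v) {
  list(speed = sqrt(u^2 + v^2), direction = atan2(v, u) * 180 / pi)
}
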