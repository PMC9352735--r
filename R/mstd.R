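# Model area MSTd: spiral-space template bank, sparse MT connectivity, and
# the three processing layers (temporal averaging, spatial/pattern smoothing,
# recurrent competition) whose final-frame Layer-2 activity is decoded.

#' Spiral-space template bank
#'
#' Defines the set of preferred optic-flow patterns and center-of-motion
#' (CoM) positions of the MSTd population. Patterns live on a closed ring of
#' length `4 * n_spirality` (84 by default) made of four arms: CCW full-field
#' spirals running from concentric to radial, CW full-field spirals from
#' radial to concentric, CW lower hemi-field spirals from concentric to
#' radial, and CCW hemi-field spirals from radial back to concentric.
#' Spirality 0 is radial expansion, 1 is concentric motion; the rotation sign
#' is +1 for CW and -1 for CCW patterns. Hemi-field ("ground flow") templates
#' carry no motion above their CoM. Each pattern is replicated over a regular
#' `com_n x com_n` grid of CoM positions spanning the pixel field.
#'
#' @param com_n CoM grid side (default 16, giving 256 CoM positions).
#' @param resolution Pixels per side of the flow grid the templates cover.
#' @param n_spirality Number of spirality levels per arm (default 21:
#'   0, 0.05, ..., 1).
#'
#' @return An object of class `spiral_bank`: pattern table (`$patterns`),
#'   CoM pixel coordinates (`$com_x`, `$com_y`), per-unit metadata
#'   (`$units`, one row per (pattern, CoM) unit in state order), and counts.
#' @export
spiral_bank <- function(com_n = 16, resolution = 64, n_spirality = 21) {
  lam <- seq(0, 1, length.out = n_spirality)
  patterns <- data.frame(
    pattern = seq_len(4 * n_spirality),
    lambda = c(rev(lam), lam, rev(lam), lam),
    zeta = rep(c(-1, 1, 1, -1), each = n_spirality),
    field = rep(c("full", "full", "hemi", "hemi"), each = n_spirality))
  com <- (seq_len(com_n) - 0.5) * (resolution / com_n) + 0.5
  n_pat <- nrow(patterns)
  tpl_pat <- rep(patterns$pattern, each = com_n^2)
  tpl_ci <- rep(rep(seq_len(com_n), com_n), n_pat)
  tpl_cj <- rep(rep(seq_len(com_n), each = com_n), n_pat)
  units <- data.frame(
    unit = seq_len(n_pat * com_n^2),
    pattern = tpl_pat,
    lambda = patterns$lambda[tpl_pat],
    zeta = patterns$zeta[tpl_pat],
    field = patterns$field[tpl_pat],
    com_i = tpl_ci, com_j = tpl_cj,
    com_x = com[tpl_ci], com_y = com[tpl_cj])
  units$abs_lambda <- abs(units$lambda)
  structure(
    list(patterns = patterns, com_x = com, com_y = com,
         com_n = as.integer(com_n), resolution = as.integer(resolution),
         n_patterns = n_pat, n_units = n_pat * com_n^2, units = units),
    class = "spiral_bank")
}

#' Template flow field of one MSTd unit
#'
#' The preferred flow at pixel (x, y) for a unit with CoM at pixel
#' coordinates (i, j) blends a radial field `(x - i, y - j)` and a circular
#' field `(y - j, -(x - i))`:
#' `(1 - lambda) radial + lambda zeta circular`. Hemi-field templates are
#' valid only at or below the CoM row.
#'
#' @param bank A [spiral_bank()].
#' @param pattern Pattern index on the ring.
#' @param ci,cj CoM grid indices.
#' @return List of `vx`, `vy` (resolution x resolution matrices, indexed
#'   `[x, y]` with y increasing upward) and logical `valid`.
#' @export
template_flow <- function(bank, pattern, ci, cj) {
  res <- bank$resolution
  p <- bank$patterns[pattern, ]
  dx <- matrix(seq_len(res) - bank$com_x[ci], res, res)
  dy <- matrix(seq_len(res) - bank$com_y[cj], res, res, byrow = TRUE)
  vx <- (1 - p$lambda) * dx + p$lambda * p$zeta * dy
  vy <- (1 - p$lambda) * dy - p$lambda * p$zeta * dx
  valid <- matrix(TRUE, res, res)
  if (p$field == "hemi")
    valid <- dy <= 0   # at or below the CoM row
  list(vx = vx, vy = vy, valid = valid)
}

# Assign flow angles (degrees) to one of n_dirs uniform wrapped bins
# centered on the evenly spaced preferred directions 0, 360/n_dirs, ...
direction_bin <- function(angle_deg, n_dirs) {
  step <- 360 / n_dirs
  (((round(angle_deg / step) %% n_dirs) + n_dirs) %% n_dirs) + 1
}

#' Sample sparse MT-to-MSTd connections
#'
#' Each (pattern, CoM) template receives `n_connections` sampled MT
#' connections: spatial locations drawn uniformly from the template's valid
#' region (without replacement where possible; hemi-field templates near the
#' bottom of the CoM grid have fewer valid pixels than connections and are
#' sampled with replacement) and a direction channel drawn uniformly from
#' the `n_dirs` preferred directions. A connection contributes only if its
#' sampled direction matches the template's flow-angle bin at that location;
#' contributing connections are weighted by a Gaussian falloff
#' `exp(-b ((x-i)^2 + (y-j)^2))` in distance from the CoM and normalized by
#' the connection count and the pooled-cell count (`resolution^2`).
#'
#' @param bank A [spiral_bank()].
#' @param n_connections Connections per template (default 200).
#' @param n_dirs Number of MT direction channels.
#' @param b_mstd CoM distance-falloff rate (1/pixel^2).
#' @param seed Integer seed; sampling is a pure function of it.
#'
#' @return An object of class `mstd_connectivity`: sampled index matrices
#'   `$x`, `$y`, `$d` (`n_connections` x `n_units`), and the precomputed
#'   sparse weight matrix `$A` (`n_units` x `resolution^2 * n_dirs`) used to
#'   evaluate the MSTd net input.
#' @export
sample_connections <- function(bank, n_connections = 200, n_dirs = 24,
                               b_mstd = 1e-3, seed = 1L) {
  set.seed(seed)
  res <- bank$resolution
  n_units <- bank$n_units
  N <- as.integer(n_connections)
  units <- bank$units

  # valid flat pixel indices for hemi templates are a contiguous prefix
  # (x varies fastest), so sampling reduces to sample.int on a count
  ymax <- ifelse(units$field == "hemi", floor(units$com_y), res)
  n_valid <- res * ymax
  loc <- matrix(0L, N, n_units)
  for (t in seq_len(n_units))
    loc[, t] <- sample.int(n_valid[t], N, replace = n_valid[t] < N)
  d <- matrix(sample.int(n_dirs, N * n_units, replace = TRUE), N, n_units)

  x <- ((loc - 1L) %% res) + 1L
  y <- ((loc - 1L) %/% res) + 1L
  dx <- x - rep(units$com_x, each = N)
  dy <- y - rep(units$com_y, each = N)
  lam <- rep(units$lambda, each = N)
  zet <- rep(units$zeta, each = N)
  vx <- (1 - lam) * dx + lam * zet * dy
  vy <- (1 - lam) * dy - lam * zet * dx
  tb <- direction_bin(atan2(vy, vx) * 180 / pi, n_dirs)
  w <- exp(-b_mstd * (dx^2 + dy^2)) * (tb == as.vector(d)) / (N * res^2)

  nz <- which(w > 0)
  A <- Matrix::sparseMatrix(
    i = rep(seq_len(n_units), each = N)[nz],
    j = (x + res * (y - 1L) + res^2 * (as.vector(d) - 1L))[nz],
    x = w[nz], dims = c(n_units, res^2 * n_dirs))
  structure(
    list(A = A, x = x, y = y, d = d, template_bin = matrix(tb, N, n_units),
         n_connections = N, n_dirs = as.integer(n_dirs), b_mstd = b_mstd,
         seed = as.integer(seed)),
    class = "mstd_connectivity")
}

#' MSTd net input from the MT output
#'
#' For each (pattern, CoM) unit, sums the direction-template-matched,
#' CoM-distance-weighted MT output over the unit's sampled connections and
#' the speed channels. At every sampled site the MT output is first divided
#' by the maximum output across direction channels at that (speed, x, y), so
#' dominant local motions contribute comparably across the visual field;
#' sites where that maximum is zero (no dot) contribute nothing.
#'
#' @param O MT output array (`res x res x n_dirs x n_speeds`).
#' @param conn An [sample_connections()] result.
#' @param bank The [spiral_bank()] the connectivity was built for.
#' @return Matrix `com_n^2 x n_patterns` of net inputs (state layout).
#' @export
mstd_net_input <- function(O, conn, bank) {
  dims <- dim(O)
  res2 <- dims[1] * dims[2]
  nd <- dims[3]
  ns <- dims[4]
  A3 <- array(O, c(res2, nd, ns))
  mx <- A3[, 1, ]
  for (dd in seq_len(nd)[-1]) mx <- pmax(mx, A3[, dd, ])
  if (ns == 1) mx <- matrix(mx, res2, 1)
  zero <- mx == 0
  Ot <- array(0, c(res2, nd, ns))
  for (dd in seq_len(nd)) {
    sl <- A3[, dd, ] / mx
    sl[zero] <- 0
    Ot[, dd, ] <- sl
  }
  dim(Ot) <- c(res2 * nd, ns)
  R <- Matrix::rowSums(conn$A %*% Ot)
  matrix(R, bank$com_n^2, bank$n_patterns)
}

#' Smoothing kernels for MSTd Layer 1b
#'
#' Layer 1b pools activity across neighboring CoM positions (truncated 2D
#' Gaussian on the CoM grid, renormalized to unit mass at every position so
#' constant fields pass unchanged) and across neighboring patterns on the
#' closed spiral-space ring (truncated 1D Gaussian, wrapped).
#'
#' @param bank A [spiral_bank()].
#' @param sigma_com 2D kernel standard deviations (CoM grid units).
#' @param radius_com 2D kernel truncation radius (taps at offsets
#'   `-radius_com ... radius_com`).
#' @param sigma_pat 1D pattern kernel standard deviation.
#' @param radius_pat 1D kernel truncation radius.
#' @return List of row-stochastic matrices `K2` (`com_n^2` square) and
#'   `K1` (`n_patterns` square, circulant).
#' @export
mstd_kernels <- function(bank, sigma_com = c(5, 5), radius_com = 4,
                         sigma_pat = 1.5, radius_pat = 3) {
  n <- bank$com_n
  ci <- rep(seq_len(n), n)
  cj <- rep(seq_len(n), each = n)
  di <- outer(ci, ci, "-")
  dj <- outer(cj, cj, "-")
  K2 <- exp(-((di / (sqrt(2) * sigma_com[1]))^2 +
                (dj / (sqrt(2) * sigma_com[2]))^2))
  K2[abs(di) > radius_com | abs(dj) > radius_com] <- 0
  K2 <- K2 / rowSums(K2)

  np <- bank$n_patterns
  p <- seq_len(np)
  dp <- outer(p, p, "-")
  dp <- pmin(abs(dp), np - abs(dp))   # wrapped ring distance
  K1 <- exp(-(dp / (sqrt(2) * sigma_pat))^2)
  K1[dp > radius_pat] <- 0
  K1 <- K1 / rowSums(K1)
  list(K2 = K2, K1 = K1)
}

#' Layer 1b pooling of Layer 1a activity
#'
#' @param a Layer 1a activation matrix (`com_n^2 x n_patterns`).
#' @param kernels A [mstd_kernels()] result.
#' @return Smoothed drive `J`, same shape.
#' @export
smooth_layer1b <- function(a, kernels) {
  tcrossprod(kernels$K2 %*% a, kernels$K1)
}

#' Shunting layer updates (Euler steps)
#'
#' Layers 1a and 1b integrate their drive through the shunting form
#' `dx/dt = -alpha x + (1 - x) input`, which keeps activations in \[0, 1\]
#' for non-negative input with equilibrium `input / (alpha + input)`.
#'
#' @param a,b Current activation matrices.
#' @param R,J Drive matrices (net input / pooled Layer-1a activity).
#' @param dt Euler step.
#' @param alpha Passive decay rate.
#' @return Updated activation matrix.
#' @export
step_layer1a <- function(a, R, dt = 0.1, alpha = 1) {
  a + dt * (-alpha * a + (1 - a) * R)
}

#' @rdname step_layer1a
#' @export
step_layer1b <- function(b, J, dt = 0.1, alpha = 1) {
  b + dt * (-alpha * b + (1 - b) * J)
}

#' Adaptive per-pattern threshold and Layer-2 input
#'
#' The threshold for pattern `psi` integrates the mean Layer-1b activation
#' over that pattern's CoM grid (`dc/dt = -alpha c + (1 - c) mean(b)`); the
#' Layer-2 input is the half-wave-rectified difference `max(b - c, 0)`,
#' suppressing units weaker than the recent pattern average.
#'
#' @param c_thr Threshold vector (length `n_patterns`).
#' @param b Layer 1b activation matrix.
#' @param dt Euler step.
#' @param alpha Passive decay rate.
#' @return Updated threshold vector / input matrix.
#' @export
step_threshold <- function(c_thr, b, dt = 0.1, alpha = 1) {
  mb <- colMeans(b)
  c_thr + dt * (-alpha * c_thr + (1 - c_thr) * mb)
}

#' @rdname step_threshold
#' @export
layer2_input <- function(b, c_thr) {
  pmax(sweep(b, 2, c_thr, "-"), 0)
}

#' Layer 2 recurrent competitive field (Euler step)
#'
#' Units integrate the thresholded drive in an on-center/off-surround
#' shunting network with the contrast-enhancing feedback transfer function
#' `f(w) = w^2`. Within a pattern, units excite themselves through `f` and
#' inhibit each other; a second set of recurrent terms built from the
#' unit-wise rectified discrepancy between feedforward input and activation,
#' `D = max(I - z, 0)`, and its layer-wide total `E` feeds each unit in
#' proportion to its unmet input while inhibiting it by the unmet input of
#' units tuned to other patterns, so the layer as a whole tends to conserve
#' total activation. (Written with the operands the other way around the
#' discrepancy terms vanish at rest and the layer could never leave the
#' silent state.) Activations remain in `[0, beta]`.
#'
#' @param z Layer 2 activation matrix (`com_n^2 x n_patterns`).
#' @param I2 Thresholded input from [layer2_input()].
#' @param dt Euler step.
#' @param alpha Passive decay rate.
#' @param beta Excitatory upper bound.
#' @return Updated activation matrix.
#' @export
step_layer2 <- function(z, I2, dt = 0.1, alpha = 10, beta = 3) {
  f <- z^2
  D <- pmax(I2 - z, 0)
  E <- sum(D)
  same_f <- sweep(-f, 2, colSums(f), "+")      # f-sum over same-pattern others
  other_D <- E - rep(colSums(D), each = nrow(z))  # D-sum over other patterns
  zn <- z + dt * (-alpha * z + (beta - z) * (f + D * E) -
                    z * (same_f + other_D))
  if (any(zn < -1e-8) || any(zn > beta + 1e-8))
    stop("Layer 2 activation left [0, beta]: reduce the integration step")
  zn
}
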