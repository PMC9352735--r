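# Dataset specifications: which trials make up the training, test, and
# human-comparison condition splits, with reproducible per-trial seeds.

new_dataset_spec <- function(trials, split, master_seed) {
  structure(list(trials = trials, split = split,
                 master_seed = as.integer(master_seed)),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("<dataset_spec> split = %s, %d trials, master seed %d\n",
              x$split, length(x$trials), x$master_seed))
  invisible(x)
}

#' Training dataset specification
#'
#' The training design crosses a regular 9-point grid of gaze offsets over
#' \[-35, 35\] degrees with the geometric sequence of path radii from
#' [generate_radii()] and both path signs: 9 x 50 x 2 = 900 trials.
#'
#' @param master_seed Integer seed from which every trial's dot-placement
#'   seed is derived.
#' @param scene_kind `"ground"` or `"cloud"`.
#' @param radii Optional radius vector (defaults to the 50-radius sequence).
#' @param gaze_grid Optional gaze-offset grid in degrees.
#'
#' @return A `dataset_spec` with `split = "train"`.
#' @export
build_training_spec <- function(master_seed = 1L, scene_kind = "ground",
                                radii = generate_radii(),
                                gaze_grid = seq(-35, 35, length.out = 9)) {
  grid <- expand.grid(gaze = gaze_grid, radius = radii, sign = c(1, -1),
                      KEEP.OUT.ATTRS = FALSE)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    trial_params(radius = grid$radius[i], path_sign = grid$sign[i],
                 gaze_offset = grid$gaze[i], scene_kind = scene_kind,
                 seed = derive_seed(master_seed, i))
  })
  new_dataset_spec(trials, "train", master_seed)
}

#' Sample path radii from a density estimate of the training radii
#'
#' Fits a Gaussian kernel density estimate (Silverman's bandwidth rule) to
#' the training radii and samples from it, so small radii -- where curvature
#' varies fastest -- are drawn more often. Draws falling outside the training
#' range are redrawn, and accepted values are discretized to 0.1 m.
#'
#' @param n Number of radii to draw.
#' @param train_radii Radii the density is fitted to.
#' @param range Admissible radius range, meters.
#'
#' @return Numeric vector of `n` radii, multiples of 0.1 m within `range`.
#' @export
sample_path_radii <- function(n, train_radii = generate_radii(),
                              range = c(5, 200)) {
  bw <- stats::bw.nrd0(train_radii)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- sample(train_radii, n - length(out), replace = TRUE) +
      stats::rnorm(n - length(out), 0, bw)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  round(out * 10) / 10
}

#' Test dataset specification
#'
#' Half of the trials are clockwise paths with radii sampled from the
#' kernel-density estimate of the training radii ([sample_path_radii()]) and
#' gaze offsets drawn uniformly from \[-35, 35\] degrees; the other half are
#' the mirror versions of those trials (path sign flipped, gaze offset
#' negated, same radius) with independent dot placement.
#'
#' @param n Total trial count (even); default 500.
#' @param master_seed Integer master seed.
#' @param scene_kind `"ground"` or `"cloud"`.
#'
#' @return A `dataset_spec` with `split = "test"`.
#' @export
build_test_spec <- function(n = 500, master_seed = 2L, scene_kind = "ground") {
  if (n %% 2 != 0) stop("`n` must be even (trials come in CW/CCW pairs)")
  half <- n / 2
  set.seed(master_seed)
  radii <- sample_path_radii(half)
  gaze <- stats::runif(half, -35, 35)
  trials <- vector("list", n)
  for (i in seq_len(half)) {
    trials[[i]] <- trial_params(radius = radii[i], path_sign = 1,
                                gaze_offset = gaze[i], scene_kind = scene_kind,
                                seed = derive_seed(master_seed, i))
    trials[[half + i]] <- trial_params(radius = radii[i], path_sign = -1,
                                       gaze_offset = -gaze[i],
                                       scene_kind = scene_kind,
                                       seed = derive_seed(master_seed, half + i))
  }
  new_dataset_spec(trials, "test", master_seed)
}

#' Gaze-along-heading condition specification
#'
#' Sixty ground-plane trials emulating the psychophysical condition in which
#' gaze is locked to the instantaneous heading: gaze offset 0, path radii of
#' 28, 38, and 58 m, 20 dot-placement repetitions per radius.
#'
#' @param master_seed Integer master seed.
#' @param radii Condition radii, meters.
#' @param n_reps Repetitions per radius (only dot placement varies).
#'
#' @return A `dataset_spec` with `split = "li_cheng"`.
#' @export
build_li_cheng_spec <- function(master_seed = 3L, radii = c(28, 38, 58),
                                n_reps = 20) {
  grid <- expand.grid(rep = seq_len(n_reps), radius = radii,
                      KEEP.OUT.ATTRS = FALSE)
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    trial_params(radius = grid$radius[i], path_sign = 1, gaze_offset = 0,
                 scene_kind = "ground", seed = derive_seed(master_seed, i))
  })
  new_dataset_spec(trials, "li_cheng", master_seed)
}

#' Tabulate the trials of a dataset specification
#'
#' @param spec A `dataset_spec`.
#' @return A data frame with one row per trial: radius, curvature, path sign,
#'   gaze offset, scene kind, and seed.
#' @export
spec_table <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  data.frame(
    radius = vapply(spec$trials, `[[`, numeric(1), "radius"),
    curvature = vapply(spec$trials, `[[`, numeric(1), "curvature"),
    path_sign = vapply(spec$trials, `[[`, numeric(1), "path_sign"),
    gaze_offset = vapply(spec$trials, `[[`, numeric(1), "gaze_offset"),
    scene_kind = vapply(spec$trials, `[[`, character(1), "scene_kind"),
    seed = vapply(spec$trials, `[[`, integer(1), "seed"))
}
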