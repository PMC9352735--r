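# Accuracy metrics, model comparison, and tuning summaries.

#' Mean absolute error
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @return Mean of `|estimate - truth|`.
#' @export
mae <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) > 0)
  mean(abs(estimate - truth))
}

#' Visual angle of a circular path at a fixed distance
#'
#' For an observer on a circular path of curvature `kappa` (1/m), the point
#' of the path at chord distance `d` meters lies at bearing
#' `sign * asin(d kappa / 2)` from the current gaze line (inscribed-angle
#' identity for a circle through the observer tangent to the gaze line).
#'
#' @param curvature Path curvature, 1/m (0 for a straight path).
#' @param path_sign `+1` CW / `-1` CCW.
#' @param distance Evaluation distance, meters.
#' @return Signed visual angle, degrees.
#' @export
path_angle <- function(curvature, path_sign = 1, distance = 10) {
  x <- distance * curvature / 2
  if (any(abs(x) > 1))
    stop("distance exceeds the path diameter: visual angle undefined")
  path_sign * asin(x) * 180 / pi
}

#' Path error between true and estimated circular paths
#'
#' The absolute (or signed) difference in the visual angle subtended by the
#' true and estimated paths at a fixed distance from the observer. Small
#' values mean the two paths nearly coincide from the observer's vantage
#' point. In the signed variant the error is expressed in the direction of
#' the true turn, so a positive value means curvature overestimation.
#'
#' @param true_curv,est_curv Curvatures, 1/m.
#' @param true_sign,est_sign Path signs.
#' @param distance Evaluation distance, meters (default 10).
#' @param signed Return signed errors instead of magnitudes.
#' @return Per-trial path error, degrees.
#' @export
path_error <- function(true_curv, true_sign, est_curv, est_sign,
                       distance = 10, signed = FALSE) {
  theta_true <- path_angle(true_curv, true_sign, distance)
  theta_est <- path_angle(est_curv, est_sign, distance)
  if (signed) true_sign * (theta_est - theta_true)
  else abs(theta_est - theta_true)
}

#' Akaike information criterion for a least-squares fit
#'
#' Gaussian-likelihood form `n log(rss / n) + 2 k`, where `k` counts the
#' free parameters (nonzero weights plus the intercept).
#'
#' @param n Number of observations.
#' @param rss Residual sum of squares (> 0).
#' @param k Number of free parameters.
#' @return AIC value.
#' @export
aic_ls <- function(n, rss, k) {
  stopifnot(n > 0, k >= 0)
  if (rss <= 0) stop("zero residual sum of squares: AIC undefined")
  n * log(rss / n) + 2 * k
}

#' Bootstrap distribution of the test MAE of a lasso decoder
#'
#' Repeatedly refits the decoder on training sets resampled with replacement
#' (preserving the sample count) and records the resulting test MAE,
#' quantifying the sensitivity of the reported error to the particular
#' stimuli included in the fit.
#'
#' @param X_train,y_train Training activations and target.
#' @param X_test,y_test Held-out activations and target.
#' @param unit_mask Logical eligible-unit mask.
#' @param reps Number of bootstrap resamples.
#' @param seed Seed for the resampling.
#' @param folds CV folds used inside each refit.
#' @param max_support Optional support cap (support-limited decoder).
#' @return List with `mean`, `sd`, and the per-rep `values`.
#' @export
bootstrap_mae <- function(X_train, y_train, X_test, y_test,
                          unit_mask = NULL, reps = 50, seed = 1L,
                          folds = 5, max_support = Inf) {
  stopifnot(reps >= 2)
  set.seed(seed)
  idx_list <- replicate(reps, sample.int(nrow(X_train), replace = TRUE),
                        simplify = FALSE)
  values <- vapply(seq_len(reps), function(r) {
    idx <- idx_list[[r]]
    fit <- fit_lasso(X_train[idx, , drop = FALSE], y_train[idx],
                     unit_mask = unit_mask, folds = folds,
                     seed = derive_seed(seed, r), max_support = max_support)
    mae(y_test, predict(fit, X_test))
  }, numeric(1))
  list(mean = mean(values), sd = stats::sd(values), values = values)
}

#' Pattern- and position-tuning summary of a fitted decoder
#'
#' Groups the decoder's nonzero weights by the absolute spirality of the
#' units carrying them (CW and CCW pool together) and reports each group's
#' share of the total absolute regression weight and its unit count, plus a
#' histogram of the included units' preferred-CoM eccentricity in three
#' concentric square bands of the CoM grid (center 4x4 block, middle ring,
#' outer ring).
#'
#' @param model A fitted `decoder_model`.
#' @param units Unit metadata (`bank$units`).
#' @return List with `weight_share` (data frame: `abs_lambda`, `share`,
#'   `n_units`) and `com_counts` (data frame: `band`, `count`).
#' @export
tuning_summary <- function(model, units) {
  w <- model$weights
  if (all(w == 0)) stop("decoder has no nonzero weights to summarize")
  inc <- w != 0
  total <- sum(abs(w))
  lam_levels <- sort(unique(units$abs_lambda))
  share <- vapply(lam_levels, function(l)
    sum(abs(w[inc & units$abs_lambda == l])) / total, numeric(1))
  n_units <- vapply(lam_levels, function(l)
    sum(inc & units$abs_lambda == l), integer(1))
  com_n <- max(units$com_i)
  ctr <- (com_n + 1) / 2
  ecc <- pmax(abs(units$com_i - ctr), abs(units$com_j - ctr))
  # bands: center 4x4 block, surrounding ring out to 10x10, remainder
  band <- cut(ecc, c(-Inf, com_n / 8 - 0.5, com_n * 5 / 16 - 0.5, Inf),
              labels = c("center", "middle", "outer"))
  list(
    weight_share = data.frame(abs_lambda = lam_levels, share = share,
                              n_units = n_units),
    com_counts = data.frame(band = levels(band),
                            count = as.integer(table(band[inc]))))
}
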