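# End-to-end pipeline: generate datasets, encode, fit every decoding model,
# and evaluate on the held-out split.

# Decoded curvature can stray outside the range for which the 10 m path
# angle exists (paths tighter than the evaluation chord); such estimates are
# reported at the limiting 90-degree angle.
clamp_curvature <- function(est, distance = 10) {
  pmin(pmax(est, -2 / distance), 2 / distance)
}

#' Run the full encoder-decoder experiment
#'
#' Generates a training and a test dataset, encodes both with a freshly
#' sampled MT-MSTd model, fits the gaze-offset and path-curvature lasso
#' decoders and path-sign classifiers for each requested sub-population
#' (the support-limited full model is capped at the radial-only support),
#' and evaluates everything on the test split. Defaults reproduce the
#' reference configuration: 900 training and 500 test trials over a ground
#' plane, 200 connections per template, and the 21,504-unit bank.
#'
#' @param n_train,n_test Trial counts for the two splits.
#' @param n_connections MT connections per MSTd template.
#' @param scene_kind `"ground"` or `"cloud"`.
#' @param camera A [camera_config()].
#' @param master_seed Single seed driving dataset sampling, model
#'   construction, CV folds, and bootstraps.
#' @param folds Cross-validation folds for the lasso.
#' @param populations Sub-population models to fit (see [apply_filter()]).
#' @param bootstrap_reps If > 0, bootstrap the test MAE of every regression
#'   decoder this many times (the reference analysis uses 50).
#' @param keep_activations Retain the activation matrices in the result
#'   (needed by [run_burlingham()] and [bootstrap_mae()] afterwards).
#' @param verbose Print progress messages.
#'
#' @return An object of class `experiment_result`: the `model`, dataset
#'   specs, fitted `decoders` (nested list: target, then population), a tidy
#'   `metrics` data frame (one row per population x target with test MAE,
#'   path error at 10 m, sign error rate, support size, and AIC), tuning
#'   summaries for the full-model decoders, and (optionally) the activation
#'   matrices `X_train` / `X_test`.
#' @export
run_full_experiment <- function(n_train = 900, n_test = 500,
                                n_connections = 200,
                                scene_kind = "ground",
                                camera = camera_config(),
                                master_seed = 1L, folds = 5,
                                populations = c("Full", "FullLimited",
                                                "RadialOnly", "LowestThird",
                                                "MiddleThird", "UpperThird",
                                                "ConcentricOnly"),
                                bootstrap_reps = 0,
                                keep_activations = TRUE,
                                verbose = FALSE) {
  if (n_train %% 18 != 0)
    stop("`n_train` must be a multiple of 18 (9 gaze offsets x CW/CCW pairs)")
  if ("FullLimited" %in% populations && !"RadialOnly" %in% populations)
    stop("the support-limited model needs the radial-only support size")
  radii <- generate_radii()
  n_radii <- n_train / 18
  train_spec <- if (n_radii == length(radii))
    build_training_spec(derive_seed(master_seed, 1), scene_kind)
  else  # reduced designs subsample the radius ladder, keep the gaze grid
    build_training_spec(derive_seed(master_seed, 1), scene_kind,
                        radii = radii[unique(round(seq(1, length(radii),
                                                       length.out = n_radii)))])
  test_spec <- build_test_spec(n_test, derive_seed(master_seed, 2),
                               scene_kind)

  model <- spiral_model(camera, n_connections = n_connections,
                        seed = derive_seed(master_seed, 3))
  if (verbose) message("encoding training split...")
  X_train <- encode_spec(model, train_spec, verbose)
  if (verbose) message("encoding test split...")
  X_test <- encode_spec(model, test_spec, verbose)

  tr <- spec_table(train_spec)
  te <- spec_table(test_spec)
  strata <- interaction(tr$path_sign,
                        cut(tr$radius, unique(stats::quantile(tr$radius)),
                            include.lowest = TRUE))
  units <- model$bank$units
  masks <- lapply(populations, function(p) apply_filter(units, p))
  names(masks) <- populations

  targets <- list(gaze_offset = tr$gaze_offset, curvature = tr$curvature)
  truth <- list(gaze_offset = te$gaze_offset, curvature = te$curvature)
  decoders <- list()
  sign_models <- list()
  rows <- list()
  for (tg in names(targets)) {
    decoders[[tg]] <- list()
    # FullLimited is capped at the radial-only support, so it is fit last
    fit_order <- c(setdiff(populations, "FullLimited"),
                   intersect("FullLimited", populations))
    for (p in fit_order) {
      if (verbose) message(sprintf("fitting %s / %s", tg, p))
      seed_fit <- derive_seed(master_seed, 100 + match(p, populations) * 10 +
                                match(tg, names(targets)))
      fit <- if (p == "FullLimited") {
        fit_lasso_limited(
          X_train, targets[[tg]],
          max_support = max(1, decoders[[tg]][["RadialOnly"]]$support_size),
          unit_mask = masks[[p]], mask_name = p,
          folds = folds, seed = seed_fit, strata = strata)
      } else {
        fit_lasso(X_train, targets[[tg]], unit_mask = masks[[p]],
                  mask_name = p, folds = folds, seed = seed_fit,
                  strata = strata)
      }
      fit$target <- tg
      decoders[[tg]][[p]] <- fit
    }
  }
  for (p in populations) {
    sign_models[[p]] <- if (p == "FullLimited") sign_models[["Full"]] else
      fit_sign_classifier(X_train, tr$path_sign, unit_mask = masks[[p]],
                          mask_name = p,
                          seed = derive_seed(master_seed, 300))
  }

  for (p in populations) {
    sign_pred <- predict(sign_models[[p]], X_test)
    sign_err <- mean(sign_pred != te$path_sign)
    for (tg in names(targets)) {
      fit <- decoders[[tg]][[p]]
      est <- predict(fit, X_test)
      est_train <- predict(fit, X_train)
      rss <- sum((est_train - targets[[tg]])^2)
      pe <- if (tg == "curvature")
        mean(path_error(te$curvature, te$path_sign,
                        clamp_curvature(est), sign_pred)) else NA
      boot <- if (bootstrap_reps > 0) {
        bootstrap_mae(X_train, targets[[tg]], X_test, truth[[tg]],
                      unit_mask = masks[[p]], reps = bootstrap_reps,
                      seed = derive_seed(master_seed, 400 +
                                           match(p, populations)),
                      folds = folds,
                      max_support = if (p == "FullLimited")
                        max(1, decoders[[tg]][["RadialOnly"]]$support_size)
                      else Inf)
      } else list(mean = NA_real_, sd = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        population = p, target = tg,
        mae = mae(truth[[tg]], est),
        path_error_deg = pe,
        sign_error_rate = sign_err,
        support_size = fit$support_size,
        eligible_units = sum(masks[[p]]),
        aic = if (rss > 0) aic_ls(n_train, rss, fit$support_size + 1) else NA,
        boot_mean = boot$mean, boot_sd = boot$sd)
    }
  }
  metrics <- do.call(rbind, rows)

  tuning <- lapply(decoders, function(d)
    tryCatch(tuning_summary(d[["Full"]], units), error = function(e) NULL))

  structure(
    list(model = model, train_spec = train_spec, test_spec = test_spec,
         decoders = decoders, sign_models = sign_models, masks = masks,
         metrics = metrics, tuning = tuning,
         X_train = if (keep_activations) X_train,
         X_test = if (keep_activations) X_test,
         master_seed = master_seed),
    class = "experiment_result")
}

#' Gaze-along-heading condition analysis
#'
#' Encodes the 0-degree-gaze condition trials (path radii 28, 38, 58 m by
#' default) with the experiment's model and applies the previously fitted
#' curvature decoders and sign classifiers. Reports the signed path error at
#' 10 m per trial -- positive values mean the decoded path overestimates the
#' true curvature -- and its mean per radius and population.
#'
#' @param result An [run_full_experiment()] result.
#' @param populations Populations to evaluate (default Full and RadialOnly).
#' @param master_seed Seed for the condition's dot placement.
#' @return List with per-trial errors (`trials`) and the per-radius summary
#'   table (`summary`).
#' @export
run_li_cheng <- function(result, populations = c("Full", "RadialOnly"),
                         master_seed = 3L) {
  stopifnot(inherits(result, "experiment_result"))
  spec <- build_li_cheng_spec(master_seed)
  X <- encode_spec(result$model, spec)
  tab <- spec_table(spec)
  rows <- list()
  for (p in populations) {
    est <- clamp_curvature(predict(result$decoders$curvature[[p]], X))
    sign_pred <- predict(result$sign_models[[p]], X)
    err <- path_error(tab$curvature, tab$path_sign, est, sign_pred,
                      signed = TRUE)
    rows[[p]] <- data.frame(population = p, radius = tab$radius,
                            signed_path_error = err)
  }
  trials <- do.call(rbind, rows)
  summary <- stats::aggregate(signed_path_error ~ population + radius,
                              trials, mean)
  list(trials = trials, summary = summary)
}

#' Rotation-rate condition analysis on the 3D cloud dataset
#'
#' For an experiment run on the cloud scene, groups the test trials by path
#' radius -- within 2.5 m of 43 m (2.0 deg/s rotation at 1.5 m/s) or 107 m
#' (0.8 deg/s), or at least 180 m (effectively straight) -- and reports the
#' gaze-offset MAE per group and population.
#'
#' @param result An [run_full_experiment()] result with activations kept
#'   (ideally with `scene_kind = "cloud"`).
#' @param populations Populations to evaluate.
#' @param radii Curvilinear reference radii, meters.
#' @param tolerance Radius matching tolerance, meters.
#' @param straight_min Minimum radius treated as straight, meters.
#' @param speed Translation speed used to label rotation rates, m/s.
#' @return Data frame: rotation rate (deg/s), population, trial count, gaze
#'   MAE.
#' @export
run_burlingham <- function(result, populations = c("Full", "RadialOnly"),
                           radii = c(43, 107), tolerance = 2.5,
                           straight_min = 180, speed = 1.5) {
  stopifnot(inherits(result, "experiment_result"),
            !is.null(result$X_test))
  te <- spec_table(result$test_spec)
  groups <- c(lapply(radii, function(r) which(abs(te$radius - r) <= tolerance)),
              list(which(te$radius >= straight_min)))
  rates <- c(round(path_rotation_rate(speed, radii), 1), 0)
  rows <- list()
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0) next
    for (p in populations) {
      est <- predict(result$decoders$gaze_offset[[p]],
                     result$X_test[idx, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        rotation_rate = rates[g], population = p, n = length(idx),
        gaze_mae = mae(te$gaze_offset[idx], est))
    }
  }
  do.call(rbind, rows)
}
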