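# Sparse linear decoders over the MSTd population: lasso regressions for
# gaze offset and path curvature, a linear SVM for path sign, and the
# sub-population filters used for model comparison.

new_decoder_model <- function(target, type, weights, intercept, unit_mask,
                              mask_name, support_size, lambda = NA_real_,
                              cv_folds = NA_integer_, seed = NA_integer_,
                              fit = NULL, extra = list()) {
  structure(
    c(list(target = target, type = type, weights = weights,
           intercept = intercept, unit_mask = unit_mask,
           mask_name = mask_name, support_size = support_size,
           lambda = lambda, cv_folds = cv_folds, seed = seed, fit = fit),
      extra),
    class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model> %s (%s), population %s: %d nonzero weights of %d eligible\n",
    x$target, x$type, x$mask_name, x$support_size, sum(x$unit_mask)))
  invisible(x)
}

# Stratified, seeded cross-validation fold assignment. Strata default to
# quantile bins of the response so folds see a balanced target range; the
# experiment pipeline stratifies by path sign and radius quantile instead.
make_foldid <- function(n, folds, seed, strata = NULL) {
  set.seed(seed)
  if (is.null(strata)) strata <- rep(1L, n)
  strata <- as.integer(factor(strata))
  foldid <- integer(n)
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' Fit a lasso decoder with the one-standard-error rule
#'
#' L1-regularized least squares over the eligible units. The regularization
#' strength is chosen by fivefold cross validation as the largest (sparsest)
#' lambda whose CV mean-squared error lies within one standard error of the
#' minimum; the returned weights are the full-data path fit at that lambda,
#' on the original predictor scale (predictors are standardized internally
#' for the path).
#'
#' @param X Activation matrix, trials x units.
#' @param y Numeric target (gaze offset in degrees, or curvature in 1/m).
#' @param unit_mask Logical vector of eligible units (default all).
#' @param mask_name Label of the sub-population the mask came from.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param strata Optional stratification variable for fold balance.
#' @param max_support If finite, truncate the lambda path at the first
#'   lambda whose support exceeds `max_support` and select the densest
#'   remaining path point (the smallest admissible lambda), so the fitted
#'   model carries as many nonzero weights as the cap allows -- the
#'   support-limited decoder is meant to match a reference model's number
#'   of free parameters, not to re-sparsify below it.
#'
#' @return A `decoder_model` with full-length `weights` (exact zeros outside
#'   `unit_mask`), `intercept`, selected `lambda`, and `support_size`.
#' @export
fit_lasso <- function(X, y, unit_mask = NULL, mask_name = "Full",
                      folds = 5, seed = 1L, strata = NULL,
                      max_support = Inf) {
  if (is.null(unit_mask)) unit_mask <- rep(TRUE, ncol(X))
  stopifnot(nrow(X) == length(y), length(unit_mask) == ncol(X))
  if (!any(unit_mask)) stop("empty unit mask")
  Xs <- X[, unit_mask, drop = FALSE]
  if (diff(range(Xs)) == 0)
    stop("degenerate predictors: all eligible activations are constant")
  weights <- numeric(ncol(X))
  if (stats::sd(y) == 0) {   # constant target: the null model is exact
    return(new_decoder_model("y", "regression", weights, mean(y), unit_mask,
                             mask_name, 0L, lambda = Inf, cv_folds = folds,
                             seed = seed))
  }
  foldid <- make_foldid(nrow(X), folds, seed, strata)
  dfmax <- if (is.finite(max_support)) as.integer(max_support) else
    ncol(Xs) + 1L
  cv <- glmnet::cv.glmnet(Xs, y, foldid = foldid, standardize = TRUE,
                          dfmax = dfmax)
  if (is.finite(max_support)) {
    ok <- which(cv$nzero <= max_support)
    lambda <- min(cv$lambda[ok])   # densest admissible model
  } else {
    lambda <- cv$lambda.1se
  }
  cf <- stats::coef(cv$glmnet.fit, s = lambda)
  weights[unit_mask] <- as.numeric(cf[-1])
  new_decoder_model(
    "y", "regression", weights, as.numeric(cf[1]), unit_mask, mask_name,
    sum(weights != 0), lambda = lambda, cv_folds = folds, seed = seed,
    extra = list(lambda_path = cv$lambda, df_path = as.integer(cv$nzero),
                 cvm = cv$cvm, cvsd = cv$cvsd))
}

#' @rdname fit_lasso
#' @export
fit_lasso_limited <- function(X, y, max_support, unit_mask = NULL,
                              mask_name = "FullLimited", folds = 5,
                              seed = 1L, strata = NULL) {
  stopifnot(max_support >= 1)
  fit_lasso(X, y, unit_mask = unit_mask, mask_name = mask_name,
            folds = folds, seed = seed, strata = strata,
            max_support = max_support)
}

#' Linear support-vector classifier for path sign
#'
#' Fits a binary SVM with a linear kernel to separate clockwise from
#' counterclockwise trials from the population activity.
#'
#' @param X Activation matrix, trials x units.
#' @param sign Path signs, `+1` / `-1` (or a two-level factor).
#' @param unit_mask Logical vector of eligible units.
#' @param mask_name Population label.
#' @param seed Seed (the fit itself is deterministic; recorded for
#'   provenance).
#'
#' @return A `decoder_model` of type `"classifier"`. `weights` and
#'   `intercept` give the linear decision function `X w + b`, positive for
#'   the clockwise class.
#' @export
fit_sign_classifier <- function(X, sign, unit_mask = NULL,
                                mask_name = "Full", seed = 1L) {
  if (is.null(unit_mask)) unit_mask <- rep(TRUE, ncol(X))
  y <- factor(as.numeric(as.character(factor(sign))), levels = c(-1, 1))
  if (length(unique(y[!is.na(y)])) < 2)
    stop("both path signs must be present to fit the classifier")
  Xs <- X[, unit_mask, drop = FALSE]
  fit <- e1071::svm(Xs, y, kernel = "linear", scale = FALSE)
  w_sub <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the decision function so positive scores mean CW (+1)
  if (fit$levels[1] == "1") { w_sub <- -w_sub; b <- -b }
  weights <- numeric(ncol(X))
  weights[unit_mask] <- w_sub
  new_decoder_model("path_sign", "classifier", weights, b, unit_mask,
                    mask_name, sum(weights != 0), seed = seed, fit = fit)
}

#' Sub-population unit filters
#'
#' Selects the MSTd units eligible for a decoding model by their pattern
#' tuning. `Full` and `FullLimited` admit every unit. `RadialOnly` is the
#' single full-field radial-expansion pattern (one unit per CoM position;
#' 256 on the default grid). The three thirds partition the strictly
#' intermediate absolute spiralities into equal-width bands
#' (0, 1/3], (1/3, 2/3], (2/3, 1); `ConcentricOnly` selects the
#' absolute-spirality-1 units. CW and CCW units pool by absolute spirality.
#'
#' @param units Unit metadata table (`bank$units`).
#' @param name Filter name.
#' @return Logical unit mask.
#' @export
apply_filter <- function(units,
                         name = c("Full", "FullLimited", "RadialOnly",
                                  "LowestThird", "MiddleThird", "UpperThird",
                                  "ConcentricOnly")) {
  name <- match.arg(name)
  al <- units$abs_lambda
  mask <- switch(
    name,
    Full = ,
    FullLimited = rep(TRUE, nrow(units)),
    RadialOnly = {
      rad_pat <- min(units$pattern[al == 0 & units$field == "full"])
      units$pattern == rad_pat
    },
    LowestThird = al > 0 & al <= 1 / 3,
    MiddleThird = al > 1 / 3 & al <= 2 / 3,
    UpperThird = al > 2 / 3 & al < 1,
    ConcentricOnly = al == 1)
  if (!any(mask)) stop("filter selects no units")
  mask
}

#' Predict from a fitted decoder
#'
#' @param object A `decoder_model`.
#' @param X Activation matrix with the same column layout as at fit time.
#' @param ... Unused.
#' @return Numeric estimates (regression) or path signs in `{-1, +1}`
#'   (classifier).
#' @export
predict.decoder_model <- function(object, X, ...) {
  if (ncol(X) != length(object$weights))
    stop("activation matrix has the wrong number of units")
  score <- drop(X %*% object$weights) + object$intercept
  if (object$type == "classifier") ifelse(score >= 0, 1, -1) else score
}
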