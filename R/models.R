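#' Per-sample weights for the origin classifier
#'
#' Counteracts city sample-size imbalance: every sample of city c gets
#' weight 1 - n_c / N, so samples from heavily sampled cities count less.
#'
#' @param city_labels character/factor vector of city labels, one per
#'   sample (at least 2 distinct cities).
#' @return named numeric vector of weights in \[0, 1).
#' @export
compute_weights <- function(city_labels) {
  city_labels <- as.character(city_labels)
  tab <- table(city_labels)
  if (length(tab) < 2)
    stop("need at least 2 distinct cities to weight samples")
  w <- 1 - as.numeric(tab[city_labels]) / length(city_labels)
  names(w) <- city_labels
  w
}

# balanced fold assignment; stratified within city when labels are given
make_foldid <- function(n, n_folds, city = NULL) {
  if (is.null(city)) return(sample(rep_len(seq_len(n_folds), n)))
  foldid <- integer(n)
  for (cty in unique(city)) {
    idx <- which(city == cty)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

feature_x <- function(features) {
  if (inherits(features, "feature_matrix")) features$X
  else as.matrix(features)
}

#' Multi-task Lasso regression of geographic coordinates
#'
#' Latitude and longitude are modeled jointly: each feature's coefficient
#' pair is penalized by its Euclidean norm, so a taxon enters or leaves
#' both responses together (the grouped multi-response Lasso,
#' `family = "mgaussian"` in glmnet). The penalty strength is chosen by
#' internal cross-validation with the one-standard-error rule: the
#' largest lambda whose CV mean squared error is within one standard
#' error of the minimum — the parsimony-favoring choice.
#'
#' @param features a `feature_matrix` from [make_features()] (or an
#'   already standardized numeric matrix).
#' @param coords data.frame/matrix with columns `latitude` and
#'   `longitude`, in degrees.
#' @param n_folds internal CV folds for the lambda path.
#' @param seed integer seed for fold assignment.
#' @param city optional city labels; when given, folds are stratified by
#'   city so each fold mirrors the city composition.
#' @param multi_task `FALSE` fits two independent Lasso regressions (one
#'   per coordinate) instead of the grouped penalty.
#' @param nlambda,lambda_min_ratio lambda path: `nlambda` log-spaced
#'   values down to `lambda_min_ratio` times the smallest lambda that
#'   zeroes all coefficients.
#' @param lambda_fixed bypass CV selection and evaluate the model at this
#'   penalty instead (the path is still fit).
#' @param ... passed on to [glmnet::cv.glmnet()] (e.g. an explicit
#'   `lambda` path or a tighter `thresh`); an explicit `lambda`
#'   overrides `nlambda`/`lambda_min_ratio`.
#' @return object of class `geo_lasso`: selected lambda(s), lambda path
#'   with CV mean/SE, coefficient matrix (features x 2), intercepts, and
#'   `df`, the number of features with a nonzero coefficient group.
#' @export
fit_geo_regression <- function(features, coords, n_folds = 10, seed,
                               city = NULL, multi_task = TRUE, ...,
                               nlambda = 100, lambda_min_ratio = 1e-3,
                               lambda_fixed = NULL) {
  if (missing(seed)) stop("`seed` is required")
  X <- feature_x(features)
  if (any(!is.finite(X))) stop("non-finite feature values")
  coords <- as.matrix(as.data.frame(coords)[, c("latitude", "longitude")])
  if (nrow(X) != nrow(coords)) stop("features and coords disagree on n")
  if (nrow(X) <= n_folds)
    stop("need more samples than folds")
  set.seed(seed)
  foldid <- make_foldid(nrow(X), n_folds, city)
  # an explicit lambda path in ... overrides the nlambda/ratio defaults
  path_args <- if ("lambda" %in% names(list(...))) list()
               else list(nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio)

  if (multi_task) {
    cvfit <- do.call(glmnet::cv.glmnet, c(
      list(X, coords, family = "mgaussian", foldid = foldid,
           standardize = FALSE), path_args, list(...)))
    lambda_sel <- if (is.null(lambda_fixed)) cvfit$lambda.1se
                  else lambda_fixed
    co <- stats::coef(cvfit, s = lambda_sel)
    beta <- cbind(latitude = as.numeric(co$latitude)[-1],
                  longitude = as.numeric(co$longitude)[-1])
    rownames(beta) <- rownames(co$latitude)[-1]
    intercepts <- c(latitude = as.numeric(co$latitude)[1],
                    longitude = as.numeric(co$longitude)[1])
    fits <- list(joint = cvfit)
  } else {
    fits <- lapply(c(latitude = 1, longitude = 2), function(j)
      do.call(glmnet::cv.glmnet, c(
        list(X, coords[, j], family = "gaussian", foldid = foldid,
             standardize = FALSE), path_args, list(...))))
    lambda_sel <- if (is.null(lambda_fixed))
      vapply(fits, function(f) f$lambda.1se, 0)
    else rep(lambda_fixed, 2)
    beta <- do.call(cbind, lapply(seq_along(fits), function(j)
      as.numeric(stats::coef(fits[[j]], s = lambda_sel[j]))[-1]))
    dimnames(beta) <- list(colnames(X), c("latitude", "longitude"))
    intercepts <- vapply(seq_along(fits), function(j)
      as.numeric(stats::coef(fits[[j]], s = lambda_sel[j]))[1], 0)
    names(intercepts) <- c("latitude", "longitude")
  }
  active <- rowSums(beta != 0) > 0
  cv1 <- fits[[1]]
  structure(list(fits = fits,
                 multi_task = multi_task,
                 lambda_1se = lambda_sel,
                 lambda_path = cv1$lambda,
                 cv_mse = cv1$cvm, cv_mse_se = cv1$cvsd,
                 coefficients = beta,
                 intercepts = intercepts,
                 df = sum(active),
                 selected_features = rownames(beta)[active],
                 features = colnames(X),
                 seed = seed),
            class = "geo_lasso")
}

#' @export
print.geo_lasso <- function(x, ...) {
  cat(sprintf(
    "geo_lasso: %s penalty, lambda.1se = %s, df = %d of %d features\n",
    if (x$multi_task) "multi-task (grouped)" else "per-coordinate",
    paste(signif(x$lambda_1se, 4), collapse = "/"),
    x$df, length(x$features)))
  invisible(x)
}

#' Predict coordinates from a fitted geo_lasso model
#'
#' @param object a `geo_lasso` model.
#' @param newdata `feature_matrix` or matrix scaled with the training
#'   scaler.
#' @param ... unused.
#' @return matrix (samples x 2) of predicted latitude and longitude.
#' @export
predict.geo_lasso <- function(object, newdata, ...) {
  X <- feature_x(newdata)[, object$features, drop = FALSE]
  out <- X %*% object$coefficients
  out <- sweep(out, 2, object$intercepts, "+")
  colnames(out) <- c("latitude", "longitude")
  out
}

#' City-weighted Lasso multinomial classifier of sample origin
#'
#' L1-penalized multinomial logistic regression of city labels on
#' standardized abundance features, with per-sample weights from
#' [compute_weights()] to offset city sample-size imbalance. Lambda is
#' selected by the one-standard-error rule on cross-validated multinomial
#' deviance. The penalty is ungrouped across classes by default
#' (each class's coefficient for a feature can be zero independently);
#' `grouped = TRUE` ties them.
#'
#' @inheritParams fit_geo_regression
#' @param city_labels city label per sample (at least 2 distinct).
#' @param weights per-sample weights; default [compute_weights()] on the
#'   labels. Weights are used as given, not renormalized.
#' @param grouped use glmnet's grouped multinomial penalty.
#' @param ... passed on to [glmnet::cv.glmnet()].
#' @return object of class `origin_classifier`.
#' @export
fit_origin_classifier <- function(features, city_labels, weights = NULL,
                                  n_folds = 10, seed, grouped = FALSE,
                                  ..., nlambda = 100,
                                  lambda_min_ratio = 1e-3) {
  if (missing(seed)) stop("`seed` is required")
  X <- feature_x(features)
  city_labels <- as.character(city_labels)
  classes <- sort(unique(city_labels))
  if (length(classes) < 2) stop("need at least 2 cities")
  if (is.null(weights)) weights <- compute_weights(city_labels)
  set.seed(seed)
  foldid <- make_foldid(nrow(X), n_folds, city_labels)
  y <- factor(city_labels, levels = classes)
  path_args <- if ("lambda" %in% names(list(...))) list()
               else list(nlambda = nlambda,
                         lambda.min.ratio = lambda_min_ratio)
  cvfit <- suppressWarnings(do.call(glmnet::cv.glmnet, c(
    list(X, y, family = "multinomial", weights = weights,
         foldid = foldid, type.measure = "deviance",
         type.multinomial = if (grouped) "grouped" else "ungrouped",
         standardize = FALSE), path_args, list(...))))
  structure(list(fit = cvfit,
                 classes = classes,
                 lambda_1se = cvfit$lambda.1se,
                 lambda_path = cvfit$lambda,
                 cv_deviance = cvfit$cvm, cv_deviance_se = cvfit$cvsd,
                 weights_used = weights,
                 features = colnames(X),
                 seed = seed),
            class = "origin_classifier")
}

#' Predict origin probabilities or labels
#'
#' Argmax ties are broken in favor of the first class in sorted city
#' order.
#'
#' @param object an `origin_classifier`.
#' @param newdata `feature_matrix` or matrix scaled with the training
#'   scaler.
#' @param type `"prob"` for the class-probability matrix (rows sum to 1)
#'   or `"class"` for labels.
#' @param ... unused.
#' @export
predict.origin_classifier <- function(object, newdata,
                                      type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- feature_x(newdata)[, object$features, drop = FALSE]
  probs <- stats::predict(object$fit, newx = X, s = object$lambda_1se,
                          type = "response")[, , 1]
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(
                                             rownames(X)[1],
                                             object$classes))
  probs <- probs[, object$classes, drop = FALSE]
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' Random forest origin classifier with per-class down-sampling
#'
#' Each tree's bootstrap is down-sampled to the minority class size
#' within every class, so imbalanced cities cannot dominate the votes.
#' Out-of-bag predictions are retained on the fitted object.
#'
#' @inheritParams fit_origin_classifier
#' @param n_trees number of trees.
#' @return object of class `rf_downsampled` wrapping the randomForest
#'   fit (`$fit`), with `$oob_pred` and `$classes`.
#' @export
fit_rf_downsampled <- function(features, city_labels, n_trees = 500,
                               seed) {
  if (missing(seed)) stop("`seed` is required")
  X <- feature_x(features)
  city_labels <- as.character(city_labels)
  tab <- table(city_labels)
  if (length(tab) < 2) stop("need at least 2 cities")
  if (any(tab < 2))
    stop("cannot down-sample: city with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  y <- factor(city_labels, levels = sort(names(tab)))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = n_trees, strata = y,
    sampsize = rep(min(tab), nlevels(y)), replace = TRUE)
  structure(list(fit = fit,
                 classes = levels(y),
                 oob_pred = as.character(fit$predicted),
                 oob_votes = fit$votes,
                 features = colnames(X),
                 seed = seed),
            class = "rf_downsampled")
}

#' @export
predict.rf_downsampled <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- feature_x(newdata)[, object$features, drop = FALSE]
  if (type == "prob")
    return(stats::predict(object$fit, X, type = "prob")[, object$classes,
                                                        drop = FALSE])
  as.character(stats::predict(object$fit, X, type = "response"))
}

#' Turn any origin model's output into coordinate predictions
#'
#' The regression model predicts coordinates directly. Classifiers
#' predict a city; to make their error comparable with the regression on
#' the same squared-degree scale, each predicted city is bridged to its
#' panel coordinates.
#'
#' @param model a `geo_lasso`, `origin_classifier` or `rf_downsampled`.
#' @param features `feature_matrix`/matrix scaled with the training
#'   scaler.
#' @param city_panel for classifiers: data.frame with `city_id`,
#'   `latitude`, `longitude` covering every predictable class.
#' @return data.frame of class `prediction_set`: `sample_id`,
#'   `pred_latitude`, `pred_longitude`, `pred_city` (NA for regression);
#'   classifier probability matrices are attached as
#'   `attr(, "probabilities")`.
#' @export
predict_origin <- function(model, features, city_panel = NULL) {
  X <- feature_x(features)
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(X)))
  if (inherits(model, "geo_lasso")) {
    co <- stats::predict(model, X)
    out <- data.frame(sample_id = ids,
                      pred_latitude = co[, "latitude"],
                      pred_longitude = co[, "longitude"],
                      pred_city = NA_character_,
                      stringsAsFactors = FALSE)
    probs <- NULL
  } else if (inherits(model, c("origin_classifier", "rf_downsampled"))) {
    probs <- stats::predict(model, X, type = "prob")
    rownames(probs) <- ids
    cls <- model$classes[max.col(probs, ties.method = "first")]
    if (is.null(city_panel))
      stop("`city_panel` is required to bridge classes to coordinates")
    hit <- match(cls, city_panel$city_id)
    if (anyNA(hit))
      stop("predicted city missing from panel: ",
           paste(unique(cls[is.na(hit)]), collapse = ", "))
    out <- data.frame(sample_id = ids,
                      pred_latitude = city_panel$latitude[hit],
                      pred_longitude = city_panel$longitude[hit],
                      pred_city = cls,
                      stringsAsFactors = FALSE)
  } else stop("unsupported model class: ", class(model)[1])
  rownames(out) <- NULL
  attr(out, "probabilities") <- probs
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' Build a city coordinate panel from sample metadata
#'
#' @param metadata data.frame with `city`, `latitude`, `longitude` (and
#'   optionally `continent`) per sample.
#' @return data.frame with one row per city.
#' @export
city_panel_from_metadata <- function(metadata) {
  keep <- intersect(c("city", "latitude", "longitude", "continent"),
                    names(metadata))
  panel <- unique(metadata[, keep, drop = FALSE])
  names(panel)[names(panel) == "city"] <- "city_id"
  if (anyDuplicated(panel$city_id))
    stop("inconsistent coordinates within a city")
  rownames(panel) <- NULL
  panel
}
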