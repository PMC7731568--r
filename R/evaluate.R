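#' Score coordinate and city predictions
#'
#' Mean squared error per coordinate (squared degrees), their sum, r
#' squared per coordinate — defined as the squared Pearson correlation
#' between predicted and true values, matching how prediction
#' scatterplots are usually annotated (this differs from 1 - SSres/SStot
#' for biased predictors) — plus classification accuracy and a confusion
#' table when city labels are available.
#'
#' @param pred a `prediction_set` from [predict_origin()] (or pooled CV
#'   predictions).
#' @param truth data.frame with `sample_id`, `latitude`, `longitude` and
#'   optionally `city`; every predicted sample must appear.
#' @return object of class `evaluation_result` with fields
#'   `mse_latitude`, `mse_longitude`, `mse_total`, `r2_latitude`,
#'   `r2_longitude`, `accuracy` (NA without labels),
#'   `per_city_sq_errors` (per-sample squared errors tagged by true
#'   city), and `confusion`.
#' @export
score_predictions <- function(pred, truth) {
  hit <- match(pred$sample_id, truth$sample_id)
  if (anyNA(hit))
    stop("samples missing from truth: ",
         paste(pred$sample_id[is.na(hit)], collapse = ", "))
  truth <- truth[hit, , drop = FALSE]
  e_lat <- (pred$pred_latitude - truth$latitude)^2
  e_lon <- (pred$pred_longitude - truth$longitude)^2
  r2 <- function(p, t) {
    if (stats::sd(p) == 0 || stats::sd(t) == 0) {
      warning("constant predictions or truth: r-squared reported as 0")
      return(0)
    }
    stats::cor(p, t)^2
  }
  have_city <- "city" %in% names(truth) && any(!is.na(pred$pred_city))
  acc <- NA_real_; confusion <- NULL
  if (have_city) {
    acc <- mean(pred$pred_city == truth$city)
    confusion <- table(predicted = pred$pred_city,
                       reference = truth$city)
  }
  per_city <- data.frame(
    sample_id = pred$sample_id,
    city = if ("city" %in% names(truth)) truth$city else NA_character_,
    sq_latitude = e_lat, sq_longitude = e_lon,
    sq_total = e_lat + e_lon,
    stringsAsFactors = FALSE)
  structure(list(mse_latitude = mean(e_lat),
                 mse_longitude = mean(e_lon),
                 mse_total = mean(e_lat) + mean(e_lon),
                 r2_latitude = r2(pred$pred_latitude, truth$latitude),
                 r2_longitude = r2(pred$pred_longitude, truth$longitude),
                 accuracy = acc,
                 per_city_sq_errors = per_city,
                 confusion = confusion,
                 n = nrow(pred)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "evaluation_result (n = %d)\n  MSE: lat %.2f + long %.2f = %.2f\n",
    x$n, x$mse_latitude, x$mse_longitude, x$mse_total))
  cat(sprintf("  r2:  lat %.4f, long %.4f\n",
              x$r2_latitude, x$r2_longitude))
  if (!is.na(x$accuracy))
    cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  invisible(x)
}

fit_origin_model <- function(model, fm_tr, md_tr, n_inner, seed, ...) {
  switch(model,
    regression = fit_geo_regression(
      fm_tr, md_tr[, c("latitude", "longitude")],
      n_folds = n_inner, seed = seed, city = md_tr$city, ...),
    classification = fit_origin_classifier(
      fm_tr, md_tr$city, n_folds = n_inner, seed = seed, ...),
    rf = fit_rf_downsampled(fm_tr, md_tr$city, seed = seed, ...),
    stop("unknown model: ", model))
}

pool_probabilities <- function(prob_list, classes, sample_ids) {
  probs <- matrix(NA_real_, length(sample_ids), length(classes),
                  dimnames = list(sample_ids, classes))
  for (p in prob_list)
    probs[rownames(p), colnames(p)] <- p
  probs
}

#' Nested 10-fold cross-validation of an origin model
#'
#' Estimates prediction performance for samples from *pre-trained*
#' cities. Outer folds are stratified by city so every training portion
#' contains every city; within each outer fold the scaler and the model
#' (with its own internal lambda-selection CV) are fit on the training
#' portion only, and the held-out samples are predicted once. Pooled
#' predictions are scored against the truth.
#'
#' @param norm a `css_norm` object (or normalized matrix, samples x
#'   taxa) for all samples.
#' @param metadata data.frame with `sample_id`, `city`, `latitude`,
#'   `longitude` (and `continent` if later needed); every city needs at
#'   least 2 samples.
#' @param model `"regression"`, `"classification"` or `"rf"`.
#' @param n_outer outer folds.
#' @param n_inner internal CV folds for lambda selection.
#' @param seed integer seed controlling fold assignment and model fits.
#' @param ... passed to the model fitting function.
#' @return list with `predictions` (a `prediction_set`; classifier
#'   probability rows attached as `attr(, "probabilities")`), `result`
#'   (an `evaluation_result`) and `foldid`.
#' @export
nested_cv <- function(norm, metadata, model = c("regression",
                                                "classification", "rf"),
                      n_outer = 10, n_inner = 10, seed, ...) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is required")
  V <- norm_values(norm)
  hit <- match(metadata$sample_id, rownames(V))
  if (anyNA(hit)) stop("metadata samples missing from the table")
  V <- V[hit, , drop = FALSE]
  tab <- table(metadata$city)
  if (any(tab < 2))
    stop("every city needs at least 2 samples for stratified folds")
  set.seed(seed)
  foldid <- make_foldid(nrow(V), n_outer, metadata$city)
  panel <- city_panel_from_metadata(metadata)
  preds <- vector("list", n_outer)
  probs <- vector("list", n_outer)
  for (k in seq_len(n_outer)) {
    tr <- foldid != k; te <- !tr
    if (!any(te)) next
    unseen <- setdiff(metadata$city[te], metadata$city[tr])
    if (length(unseen))
      stop("outer fold ", k, " holds every sample of city ",
           paste(unseen, collapse = ", "),
           "; use fewer folds or more samples")
    fm_tr <- suppressWarnings(make_features(V[tr, , drop = FALSE]))
    fm_te <- make_features(V[te, , drop = FALSE], scaler = fm_tr$scaler)
    fit <- fit_origin_model(model, fm_tr, metadata[tr, , drop = FALSE],
                            n_inner, seed = seed + k, ...)
    p <- predict_origin(fit, fm_te,
                        city_panel = if (model == "regression") NULL
                                     else panel)
    preds[[k]] <- p
    probs[[k]] <- attr(p, "probabilities")
  }
  pred <- do.call(rbind, preds)
  pred <- pred[match(metadata$sample_id, pred$sample_id), , drop = FALSE]
  rownames(pred) <- NULL
  class(pred) <- c("prediction_set", "data.frame")
  if (model != "regression")
    attr(pred, "probabilities") <-
      pool_probabilities(probs, panel$city_id, metadata$sample_id)
  list(predictions = pred,
       result = score_predictions(pred, metadata),
       foldid = foldid)
}

#' Leave-one-city-out cross-validation of an origin model
#'
#' Estimates prediction performance for samples from *new* origins: for
#' each city, the scaler and model are fit on all other cities and every
#' sample of the held-out city is predicted. For classification the
#' confusion diagonal is structurally zero — the true city is never a
#' predictable class.
#'
#' @inheritParams nested_cv
#' @return As [nested_cv()], with `foldid` the held-out city per sample.
#' @export
l1co_cv <- function(norm, metadata, model = c("regression",
                                              "classification", "rf"),
                    n_inner = 10, seed, ...) {
  model <- match.arg(model)
  if (missing(seed)) stop("`seed` is required")
  V <- norm_values(norm)
  hit <- match(metadata$sample_id, rownames(V))
  if (anyNA(hit)) stop("metadata samples missing from the table")
  V <- V[hit, , drop = FALSE]
  cities <- sort(unique(metadata$city))
  if (length(cities) < 3)
    stop("leave-one-city-out needs at least 3 cities")
  panel <- city_panel_from_metadata(metadata)
  preds <- vector("list", length(cities))
  probs <- vector("list", length(cities))
  for (k in seq_along(cities)) {
    te <- metadata$city == cities[k]; tr <- !te
    fm_tr <- suppressWarnings(make_features(V[tr, , drop = FALSE]))
    fm_te <- make_features(V[te, , drop = FALSE], scaler = fm_tr$scaler)
    train_panel <- panel[panel$city_id != cities[k], , drop = FALSE]
    fit <- fit_origin_model(model, fm_tr, metadata[tr, , drop = FALSE],
                            n_inner, seed = seed + k, ...)
    p <- predict_origin(fit, fm_te,
                        city_panel = if (model == "regression") NULL
                                     else train_panel)
    preds[[k]] <- p
    probs[[k]] <- attr(p, "probabilities")
  }
  pred <- do.call(rbind, preds)
  pred <- pred[match(metadata$sample_id, pred$sample_id), , drop = FALSE]
  rownames(pred) <- NULL
  class(pred) <- c("prediction_set", "data.frame")
  if (model != "regression")
    attr(pred, "probabilities") <-
      pool_probabilities(probs, panel$city_id, metadata$sample_id)
  list(predictions = pred,
       result = score_predictions(pred, metadata),
       foldid = metadata$city)
}

#' Per-city one-sided comparison of two models' squared errors
#'
#' For each city present in both inputs, a one-sided Wilcoxon rank-sum
#' test of total squared errors (alternative: model a's errors are
#' smaller), Benjamini-Hochberg adjusted across cities.
#'
#' @param sq_errors_a,sq_errors_b `per_city_sq_errors` data.frames from
#'   [score_predictions()] for the two models.
#' @return data.frame with `city`, `n_a`, `n_b`, `p_value`,
#'   `p_adjusted`.
#' @export
compare_models_per_city <- function(sq_errors_a, sq_errors_b) {
  cities <- intersect(unique(sq_errors_a$city),
                      unique(sq_errors_b$city))
  skipped <- setdiff(union(unique(sq_errors_a$city),
                           unique(sq_errors_b$city)), cities)
  if (length(skipped))
    warning("cities present in only one model skipped: ",
            paste(skipped, collapse = ", "))
  res <- lapply(cities, function(cty) {
    a <- sq_errors_a$sq_total[sq_errors_a$city == cty]
    b <- sq_errors_b$sq_total[sq_errors_b$city == cty]
    if (length(a) < 2 || length(b) < 2)
      stop("city ", cty, " has fewer than 2 samples per model")
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "less",
                         exact = length(a) + length(b) < 50))$p.value
    data.frame(city = cty, n_a = length(a), n_b = length(b),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Continent-level assessment of city predictions
#'
#' Maps predicted and true cities to continents and reports, per true
#' city and overall, the fraction of predictions landing on the correct
#' continent — the coarser question a classifier can still answer about
#' a new origin.
#'
#' @param pred_city,true_city character vectors, aligned per sample.
#' @param city_panel data.frame with `city_id` and `continent` covering
#'   every city appearing in either vector.
#' @return list with `per_city` (named fractions by true city) and
#'   `overall`.
#' @export
continent_assessment <- function(pred_city, true_city, city_panel) {
  cont <- stats::setNames(city_panel$continent, city_panel$city_id)
  unknown <- setdiff(c(pred_city, true_city), names(cont))
  if (length(unknown))
    stop("city missing from panel: ", paste(unknown, collapse = ", "))
  same <- cont[pred_city] == cont[true_city]
  list(per_city = tapply(same, true_city, mean),
       overall = mean(same))
}
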