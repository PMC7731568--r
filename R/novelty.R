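#' Simpson index of a class-probability vector
#'
#' 1 - sum(p_k^2): the Gini impurity of the prediction. 0 for a
#' confident one-hot prediction; 1 - 1/K (its maximum, attained by the
#' uniform vector) for a prediction spread evenly over K classes. Used
#' here as the per-sample prediction-ambiguity score.
#'
#' @param p probability vector summing to 1 (tolerance 1e-6), or a
#'   matrix of probability rows. NA entries (classes unavailable to the
#'   model that produced the row) are ignored.
#' @return numeric ambiguity value(s) in \[0, 1 - 1/K\].
#' @export
simpson_ambiguity <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    return(apply(as.matrix(p), 1,
                 function(row) simpson_ambiguity(row[!is.na(row)])))
  }
  p <- as.numeric(p)
  if (any(p < 0)) stop("negative probability")
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1, got ", format(sum(p)))
  1 - sum(p^2)
}

#' Build the ambiguity training set from two CV settings
#'
#' Runs the weighted multinomial origin classifier through both
#' evaluation designs and records, for every sample, the Simpson
#' ambiguity of its held-out class-probability vector: once under nested
#' 10-fold CV (mimicking a *pre-trained* origin) and once under
#' leave-one-city-out CV (mimicking a *new* origin). These 2N labeled
#' ambiguity values are the training data for the novelty detector.
#'
#' @inheritParams nested_cv
#' @return data.frame with `sample_id`, `setting`
#'   (`"pretrained_10fold"` or `"new_l1co"`), `simpson`.
#' @export
build_ambiguity_dataset <- function(norm, metadata, seed, n_outer = 10,
                                    n_inner = 10, ...) {
  if (missing(seed)) stop("`seed` is required")
  ncv <- nested_cv(norm, metadata, model = "classification",
                   n_outer = n_outer, n_inner = n_inner, seed = seed,
                   ...)
  lcv <- l1co_cv(norm, metadata, model = "classification",
                 n_inner = n_inner, seed = seed, ...)
  rec <- function(cv, setting) {
    probs <- attr(cv$predictions, "probabilities")
    data.frame(sample_id = rownames(probs),
               setting = setting,
               simpson = unname(simpson_ambiguity(probs)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(rec(ncv, "pretrained_10fold"), rec(lcv, "new_l1co"))
  rownames(out) <- NULL
  out
}

kde_density <- function(s, points, bw) {
  vapply(s, function(si) mean(stats::dnorm(si, mean = points, sd = bw)),
         0)
}

#' Kernel-density Bayes classifier over prediction ambiguity
#'
#' Learns one Gaussian-kernel density per CV setting (bandwidth by
#' Silverman's rule per class) from the labeled Simpson values, and
#' classifies a sample as coming from a new origin when the posterior
#' probability of the new-origin class reaches the decision threshold.
#'
#' @param records data.frame from [build_ambiguity_dataset()]; both
#'   settings need at least 5 records.
#' @param priors `"empirical"` (class frequencies of the records) or
#'   `"equal"`.
#' @param decision_threshold posterior cutoff for flagging a new origin.
#' @return object of class `novelty_model` holding the two KDEs
#'   (support points and bandwidths), priors and threshold.
#' @export
fit_kde_bayes <- function(records, priors = c("empirical", "equal"),
                          decision_threshold = 0.5) {
  priors <- match.arg(priors)
  stopifnot(all(c("setting", "simpson") %in% names(records)))
  s_new <- records$simpson[records$setting == "new_l1co"]
  s_pre <- records$simpson[records$setting == "pretrained_10fold"]
  if (length(s_new) < 5 || length(s_pre) < 5)
    stop("need at least 5 records per setting, got ",
         length(s_new), " new / ", length(s_pre), " pretrained")
  bw_of <- function(x) {
    if (stats::sd(x) == 0) {
      warning("zero-variance ambiguity group: bandwidth fallback 1e-3")
      return(1e-3)
    }
    stats::bw.nrd0(x)
  }
  pr_new <- if (priors == "equal") 0.5
            else length(s_new) / (length(s_new) + length(s_pre))
  structure(list(points_new = s_new, bw_new = bw_of(s_new),
                 points_pretrained = s_pre, bw_pretrained = bw_of(s_pre),
                 prior_new = pr_new, prior_pretrained = 1 - pr_new,
                 decision_threshold = decision_threshold),
            class = "novelty_model")
}

#' Posterior probability of a new origin given ambiguity values
#'
#' @param object a `novelty_model`.
#' @param newdata numeric Simpson ambiguity value(s).
#' @param type `"posterior"` for P(new origin | s), `"flag"` for the
#'   thresholded logical.
#' @param ... unused.
#' @export
predict.novelty_model <- function(object, newdata,
                                  type = c("posterior", "flag"), ...) {
  type <- match.arg(type)
  s <- as.numeric(newdata)
  f_new <- object$prior_new *
    kde_density(s, object$points_new, object$bw_new)
  f_pre <- object$prior_pretrained *
    kde_density(s, object$points_pretrained, object$bw_pretrained)
  tot <- f_new + f_pre
  post <- ifelse(tot > 0, f_new / tot, object$prior_new)
  if (type == "posterior") post
  else post >= object$decision_threshold
}

#' Leave-one-out evaluation of the ambiguity classifier
#'
#' Each Simpson value is left out in turn; the two KDEs (including their
#' bandwidths) and priors are refit on the remaining records and the
#' left-out value is classified. Sensitivity is recall of the new-origin
#' setting, specificity recall of the pre-trained setting. ROC points
#' come from sweeping the posterior threshold.
#'
#' @param records data.frame from [build_ambiguity_dataset()] (at least
#'   10 rows).
#' @param priors,decision_threshold as in [fit_kde_bayes()].
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `posteriors` (per record), `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`, including the (0,0) and (1,1) endpoints).
#' @export
evaluate_novelty_loo <- function(records, priors = "empirical",
                                 decision_threshold = 0.5) {
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records for leave-one-out")
  post <- numeric(n)
  for (i in seq_len(n)) {
    m <- suppressWarnings(
      fit_kde_bayes(records[-i, , drop = FALSE], priors = priors,
                    decision_threshold = decision_threshold))
    post[i] <- stats::predict(m, records$simpson[i])
  }
  is_new <- records$setting == "new_l1co"
  flag <- post >= decision_threshold
  sens <- mean(flag[is_new])
  spec <- mean(!flag[!is_new])
  acc <- mean(flag == is_new)
  thr <- c(Inf, sort(unique(post), decreasing = TRUE), -Inf)
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(post[!is_new] >= t), 0),
    tpr = vapply(thr, function(t) mean(post[is_new] >= t), 0))
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       posteriors = post, roc = roc)
}

#' Flag samples as coming from a new origin
#'
#' Applies a fitted origin classifier to scaled features, converts each
#' sample's class-probability vector to its Simpson ambiguity, and runs
#' the ambiguity Bayes classifier to obtain the new-origin posterior and
#' flag.
#'
#' @param novelty_model a `novelty_model` from [fit_kde_bayes()].
#' @param origin_classifier a fitted `origin_classifier` (or
#'   `rf_downsampled`).
#' @param features `feature_matrix`/matrix scaled with the origin
#'   classifier's training scaler.
#' @return data.frame with `sample_id`, `simpson`, `posterior_new`,
#'   `flag_new`.
#' @export
flag_new_origin <- function(novelty_model, origin_classifier, features) {
  stopifnot(inherits(novelty_model, "novelty_model"))
  probs <- stats::predict(origin_classifier, features, type = "prob")
  simpson <- unname(simpson_ambiguity(probs))
  post <- stats::predict(novelty_model, simpson)
  ids <- rownames(feature_x(features))
  data.frame(sample_id = ids,
             simpson = simpson,
             posterior_new = post,
             flag_new = post >= novelty_model$decision_threshold,
             stringsAsFactors = FALSE)
}
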