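std_mat <- function(n, p, seed) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p))
  dimnames(X) <- list(sprintf("s%03d", 1:n), sprintf("f%02d", 1:p))
  X
}

test_that("compute_weights implements 1 - n_city/N", {
  lab <- c(rep("X", 30), rep("Y", 70))
  w <- compute_weights(lab)
  expect_equal(unname(w[lab == "X"][1]), 0.7)
  expect_equal(unname(w[lab == "Y"][1]), 0.3)
  w4 <- compute_weights(rep(c("a", "b", "c", "d"), each = 5))
  expect_true(all(abs(w4 - 0.75) < 1e-12))
  expect_error(compute_weights(rep("only", 10)), "at least 2")
})

test_that("full shrinkage gives zero coefficients and mean predictions", {
  X <- std_mat(60, 8, 31)
  Y <- cbind(latitude = rnorm(60, 10, 5), longitude = rnorm(60, 0, 20))
  m <- fit_geo_regression(X, Y, seed = 1, lambda_fixed = 1e6)
  expect_true(all(m$coefficients == 0))
  expect_equal(m$df, 0)
  p <- predict(m, X)
  expect_equal(unname(p[1, ]), unname(colMeans(Y)))
})

test_that("the small-lambda limit matches ordinary least squares", {
  X <- std_mat(200, 10, 32)
  B <- matrix(0, 10, 2); B[1:3, 1] <- c(5, -3, 2); B[1:3, 2] <- c(1, 4, -2)
  Y <- X %*% B
  colnames(Y) <- c("latitude", "longitude")
  m <- fit_geo_regression(X, Y, seed = 1, lambda_fixed = 1e-10,
                          thresh = 1e-20,
                          lambda = 10^seq(1, -10, length.out = 60))
  ols <- qr.solve(cbind(1, X), Y)
  expect_equal(unname(m$coefficients), unname(ols[-1, ]),
               tolerance = 1e-6)
})

test_that("the multi-task penalty selects coefficient pairs jointly", {
  X <- std_mat(80, 15, 33)
  Y <- cbind(latitude = X[, 1] * 3 + rnorm(80),
             longitude = X[, 2] * -4 + rnorm(80))
  m <- fit_geo_regression(X, Y, n_folds = 5, seed = 2)
  beta <- m$coefficients
  expect_identical(unname(beta[, 1] == 0), unname(beta[, 2] == 0))
  # 1-SE rule bound
  expect_gte(m$lambda_1se, m$fits$joint$lambda.min)
  # feature-order permutation leaves predictions unchanged
  perm <- sample(ncol(X))
  m2 <- fit_geo_regression(X[, perm], Y, n_folds = 5, seed = 2)
  expect_equal(predict(m2, X[, perm]), predict(m, X), tolerance = 1e-8)
})

test_that("independent per-coordinate fits are available as an option", {
  X <- std_mat(70, 10, 34)
  Y <- cbind(latitude = X[, 1] * 5 + rnorm(70, sd = 0.5),
             longitude = X[, 2] * 5 + rnorm(70, sd = 0.5))
  m <- fit_geo_regression(X, Y, n_folds = 5, seed = 3,
                          multi_task = FALSE)
  expect_length(m$lambda_1se, 2)
  expect_equal(dim(m$coefficients), c(10L, 2L))
})

test_that("classifier separates separable classes and respects weights", {
  set.seed(35)
  n <- 60
  X <- matrix(c(rnorm(n / 2, -3), rnorm(n / 2, 3)), ncol = 1)
  X <- cbind(X, rnorm(n)); colnames(X) <- c("f1", "f2")
  rownames(X) <- sprintf("s%02d", 1:n)
  lab <- rep(c("aa", "bb"), each = n / 2)
  clf <- fit_origin_classifier(scale(X), lab, n_folds = 5, seed = 4)
  expect_equal(predict(clf, scale(X), type = "class"), lab)
  probs <- predict(clf, scale(X), type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, n), tolerance = 1e-9)
  # all-equal weights reproduce the unweighted fit
  clf_w <- fit_origin_classifier(scale(X), lab,
                                 weights = rep(0.6, n), n_folds = 5,
                                 seed = 4)
  expect_equal(predict(clf_w, scale(X), type = "prob"), probs,
               tolerance = 1e-8)
})

test_that("intercept-only classifier predicts the weighted priors", {
  set.seed(36)
  n <- 90
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%02d", 1:n), c("a", "b", "c")))
  lab <- rep(c("p", "q", "r"), each = n / 3)
  w <- compute_weights(lab)
  # a penalty above lambda_max forces the intercept-only model
  clf <- fit_origin_classifier(X, lab, n_folds = 5, seed = 5,
                               lambda = c(1e4, 1e3))
  probs <- predict(clf, X, type = "prob")
  prior <- tapply(w, lab, sum) / sum(w)
  expect_equal(unname(probs[1, ]), as.numeric(prior[clf$classes]),
               tolerance = 1e-6)
})

test_that("weighting raises minority-class recall under imbalance", {
  wins <- vapply(1:10, function(s) {
    set.seed(s + 700)
    n_maj <- 60; n_min <- 6
    X <- rbind(matrix(rnorm(n_maj * 4, 0), n_maj, 4),
               matrix(rnorm(n_maj * 4, 0.8), n_maj, 4),
               matrix(rnorm(n_min * 4, -1.2), n_min, 4))
    rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
    colnames(X) <- paste0("f", 1:4)
    lab <- c(rep("m1", n_maj), rep("m2", n_maj), rep("tiny", n_min))
    rec <- function(weights) {
      clf <- fit_origin_classifier(X, lab, weights = weights,
                                   n_folds = 5, seed = s)
      mean(predict(clf, X, type = "class")[lab == "tiny"] == "tiny")
    }
    rec(NULL) >= rec(rep(1, length(lab)))
  }, TRUE)
  expect_gte(mean(wins), 0.8)
})

test_that("down-sampled random forest behaves on separable and null data", {
  set.seed(37)
  n <- 80
  X <- rbind(matrix(rnorm(n / 2 * 5, -2), n / 2, 5),
             matrix(rnorm(n / 2 * 5, 2), n / 2, 5))
  dimnames(X) <- list(sprintf("s%02d", 1:n), paste0("f", 1:5))
  lab <- rep(c("u", "v"), each = n / 2)
  rf <- fit_rf_downsampled(X, lab, n_trees = 200, seed = 6)
  expect_gte(mean(rf$oob_pred == lab), 0.95)
  rf2 <- fit_rf_downsampled(X, lab, n_trees = 200, seed = 6)
  expect_identical(rf$oob_pred, rf2$oob_pred)
  # permuted labels give chance-level OOB accuracy
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    perm <- sample(lab)
    mean(fit_rf_downsampled(X, perm, n_trees = 150,
                            seed = s)$oob_pred == perm)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(fit_rf_downsampled(X, c("w", lab[-1]), seed = 1),
               "single sample")
})

test_that("predict_origin bridges classifier output to coordinates", {
  set.seed(38)
  n <- 40
  X <- rbind(matrix(rnorm(n / 2 * 2, -3), n / 2, 2),
             matrix(rnorm(n / 2 * 2, 3), n / 2, 2))
  dimnames(X) <- list(sprintf("s%02d", 1:n), c("f1", "f2"))
  lab <- rep(c("paris", "tokyo"), each = n / 2)
  panel <- data.frame(city_id = c("paris", "tokyo"),
                      latitude = c(48.8, 35.7),
                      longitude = c(2.3, 139.7))
  clf <- fit_origin_classifier(X, lab, n_folds = 5, seed = 7)
  ps <- predict_origin(clf, X, city_panel = panel)
  expect_s3_class(ps, "prediction_set")
  expect_equal(ps$pred_latitude[ps$pred_city == "paris"][1], 48.8)
  expect_equal(ps$pred_longitude[ps$pred_city == "tokyo"][1], 139.7)
  probs <- attr(ps, "probabilities")
  expect_equal(unname(rowSums(probs)), rep(1, n), tolerance = 1e-9)
  expect_error(predict_origin(clf, X, city_panel = panel[1, ]),
               "missing from panel")
  expect_error(predict_origin(clf, X), "city_panel")
})
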