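fake_pred <- function(md, lat, lon, city = NA_character_) {
  structure(data.frame(sample_id = md$sample_id, pred_latitude = lat,
                       pred_longitude = lon, pred_city = city,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

test_that("score_predictions computes MSE, r2, accuracy and confusion", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   city = rep(c("a", "b"), each = 3),
                   latitude = c(10, 11, 12, -20, -21, -22),
                   longitude = c(100, 101, 102, 30, 31, 32))
  perfect <- fake_pred(md, md$latitude, md$longitude, md$city)
  res <- score_predictions(perfect, md)
  expect_equal(res$mse_total, 0)
  expect_equal(res$r2_latitude, 1)
  expect_equal(res$accuracy, 1)
  off <- fake_pred(md, md$latitude + 2, md$longitude - 3,
                   rep(c("b", "a"), each = 3))
  res2 <- score_predictions(off, md)
  expect_equal(res2$mse_latitude, 4)
  expect_equal(res2$mse_longitude, 9)
  expect_equal(res2$mse_total, 13)
  expect_equal(res2$accuracy, 0)
  expect_equal(sum(res2$confusion), 6)
  # constant predictor: r2 degenerates to 0 with a warning per axis
  w <- capture_warnings(res3 <- score_predictions(fake_pred(md, 0, 0),
                                                  md))
  expect_match(w, "constant", all = TRUE)
  expect_equal(res3$r2_latitude, 0)
  expect_error(score_predictions(fake_pred(md, 0, 0),
                                 md[1:3, ]), "missing from truth")
})

test_that("nested and leave-one-city-out CV predict each sample once
           without city leakage", {
  st <- small_study(seed = 50, n_train = 6, samples_per_city = 8)
  norm <- css_normalize(filter_taxa(st$dat$species))
  md <- st$dat$metadata
  ncv <- nested_cv(norm, md, "regression", n_outer = 5, n_inner = 5,
                   seed = 51)
  expect_setequal(ncv$predictions$sample_id, md$sample_id)
  expect_equal(anyDuplicated(ncv$predictions$sample_id), 0L)
  # determinism of fold assignment and results
  ncv2 <- nested_cv(norm, md, "regression", n_outer = 5, n_inner = 5,
                    seed = 51)
  expect_identical(ncv$foldid, ncv2$foldid)
  expect_equal(ncv$result$mse_total, ncv2$result$mse_total)

  lcv <- l1co_cv(norm, md, "classification", n_inner = 5, seed = 52)
  expect_setequal(lcv$predictions$sample_id, md$sample_id)
  # structurally impossible to predict the held-out city
  expect_true(all(lcv$predictions$pred_city !=
                    md$city[match(lcv$predictions$sample_id,
                                  md$sample_id)]))
  expect_true(all(diag(lcv$result$confusion[
    intersect(rownames(lcv$result$confusion),
              colnames(lcv$result$confusion)),
    intersect(rownames(lcv$result$confusion),
              colnames(lcv$result$confusion))]) == 0))
})

test_that("fold scalers are fit without the held-out samples", {
  st <- small_study(seed = 53, n_train = 5, samples_per_city = 6)
  norm <- css_normalize(filter_taxa(st$dat$species))
  md <- st$dat$metadata
  V <- norm$values
  # recompute one fold's scaler by hand and confirm it ignores the fold
  set.seed(54)
  foldid <- nested_cv(norm, md, "regression", n_outer = 5, n_inner = 5,
                      seed = 54)$foldid
  tr <- foldid != 1
  fm_tr <- suppressWarnings(make_features(V[tr, , drop = FALSE]))
  full <- suppressWarnings(make_features(V))
  common <- intersect(names(fm_tr$scaler$means),
                      names(full$scaler$means))
  expect_false(isTRUE(all.equal(fm_tr$scaler$means[common],
                                full$scaler$means[common])))
})

test_that("degenerate designs are rejected", {
  st <- small_study(seed = 55, n_train = 3, samples_per_city = 4)
  norm <- css_normalize(filter_taxa(st$dat$species))
  md <- st$dat$metadata
  md2 <- md[md$city != md$city[1], ]
  expect_error(l1co_cv(norm, md2, "regression", seed = 1),
               "at least 3 cities")
  md_single <- md
  md_single <- md_single[-(1:3), ]  # city 1 keeps a single sample
  expect_error(nested_cv(norm, md_single, "regression", seed = 1),
               "at least 2 samples")
})

test_that("per-city Wilcoxon comparison matches exact enumeration", {
  errs <- function(city, v)
    data.frame(city = city, sq_total = v, stringsAsFactors = FALSE)
  # identical errors: one-sided p is not small
  a <- errs("c1", c(1, 2, 3, 4))
  out <- compare_models_per_city(a, a)
  expect_gte(out$p_value, 0.5)
  # strict dominance with n = 4 per group: p = 1 / choose(8, 4)
  b <- errs("c1", c(10, 11, 12, 13))
  out2 <- compare_models_per_city(a, b)
  expect_equal(out2$p_value, 1 / choose(8, 4))
  # exact enumeration oracle for a mixed case
  x <- c(1, 5, 2.5); y <- c(3, 4, 6)
  W <- sum(rank(c(x, y))[1:3])
  perms <- combn(6, 3)
  ranks <- rank(c(x, y))
  stat_null <- apply(perms, 2, function(id) sum(ranks[id]))
  p_exact <- mean(stat_null <= W)
  out3 <- compare_models_per_city(errs("c1", x), errs("c1", y))
  expect_equal(out3$p_value, p_exact)
  # BH adjustment across cities
  many_a <- rbind(errs("c1", c(1, 2, 3, 4)), errs("c2", c(1, 2, 3, 4)))
  many_b <- rbind(errs("c1", c(10, 11, 12, 13)), errs("c2", c(2, 3, 4, 5)))
  out4 <- compare_models_per_city(many_a, many_b)
  expect_equal(out4$p_adjusted,
               p.adjust(out4$p_value, method = "BH"))
  expect_warning(compare_models_per_city(a, rbind(a, errs("c9", 1:3))),
                 "skipped")
})

test_that("continent assessment maps cities through the panel", {
  panel <- data.frame(city_id = c("a", "b", "c"),
                      continent = c("NorthWest", "NorthWest",
                                    "SouthEast"))
  res <- continent_assessment(c("b", "b", "a"), c("a", "a", "c"), panel)
  expect_equal(unname(res$per_city["a"]), 1)
  expect_equal(unname(res$per_city["c"]), 0)
  expect_equal(res$overall, 2 / 3)
  expect_error(continent_assessment("zz", "a", panel), "missing")
})
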