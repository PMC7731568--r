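test_that("simpson_ambiguity implements 1 - sum(p^2)", {
  expect_equal(simpson_ambiguity(c(1, 0, 0)), 0)
  expect_equal(simpson_ambiguity(rep(1 / 15, 15)), 1 - 1 / 15)
  expect_equal(simpson_ambiguity(c(0.5, 0.5, 0, 0)), 0.5)
  expect_error(simpson_ambiguity(c(-0.1, 1.1)), "negative")
  expect_error(simpson_ambiguity(c(0.5, 0.4)), "sum to 1")
  # rows of a matrix, with NA-masked (untrained) classes
  m <- rbind(c(1, 0, NA), c(NA, 0.5, 0.5))
  expect_equal(unname(simpson_ambiguity(m)), c(0, 0.5))
})

test_that("simpson_ambiguity is maximized by the uniform vector", {
  set.seed(61)
  for (k in c(3, 7, 12)) {
    cap <- 1 - 1 / k
    vals <- replicate(200, {
      p <- rexp(k); simpson_ambiguity(p / sum(p))
    })
    expect_true(all(vals >= 0 & vals <= cap + 1e-12))
    expect_equal(simpson_ambiguity(rep(1 / k, k)), cap)
    expect_true(max(vals) <= cap)
  }
})

test_that("kde Bayes posterior matches explicit kernel sums", {
  set.seed(62)
  records <- data.frame(
    setting = rep(c("new_l1co", "pretrained_10fold"), each = 30),
    simpson = c(rbeta(30, 6, 2), rbeta(30, 2, 6)))
  m <- fit_kde_bayes(records)
  s_grid <- seq(0, 1, length.out = 23)
  oracle <- vapply(s_grid, kde_posterior_oracle,
                   pts_new = m$points_new, bw_new = m$bw_new,
                   pts_pre = m$points_pretrained,
                   bw_pre = m$bw_pretrained,
                   prior_new = m$prior_new, FUN.VALUE = 0)
  expect_equal(predict(m, s_grid), oracle, tolerance = 1e-10)
  # posteriors of the two classes always sum to 1
  post_new <- predict(m, s_grid)
  expect_true(all(post_new >= 0 & post_new <= 1))
  # empirical priors reflect the group sizes
  expect_equal(m$prior_new, 0.5)
  m_eq <- fit_kde_bayes(records, priors = "equal")
  expect_equal(m_eq$prior_new, 0.5)
})

test_that("mirror-image classes give a boundary at the midpoint", {
  offs <- c(-0.03, -0.01, 0, 0.01, 0.03)
  records <- data.frame(
    setting = rep(c("new_l1co", "pretrained_10fold"), each = 5),
    simpson = c(1 + offs, -offs))     # mirror images around 0.5
  m <- fit_kde_bayes(records)
  expect_equal(predict(m, 0.5), 0.5, tolerance = 1e-12)
  expect_gt(predict(m, 0.9), 0.5)
  expect_lt(predict(m, 0.1), 0.5)
})

test_that("fit_kde_bayes validates inputs", {
  rec <- data.frame(setting = c(rep("new_l1co", 5),
                                rep("pretrained_10fold", 3)),
                    simpson = runif(8))
  expect_error(fit_kde_bayes(rec), "at least 5")
})

test_that("LOO evaluation separates separable groups and stays at
           chance on permuted labels", {
  set.seed(63)
  sep <- data.frame(
    setting = rep(c("new_l1co", "pretrained_10fold"), each = 25),
    simpson = c(runif(25, 0.8, 1), runif(25, 0, 0.2)))
  res <- evaluate_novelty_loo(sep)
  expect_equal(res$accuracy, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  expect_equal(res$roc$fpr[1], 0); expect_equal(res$roc$tpr[1], 0)
  expect_equal(res$roc$fpr[nrow(res$roc)], 1)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)

  accs <- vapply(1:10, function(s) {
    set.seed(s + 400)
    perm <- sep
    perm$setting <- sample(perm$setting)
    evaluate_novelty_loo(perm)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  # identical distributions: accuracy near the larger prior
  set.seed(64)
  same <- data.frame(
    setting = rep(c("new_l1co", "pretrained_10fold"), c(40, 20)),
    simpson = runif(60, 0.4, 0.6))
  expect_lt(abs(evaluate_novelty_loo(same)$accuracy - 2 / 3), 0.15)
})

test_that("samples from new synthetic cities are flagged as new origins", {
  st <- small_study(seed = 90, n_train = 8, n_mystery = 4,
                    samples_per_city = 10)
  tab <- filter_taxa(st$dat$species)
  norm <- css_normalize(tab)
  md <- st$dat$metadata
  records <- build_ambiguity_dataset(norm, md, seed = 91, n_inner = 5)
  nov <- fit_kde_bayes(records)
  fm <- suppressWarnings(make_features(norm))
  clf <- fit_origin_classifier(fm, md$city, n_folds = 5, seed = 91)
  mys <- generate_counts(st$world$mystery, st$truth)
  keep <- intersect(colnames(tab$counts), colnames(mys$species$counts))
  mt <- taxa_count_table(
    mys$species$counts[, keep, drop = FALSE],
    mys$species$taxonomy[match(keep, mys$species$taxonomy$taxon_id), ],
    rank = "species")
  fmm <- make_features(css_normalize(mt), scaler = fm$scaler)
  flags <- flag_new_origin(nov, clf, fmm)
  expect_gte(mean(flags$flag_new), 0.6)
})

test_that("flag_new_origin runs the classifier-to-flag chain", {
  set.seed(65)
  n <- 60
  X <- rbind(matrix(rnorm(n / 2 * 3, -2), n / 2, 3),
             matrix(rnorm(n / 2 * 3, 2), n / 2, 3))
  dimnames(X) <- list(sprintf("s%02d", 1:n), paste0("f", 1:3))
  lab <- rep(c("k1", "k2"), each = n / 2)
  clf <- fit_origin_classifier(X, lab, n_folds = 5, seed = 8)
  records <- data.frame(
    setting = rep(c("new_l1co", "pretrained_10fold"), each = 20),
    simpson = c(runif(20, 0.3, 0.5), runif(20, 0, 0.2)))
  nov <- fit_kde_bayes(records)
  flags <- flag_new_origin(nov, clf, X)
  expect_equal(nrow(flags), n)
  expect_true(all(flags$posterior_new >= 0 & flags$posterior_new <= 1))
  # confident one-hot-ish predictions carry near-zero ambiguity and are
  # not flagged
  expect_false(any(flags$flag_new[flags$simpson < 0.05]))
})
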