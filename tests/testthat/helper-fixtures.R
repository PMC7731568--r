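# Shared fixture builders. Everything is generated in code under a seed
# so the test tree carries no data files.

toy_table <- function(counts, rank = "species") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  tax <- data.frame(taxon_id = colnames(counts), rank = rank,
                    genus = paste0("g", rep_len(1:3, ncol(counts))),
                    family = paste0("f", rep_len(1:2, ncol(counts))),
                    stringsAsFactors = FALSE)
  taxa_count_table(counts, tax, rank = rank)
}

# a small but fully structured synthetic study used across test files
small_study <- function(seed, n_train = 8, n_mystery = 0,
                        samples_per_city = 10, ...) {
  world <- generate_world(n_train, n_mystery, samples_per_city,
                          seed = seed)
  truth <- synthetic_truth(n_species = 120, n_genera = 40,
                           n_families = 15, seed = seed + 5000, ...)
  dat <- generate_counts(world$train, truth)
  list(world = world, truth = truth, dat = dat)
}

# independent CSS oracle: explicit sort / interpolated quantile / masked
# sum, kept deliberately naive
css_oracle_factors <- function(counts, p = 0.5) {
  vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    pos <- sort(x[x > 0])
    n <- length(pos)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    q <- pos[lo] + (h - lo) * (pos[hi] - pos[lo])
    sum(x[x <= q])
  }, 0)
}

random_count_matrix <- function(n, p, max_count = 500) {
  m <- matrix(rpois(n * p, lambda = 5) *
                rbinom(n * p, 1, 0.6), n, p)
  m[sample(length(m), max(1, length(m) %/% 10))] <-
    sample(max_count, max(1, length(m) %/% 10), replace = TRUE)
  # ensure every sample has a positive count
  m[cbind(seq_len(n), sample(p, n, TRUE))] <- 7
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("t%02d", seq_len(p))
  m
}

# brute-force KDE Bayes posterior: explicit Gaussian kernel sums
kde_posterior_oracle <- function(s, pts_new, bw_new, pts_pre, bw_pre,
                                 prior_new) {
  dens <- function(x, pts, bw)
    sum(exp(-(x - pts)^2 / (2 * bw^2)) / (sqrt(2 * pi) * bw)) /
      length(pts)
  f_new <- prior_new * dens(s, pts_new, bw_new)
  f_pre <- (1 - prior_new) * dens(s, pts_pre, bw_pre)
  f_new / (f_new + f_pre)
}
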