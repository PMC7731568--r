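#' Taxon-set overlap between two technologies
#'
#' Counts the taxa detected by both methods and expresses the overlap as
#' a whole percent of one method's taxon set (the "perspective"
#' denominator).
#'
#' @param taxa_a,taxa_b character vectors of taxon ids at one rank.
#' @param denominator which set the percentage is taken over.
#' @return list with `overlap_count` and `percent` (rounded to the
#'   nearest whole percent).
#' @export
overlap_summary <- function(taxa_a, taxa_b, denominator = c("a", "b")) {
  denominator <- match.arg(denominator)
  denom_set <- if (denominator == "a") unique(taxa_a) else unique(taxa_b)
  if (!length(denom_set)) stop("denominator taxon set is empty")
  ov <- length(intersect(unique(taxa_a), unique(taxa_b)))
  list(overlap_count = ov,
       percent = round(100 * ov / length(denom_set)))
}

#' Cross-technology abundance correlation
#'
#' Pearson correlation over all common (sample, taxon) pairs of two
#' normalized tables, computed on the normalized (not log-transformed)
#' scale, with a Fisher-z 95 percent confidence interval.
#'
#' @param norm_a,norm_b `css_norm` objects or normalized matrices
#'   (samples x taxa) from two technologies.
#' @return list with `pearson_r`, `ci95` (length 2), `n_pairs`.
#' @export
correlate_technologies <- function(norm_a, norm_b) {
  A <- norm_values(norm_a); B <- norm_values(norm_b)
  samples <- intersect(rownames(A), rownames(B))
  taxa <- intersect(colnames(A), colnames(B))
  if (length(taxa) < 3 || length(samples) < 3)
    stop("need at least 3 common taxa and 3 common samples, got ",
         length(taxa), " and ", length(samples))
  x <- as.vector(A[samples, taxa]); y <- as.vector(B[samples, taxa])
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(pearson_r = unname(ct$estimate),
       ci95 = as.numeric(ct$conf.int),
       n_pairs = length(x))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over taxa; 0 for identical
#' samples, 1 for disjoint supports.
#'
#' @param norm a `css_norm` object or nonnegative matrix (samples x taxa).
#' @return A symmetric `matrix` of dissimilarities with zero diagonal.
#' @export
bray_curtis <- function(norm) {
  V <- norm_values(norm)
  if (any(V < 0)) stop("Bray-Curtis requires nonnegative values")
  zero <- rowSums(V) == 0
  if (sum(zero) >= 2)
    stop("dissimilarity undefined between all-zero samples: ",
         paste(rownames(V)[zero], collapse = ", "))
  D <- as.matrix(suppressWarnings(vegan::vegdist(V, method = "bray")))
  dimnames(D) <- list(rownames(V), rownames(V))
  D
}

#' Principal coordinate analysis with the Cailliez correction
#'
#' Classical metric scaling of a dissimilarity matrix. When the matrix is
#' non-Euclidean (negative eigenvalues), the Cailliez constant — the
#' smallest constant whose addition to all off-diagonal dissimilarities
#' makes them Euclidean — is applied first.
#'
#' @param dissimilarity square symmetric matrix with zero diagonal (or a
#'   `dist`).
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (post-correction), `explained` (variance fractions), and
#'   `correction_constant` (0 when no correction was needed).
#' @export
pcoa_cailliez <- function(dissimilarity) {
  if (inherits(dissimilarity, "dist"))
    dissimilarity <- as.matrix(dissimilarity)
  if (nrow(dissimilarity) != ncol(dissimilarity) ||
      !isSymmetric(unname(dissimilarity), tol = 1e-8))
    stop("dissimilarity must be a square symmetric matrix")
  if (any(abs(diag(dissimilarity)) > 1e-12))
    stop("dissimilarity must have a zero diagonal")
  res <- ape::pcoa(stats::as.dist(dissimilarity), correction = "cailliez")
  corrected <- res$correction[1] == "cailliez" &&
    !grepl("No correction", res$note)
  if (corrected) {
    cc <- as.numeric(sub(".*\\(D \\+ ([0-9.eE+-]+) \\).*", "\\1",
                         res$note))
    coords <- res$vectors.cor
    eig <- res$values$Corr_eig
    expl <- res$values$Rel_corr_eig
  } else {
    cc <- 0
    coords <- res$vectors
    eig <- res$values$Eigenvalues
    expl <- res$values$Relative_eig
  }
  keep <- seq_len(ncol(coords))
  list(coordinates = coords,
       eigenvalues = eig,
       explained = expl[keep],
       correction_constant = cc)
}

#' Sweep read-count thresholds for taxon filtering
#'
#' For each (threshold, minimum-supporting-samples) setting, reports how
#' many taxa of `table_a` survive and the cross-technology Pearson
#' correlation of the surviving common taxa against `table_b` — the
#' stringency/concordance tradeoff used to choose a filtering cutoff.
#'
#' @param table_a,table_b `taxa_count_table`s at one rank (a is the
#'   perspective whose taxa are filtered and counted).
#' @param thresholds ascending nonnegative read-count thresholds
#'   (0 means every taxon counts).
#' @param min_sample_settings vector of "at least this many samples"
#'   support requirements.
#' @param params [css_params()] used to normalize before correlating.
#' @return data.frame with columns `threshold`, `min_samples`, `n_taxa`,
#'   `pearson_r` (NA when fewer than 3 common taxa survive).
#' @export
threshold_sweep <- function(table_a, table_b, thresholds,
                            min_sample_settings = 1L,
                            params = css_params()) {
  stopifnot(inherits(table_a, "taxa_count_table"),
            inherits(table_b, "taxa_count_table"))
  if (!length(thresholds)) stop("`thresholds` is empty")
  if (is.unsorted(thresholds)) stop("`thresholds` must be ascending")
  norm_b <- css_normalize(table_b, params)
  out <- expand.grid(threshold = thresholds,
                     min_samples = min_sample_settings)
  out$n_taxa <- NA_integer_; out$pearson_r <- NA_real_
  for (i in seq_len(nrow(out))) {
    t_ <- out$threshold[i]; m <- out$min_samples[i]
    keep <- colSums(table_a$counts >= t_) >= m
    out$n_taxa[i] <- sum(keep)
    if (sum(keep) == 0) next
    sub <- taxa_count_table(table_a$counts[, keep, drop = FALSE],
                            table_a$taxonomy[keep, , drop = FALSE],
                            rank = table_a$rank)
    common <- intersect(colnames(sub$counts), colnames(table_b$counts))
    if (length(common) >= 3) {
      norm_a <- css_normalize(sub, params)
      out$pearson_r[i] <-
        correlate_technologies(norm_a, norm_b)$pearson_r
    }
  }
  out
}
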