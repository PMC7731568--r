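#' Normalization parameters
#'
#' Settings for sparse-taxon filtering and cumulative sum scaling (CSS).
#' CSS corrects library-size differences by scaling each sample by the
#' summed counts of its lower-abundance taxa — those at or below a chosen
#' quantile of the sample's positive counts — so a handful of dominant
#' taxa cannot drive the scaling factor the way they drive a total-sum
#' (relative abundance) normalization.
#'
#' @param css_percentile quantile of each sample's positive counts used as
#'   the cumulative-sum cutoff; must be strictly inside (0, 1). Default
#'   0.5, the 50th percentile.
#' @param scale_constant positive constant the ratios are multiplied by so
#'   normalized abundances sit on a convenient scale. Only shifts the
#'   log2 intercept downstream.
#' @param min_reads count a taxon must reach in a sample for that sample
#'   to "support" the taxon during filtering.
#' @param min_samples_exceed a taxon is kept only if strictly more than
#'   this many samples support it.
#' @return A list of class `css_params`.
#' @export
css_params <- function(css_percentile = 0.5, scale_constant = 1000,
                       min_reads = 100, min_samples_exceed = 1) {
  if (!(css_percentile > 0 && css_percentile < 1))
    stop("`css_percentile` must be strictly inside (0, 1)")
  if (scale_constant <= 0) stop("`scale_constant` must be positive")
  if (min_reads <= 0 || min_samples_exceed <= 0)
    stop("filter thresholds must be positive")
  structure(list(css_percentile = css_percentile,
                 scale_constant = scale_constant,
                 min_reads = min_reads,
                 min_samples_exceed = min_samples_exceed),
            class = "css_params")
}

#' Remove sparse taxa
#'
#' Keeps a taxon only if the number of samples in which it reaches
#' `min_reads` reads is strictly greater than `min_samples_exceed`.
#' Sample set is unchanged.
#'
#' @param table a [taxa_count_table()].
#' @param min_reads minimum per-sample read count for support.
#' @param min_samples_exceed required support must exceed this.
#' @return The filtered `taxa_count_table`.
#' @export
filter_taxa <- function(table, min_reads = 100, min_samples_exceed = 1) {
  stopifnot(inherits(table, "taxa_count_table"))
  if (min_reads <= 0 || min_samples_exceed <= 0)
    stop("filter thresholds must be positive")
  support <- colSums(table$counts >= min_reads)
  keep <- support > min_samples_exceed
  if (!any(keep))
    warning("no taxa pass the filter (min_reads = ", min_reads,
            ", min_samples_exceed = ", min_samples_exceed, ")")
  taxa_count_table(table$counts[, keep, drop = FALSE],
                   table$taxonomy[keep, , drop = FALSE],
                   rank = table$rank)
}

#' Cumulative sum scaling normalization
#'
#' For each sample j, the cutoff q_j is the `css_percentile` quantile
#' (linear interpolation) of the sample's positive counts; the scaling
#' factor s_j is the sum of all counts at or below q_j; and the
#' normalized value is count / s_j * scale_constant. Samples whose count
#' vectors are proportional get identical normalized rows.
#'
#' @param table a [taxa_count_table()]; every sample must have at least
#'   one positive count.
#' @param params a [css_params()] object.
#' @return An object of class `css_norm`: `values` (samples x taxa
#'   normalized abundance), `scaling_factors` (per sample), `params`.
#' @export
css_normalize <- function(table, params = css_params()) {
  stopifnot(inherits(table, "taxa_count_table"),
            inherits(params, "css_params"))
  counts <- table$counts
  zero_samp <- rowSums(counts) == 0
  if (any(zero_samp))
    stop("sample(s) with no reads cannot be CSS-normalized: ",
         paste(rownames(counts)[zero_samp], collapse = ", "))
  factors <- apply(counts, 1, function(x) {
    pos <- x[x > 0]
    q <- stats::quantile(pos, probs = params$css_percentile,
                         names = FALSE, type = 7)
    sum(x[x <= q])
  })
  values <- counts / factors * params$scale_constant
  structure(list(values = values,
                 scaling_factors = factors,
                 params = params,
                 rank = table$rank),
            class = "css_norm")
}

#' @export
print.css_norm <- function(x, ...) {
  cat(sprintf(
    "css_norm: %d samples x %d taxa (%s rank), percentile %.2f\n",
    nrow(x$values), ncol(x$values), x$rank, x$params$css_percentile))
  invisible(x)
}

norm_values <- function(x) {
  if (inherits(x, "css_norm")) x$values else as.matrix(x)
}

#' Build standardized model features from normalized abundance
#'
#' log2-transforms the normalized abundance (pseudocount 1, so zeros stay
#' zero before standardization) and z-scores each taxon. When `scaler` is
#' `NULL` the scaler is fit on the input (training data): per-feature
#' means and standard deviations are recorded and zero-variance features
#' are dropped. Supplying a fitted scaler applies the *training*
#' statistics unchanged — the contract that keeps test folds leakage-free.
#'
#' @param norm a `css_norm` object or a nonnegative matrix of normalized
#'   abundance (samples x taxa).
#' @param scaler a scaler returned in a previous `feature_matrix`'s
#'   `$scaler`, or `NULL` to fit one.
#' @param pseudocount added before log2.
#' @return An object of class `feature_matrix`: `X` (samples x features,
#'   standardized), `scaler` (`means`, `sds`, `features`, `dropped`).
#' @export
make_features <- function(norm, scaler = NULL, pseudocount = 1) {
  V <- norm_values(norm)
  if (any(V < 0)) stop("normalized abundance must be nonnegative")
  L <- log2(V + pseudocount)
  if (is.null(scaler)) {
    mu <- colMeans(L)
    sd_ <- apply(L, 2, stats::sd)
    drop <- sd_ == 0 | !is.finite(sd_)
    if (any(drop))
      warning(sum(drop), " zero-variance feature(s) dropped: ",
              paste(utils::head(colnames(L)[drop], 5), collapse = ", "),
              if (sum(drop) > 5) ", ..." else "")
    scaler <- list(means = mu[!drop], sds = sd_[!drop],
                   features = colnames(L)[!drop],
                   dropped = colnames(L)[drop])
  } else {
    miss <- setdiff(scaler$features, colnames(L))
    if (length(miss))
      stop("features required by scaler but absent from input: ",
           paste(miss, collapse = ", "))
  }
  X <- sweep(L[, scaler$features, drop = FALSE], 2, scaler$means, "-")
  X <- sweep(X, 2, scaler$sds, "/")
  structure(list(X = X, scaler = scaler), class = "feature_matrix")
}
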