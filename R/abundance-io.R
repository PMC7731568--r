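#' Load a taxa-by-sample count table
#'
#' Two input layouts are supported. `"bracken_reports"` takes one Bracken
#' species-report TSV per sample (the standard columns `name`,
#' `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`,
#' `new_est_reads`, `fraction_total_reads`) and assembles the per-sample
#' `new_est_reads` — Bracken's re-estimated read counts — into one table,
#' filling taxa absent from a sample with zero. `"wide_tsv"` reads the
#' matrix layout written by [write_abundance()].
#'
#' @param path for `"bracken_reports"`, a character vector of report files
#'   (sample ids are the file basenames without extension) or a directory
#'   containing them; for `"wide_tsv"`, a single file.
#' @param format input layout.
#' @param rank rank to assign when reading Bracken reports
#'   (`taxonomy_lvl` is checked against its one-letter code).
#' @return A [taxa_count_table()].
#' @export
load_abundance <- function(path, format = c("wide_tsv", "bracken_reports"),
                           rank = "species") {
  format <- match.arg(format)
  if (format == "wide_tsv") {
    stopifnot(length(path) == 1L)
    raw <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!all(c("lineage", "rank") %in% names(raw)))
      stop("malformed wide TSV ", path,
           ": expected `lineage` and `rank` columns")
    parts <- strsplit(raw$lineage, "|", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad))
      stop("malformed lineage string in ", path, " at row ",
           which(bad)[1])
    lin <- do.call(rbind, parts)
    counts <- as.matrix(raw[, setdiff(names(raw), c("lineage", "rank")),
                            drop = FALSE])
    if (any(counts < 0)) stop("negative count in ", path)
    rownames(counts) <- lin[, 3]
    tax <- data.frame(taxon_id = lin[, 3], rank = raw$rank,
                      genus = ifelse(lin[, 2] == "", NA, lin[, 2]),
                      family = ifelse(lin[, 1] == "", NA, lin[, 1]),
                      stringsAsFactors = FALSE)
    return(taxa_count_table(t(counts), tax, rank = unique(raw$rank)))
  }

  # bracken_reports
  if (length(path) == 1L && dir.exists(path))
    path <- list.files(path, pattern = "\\.(tsv|txt)$", full.names = TRUE)
  if (!length(path)) stop("no Bracken report files found")
  needed <- c("name", "taxonomy_id", "taxonomy_lvl",
              "kraken_assigned_reads", "added_reads", "new_est_reads",
              "fraction_total_reads")
  lvl_code <- c(species = "S", genus = "G", family = "F",
                order = "O", class = "C", phylum = "P")[[rank]]
  per_sample <- lapply(path, function(f) {
    rep <- utils::read.delim(f, check.names = FALSE,
                             stringsAsFactors = FALSE)
    miss <- setdiff(needed, names(rep))
    if (length(miss))
      stop("malformed Bracken report ", f, ": missing column(s) ",
           paste(miss, collapse = ", "))
    rep <- rep[rep$taxonomy_lvl == lvl_code, , drop = FALSE]
    if (any(rep$new_est_reads < 0))
      stop("negative count in Bracken report ", f)
    stats::setNames(rep$new_est_reads, rep$name)
  })
  ids <- sub("\\.(tsv|txt)$", "", basename(path))
  taxa <- sort(unique(unlist(lapply(per_sample, names))))
  counts <- matrix(0, length(path), length(taxa),
                   dimnames = list(ids, taxa))
  for (i in seq_along(per_sample))
    counts[i, names(per_sample[[i]])] <- per_sample[[i]]
  tax <- data.frame(taxon_id = taxa, rank = rank,
                    stringsAsFactors = FALSE)
  taxa_count_table(counts, tax, rank = rank)
}

#' Read a sample metadata table
#'
#' CSV with columns `sample_id`, `city`, `latitude`, `longitude`,
#' `continent`, `paired_end`, `read_length_bp`.
#'
#' @param path CSV file.
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "city", "latitude", "longitude", "continent")
  miss <- setdiff(needed, names(md))
  if (length(miss))
    stop("metadata ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  md
}
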