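#' Taxa-by-sample count table
#'
#' Container for integer abundance counts at a single taxonomic rank.
#' Rows are samples, columns are taxa. The taxonomy table carries, for each
#' taxon, its rank and parent lineage (genus and family for species-rank
#' tables, family for genus-rank tables), which is what rank roll-ups use.
#'
#' @param counts numeric matrix of non-negative counts, samples x taxa,
#'   with unique rownames (sample ids) and colnames (taxon ids).
#' @param taxonomy data.frame with one row per taxon: `taxon_id`, `rank`,
#'   and any parent-lineage columns (`genus`, `family`). Row order must
#'   cover every column of `counts`.
#' @param rank taxonomic rank of the table, one of
#'   `"species"`, `"genus"`, `"family"`, `"order"`, `"class"`, `"phylum"`.
#' @return An object of class `taxa_count_table`.
#' @export
taxa_count_table <- function(counts, taxonomy, rank = "species") {
  rank <- match.arg(rank, c("species", "genus", "family", "order",
                            "class", "phylum"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("`counts` must have sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("taxon ids must be unique")
  if (any(counts < 0))
    stop("negative counts are not allowed")
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  taxonomy <- as.data.frame(taxonomy)
  if (!all(c("taxon_id", "rank") %in% names(taxonomy)))
    stop("`taxonomy` needs columns `taxon_id` and `rank`")
  missing <- setdiff(colnames(counts), taxonomy$taxon_id)
  if (length(missing))
    stop("taxa missing from taxonomy: ", paste(missing, collapse = ", "))
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, rank = rank),
            class = "taxa_count_table")
}

#' @export
print.taxa_count_table <- function(x, ...) {
  cat(sprintf("taxa_count_table: %d samples x %d taxa (%s rank)\n",
              nrow(x$counts), ncol(x$counts), x$rank))
  cat(sprintf("total reads: %s; zero fraction: %.2f\n",
              format(sum(x$counts), big.mark = ","),
              mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.taxa_count_table <- function(x) dim(x$counts)

sample_ids <- function(x) rownames(x$counts)
taxon_ids <- function(x) colnames(x$counts)

#' Aggregate a species-rank table to a coarser rank
#'
#' Column-sums species counts by their parent lineage, so totals are
#' conserved exactly: the genus table's column sums equal the species
#' table's sums grouped by genus.
#'
#' @param table a `taxa_count_table` at species (or genus) rank.
#' @param rank target rank, a parent lineage column present in the
#'   taxonomy (`"genus"` or `"family"`).
#' @return A `taxa_count_table` at the requested rank.
#' @export
aggregate_taxa <- function(table, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  stopifnot(inherits(table, "taxa_count_table"))
  if (!rank %in% names(table$taxonomy))
    stop("taxonomy has no `", rank, "` lineage column")
  group <- table$taxonomy[[rank]]
  agg <- t(rowsum(t(table$counts), group = group))
  tax <- unique(table$taxonomy[, names(table$taxonomy) %in%
                                 c(rank, "family"), drop = FALSE])
  # the target rank becomes the taxon id; deeper lineage columns drop out
  tax <- unique(data.frame(
    taxon_id = table$taxonomy[[rank]],
    rank = rank,
    family = if (rank == "genus" && "family" %in% names(table$taxonomy))
      table$taxonomy$family else NA_character_,
    stringsAsFactors = FALSE))
  tax <- tax[!duplicated(tax$taxon_id), , drop = FALSE]
  taxa_count_table(agg[, tax$taxon_id, drop = FALSE], tax, rank = rank)
}

#' Write / read a count table as a wide TSV
#'
#' Rows are taxa (first column a `lineage` string `family|genus|taxon`),
#' remaining columns one per sample. The inverse of [load_abundance()]
#' with `format = "wide_tsv"`.
#'
#' @param table a `taxa_count_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "taxa_count_table"))
  tx <- table$taxonomy
  fam <- if ("family" %in% names(tx)) tx$family else NA
  gen <- if ("genus" %in% names(tx)) tx$genus else NA
  lineage <- paste(ifelse(is.na(fam), "", fam),
                   ifelse(is.na(gen), "", gen),
                   tx$taxon_id, sep = "|")
  out <- data.frame(lineage = lineage, rank = tx$rank,
                    t(table$counts), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
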