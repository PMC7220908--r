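# Operations on taxa-by-samples count tibbles (first column `taxon_id`).

# Internal: wide count tibble -> integer matrix (taxa x samples).
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (names(counts)[1] != "taxon_id") abort("count table must start with a `taxon_id` column")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("count table has missing values")
  if (any(m < 0)) abort("count table has negative values")
  rownames(m) <- counts$taxon_id
  m
}

#' Filter samples and taxa by total read count
#'
#' Low-coverage samples are dropped first: a sample is retained when its total
#' read count is strictly greater than `min_reads_per_sample`. Taxa are then
#' filtered on their totals across the *retained* samples: a taxon is removed
#' when that total is below `min_reads_per_taxon` (kept when `>=`). The
#' defaults mirror the common survey-quality rules of keeping samples with
#' more than 10,000 reads and discarding taxa with fewer than 100 reads
#' overall.
#'
#' @param counts Count tibble (`taxon_id` + one integer column per sample).
#' @param min_reads_per_sample Samples with totals `<=` this are dropped.
#' @param min_reads_per_taxon Taxa with post-filter totals `<` this are dropped.
#' @param metadata Optional per-sample metadata tibble; if supplied it is
#'   subset to the retained samples and the result is a list with `counts`
#'   and `metadata`.
#' @return The filtered count tibble, or a list of `counts` and `metadata`
#'   when `metadata` is supplied.
#' @export
filter_samples_taxa <- function(counts, min_reads_per_sample = 10000,
                                min_reads_per_taxon = 100, metadata = NULL) {
  stopifnot(min_reads_per_sample >= 0, min_reads_per_taxon >= 0)
  m <- counts_matrix(counts)
  keep_s <- colSums(m) > min_reads_per_sample
  if (!any(keep_s)) abort("empty result: no sample exceeds `min_reads_per_sample`")
  m <- m[, keep_s, drop = FALSE]
  keep_t <- rowSums(m) >= min_reads_per_taxon
  out <- counts[keep_t, c(TRUE, keep_s), drop = FALSE]
  if (is.null(metadata)) return(out)
  meta <- metadata[metadata$sample_id %in% colnames(m), , drop = FALSE]
  list(counts = out, metadata = meta)
}

#' Relative abundances
#'
#' Column-normalises a count table so every sample (column) sums to one.
#'
#' @param counts Count tibble (`taxon_id` + one column per sample).
#' @return A numeric taxa-by-samples matrix of proportions with dimnames.
#' @export
relative_abundance <- function(counts) {
  m <- counts_matrix(counts)
  tot <- colSums(m)
  zero <- which(tot == 0)
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero total reads: %s",
                  paste(colnames(m)[zero], collapse = ", ")))
  }
  sweep(m, 2, tot, "/")
}

#' Shannon diversity per sample
#'
#' `H = -sum(p * log(p))` over taxa with positive abundance, natural log.
#'
#' @param counts Count tibble.
#' @return A tibble with columns `sample_id` and `shannon`.
#' @export
shannon_diversity <- function(counts) {
  p <- relative_abundance(counts)
  h <- apply(p, 2, function(x) {
    x <- x[x > 0]
    -sum(x * log(x))
  })
  tibble(sample_id = colnames(p), shannon = unname(h))
}
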