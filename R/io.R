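#' Read an OTU count table
#'
#' Reads a tab-delimited taxa-by-samples table of integer read counts. The
#' first column holds the taxon (OTU) identifier and the header row holds the
#' sample identifiers.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column is `taxon_id` followed by one integer
#'   column per sample, in file order.
#' @export
read_count_table <- function(path) {
  # check the raw header first: readr would silently repair duplicated names
  hdr_line <- readLines(path, n = 1)
  hdr_ids <- strsplit(hdr_line, "\t", fixed = TRUE)[[1]][-1]
  dup_h <- hdr_ids[duplicated(hdr_ids)]
  if (length(dup_h) > 0) {
    abort(sprintf("duplicated sample id(s) in header: %s",
                  paste(unique(dup_h), collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) abort("count table has an empty data section")
  if (ncol(raw) < 2) abort("count table must have at least one sample column")
  hdr <- names(raw)
  sample_ids <- hdr[-1]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) {
    abort(sprintf("duplicated sample id(s) in header: %s", paste(unique(dup_s), collapse = ", ")))
  }
  taxon_id <- raw[[1]]
  dup_t <- taxon_id[duplicated(taxon_id)]
  if (length(dup_t) > 0) {
    abort(sprintf("duplicated taxon id(s): %s", paste(unique(dup_t), collapse = ", ")))
  }
  counts <- lapply(seq_along(sample_ids), function(j) {
    col <- raw[[j + 1]]
    x <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric count at row '%s', column '%s'",
                    taxon_id[bad[1]], sample_ids[j]))
    }
    neg <- which(x < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative count at row '%s', column '%s'",
                    taxon_id[neg[1]], sample_ids[j]))
    }
    nonint <- which(abs(x - round(x)) > 1e-9)
    if (length(nonint) > 0) {
      abort(sprintf("non-integer count at row '%s', column '%s'",
                    taxon_id[nonint[1]], sample_ids[j]))
    }
    as.integer(round(x))
  })
  names(counts) <- sample_ids
  dplyr::bind_cols(tibble(taxon_id = taxon_id), tibble::as_tibble(counts))
}

#' Write an OTU count table
#'
#' @param counts A count tibble as returned by [read_count_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "taxon_id")
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects columns `SampleID`, `Date` (ISO 8601, `YYYY-MM-DD`), `Site`, and
#' either planar coordinates `X_m`/`Y_m` (metres) or geographic `Lat`/`Lon`
#' (degrees).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `date` (Date), `site` and the
#'   coordinate columns (`x_m`/`y_m` or `lat`/`lon`).
#' @export
read_sample_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("SampleID", "Date", "Site")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) abort(sprintf("metadata is missing column(s): %s", paste(miss, collapse = ", ")))
  has_xy <- all(c("X_m", "Y_m") %in% names(raw))
  has_ll <- all(c("Lat", "Lon") %in% names(raw))
  if (!has_xy && !has_ll) abort("metadata needs either X_m/Y_m or Lat/Lon coordinates")
  if (anyDuplicated(raw$SampleID)) abort("duplicated sample ids in metadata")
  out <- tibble(
    sample_id = raw$SampleID,
    date = as.Date(raw$Date),
    site = raw$Site
  )
  if (anyNA(out$date)) abort("unparseable Date value(s); expected YYYY-MM-DD")
  if (has_xy) {
    out$x_m <- as.numeric(raw$X_m)
    out$y_m <- as.numeric(raw$Y_m)
  }
  if (has_ll) {
    out$lat <- as.numeric(raw$Lat)
    out$lon <- as.numeric(raw$Lon)
  }
  out
}

#' Write per-sample metadata
#'
#' @param meta Metadata tibble as returned by [read_sample_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- tibble(SampleID = meta$sample_id, Date = format(meta$date), Site = meta$site)
  if (all(c("x_m", "y_m") %in% names(meta))) {
    out$X_m <- meta$x_m
    out$Y_m <- meta$y_m
  }
  if (all(c("lat", "lon") %in% names(meta))) {
    out$Lat <- meta$lat
    out$Lon <- meta$lon
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a functional-measurement table
#'
#' Expects columns `SampleID` plus the seven replicate-averaged community
#' functions: exoenzyme activities `X` (xylosidase), `G` (beta-glucosidase),
#' `N` (beta-chitinase), `P` (phosphatase), `ATP`, `Yield` (cell counts) and
#' `CO2` (cumulative respiration).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `X`, `G`, `N`, `P`, `ATP`,
#'   `Yield`, `CO2`.
#' @export
read_function_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("SampleID", function_variables())
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) abort(sprintf("function table is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(raw$SampleID)) abort("duplicated sample ids in function table")
  out <- tibble(sample_id = raw$SampleID)
  for (v in function_variables()) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    if (anyNA(x)) abort(sprintf("missing or non-numeric values in column %s", v))
    out[[v]] <- x
  }
  out
}

#' Write a functional-measurement table
#'
#' @param f Function table tibble as returned by [read_function_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_function_table <- function(f, path) {
  out <- dplyr::rename(f, SampleID = "sample_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' The seven functional variables
#'
#' @return Character vector `c("X","G","N","P","ATP","Yield","CO2")`.
#' @export
function_variables <- function() c("X", "G", "N", "P", "ATP", "Yield", "CO2")

#' Read a square distance matrix
#'
#' Square TSV with a leading id column and a matching header row of sample
#' ids.
#'
#' @param path Path to a TSV file.
#' @return A validated numeric matrix with sample ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) abort("distance matrix header does not match its id column")
  validate_distance_matrix(m, "matrix")
}

#' Write a square distance matrix
#'
#' @param d A square named distance matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  d <- validate_distance_matrix(d)
  df <- data.frame(SampleID = rownames(d), d, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Turn a distance matrix into a long tibble of pairs
#'
#' @param d A square named distance matrix.
#' @return A tibble with columns `sample_a`, `sample_b`, `distance`, one row
#'   per unordered pair.
#' @export
dist_pairs <- function(d) {
  d <- validate_distance_matrix(d)
  idx <- lower_pairs(nrow(d))
  tibble(
    sample_a = rownames(d)[idx[, 2]],
    sample_b = rownames(d)[idx[, 1]],
    distance = d[idx]
  )
}
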