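#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr
NULL

# Symmetry tolerance used when validating user-supplied distance matrices.
.dist_tol <- 1e-8

#' Validate a sample-by-sample distance matrix
#'
#' Checks that `d` is a square numeric matrix with matching row/column names,
#' a zero diagonal, nonnegative finite entries and symmetry (up to a small
#' tolerance). Dissimilarities need not satisfy the triangle inequality.
#'
#' @param d A square numeric matrix with sample ids as dimnames.
#' @param arg Name used in error messages.
#' @return `d`, invisibly, with the symmetric average enforced exactly.
#' @export
validate_distance_matrix <- function(d, arg = "d") {
  if (!is.matrix(d) || !is.numeric(d)) {
    abort(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(d) != ncol(d)) abort(sprintf("`%s` must be square", arg))
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    abort(sprintf("`%s` must carry sample ids as dimnames", arg))
  }
  if (!identical(rownames(d), colnames(d))) {
    abort(sprintf("row and column names of `%s` disagree", arg))
  }
  if (anyNA(d) || any(!is.finite(d))) abort(sprintf("`%s` has non-finite entries", arg))
  if (any(d < 0)) abort(sprintf("`%s` has negative entries", arg))
  if (any(abs(diag(d)) > .dist_tol)) abort(sprintf("`%s` has a nonzero diagonal", arg))
  if (max(abs(d - t(d))) > .dist_tol) abort(sprintf("`%s` is not symmetric", arg))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  invisible(d)
}

# Coerce a grouping to a factor aligned with the sample ids of `d`.
# Accepts a tibble/data.frame with sample_id + label columns, a named vector,
# or a plain vector in matrix order.
as_group_factor <- function(g, sample_ids) {
  if (is.data.frame(g)) {
    cols <- names(g)
    id_col <- intersect(c("sample_id", "SampleID"), cols)[1]
    lab_col <- setdiff(cols, id_col)[1]
    if (is.na(id_col) || is.na(lab_col)) {
      abort("grouping data frame must have a sample id column and a label column")
    }
    if (!setequal(g[[id_col]], sample_ids)) {
      abort("grouping sample ids do not match the distance matrix")
    }
    lab <- g[[lab_col]][match(sample_ids, g[[id_col]])]
  } else if (!is.null(names(g))) {
    if (!all(sample_ids %in% names(g))) {
      abort("grouping names do not cover the distance matrix sample ids")
    }
    lab <- unname(g[sample_ids])
  } else {
    if (length(g) != length(sample_ids)) {
      abort("grouping length does not match the number of samples")
    }
    lab <- g
  }
  factor(lab)
}

# Classification tibble in the standard shape used across the package.
new_classification <- function(sample_ids, labels, kind = "class") {
  out <- tibble(sample_id = sample_ids, label = as.character(labels))
  attr(out, "kind") <- kind
  out
}

# Strictly-lower-triangle index pairs of an n x n matrix (i > j).
lower_pairs <- function(n) {
  which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Run `expr` under `seed` if non-NULL, otherwise with the current RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Permutation p-value with the +1 correction; never 0, in (0, 1].
perm_pvalue <- function(observed, nulls, tail = c("greater", "less", "two_sided")) {
  tail <- match.arg(tail)
  hits <- switch(tail,
    greater   = sum(nulls >= observed),
    less      = sum(nulls <= observed),
    two_sided = sum(abs(nulls) >= abs(observed))
  )
  (1 + hits) / (1 + length(nulls))
}

# Truncated-normal draws on [lo, hi] by inverse-CDF; exact, no rejection.
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  if (any(sd < 0)) abort("sd must be nonnegative")
  out <- numeric(n)
  zero <- sd == 0
  if (length(mean) == 1) mean <- rep(mean, n)
  if (length(sd) == 1) sd <- rep(sd, n)
  out[zero] <- pmin(pmax(mean[zero], lo), hi)
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    plo <- stats::pnorm(lo, m, s)
    phi <- stats::pnorm(hi, m, s)
    u <- stats::runif(sum(!zero), plo, phi)
    out[!zero] <- stats::qnorm(u, m, s)
  }
  pmin(pmax(out, lo), hi)
}
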