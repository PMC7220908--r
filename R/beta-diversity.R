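# Beta-diversity dissimilarities: Jensen-Shannon divergence and a
# SparCC-derived compositional distance, plus the Mantel test.

#' Options for the beta-diversity metrics
#'
#' The exact JSD variant (log base, square root) and the SparCC-to-distance
#' transformation differ between studies, so all knobs are explicit. Defaults:
#' base-2 entropy and the square root of the divergence (the metric form used
#' in the enterotype literature), `(1 - rho) / 2` for the SparCC distance with
#' pseudocount 0.5 and no exclusion iterations.
#'
#' @param jsd_log_base 2 or `exp(1)`; entropy base for the JSD.
#' @param jsd_take_sqrt Return `sqrt(JSD)` (a metric) instead of the raw
#'   divergence.
#' @param sparcc_pseudocount Positive count added to every cell before
#'   computing log-ratio fractions.
#' @param sparcc_transform `"half_one_minus_rho"` for `(1 - rho)/2` or
#'   `"sqrt_half_one_minus_rho"` for its square root.
#' @param sparcc_exclusion_rounds Number of iterations excluding the currently
#'   most-correlated sample pair from the basis-variance system (0 = basic
#'   estimator).
#' @param sparcc_exclusion_threshold Minimum `|rho|` for a pair to be eligible
#'   for exclusion.
#' @return A list of class `beta_div_options`.
#' @export
beta_div_options <- function(jsd_log_base = 2,
                             jsd_take_sqrt = TRUE,
                             sparcc_pseudocount = 0.5,
                             sparcc_transform = c("half_one_minus_rho",
                                                  "sqrt_half_one_minus_rho"),
                             sparcc_exclusion_rounds = 0,
                             sparcc_exclusion_threshold = 0.1) {
  sparcc_transform <- match.arg(sparcc_transform)
  if (!jsd_log_base %in% c(2, exp(1))) abort("jsd_log_base must be 2 or exp(1)")
  if (sparcc_pseudocount <= 0) abort("sparcc_pseudocount must be > 0")
  if (sparcc_exclusion_rounds < 0) abort("sparcc_exclusion_rounds must be >= 0")
  if (sparcc_exclusion_threshold <= 0 || sparcc_exclusion_threshold >= 1) {
    abort("sparcc_exclusion_threshold must be in (0, 1)")
  }
  structure(list(
    jsd_log_base = jsd_log_base,
    jsd_take_sqrt = isTRUE(jsd_take_sqrt),
    sparcc_pseudocount = sparcc_pseudocount,
    sparcc_transform = sparcc_transform,
    sparcc_exclusion_rounds = as.integer(sparcc_exclusion_rounds),
    sparcc_exclusion_threshold = sparcc_exclusion_threshold
  ), class = "beta_div_options")
}

# x * log(x) with the 0*log(0) = 0 convention.
xlogx <- function(x, base) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos], base = base)
  dim(out) <- dim(x)
  out
}

#' Jensen-Shannon divergence matrix
#'
#' Pairwise `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q)/2`,
#' entropy in the configured base. With base 2 the divergence lies in
#' `[0, 1]`; its square root is a metric.
#'
#' @param p Either a taxa-by-samples matrix of relative abundances (columns
#'   sum to 1) or a count tibble, which is normalised first.
#' @param opts A [beta_div_options()] object.
#' @return A symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
jsd_matrix <- function(p, opts = beta_div_options()) {
  if (is.data.frame(p)) p <- relative_abundance(p)
  if (!is.matrix(p)) abort("`p` must be a matrix or a count tibble")
  if (any(p < 0)) abort("relative abundances must be nonnegative")
  colsums <- colSums(p)
  if (any(abs(colsums - 1) > 1e-6)) abort("columns of `p` must sum to 1")
  base <- opts$jsd_log_base
  n <- ncol(p)
  ids <- colnames(p)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  # Column entropies once; mixture entropies in column blocks.
  hcol <- -colSums(xlogx(p, base))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      m <- (p[, i] + p[, j, drop = FALSE]) / 2
      hm <- -colSums(xlogx(m, base))
      v <- hm - (hcol[i] + hcol[j]) / 2
      v <- pmax(v, 0)  # guard tiny negative rounding
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  if (opts$jsd_take_sqrt) d <- sqrt(d)
  diag(d) <- 0
  d
}

#' SparCC-derived sample distance matrix
#'
#' Applies the SparCC log-ratio variance estimator with *samples as the
#' compositional components*: each sample's pseudocounted taxon fractions play
#' the role of component fractions, the log-ratio variance over taxa
#' `t_ij = var_a log(f_ai / f_aj)` is computed for every sample pair, the
#' basic SparCC linear system `t_i. = (n - 2) w_i + sum_j w_j` is solved for
#' the basis variances `w`, and correlations
#' `rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))` (clipped to `[-1, 1]`)
#' are mapped to distances by the configured transform. This orientation
#' yields a sample-by-sample dissimilarity: the usual SparCC, written for
#' taxa, is transposed here by design.
#'
#' @param counts Count tibble (`taxon_id` + one column per sample).
#' @param opts A [beta_div_options()] object.
#' @return A symmetric sample-by-sample distance matrix in `[0, 1]`.
#' @export
sparcc_distance_matrix <- function(counts, opts = beta_div_options()) {
  m <- counts_matrix(counts)
  if (ncol(m) < 3) abort("SparCC needs at least 3 samples")
  if (nrow(m) < 2) abort("SparCC needs at least 2 taxa")
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(sprintf("sample(s) with zero total reads: %s",
                  paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  f <- sweep(m + opts$sparcc_pseudocount, 2,
             colSums(m + opts$sparcc_pseudocount), "/")
  lf <- log(f)
  n <- ncol(f)
  ids <- colnames(f)
  # t_ij = var over taxa of (log f_i - log f_j), computed via cross-products.
  cv <- stats::cov(lf)  # taxa treated as observations
  tmat <- outer(diag(cv), diag(cv), "+") - 2 * cv
  diag(tmat) <- 0

  rho <- sparcc_solve(tmat, opts)
  d <- switch(opts$sparcc_transform,
    half_one_minus_rho = (1 - rho) / 2,
    sqrt_half_one_minus_rho = sqrt((1 - rho) / 2)
  )
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  d
}

# Solve the SparCC basis system, optionally iterating pair exclusions.
# `incl` marks pairs currently included in the system.
sparcc_solve <- function(tmat, opts) {
  n <- nrow(tmat)
  incl <- matrix(TRUE, n, n)
  diag(incl) <- FALSE
  rho <- NULL
  for (round in 0:opts$sparcc_exclusion_rounds) {
    m_i <- rowSums(incl)
    if (any(m_i < 2)) abort("too many excluded pairs; reduce sparcc_exclusion_rounds")
    t_i <- rowSums(tmat * incl)
    # Sparse assumption: t_ij ~ w_i + w_j, so t_i = m_i w_i + sum_{j in M_i} w_j,
    # i.e. A = diag(m_i) + incl (for the full system this is the classic
    # (n - 2) w_i + sum_j w_j form).
    A <- incl * 1
    diag(A) <- m_i
    w <- solve(A, t_i)
    if (any(w <= 0)) {
      abort("nonpositive basis variance; add samples or increase the pseudocount")
    }
    denom <- 2 * sqrt(outer(w, w))
    rho <- (outer(w, w, "+") - tmat) / denom
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (round == opts$sparcc_exclusion_rounds) break
    cand <- abs(rho)
    cand[!incl] <- -Inf
    diag(cand) <- -Inf
    mx <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (cand[mx[1], mx[2]] < opts$sparcc_exclusion_threshold) break
    incl[mx[1], mx[2]] <- FALSE
    incl[mx[2], mx[1]] <- FALSE
  }
  rho
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' two-sided permutation p-value: rows and columns of `b` are permuted
#' jointly and `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)`.
#'
#' @param a,b Square named distance matrices over the same samples.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed.
#' @return A `perm_test` object with `statistic` (r), `p_value` and `n_perm`;
#'   see [tidy.perm_test()].
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = NULL) {
  a <- validate_distance_matrix(a, "a")
  b <- validate_distance_matrix(b, "b")
  if (!setequal(rownames(a), rownames(b))) abort("sample ids of `a` and `b` differ")
  b <- b[rownames(a), rownames(a)]
  if (n_perm < 1) abort("n_perm must be >= 1")
  n <- nrow(a)
  lt <- lower.tri(a)
  av <- a[lt]
  bv <- b[lt]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    abort("constant lower triangle: Mantel correlation is undefined")
  }
  r_obs <- stats::cor(av, bv)
  nulls <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(av, b[p, p][lt])
    }, numeric(1))
  })
  new_perm_test(
    statistic = c(r = r_obs),
    p_value = perm_pvalue(r_obs, nulls, "two_sided"),
    n_perm = n_perm,
    method = "mantel",
    null_statistics = nulls
  )
}
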