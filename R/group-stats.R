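# From-formula ANOSIM, MRPP and PERMANOVA sharing one permutation engine.

new_perm_test <- function(statistic, p_value, n_perm, method,
                          null_statistics = NULL, extra = list()) {
  structure(
    c(list(
      statistic = statistic,
      p_value = p_value,
      n_perm = n_perm,
      method = method,
      null_statistics = null_statistics
    ), extra),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s)\n", x$method))
  for (s in names(x$statistic)) cat(sprintf("  %-8s %0.6g\n", s, x$statistic[[s]]))
  if (!is.null(x$p_value) && !is.na(x$p_value)) {
    cat(sprintf("  p = %0.4g (%d permutations)\n", x$p_value, x$n_perm))
  }
  invisible(x)
}

#' Tidy a permutation-test result
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble with the statistic(s), p-value and permutation
#'   count.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  out <- tibble::as_tibble(as.list(x$statistic))
  out$p_value <- x$p_value
  out$n_perm <- x$n_perm
  out$method <- x$method
  out
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x, ...)

# Shared checks: distance matrix + grouping -> list(d, g) with g a factor.
check_test_inputs <- function(d, g, min_big_groups = 2) {
  d <- validate_distance_matrix(d)
  g <- as_group_factor(g, rownames(d))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  sizes <- table(g)
  if (sum(sizes >= 2) < min_big_groups) {
    abort(sprintf("need at least %d groups with >= 2 members", min_big_groups))
  }
  list(d = d, g = g)
}

# Draw `n_perm` label permutations of 1..n, seeded.
label_perms <- function(n, n_perm, seed) {
  with_seed_if(seed, lapply(seq_len(n_perm), function(i) sample.int(n)))
}

#' Analysis of similarities (ANOSIM)
#'
#' All `n(n-1)/2` dissimilarities are ranked (average ranks for ties) and
#' `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2`. `R` lies in `[-1, 1]`; 1 means all within-group
#' dissimilarities are smaller than all between-group ones. Significance is a
#' one-sided (large R) permutation test over group labels with the +1
#' correction.
#'
#' @param d Square named distance matrix.
#' @param g Grouping: a tibble (`sample_id`, label), a named vector, or a
#'   vector in matrix order. At least two groups with two or more members are
#'   required; singleton groups contribute only between-group pairs.
#' @param n_perm Number of label permutations (0 = statistic only, p = NA).
#' @param seed Optional integer seed.
#' @return A `perm_test` object with statistic `R`.
#' @export
anosim_test <- function(d, g, n_perm = 999, seed = NULL) {
  inp <- check_test_inputs(d, g)
  d <- inp$d; g <- inp$g
  n <- nrow(d)
  idx <- lower_pairs(n)
  rk <- rank(d[idx])
  gi <- as.integer(g)
  half_m <- length(rk) / 2
  tot <- sum(rk)
  stat_fn <- function(lab) {
    within <- lab[idx[, 1]] == lab[idx[, 2]]
    nw <- sum(within)
    sw <- sum(rk[within])
    ((tot - sw) / (length(rk) - nw) - sw / nw) / half_m
  }
  r_obs <- stat_fn(gi)
  if (n_perm >= 1) {
    nulls <- vapply(label_perms(n, n_perm, seed), function(p) stat_fn(gi[p]), numeric(1))
    p <- perm_pvalue(r_obs, nulls, "greater")
  } else {
    nulls <- NULL; p <- NA_real_
  }
  new_perm_test(c(R = r_obs), p, n_perm, "anosim", nulls)
}

# Weighted mean within-group dissimilarity; groups of size 1 excluded.
mrpp_delta <- function(d, gi, weight) {
  sizes <- tabulate(gi)
  use <- which(sizes >= 2)
  w <- switch(weight,
    group_size = sizes[use] / sum(sizes[use]),
    group_size_minus_1 = (sizes[use] - 1) / sum(sizes[use] - 1)
  )
  means <- vapply(use, function(k) {
    m <- which(gi == k)
    sub <- d[m, m]
    sum(sub) / (length(m) * (length(m) - 1))
  }, numeric(1))
  sum(w * means)
}

#' Multi-response permutation procedure (MRPP)
#'
#' `delta` is the group-size-weighted mean within-group dissimilarity
#' (singleton groups are excluded); the chance-corrected effect size is
#' `A = 1 - delta / E[delta]` with `E[delta]` the mean of the permutation
#' null. Small `delta` (tight groups) is the extreme direction:
#' `p = (1 + #{delta* <= delta}) / (1 + n_perm)`.
#'
#' @inheritParams anosim_test
#' @param weight `"group_size"` (w = n_g / sum n_g, the default) or
#'   `"group_size_minus_1"`.
#' @return A `perm_test` object with statistics `delta` and `A` (`A` is `NA`
#'   when `n_perm = 0`).
#' @export
mrpp_test <- function(d, g, n_perm = 999, seed = NULL,
                      weight = c("group_size", "group_size_minus_1")) {
  weight <- match.arg(weight)
  inp <- check_test_inputs(d, g)
  d <- inp$d; g <- inp$g
  n <- nrow(d)
  gi <- as.integer(g)
  delta_obs <- mrpp_delta(d, gi, weight)
  if (n_perm >= 1) {
    nulls <- vapply(label_perms(n, n_perm, seed),
                    function(p) mrpp_delta(d, gi[p], weight), numeric(1))
    p <- perm_pvalue(delta_obs, nulls, "less")
    a <- 1 - delta_obs / mean(nulls)
  } else {
    nulls <- NULL; p <- NA_real_; a <- NA_real_
  }
  new_perm_test(c(delta = delta_obs, A = a), p, n_perm, "mrpp", nulls)
}

# PERMANOVA pseudo-F from squared dissimilarities (Gower identity).
permanova_f <- function(d2, gi, n, k) {
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (g in seq_len(max(gi))) {
    m <- which(gi == g)
    if (length(m) >= 2) {
      sub <- d2[m, m]
      ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(m)
    }
  }
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based sums of squares: `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `pseudo-F = (SS_between / (k-1)) / (SS_within / (n-k))`. On Euclidean
#' distances of one-dimensional points this equals the classical one-way
#' ANOVA F. One-sided (large F) label-permutation p-value.
#'
#' @inheritParams anosim_test
#' @return A `perm_test` object with statistics `F`, `R2` (SS_between /
#'   SS_total).
#' @export
permanova_test <- function(d, g, n_perm = 999, seed = NULL) {
  d <- validate_distance_matrix(d)
  g <- droplevels(as_group_factor(g, rownames(d)))
  n <- nrow(d)
  k <- nlevels(g)
  if (k < 2) abort("need at least 2 groups")
  if (n <= k) abort("need more samples than groups")
  gi <- as.integer(g)
  d2 <- d^2
  f_obs <- permanova_f(d2, gi, n, k)
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  r2 <- f_obs * (k - 1) / (f_obs * (k - 1) + (n - k))
  if (n_perm >= 1) {
    nulls <- vapply(label_perms(n, n_perm, seed),
                    function(p) permanova_f(d2, gi[p], n, k), numeric(1))
    p <- perm_pvalue(f_obs, nulls, "greater")
  } else {
    nulls <- NULL; p <- NA_real_
  }
  new_perm_test(c(F = f_obs, R2 = r2), p, n_perm, "permanova", nulls)
}
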