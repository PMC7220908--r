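# Community-class detection: PAM k-medoids scored by the Calinski-Harabasz
# index generalised to arbitrary dissimilarities, plus classification
# agreement and the day/month/site/class ANOSIM report.

#' Partitioning around medoids
#'
#' Thin wrapper over `cluster::pam()` on a precomputed dissimilarity
#' (BUILD + SWAP until no swap lowers the total distance to medoids).
#'
#' @param d Square named distance matrix.
#' @param k Number of clusters, `2 <= k <= n - 1`.
#' @return A list with `medoid_ids` (sample ids), `labels` (classification
#'   tibble) and `objective` (sum over samples of the distance to the
#'   assigned medoid).
#' @export
pam_medoids <- function(d, k) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (k < 2 || k > n - 1) abort("k must be in [2, n - 1]")
  fit <- cluster::pam(stats::as.dist(d), k = k, pamonce = 0)
  medoids <- rownames(d)[fit$id.med]
  labels <- new_classification(rownames(d), fit$clustering, kind = "class")
  objective <- sum(vapply(seq_len(n), function(i) {
    min(d[i, fit$id.med])
  }, numeric(1)))
  list(medoid_ids = medoids, labels = labels, objective = objective)
}

#' Calinski-Harabasz index from a dissimilarity matrix
#'
#' The classical CH index is a ratio of between- to within-cluster dispersion
#' around centroids. Centroids do not exist for arbitrary dissimilarities, so
#' the sums of squares are computed through the Gower identity also used by
#' PERMANOVA: `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `SS_B = SS_total - SS_W`, and
#' `CH = (SS_B / (k-1)) / (SS_W / (n-k))`. On Euclidean distances this equals
#' the coordinate-based index. `SS_W = 0` returns `Inf`.
#'
#' @param d Square named distance matrix.
#' @param labels Grouping (tibble, named vector, or vector in matrix order).
#' @return The CH value (possibly `Inf`).
#' @export
calinski_harabasz <- function(d, labels) {
  d <- validate_distance_matrix(d)
  g <- droplevels(as_group_factor(labels, rownames(d)))
  n <- nrow(d)
  k <- nlevels(g)
  if (k < 2 || k > n - 1) abort("number of groups must be in [2, n - 1]")
  d2 <- d^2
  ss_tot <- sum(d2[lower.tri(d2)]) / n
  ss_w <- 0
  for (lev in levels(g)) {
    m <- which(g == lev)
    if (length(m) >= 2) {
      sub <- d2[m, m]
      ss_w <- ss_w + sum(sub[lower.tri(sub)]) / length(m)
    }
  }
  ss_b <- ss_tot - ss_w
  if (ss_w <= 0) return(Inf)
  (ss_b / (k - 1)) / (ss_w / (n - k))
}

#' Detect community classes by PAM + Calinski-Harabasz selection
#'
#' Runs PAM for every `k` in `k_range`, scores each partition with
#' [calinski_harabasz()], and returns the model at the CH maximum (smallest
#' `k` on ties). A weak-structure flag is raised when the CH maximum is less
#' than `weak_ratio` times the median of the CH curve, indicating no
#' pronounced optimum.
#'
#' @param d Square named beta-diversity distance matrix.
#' @param k_range Integer candidate cluster counts (default `2:20`).
#' @param weak_ratio Threshold for the weak-structure flag (default 1.5).
#' @return An object of class `class_model` with fields `k_opt`,
#'   `medoid_ids`, `labels` (classification tibble), `ch_curve` (tibble of
#'   `k`, `ch`, `objective`), `pam_objective` and `weak_structure`.
#' @export
find_classes <- function(d, k_range = 2:20, weak_ratio = 1.5) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) abort("k_range is empty")
  if (min(k_range) < 2 || max(k_range) > n - 1) abort("k_range must lie within [2, n - 1]")
  fits <- vector("list", length(k_range))
  ch <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- pam_medoids(d, k_range[i])
    ch[i] <- calinski_harabasz(d, fits[[i]]$labels)
  }
  best <- which.max(ch)  # first maximum = smallest k on ties
  fit <- fits[[best]]
  finite_ch <- ch[is.finite(ch)]
  weak <- length(finite_ch) > 0 &&
    max(finite_ch) < weak_ratio * stats::median(finite_ch)
  structure(list(
    k_opt = k_range[best],
    medoid_ids = fit$medoid_ids,
    labels = fit$labels,
    ch_curve = tibble(k = k_range, ch = ch,
                      objective = vapply(fits, function(f) f$objective, numeric(1))),
    pam_objective = fit$objective,
    weak_structure = weak
  ), class = "class_model")
}

#' @export
print.class_model <- function(x, ...) {
  cat(sprintf("Community classes: k_opt = %d (CH = %0.4g)%s\n",
              x$k_opt, max(x$ch_curve$ch),
              if (x$weak_structure) " [weak structure]" else ""))
  cat(sprintf("  medoids: %s\n", paste(x$medoid_ids, collapse = ", ")))
  invisible(x)
}

#' Tidy methods for community-class models
#'
#' `tidy()` returns the per-sample class assignments; `glance()` a one-row
#' model summary.
#'
#' @param x A `class_model` from [find_classes()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy class_model
#' @export
tidy.class_model <- function(x, ...) x$labels

#' @rdname tidy.class_model
#' @method glance class_model
#' @export
glance.class_model <- function(x, ...) {
  tibble(
    k_opt = x$k_opt,
    ch_max = max(x$ch_curve$ch),
    pam_objective = x$pam_objective,
    weak_structure = x$weak_structure
  )
}

#' CH curve plot for a community-class model
#'
#' @param object A `class_model`.
#' @param ... Unused.
#' @return A ggplot of the Calinski-Harabasz index against `k`, with the
#'   optimum marked.
#' @method autoplot class_model
#' @export
autoplot.class_model <- function(object, ...) {
  ggplot2::ggplot(object$ch_curve, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_opt, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "Calinski-Harabasz index")
}

#' Agreement between two classifications
#'
#' Adjusted Rand index (permutation-model chance correction) and normalised
#' mutual information (arithmetic-mean normalisation), both computed from the
#' contingency table of the two labelings.
#'
#' @param a,b Classification tibbles (`sample_id`, `label`) or named label
#'   vectors over the same samples.
#' @return A one-row tibble with columns `ari` and `nmi`.
#' @export
compare_classifications <- function(a, b) {
  la <- classification_labels(a)
  lb <- classification_labels(b)
  if (!setequal(names(la), names(lb))) abort("classifications cover different samples")
  lb <- lb[names(la)]
  tab <- table(la, lb)
  tibble(ari = rand_index_adjusted(tab), nmi = nmi_arithmetic(tab))
}

classification_labels <- function(x) {
  if (is.data.frame(x)) {
    stats::setNames(as.character(x$label), x$sample_id)
  } else if (!is.null(names(x))) {
    stats::setNames(as.character(x), names(x))
  } else {
    abort("classification must be a tibble or a named vector")
  }
}

rand_index_adjusted <- function(tab) {
  n <- sum(tab)
  sum_cells <- sum(choose(tab, 2))
  sum_rows <- sum(choose(rowSums(tab), 2))
  sum_cols <- sum(choose(colSums(tab), 2))
  expected <- sum_rows * sum_cols / choose(n, 2)
  max_idx <- (sum_rows + sum_cols) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_cells - expected) / (max_idx - expected)
}

nmi_arithmetic <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  pr <- rowSums(p)
  pc <- colSums(p)
  hr <- -sum(xlogx(pr, exp(1)))
  hc <- -sum(xlogx(pc, exp(1)))
  mi <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (pr[i] * pc[j]))
    }
  }
  if (hr + hc == 0) return(1)  # both single-cluster: identical partitions
  unname(2 * mi / (hr + hc))
}

#' ANOSIM report across day, month, site and class groupings
#'
#' Builds the four standard classifications (calendar day of sampling,
#' calendar month, site label, and optionally detected community classes) and
#' reports the ANOSIM R of the beta-diversity matrix against each. Groupings
#' with fewer than two groups of two or more members are marked untestable.
#'
#' @param dbeta Beta-diversity distance matrix.
#' @param meta Metadata tibble with `sample_id`, `date`, `site`.
#' @param classes Optional classification tibble of community classes.
#' @param n_perm Permutations per ANOSIM (0 = statistic only).
#' @param seed Optional integer seed.
#' @return A tibble with one row per grouping: `grouping`, `n_groups`,
#'   `testable`, `anosim_R`, `anosim_p`.
#' @export
grouping_anosim_report <- function(dbeta, meta, classes = NULL,
                                   n_perm = 999, seed = NULL) {
  dbeta <- validate_distance_matrix(dbeta, "dbeta")
  ids <- rownames(dbeta)
  if (!all(ids %in% meta$sample_id)) abort("metadata does not cover all samples")
  meta <- meta[match(ids, meta$sample_id), ]
  groupings <- list(
    day = as.character(meta$date),
    month = format(meta$date, "%Y-%m"),
    site = as.character(meta$site)
  )
  if (!is.null(classes)) {
    lab <- classification_labels(classes)
    groupings$class <- unname(lab[ids])
  }
  rows <- purrr::imap(groupings, function(lab, nm) {
    sizes <- table(lab)
    testable <- length(sizes) >= 2 && sum(sizes >= 2) >= 2
    row <- tibble(grouping = nm, n_groups = length(sizes), testable = testable,
                  anosim_R = NA_real_, anosim_p = NA_real_)
    if (testable) {
      fit <- anosim_test(dbeta, stats::setNames(lab, ids), n_perm = n_perm, seed = seed)
      row$anosim_R <- fit$statistic[["R"]]
      row$anosim_p <- fit$p_value
    }
    row
  })
  dplyr::bind_rows(rows)
}
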