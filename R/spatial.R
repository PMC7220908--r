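# Geographic distances, threshold clustering and the multi-scale scan.

#' Default ladder of spatial thresholds
#'
#' Ten half-decade cutoffs `10^0.5 ... 10^5` metres (~3.16 m to 100 km),
#' spanning five orders of magnitude. Interpreted as `sqrt(A)` cutoffs for
#' clustering samples within areas `A`.
#'
#' @param from,to Log10 range in metres.
#' @param by Log10 step.
#' @return A strictly increasing numeric vector of thresholds in metres.
#' @export
threshold_ladder <- function(from = 0.5, to = 5, by = 0.5) {
  10^seq(from, to, by = by)
}

#' Spatial distance matrix from sample metadata
#'
#' @param meta Metadata tibble with `sample_id` plus either `x_m`/`y_m`
#'   (planar metres) or `lat`/`lon` (degrees).
#' @param mode `"euclidean_m"` for planar distances or `"haversine"` for
#'   great-circle distances on a sphere of radius 6,371,000 m.
#' @return A square named distance matrix in metres.
#' @export
spatial_distance_matrix <- function(meta, mode = c("euclidean_m", "haversine")) {
  mode <- match.arg(mode)
  ids <- meta$sample_id
  if (mode == "euclidean_m") {
    if (!all(c("x_m", "y_m") %in% names(meta))) abort("euclidean_m needs x_m and y_m columns")
    bad <- ids[is.na(meta$x_m) | is.na(meta$y_m)]
    if (length(bad) > 0) abort(sprintf("missing coordinates for: %s", paste(bad, collapse = ", ")))
    d <- as.matrix(stats::dist(cbind(meta$x_m, meta$y_m)))
  } else {
    if (!all(c("lat", "lon") %in% names(meta))) abort("haversine needs lat and lon columns")
    bad <- ids[is.na(meta$lat) | is.na(meta$lon)]
    if (length(bad) > 0) abort(sprintf("missing coordinates for: %s", paste(bad, collapse = ", ")))
    d <- geosphere::distm(cbind(meta$lon, meta$lat),
                          fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000))
  }
  dimnames(d) <- list(ids, ids)
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Cluster samples at a spatial threshold
#'
#' Agglomerative clustering of the spatial distance matrix, cut at merge
#' height `h`: two samples share a cluster when they are joined at a height
#' `<= h`. With complete linkage (the default) every cluster has diameter
#' `<= h`, so cutting at `sqrt(A)` approximates grouping samples within areas
#' of size `A`.
#'
#' @param d Square named (spatial) distance matrix.
#' @param h Positive cut height in the units of `d`.
#' @param linkage One of `"complete"`, `"single"`, `"average"`.
#' @return A classification tibble with columns `sample_id` and `label`
#'   (cluster id as character).
#' @export
cluster_at_threshold <- function(d, h, linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  d <- validate_distance_matrix(d)
  if (h <= 0) abort("h must be > 0")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  labels <- stats::cutree(hc, h = h)
  new_classification(rownames(d), labels, kind = "spatial")
}

#' Multi-scale distance-decay scan
#'
#' For each spatial threshold, samples are clustered in space
#' ([cluster_at_threshold()]) and the beta-diversity matrix is tested against
#' that classification with ANOSIM, MRPP and PERMANOVA. Thresholds where
#' fewer than two clusters have two or more members (or where there is a
#' single cluster) are marked untestable rather than silently dropped.
#'
#' @param dspace Spatial distance matrix.
#' @param dbeta Beta-diversity distance matrix over the same samples.
#' @param thresholds Increasing vector of cut heights; default
#'   [threshold_ladder()].
#' @param linkage Linkage passed to [cluster_at_threshold()].
#' @param n_perm Permutations per test (0 = statistics only).
#' @param seed Optional integer seed (each threshold uses an offset of it).
#' @return A tibble of class `scale_profile`: one row per threshold with
#'   `threshold_m`, `n_clusters`, `testable`, `anosim_R`, `anosim_p`,
#'   `mrpp_delta`, `mrpp_A`, `mrpp_p`, `permanova_F`, `permanova_p`.
#' @export
scale_scan <- function(dspace, dbeta, thresholds = threshold_ladder(),
                       linkage = "complete", n_perm = 999, seed = NULL) {
  dspace <- validate_distance_matrix(dspace, "dspace")
  dbeta <- validate_distance_matrix(dbeta, "dbeta")
  if (!setequal(rownames(dspace), rownames(dbeta))) {
    abort("sample ids of dspace and dbeta differ")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) abort("thresholds must be strictly increasing")
  dbeta <- dbeta[rownames(dspace), rownames(dspace)]
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    h <- thresholds[i]
    cl <- cluster_at_threshold(dspace, h, linkage)
    sizes <- table(cl$label)
    n_clusters <- length(sizes)
    testable <- n_clusters >= 2 && sum(sizes >= 2) >= 2
    row <- tibble(
      threshold_m = h, n_clusters = n_clusters, testable = testable,
      anosim_R = NA_real_, anosim_p = NA_real_,
      mrpp_delta = NA_real_, mrpp_A = NA_real_, mrpp_p = NA_real_,
      permanova_F = NA_real_, permanova_p = NA_real_
    )
    if (testable) {
      s <- if (is.null(seed)) NULL else seed + i
      an <- anosim_test(dbeta, cl, n_perm = n_perm, seed = s)
      mr <- mrpp_test(dbeta, cl, n_perm = n_perm, seed = s)
      pm <- permanova_test(dbeta, cl, n_perm = n_perm, seed = s)
      row$anosim_R <- an$statistic[["R"]]; row$anosim_p <- an$p_value
      row$mrpp_delta <- mr$statistic[["delta"]]; row$mrpp_A <- mr$statistic[["A"]]
      row$mrpp_p <- mr$p_value
      row$permanova_F <- pm$statistic[["F"]]; row$permanova_p <- pm$p_value
    }
    rows[[i]] <- row
  }
  out <- dplyr::bind_rows(rows)
  if (!any(out$testable)) abort("no threshold is testable")
  class(out) <- c("scale_profile", class(out))
  out
}

#' Plot a multi-scale statistic profile
#'
#' ANOSIM R, MRPP delta and PERMANOVA pseudo-F against log10 spatial
#' threshold, one panel per statistic.
#'
#' @param object A `scale_profile` tibble from [scale_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scale_profile
#' @export
autoplot.scale_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "threshold_m",
                  "anosim_R", "mrpp_delta", "permanova_F"),
    -"threshold_m", names_to = "statistic", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$threshold_m), y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "log10 spatial threshold (m)", y = "statistic")
}
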