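test_that("PAM matches exhaustive search over medoid sets on toy data", {
  d <- point_dist(c(0, 1, 2, 10, 11, 12))
  fit <- pam_medoids(d, 2)
  expect_setequal(fit$medoid_ids, c("s02", "s05"))
  expect_equal(fit$objective, 4)

  # brute force over all C(6,2) medoid pairs
  best <- Inf
  for (pair in asplit(combn(6, 2), 2)) {
    obj <- sum(apply(d[, pair, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  expect_equal(fit$objective, best)

  # k = n-1 on random instances equals the smallest pairwise link
  set.seed(14)
  for (rep in 1:5) {
    dr <- random_dist(7)
    expect_equal(pam_medoids(dr, 6)$objective, min(dr[lower.tri(dr)]))
  }
})

test_that("a duplicated medoid point is absorbed at zero cost", {
  pts <- c(0, 1, 2, 10, 11, 12, 1)  # duplicate of the first triad's medoid
  d <- point_dist(pts)
  expect_equal(pam_medoids(d, 2)$objective, 4)
  expect_error(pam_medoids(d, 1), "k must be")
  expect_error(pam_medoids(d, 7), "k must be")
})

test_that("dissimilarity-based CH equals the coordinate-space index on Euclidean data", {
  set.seed(15)
  for (rep in 1:5) {
    x <- rnorm(12)
    g <- sample(rep(c("a", "b", "c"), 4))
    expect_equal(calinski_harabasz(point_dist(x), g),
                 oracle_ch_euclidean(x, g), tolerance = 1e-10)
  }
  # two tight far-apart blobs: k=2 beats k=3
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1))
  d <- point_dist(x)
  ch2 <- calinski_harabasz(d, rep(c("a", "b"), each = 10))
  ch3 <- calinski_harabasz(d, c(rep("a", 5), rep("c", 5), rep("b", 10)))
  expect_gt(ch2, ch3)
  # SS_W = 0 -> +Inf sentinel
  dd <- point_dist(c(0, 0, 5, 5))
  expect_equal(calinski_harabasz(dd, c("a", "a", "b", "b")), Inf)
})

test_that("find_classes recovers planted succession classes", {
  sim <- simulate_succession_communities(succession_spec(seed = 33))
  d <- jsd_matrix(sim$counts)
  cm <- find_classes(d, 2:12)
  expect_equal(cm$k_opt, 6)
  expect_false(cm$weak_structure)
  agg <- compare_classifications(cm$labels, sim$classes)
  expect_gt(agg$ari, 0.95)
  # medoids belong to their own clusters, every sample to its nearest medoid
  med_lab <- cm$labels$label[match(cm$medoid_ids, cm$labels$sample_id)]
  expect_equal(sort(unique(med_lab)), sort(unique(cm$labels$label)))
  nearest <- apply(d[, cm$medoid_ids], 1, which.min)
  expect_equal(unname(med_lab[nearest]), cm$labels$label)
})

test_that("single-class data yields a flat CH curve flagged as weak structure", {
  spec <- succession_spec(n_taxa = 150, n_sites = 4, trees_per_site = 3,
                          rate_range = c(0, 0), seed = 2,
                          sampling_dates = as.Date(c("2013-09-01", "2013-09-29", "2013-10-27")))
  sim <- simulate_succession_communities(spec)
  expect_equal(unique(sim$classes$label), "C1")
  cm <- find_classes(jsd_matrix(sim$counts), 2:8)
  expect_true(cm$weak_structure)
})

test_that("find_classes is deterministic, order-invariant and breaks CH ties to smallest k", {
  sim <- simulate_succession_communities(
    succession_spec(n_taxa = 150, n_sites = 5, trees_per_site = 2, seed = 44))
  d <- jsd_matrix(sim$counts)
  cm1 <- find_classes(d, 2:8)
  perm <- sample(rownames(d))
  cm2 <- find_classes(d[perm, perm], 2:8)
  expect_equal(cm1$k_opt, cm2$k_opt)
  expect_setequal(cm1$medoid_ids, cm2$medoid_ids)

  # ties: on 4 equidistant points every 2-cluster split scores the same,
  # so the smallest k in the range is returned
  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 0
  cm3 <- find_classes(eq, 2:3)
  expect_equal(cm3$k_opt, 2)
})

test_that("classification agreement matches identity, chance and pair counting", {
  ids <- sprintf("s%d", 1:8)
  a <- setNames(rep(c("x", "y"), each = 4), ids)
  expect_equal(compare_classifications(a, a), tibble::tibble(ari = 1, nmi = 1))

  set.seed(16)
  aris <- replicate(200, {
    b <- setNames(sample(a), ids)
    compare_classifications(a, b)$ari
  })
  expect_lt(abs(mean(aris)), 0.1)

  # 4-sample toy vs pair-counting oracle
  a4 <- setNames(c("u", "u", "v", "v"), ids[1:4])
  b4 <- setNames(c("1", "2", "2", "2"), ids[1:4])
  expect_equal(compare_classifications(a4, b4)$ari,
               oracle_ari(unname(a4), unname(b4)))
  set.seed(17)
  for (rep in 1:20) {
    la <- sample(letters[1:3], 7, replace = TRUE)
    lb <- sample(letters[1:3], 7, replace = TRUE)
    expect_equal(compare_classifications(setNames(la, ids[1:7]), setNames(lb, ids[1:7]))$ari,
                 oracle_ari(la, lb))
  }
  skip_if_not_installed("mclust")
  expect_equal(compare_classifications(a4, b4)$ari,
               mclust::adjustedRandIndex(unname(a4), unname(b4)))
})

test_that("grouping report shows day > site on date-driven data and the converse", {
  sim <- simulate_succession_communities(succession_spec(seed = 55))
  d <- jsd_matrix(sim$counts)
  rep_date <- grouping_anosim_report(d, sim$metadata, classes = sim$classes, n_perm = 0)
  r <- setNames(rep_date$anosim_R, rep_date$grouping)
  expect_gt(r[["day"]], r[["site"]])
  expect_gt(r[["day"]], r[["month"]])
  expect_gt(r[["class"]], r[["site"]])

  sim2 <- simulate_succession_communities(succession_spec(seed = 55, class_driver = "site"))
  d2 <- jsd_matrix(sim2$counts)
  rep_site <- grouping_anosim_report(d2, sim2$metadata, n_perm = 0)
  r2 <- setNames(rep_site$anosim_R, rep_site$grouping)
  expect_gt(r2[["site"]], r2[["day"]])

  # all samples on one date: day grouping untestable
  meta_one <- sim$metadata
  meta_one$date <- as.Date("2013-09-01")
  rep_one <- grouping_anosim_report(d, meta_one, n_perm = 0)
  expect_false(rep_one$testable[rep_one$grouping == "day"])
  expect_true(is.na(rep_one$anosim_R[rep_one$grouping == "day"]))
})
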