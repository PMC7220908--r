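# The three tests share a toy configuration: 6 samples in two triads on a
# line, where the grouping structure is known exactly.
triad_dist <- function() point_dist(c(0, 1, 2, 10, 11, 12))
triad_groups <- function() rep(c("A", "B"), each = 3)

test_that("ANOSIM hits its closed-form extremes", {
  d <- triad_dist()
  g <- triad_groups()
  expect_equal(anosim_test(d, g, n_perm = 0)$statistic[["R"]], 1)

  tie <- matrix(1, 6, 6, dimnames = dimnames(d))
  diag(tie) <- 0
  expect_equal(anosim_test(tie, g, n_perm = 0)$statistic[["R"]], 0)

  expect_error(anosim_test(d, rep("A", 6)), "2 groups")
})

test_that("ANOSIM R and its exhaustive-enumeration p match the rank oracle", {
  set.seed(3)
  d <- random_dist(6)
  g <- triad_groups()
  fit <- anosim_test(d, g, n_perm = 1999, seed = 4)
  expect_equal(fit$statistic[["R"]], oracle_anosim_R(d, g))

  # exact p over all C(6,3) = 20 relabelings (label swap A<->B is the same split)
  combos <- combn(6, 3)
  r_all <- apply(combos, 2, function(m) {
    lab <- rep("B", 6); lab[m] <- "A"
    oracle_anosim_R(d, lab)
  })
  p_exact <- mean(r_all >= fit$statistic[["R"]] - 1e-12)
  expect_lt(abs(fit$p_value - p_exact), 0.05)
})

test_that("MRPP delta, A and p agree with hand summation and enumeration", {
  d <- triad_dist()
  g <- triad_groups()
  # every within-group dissimilarity pattern is {1,1,2} in both triads
  expect_equal(mrpp_test(d, g, n_perm = 0)$statistic[["delta"]], mean(c(1, 1, 2)))

  set.seed(5)
  dr <- random_dist(6)
  fit <- mrpp_test(dr, g, n_perm = 1999, seed = 6)
  expect_equal(fit$statistic[["delta"]], oracle_mrpp_delta(dr, g))

  combos <- combn(6, 3)
  deltas <- apply(combos, 2, function(m) {
    lab <- rep("B", 6); lab[m] <- "A"
    oracle_mrpp_delta(dr, lab)
  })
  p_exact <- mean(deltas <= fit$statistic[["delta"]] + 1e-12)
  expect_lt(abs(fit$p_value - p_exact), 0.06)
  a_exact <- 1 - fit$statistic[["delta"]] / mean(deltas)
  expect_lt(abs(fit$statistic[["A"]] - a_exact), 0.05)

  # constant-case: every within dissimilarity c -> delta = c
  const <- matrix(0.7, 6, 6, dimnames = dimnames(d))
  diag(const) <- 0
  expect_equal(mrpp_test(const, g, n_perm = 0)$statistic[["delta"]], 0.7)
})

test_that("MRPP A is centred at zero under shuffled labels", {
  set.seed(15)
  d <- random_dist(14)
  g <- rep(c("A", "B"), 7)
  a_vals <- replicate(60, {
    mrpp_test(d, sample(g), n_perm = 99, seed = NULL)$statistic[["A"]]
  })
  expect_lt(abs(mean(a_vals)), 0.05)
})

test_that("PERMANOVA pseudo-F equals classical one-way ANOVA F on 1-D data", {
  set.seed(6)
  for (rep in 1:5) {
    x <- rnorm(12)
    g <- sample(rep(c("a", "b", "c"), 4))
    d <- point_dist(x)
    f_pkg <- permanova_test(d, g, n_perm = 0)$statistic[["F"]]
    f_anova <- anova(lm(x ~ g))$`F value`[1]
    expect_equal(f_pkg, f_anova, tolerance = 1e-10)
  }
})

test_that("PERMANOVA separates translated groups and rejects bad designs", {
  set.seed(7)
  xy <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 50, 10))
  d <- point_dist(xy)
  g <- rep(c("A", "B"), each = 10)
  fit <- permanova_test(d, g, n_perm = 199, seed = 8)
  expect_gt(fit$statistic[["F"]], 100)
  expect_equal(fit$p_value, 1 / 200)
  expect_error(permanova_test(d, rep("A", 20)), "2 groups")
  d3 <- point_dist(rnorm(3))
  expect_error(permanova_test(d3, c("a", "b", "c")), "more samples")
})

test_that("all three statistics agree with brute force on random tiny instances", {
  set.seed(9)
  for (case in 1:40) {
    n <- sample(5:8, 1)
    repeat {
      g <- sample(letters[1:sample(2:3, 1)], n, replace = TRUE)
      if (sum(table(g) >= 2) >= 2 && length(unique(g)) >= 2 && n > length(unique(g))) break
    }
    d <- random_dist(n)
    expect_equal(anosim_test(d, g, n_perm = 0)$statistic[["R"]], oracle_anosim_R(d, g))
    expect_equal(mrpp_test(d, g, n_perm = 0)$statistic[["delta"]], oracle_mrpp_delta(d, g))
    expect_equal(permanova_test(d, g, n_perm = 0)$statistic[["F"]], oracle_permanova_F(d, g))
  }
})

test_that("statistics are invariant to sample reordering and label renaming", {
  set.seed(10)
  d <- random_dist(10)
  g <- rep(c("A", "B"), 5)
  perm <- sample.int(10)
  dp <- d[perm, perm]
  gp <- setNames(g, rownames(d))[rownames(dp)]
  for (fn in list(anosim_test, mrpp_test, permanova_test)) {
    s1 <- fn(d, g, n_perm = 0)$statistic
    s2 <- fn(dp, gp, n_perm = 0)$statistic
    s3 <- fn(d, chartr("AB", "xy", g), n_perm = 0)$statistic
    expect_equal(s1[1], s2[1], tolerance = 1e-12)
    expect_equal(s1[1], s3[1], tolerance = 1e-12)
  }
})

test_that("the permutation engine is seed-reproducible and never returns p = 0", {
  set.seed(11)
  d <- random_dist(10)
  g <- rep(c("A", "B"), 5)
  for (fn in list(anosim_test, mrpp_test, permanova_test)) {
    f1 <- fn(d, g, n_perm = 99, seed = 3)
    f2 <- fn(d, g, n_perm = 99, seed = 3)
    expect_identical(f1$p_value, f2$p_value)
    expect_gt(f1$p_value, 0)
  }
})

test_that("statistics match vegan on a moderate instance", {
  skip_if_not_installed("vegan")
  set.seed(12)
  d <- random_dist(15)
  g <- factor(rep(c("A", "B", "C"), 5))
  expect_equal(anosim_test(d, g, n_perm = 0)$statistic[["R"]],
               unname(vegan::anosim(as.dist(d), g, permutations = 2)$statistic),
               tolerance = 1e-12)
  expect_equal(mrpp_test(d, g, n_perm = 0)$statistic[["delta"]],
               vegan::mrpp(as.dist(d), g, permutations = 2)$delta,
               tolerance = 1e-12)
  expect_equal(permanova_test(d, g, n_perm = 0)$statistic[["F"]],
               vegan::adonis2(as.dist(d) ~ g, permutations = 2)$F[1],
               tolerance = 1e-12)
})
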