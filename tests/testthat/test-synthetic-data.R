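test_that("all generators are byte-identical under the same seed", {
  s1 <- simulate_distance_scenario(scenario_mean_increase(seed = 31))
  s2 <- simulate_distance_scenario(scenario_mean_increase(seed = 31))
  expect_identical(s1, s2)

  spec <- succession_spec(n_taxa = 100, n_sites = 3, trees_per_site = 2, seed = 31,
                          sampling_dates = as.Date(c("2013-09-01", "2013-10-13")))
  expect_identical(simulate_succession_communities(spec),
                   simulate_succession_communities(spec))

  cls <- tibble::tibble(sample_id = sprintf("S%03d", 1:50), label = "C1")
  pspec <- path_model_spec(seed = 31)
  expect_identical(simulate_functions(pspec, cls), simulate_functions(pspec, cls))
})

test_that("degenerate-noise scenarios give exact means", {
  spec <- scenario_spec(n_locations = 4, samples_per_location = 3,
                        mu_within = 0.25, mu_between = mu_const(0.6),
                        sigma_within = 0, sigma_between = 0, seed = 32)
  sim <- simulate_distance_scenario(spec)
  loc <- sim$metadata$location
  idx <- which(lower.tri(sim$distances), arr.ind = TRUE)
  within <- loc[idx[, 1]] == loc[idx[, 2]]
  expect_true(all(sim$distances[idx][within] == 0.25))
  expect_true(all(sim$distances[idx][!within] == 0.6))
})

test_that("scenario draws match the requested truncated-normal moments", {
  spec <- scenario_spec(mu_within = 0.2, sigma_within = 0.05, seed = 33)
  sim <- simulate_distance_scenario(spec)
  loc <- sim$metadata$location
  idx <- which(lower.tri(sim$distances), arr.ind = TRUE)
  within_vals <- sim$distances[idx][loc[idx[, 1]] == loc[idx[, 2]]]
  # 10 locations x 10 samples = 450 within pairs; SE = 0.05 / sqrt(450)
  expect_lt(abs(mean(within_vals) - 0.2), 3 * 0.05 / sqrt(length(within_vals)))
})

test_that("the null scenario is exchangeable: ANOSIM R near zero", {
  spec <- scenario_spec(mu_within = 0.4, mu_between = mu_const(0.4),
                        sigma_within = 0.1, sigma_between = 0.1, seed = 34)
  sim <- simulate_distance_scenario(spec)
  r <- anosim_test(sim$distances,
                   setNames(sim$metadata$location, sim$metadata$sample_id),
                   n_perm = 0)$statistic[["R"]]
  expect_lt(abs(r), 0.1)
})

test_that("extreme truncation triggers the distribution warning", {
  spec <- scenario_spec(mu_within = 0.5, mu_between = mu_const(0.5),
                        sigma_within = 5, sigma_between = 5, seed = 35)
  expect_warning(simulate_distance_scenario(spec), "truncation")
})

test_that("succession communities are date-informed under regional rain", {
  sim <- simulate_succession_communities(succession_spec(seed = 36))
  expect_equal(nrow(sim$metadata), 300)
  expect_equal(length(unique(sim$classes$label)), 6)

  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pr <- rowSums(tab); pc <- colSums(tab)
    s <- 0
    for (i in seq_along(pr)) for (j in seq_along(pc)) {
      if (tab[i, j] > 0) s <- s + tab[i, j] * log(tab[i, j] / (pr[i] * pc[j]))
    }
    s
  }
  cls <- sim$classes$label[match(sim$metadata$sample_id, sim$classes$sample_id)]
  expect_gt(mi(cls, as.character(sim$metadata$date)),
            mi(cls, sim$metadata$site))

  # well-separated expected profiles: pairwise JSD of profile means > 0.5
  pr <- sweep(sim$profiles, 2, colSums(sim$profiles), "/")
  for (i in 1:5) for (j in (i + 1):6) {
    expect_gt(oracle_jsd(pr[, i], pr[, j]), 0.5)
  }
})

test_that("zero attenuation with a single effective rain regime gives one class", {
  spec <- succession_spec(n_taxa = 80, n_sites = 3, trees_per_site = 2,
                          rate_range = c(0, 0), seed = 37)
  sim <- simulate_succession_communities(spec)
  expect_equal(unique(sim$classes$label), "C1")
})

test_that("function generator honours zero and planted coefficients", {
  dag <- default_path_dag()
  edges <- c("N->ATP", "G->ATP", "P->ATP", "X->Yield", "ATP->Yield",
             "G->CO2", "P->CO2", "Yield->CO2")
  zero <- as.list(setNames(rep(0, 8), edges))
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:4000), label = "C1")
  f0 <- simulate_functions(path_model_spec(coefficients = zero, seed = 38), cls)
  for (endo in c("ATP", "Yield", "CO2")) {
    for (exo in c("X", "G", "N", "P")) {
      expect_lt(abs(cor(f0[[endo]], f0[[exo]])), 0.06)
    }
  }

  # single class, ATP->Yield = 0.5: regression slope recovers it within 3 SE
  f1 <- simulate_functions(
    path_model_spec(coefficients = list("ATP->Yield" = 0.5), seed = 39), cls)
  fit <- lm(Yield ~ X + ATP, data = f1)
  se <- summary(fit)$coefficients["ATP", 2]
  expect_lt(abs(coef(fit)[["ATP"]] - 0.5), 3 * se)

  expect_error(path_model_spec(exo_cov = matrix(c(1, 2, 2, 1), 2),
                               dag = path_dag(c("A -> C", "B -> C"))),
               "positive semidefinite")
})
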