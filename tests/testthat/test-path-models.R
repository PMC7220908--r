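single_class <- function(n, label = "C1") {
  tibble::tibble(sample_id = sprintf("S%05d", seq_len(n)), label = label)
}

test_that("path DAG parsing, topology and validation work", {
  dag <- default_path_dag()
  expect_setequal(dag$nodes, function_variables())
  expect_equal(nrow(dag$edges), 8)
  expect_equal(nrow(dag$bidirected), 6)  # all exogenous pairs free
  expect_error(path_dag(c("A -> B", "B -> A")), "cycle")
  expect_error(path_dag("A -- B"), "cannot parse")
  # file-style multi-line spec
  dag2 <- path_dag("A -> B\nB -> C\nA ~~ D")
  expect_equal(nrow(dag2$edges), 2)
  expect_equal(dag2$bidirected$b, "D")
})

test_that("fitted coefficients recover the generator within 3 standard errors", {
  dag <- default_path_dag()
  truth <- list("N->ATP" = 0.4, "G->ATP" = 0.6, "P->ATP" = 0.2,
                "X->Yield" = 0.7, "ATP->Yield" = 0.5,
                "G->CO2" = 0.3, "P->CO2" = 0.2, "Yield->CO2" = 0.4)
  spec <- path_model_spec(coefficients = truth, seed = 18)
  f <- simulate_functions(spec, single_class(10000))
  fit <- fit_path_model(f, dag, standardize = FALSE)
  tt <- tidy(fit)
  for (i in seq_len(nrow(tt))) {
    e <- paste(tt$from[i], tt$to[i], sep = "->")
    # SE of an OLS slope at n = 1e4 with unit-ish variances is < 0.02
    expect_lt(abs(tt$estimate[i] - truth[[e]]), 3 * 0.02)
  }
  expect_true(all(fit$r2 > 0 & fit$r2 < 1))
})

test_that("the saturated model has chi-square 0, df 0, RMSEA 0", {
  # all recursive edges X->G->N->P in some order plus every forward edge
  nodes <- c("X", "G", "N", "P")
  edges <- c()
  for (i in 1:3) for (j in (i + 1):4) {
    edges <- c(edges, sprintf("%s -> %s", nodes[i], nodes[j]))
  }
  dag <- path_dag(edges)
  set.seed(19)
  f <- tibble::tibble(sample_id = sprintf("S%03d", 1:200),
                      X = rnorm(200), G = rnorm(200), N = rnorm(200), P = rnorm(200))
  fit <- fit_path_model(f, dag)
  expect_equal(fit$df, 0)
  expect_equal(fit$chi_square, 0, tolerance = 1e-8)
  expect_equal(fit$rmsea, 0)
  expect_equal(fit$rmsea_ci, c(0, 0))
  # saturated implied covariance reproduces the sample covariance exactly
  expect_equal(unname(fit$implied_cov), unname(fit$sample_cov), tolerance = 1e-10)
})

test_that("a null generator yields near-zero standardized estimates and R2", {
  dag <- default_path_dag()
  zero <- as.list(setNames(rep(0, 8), c("N->ATP", "G->ATP", "P->ATP", "X->Yield",
                                        "ATP->Yield", "G->CO2", "P->CO2", "Yield->CO2")))
  f <- simulate_functions(path_model_spec(coefficients = zero, seed = 20),
                          single_class(5000))
  fit <- fit_path_model(f, dag)
  expect_true(all(abs(tidy(fit)$std_estimate) < 0.05))
  expect_true(all(fit$r2 < 0.01))
})

test_that("multi-group AIC prefers constraints when coefficients are shared", {
  dag <- default_path_dag()
  lv <- c("A", "B", "C")
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:900),
                        label = rep(lv, each = 300))
  f <- simulate_functions(path_model_spec(seed = 21), cls)
  fc <- fit_multigroup(f, cls, dag, "all_constrained")
  ff <- fit_multigroup(f, cls, dag, "all_free")
  expect_lt(fc$aic, ff$aic)
  expect_equal(fc$scenario, "all_constrained")
  expect_equal(ff$scenario, "all_free")
  expect_equal(fc$n_params + pattern_n_coef(pattern_free(dag, lv)) -
                 pattern_n_coef(pattern_constrained(dag, lv)), ff$n_params)
})

test_that("free multi-group fits recover planted class-specific slopes", {
  dag <- default_path_dag()
  lv <- c("A", "B")
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:1200),
                        label = rep(lv, each = 600))
  spec <- path_model_spec(coefficients = list("ATP->Yield" = c(A = 0.5, B = -0.5)),
                          seed = 22)
  f <- simulate_functions(spec, cls)
  ff <- fit_multigroup(f, cls, dag, "all_free", standardize = FALSE)
  cf <- ff$coefficients
  ay <- cf[cf$edge == "ATP->Yield", ]
  expect_gt(ay$estimate[ay$classes == "A"], 0.3)
  expect_lt(ay$estimate[ay$classes == "B"], -0.3)
})

test_that("with a single class all constraint scenarios coincide", {
  dag <- default_path_dag()
  cls <- single_class(400)
  f <- simulate_functions(path_model_spec(seed = 23), cls)
  fc <- fit_multigroup(f, cls, dag, "all_constrained")
  ff <- fit_multigroup(f, cls, dag, "all_free")
  expect_equal(fc$aic, ff$aic, tolerance = 1e-9)
  expect_equal(fc$loglik, ff$loglik, tolerance = 1e-9)
})

test_that("greedy selection isolates a planted deviating class and never loses to the extremes", {
  dag <- default_path_dag()
  lv <- paste0("C", 1:4)
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:2400),
                        label = rep(lv, each = 600))
  spec <- path_model_spec(
    coefficients = list("ATP->Yield" = c(C1 = 0.5, C2 = 0.5, C3 = 0.5, C4 = -0.4)),
    seed = 24)
  f <- simulate_functions(spec, cls)
  sel <- select_constraint_model(f, cls, dag)
  bl <- sel$pattern[["ATP->Yield"]]
  expect_equal(sum(bl == bl[["C4"]]), 1)  # the deviating class sits alone
  fc <- fit_multigroup(f, cls, dag, "all_constrained")
  ff <- fit_multigroup(f, cls, dag, "all_free")
  expect_lte(sel$aic, fc$aic + 1e-9)
  expect_lte(sel$aic, ff$aic + 1e-9)
  expect_true(nrow(sel$search) >= 2)
})

test_that("null multi-group data keeps the parsimony ordering of the extremes", {
  dag <- default_path_dag()
  lv <- paste0("C", 1:3)
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:1800),
                        label = rep(lv, each = 600))
  f <- simulate_functions(path_model_spec(seed = 25), cls)
  fc <- fit_multigroup(f, cls, dag, "all_constrained")
  ff <- fit_multigroup(f, cls, dag, "all_free")
  expect_lt(fc$aic, ff$aic)
})

test_that("backdoor adjustment sets match the path-blocking oracle", {
  # chain A->B->C plus A->C: adjust for {A}
  d3 <- path_dag(c("A -> B", "B -> C", "A -> C"))
  expect_equal(adjustment_set(d3, "B", "C"), "A")
  # no parents, no covariances: empty set
  expect_equal(adjustment_set(path_dag(c("A -> B")), "A", "B"), character(0))
  # ill-posed direction
  expect_error(adjustment_set(d3, "C", "B"), "ancestor")

  dag <- default_path_dag()
  oracle_valid <- function(x, y, z) {
    oracle_backdoor_valid(dag$edges$from, dag$edges$to,
                          dag$bidirected$a, dag$bidirected$b, x, y, z)
  }
  for (i in seq_len(nrow(dag$edges))) {
    x <- dag$edges$from[i]; y <- dag$edges$to[i]
    z <- adjustment_set(dag, x, y)
    expect_true(oracle_valid(x, y, z))
    # removal-minimal: dropping any single member opens a backdoor path
    for (node in z) {
      expect_false(oracle_valid(x, y, setdiff(z, node)))
    }
  }
  # package validity check agrees with the oracle on random subsets
  others <- setdiff(dag$nodes, c("ATP", "Yield"))
  for (k in 0:length(others)) {
    for (z in asplit(combn(others, k), 2)) {
      expect_equal(is_valid_adjustment(dag, "ATP", "Yield", as.character(z)),
                   oracle_valid("ATP", "Yield", as.character(z)))
    }
  }
})

test_that("interaction regressions flag planted deviations and not exchangeable classes", {
  dag <- default_path_dag()
  lv <- c("A", "B")
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:400),
                        label = rep(lv, each = 200))
  spec <- path_model_spec(coefficients = list("ATP->Yield" = c(A = 0.3, B = 0.8)),
                          seed = 26)
  f <- simulate_functions(spec, cls)
  it <- interaction_regression(f, cls, dag, "ATP", "Yield")
  expect_equal(attr(it, "adjustment_set"), c("G", "N", "P"))
  expect_lt(it$p_value[it$class == "B"], 0.001)
  expect_equal(it$signif[it$class == "B"], "**")

  # duplicated class: interaction estimate ~ 0
  f2 <- simulate_functions(path_model_spec(seed = 27), single_class(300, "A"))
  fdup <- dplyr::bind_rows(f2, dplyr::mutate(f2, sample_id = paste0(sample_id, "b")))
  cdup <- tibble::tibble(sample_id = fdup$sample_id,
                         label = rep(c("A", "B"), each = 300))
  it2 <- interaction_regression(fdup, cdup, dag, "ATP", "Yield")
  expect_lt(abs(it2$estimate), 1e-10)

  # classes below the predictor count are dropped with a warning
  f3 <- dplyr::bind_rows(f2, dplyr::mutate(utils::head(f2, 3),
                                           sample_id = paste0(sample_id, "c")))
  c3 <- tibble::tibble(sample_id = f3$sample_id,
                       label = c(rep("A", 300), rep("tiny", 3)))
  expect_warning(expect_error(interaction_regression(f3, c3, dag, "ATP", "Yield"),
                              "usable classes"),
                 "tiny")
})

test_that("interaction reports cover every pathway with its adjustment set", {
  dag <- default_path_dag()
  lv <- c("A", "B", "C")
  cls <- tibble::tibble(sample_id = sprintf("S%05d", 1:600),
                        label = rep(lv, each = 200))
  f <- simulate_functions(path_model_spec(seed = 28), cls)
  rep <- interaction_report(f, cls, dag)
  expect_equal(sort(unique(paste(rep$exposure, rep$outcome, sep = "->"))),
               sort(c("N->ATP", "G->ATP", "P->ATP", "X->Yield", "ATP->Yield",
                      "G->CO2", "P->CO2", "Yield->CO2")))
  expect_equal(nrow(rep), 8 * 2)  # two non-reference classes per pathway
})
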