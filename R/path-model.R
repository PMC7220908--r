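# Recursive path models over the functional variables: single-group ML fit
# via per-equation least squares, multi-group fits under coefficient
# constraint patterns, AIC-guided constraint selection, and confounder-
# adjusted class-interaction regressions.

# Extract and optionally standardize the DAG variables from a function table.
path_data <- function(f, dag, standardize = TRUE) {
  miss <- setdiff(dag$nodes, names(f))
  if (length(miss) > 0) abort(sprintf("function table lacks column(s): %s", paste(miss, collapse = ", ")))
  x <- as.matrix(f[, dag$nodes, drop = FALSE])
  if (anyNA(x)) abort("function table has missing values")
  if (standardize) x <- scale(x)[, , drop = FALSE]
  x
}

# Noncentrality bounds for the RMSEA 90% CI by inversion of the noncentral
# chi-square CDF.
rmsea_ci <- function(chisq, df, n_eff, level = 0.90) {
  if (df <= 0 || n_eff <= 0) return(c(0, 0))
  lo_p <- (1 + level) / 2  # 0.95
  hi_p <- (1 - level) / 2  # 0.05
  ncp_for <- function(target) {
    if (stats::pchisq(chisq, df, ncp = 0) < target) return(0)
    upper <- max(chisq * 2, 10)
    while (stats::pchisq(chisq, df, ncp = upper) > target) upper <- upper * 2
    stats::uniroot(function(l) stats::pchisq(chisq, df, ncp = l) - target,
                   lower = 0, upper = upper, tol = 1e-8)$root
  }
  lam_lo <- ncp_for(lo_p)
  lam_hi <- ncp_for(hi_p)
  c(sqrt(lam_lo / (df * n_eff)), sqrt(lam_hi / (df * n_eff)))
}

# ML discrepancy between implied and observed covariance.
f_ml <- function(sigma, s) {
  p <- nrow(s)
  log(det(sigma)) - log(det(s)) + sum(diag(s %*% solve(sigma))) - p
}

#' Fit a recursive path model
#'
#' For recursive models with uncorrelated errors, equation-wise least squares
#' is the maximum-likelihood fit, so each endogenous variable is regressed on
#' its parents. The implied covariance is assembled as
#' `(I - B)^-1 Psi (I - B)^-T` with the exogenous block of `Psi` saturated at
#' the sample covariance, from which the likelihood-ratio chi-square against
#' the saturated model, RMSEA with a 90% CI (noncentrality inversion), AIC
#' and per-equation R-squared are computed. `chisq = (n - 1) * F_ML` and
#' `df = p(p+1)/2 - n_params`.
#'
#' @param f Function table tibble (columns covering the DAG nodes).
#' @param dag A [path_dag()].
#' @param standardize Standardize all variables first (default TRUE);
#'   coefficients are then already standardized.
#' @return An object of class `path_fit`; see [tidy.path_fit()] and
#'   [glance.path_fit()].
#' @export
fit_path_model <- function(f, dag, standardize = TRUE) {
  x <- path_data(f, dag, standardize)
  n <- nrow(x)
  vars <- topological_order(dag)
  x <- x[, vars, drop = FALSE]
  endo <- endogenous_nodes(dag)
  exo <- setdiff(vars, endo)
  max_parents <- max(vapply(endo, function(v) length(dag_parents(dag, v)), integer(1)))
  if (n <= max_parents + 1) abort("too few rows to fit every equation")
  p <- length(vars)
  s_ml <- stats::cov(x) * (n - 1) / n
  sds <- apply(x, 2, stats::sd)

  b <- matrix(0, p, p, dimnames = list(vars, vars))
  psi <- matrix(0, p, p, dimnames = list(vars, vars))
  psi[exo, exo] <- s_ml[exo, exo]
  coefs <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  for (child in endo) {
    pa <- dag_parents(dag, child)
    dat <- as.data.frame(x[, c(child, pa), drop = FALSE])
    qrfit <- stats::lm(stats::reformulate(pa, response = child), data = dat)
    if (any(is.na(stats::coef(qrfit)))) {
      abort(sprintf("collinear predictors in the equation for %s", child))
    }
    cf <- stats::coef(qrfit)[pa]
    b[child, pa] <- cf
    res_var <- sum(stats::resid(qrfit)^2) / n
    psi[child, child] <- res_var
    r2[child] <- 1 - res_var / s_ml[child, child]
    coefs[[child]] <- tibble(
      from = pa, to = child,
      estimate = unname(cf),
      std_estimate = unname(cf) * sds[pa] / sds[child]
    )
  }
  imat <- diag(p)
  sigma <- solve(imat - b) %*% psi %*% t(solve(imat - b))
  dimnames(sigma) <- list(vars, vars)

  q <- length(exo)
  n_params <- q * (q + 1) / 2 + nrow(dag$edges) + length(endo)
  df <- p * (p + 1) / 2 - n_params
  disc <- max(f_ml(sigma, s_ml), 0)
  chisq <- (n - 1) * disc
  if (df > 0) {
    rmsea <- sqrt(max(0, (chisq - df) / (df * (n - 1))))
    ci <- rmsea_ci(chisq, df, n - 1)
    p_value <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    rmsea <- 0; ci <- c(0, 0); p_value <- NA_real_
  }
  loglik <- -n / 2 * (p * log(2 * pi) + log(det(sigma)) +
                        sum(diag(s_ml %*% solve(sigma))))
  structure(list(
    dag = dag,
    coefficients = dplyr::bind_rows(coefs),
    residual_variances = stats::setNames(diag(psi)[endo], endo),
    r2 = r2,
    implied_cov = sigma,
    sample_cov = s_ml,
    loglik = loglik,
    n_params = n_params,
    aic = -2 * loglik + 2 * n_params,
    chi_square = chisq,
    df = df,
    p_value = p_value,
    rmsea = rmsea,
    rmsea_ci = ci,
    n = n,
    standardized = standardize
  ), class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Recursive path model: %d edges, n = %d\n", nrow(x$coefficients), x$n))
  cat(sprintf("  chisq = %0.4g (df = %d), RMSEA = %0.4g (90%% CI %0.3g-%0.3g), AIC = %0.6g\n",
              x$chi_square, x$df, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2], x$aic))
  invisible(x)
}

#' Tidy methods for single-group path fits
#'
#' `tidy()` returns one row per directed edge with raw and standardized
#' estimates; `glance()` the fit indices.
#'
#' @param x A `path_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy path_fit
#' @export
tidy.path_fit <- function(x, ...) x$coefficients

#' @rdname tidy.path_fit
#' @method glance path_fit
#' @export
glance.path_fit <- function(x, ...) {
  tibble(
    chi_square = x$chi_square, df = x$df, p_value = x$p_value,
    rmsea = x$rmsea, rmsea_lo = x$rmsea_ci[1], rmsea_hi = x$rmsea_ci[2],
    aic = x$aic, loglik = x$loglik, n_params = x$n_params, n = x$n
  )
}

## ---- constraint patterns -------------------------------------------------

#' Coefficient constraint patterns for multi-group path models
#'
#' A pattern assigns, for every directed edge, each class to a block; classes
#' in the same block share that edge's coefficient. `pattern_constrained()`
#' puts all classes in one block per edge (scenario i),
#' `pattern_free()` gives every class its own block (scenario ii); anything
#' in between is a partial pattern (scenario iii).
#'
#' @param dag A `path_dag`.
#' @param class_levels Character vector of class labels.
#' @return A named list (one element per edge id) of integer block vectors
#'   named by class.
#' @export
pattern_constrained <- function(dag, class_levels) {
  ids <- edge_ids(dag)
  stats::setNames(lapply(ids, function(e) {
    stats::setNames(rep(1L, length(class_levels)), class_levels)
  }), ids)
}

#' @rdname pattern_constrained
#' @export
pattern_free <- function(dag, class_levels) {
  ids <- edge_ids(dag)
  stats::setNames(lapply(ids, function(e) {
    stats::setNames(seq_along(class_levels), class_levels)
  }), ids)
}

pattern_scenario <- function(pattern) {
  nb <- vapply(pattern, function(p) length(unique(p)), integer(1))
  ncl <- vapply(pattern, length, integer(1))
  if (all(nb == 1)) "all_constrained"
  else if (all(nb == ncl)) "all_free"
  else "partial"
}

# Number of free coefficients implied by a pattern.
pattern_n_coef <- function(pattern) {
  sum(vapply(pattern, function(p) length(unique(p)), integer(1)))
}

# Fit one equation under the blocks of its edges: pooled regression with
# class intercepts and block-indicator expanded parent columns.
# Returns ML loglik, the coefficient tibble, pooled residual variance and R2.
fit_equation <- function(child, parents, eids, pattern, x, cls) {
  n <- nrow(x)
  g <- nlevels(cls)
  # class-indicator intercept columns (works for a single level too)
  design <- vapply(levels(cls), function(l) as.numeric(cls == l), numeric(n))
  cnames <- paste0(".int", seq_len(g))
  coef_map <- list()
  for (i in seq_along(parents)) {
    blocks <- pattern[[eids[i]]]
    for (bl in sort(unique(blocks))) {
      members <- names(blocks)[blocks == bl]
      col <- x[, parents[i]] * as.numeric(cls %in% members)
      design <- cbind(design, col)
      cnames <- c(cnames, sprintf("%s|%d", eids[i], bl))
      coef_map[[length(coef_map) + 1]] <- tibble(
        edge = eids[i], block = bl, classes = paste(members, collapse = ",")
      )
    }
  }
  colnames(design) <- cnames
  fit <- stats::lm.fit(design, x[, child])
  if (any(is.na(fit$coefficients))) {
    abort(sprintf("collinear predictors in the equation for %s", child))
  }
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  # within-class total SS, for a pooled R2 net of class means
  centered <- x[, child] - stats::ave(x[, child], cls)
  tss <- sum(centered^2)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  coef_tbl <- dplyr::bind_rows(coef_map)
  if (nrow(coef_tbl) > 0) {
    coef_tbl$estimate <- unname(fit$coefficients[-seq_len(g)])
    coef_tbl$to <- child
  }
  list(loglik = ll, sigma2 = sigma2, r2 = 1 - rss / tss, coefficients = coef_tbl,
       n_coef = nrow(coef_tbl))
}

#' Fit a multi-group path model under a constraint pattern
#'
#' Every equation is fitted as one pooled regression across classes with
#' class-specific intercepts; each edge coefficient is shared within each
#' block of its constraint pattern (block-indicator expansion). Residual
#' variances are pooled per equation; exogenous covariances are saturated per
#' class. The log-likelihood sums over classes and
#' `AIC = -2 loglik + 2 n_params`.
#'
#' @param f Function table tibble.
#' @param classes Classification tibble (`sample_id`, `label`) or vector.
#' @param dag A `path_dag`.
#' @param pattern A constraint pattern ([pattern_constrained()],
#'   [pattern_free()], or any named-list pattern); also accepts the strings
#'   `"all_constrained"` / `"all_free"`.
#' @param standardize Standardize all variables first (default TRUE).
#' @return An object of class `multigroup_fit`.
#' @export
fit_multigroup <- function(f, classes, dag, pattern = "all_constrained",
                           standardize = TRUE) {
  cls <- multigroup_classes(f, classes)
  x <- path_data(f, dag, standardize)
  if (is.character(pattern) && length(pattern) == 1) {
    pattern <- switch(pattern,
      all_constrained = pattern_constrained(dag, levels(cls)),
      all_free = pattern_free(dag, levels(cls)),
      abort("unknown pattern name")
    )
  }
  if (!setequal(names(pattern), edge_ids(dag))) abort("pattern does not match the DAG edges")
  sizes <- table(cls)
  if (any(sizes == 0)) abort("empty class")
  endo <- endogenous_nodes(dag)
  exo <- setdiff(dag$nodes, unique(dag$edges$to))
  # each class needs a nonsingular full covariance for the fit statistics
  # (n_c > p) on top of enough rows for the largest equation
  if (any(sizes <= length(dag$nodes))) {
    abort("a class has too few samples for the model (need n > number of variables)")
  }

  eq <- lapply(endo, function(child) {
    pa <- dag_parents(dag, child)
    fit_equation(child, pa, paste(pa, child, sep = "->"), pattern, x, cls)
  })
  names(eq) <- endo
  ll_struct <- sum(vapply(eq, function(e) e$loglik, numeric(1)))
  ll_exo <- multigroup_exo_loglik(x, cls, exo)
  loglik <- ll_struct + ll_exo

  q <- length(exo)
  g <- nlevels(cls)
  n_coef <- pattern_n_coef(pattern)
  n_params <- g * q * (q + 1) / 2 + n_coef + length(endo) * (g + 1)
  aic <- -2 * loglik + 2 * n_params

  fitstats <- multigroup_fitstats(x, cls, dag, eq, pattern, exo, endo)
  n_params_cov <- g * q * (q + 1) / 2 + n_coef + length(endo)
  df <- g * length(dag$nodes) * (length(dag$nodes) + 1) / 2 - n_params_cov
  n <- nrow(x)
  if (df > 0) {
    rmsea <- sqrt(max(0, (fitstats$chisq - df) / (df * (n - 1))))
    ci <- rmsea_ci(fitstats$chisq, df, n - 1)
  } else {
    rmsea <- 0; ci <- c(0, 0)
  }

  structure(list(
    dag = dag,
    scenario = pattern_scenario(pattern),
    pattern = pattern,
    coefficients = dplyr::bind_rows(lapply(eq, function(e) e$coefficients)),
    residual_variances = vapply(eq, function(e) e$sigma2, numeric(1)),
    r2 = vapply(eq, function(e) e$r2, numeric(1)),
    loglik = loglik,
    n_params = n_params,
    aic = aic,
    chi_square = fitstats$chisq,
    df = df,
    rmsea = rmsea,
    rmsea_ci = ci,
    class_sizes = as.integer(sizes),
    class_levels = levels(cls),
    n = n,
    standardized = standardize
  ), class = "multigroup_fit")
}

multigroup_classes <- function(f, classes) {
  if (is.data.frame(classes)) {
    lab <- classification_labels(classes)
    if (!all(f$sample_id %in% names(lab))) abort("classes do not cover all samples")
    factor(unname(lab[f$sample_id]))
  } else if (!is.null(names(classes))) {
    factor(unname(classes[f$sample_id]))
  } else {
    if (length(classes) != nrow(f)) abort("classes length does not match the function table")
    factor(classes)
  }
}

# Saturated per-class Gaussian loglik of the exogenous block.
multigroup_exo_loglik <- function(x, cls, exo) {
  q <- length(exo)
  sum(vapply(levels(cls), function(lv) {
    xs <- x[cls == lv, exo, drop = FALSE]
    nc <- nrow(xs)
    s <- stats::cov(xs) * (nc - 1) / nc
    -nc / 2 * (q * log(2 * pi) + log(det(s)) + q)
  }, numeric(1)))
}

# Multigroup chi-square: ML discrepancy per class between the implied and the
# class sample covariance (class-centred), summed with (n_c - 1) weights.
multigroup_fitstats <- function(x, cls, dag, eq, pattern, exo, endo) {
  vars <- topological_order(dag)
  p <- length(vars)
  chisq <- 0
  for (lv in levels(cls)) {
    xs <- x[cls == lv, vars, drop = FALSE]
    nc <- nrow(xs)
    s <- stats::cov(xs) * (nc - 1) / nc
    b <- matrix(0, p, p, dimnames = list(vars, vars))
    psi <- matrix(0, p, p, dimnames = list(vars, vars))
    psi[exo, exo] <- s[exo, exo]
    for (child in endo) {
      for (pa in dag_parents(dag, child)) {
        e <- paste(pa, child, sep = "->")
        bl <- pattern[[e]][[lv]]
        cf <- eq[[child]]$coefficients
        b[child, pa] <- cf$estimate[cf$edge == e & cf$block == bl]
      }
      psi[child, child] <- eq[[child]]$sigma2
    }
    sigma <- solve(diag(p) - b) %*% psi %*% t(solve(diag(p) - b))
    chisq <- chisq + (nc - 1) * max(f_ml(sigma, s), 0)
  }
  list(chisq = chisq)
}

#' @export
print.multigroup_fit <- function(x, ...) {
  cat(sprintf("Multi-group path model (%s): %d classes, n = %d\n",
              x$scenario, length(x$class_levels), x$n))
  cat(sprintf("  loglik = %0.6g, params = %d, AIC = %0.6g\n",
              x$loglik, x$n_params, x$aic))
  cat(sprintf("  chisq = %0.4g (df = %d), RMSEA = %0.4g (90%% CI %0.3g-%0.3g)\n",
              x$chi_square, x$df, x$rmsea, x$rmsea_ci[1], x$rmsea_ci[2]))
  invisible(x)
}

#' Tidy methods for multi-group path fits
#'
#' `tidy()` returns one row per edge-block with the classes sharing the
#' coefficient; `glance()` the fit summary.
#'
#' @param x A `multigroup_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy multigroup_fit
#' @export
tidy.multigroup_fit <- function(x, ...) x$coefficients

#' @rdname tidy.multigroup_fit
#' @method glance multigroup_fit
#' @export
glance.multigroup_fit <- function(x, ...) {
  tibble(
    scenario = x$scenario, loglik = x$loglik, n_params = x$n_params,
    aic = x$aic, chi_square = x$chi_square, df = x$df,
    rmsea = x$rmsea, rmsea_lo = x$rmsea_ci[1], rmsea_hi = x$rmsea_ci[2],
    n = x$n
  )
}

#' Coefficient plot for a multi-group path fit
#'
#' @param object A `multigroup_fit`.
#' @param ... Unused.
#' @return A ggplot of per-block coefficients by edge.
#' @method autoplot multigroup_fit
#' @export
autoplot.multigroup_fit <- function(object, ...) {
  ggplot2::ggplot(object$coefficients,
                  ggplot2::aes(x = .data$edge, y = .data$estimate,
                               colour = .data$classes)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "path coefficient", colour = "classes")
}

## ---- AIC-guided constraint selection -------------------------------------

#' Select a constraint pattern by greedy AIC search
#'
#' Starts from the fully constrained pattern and repeatedly applies the
#' single move -- freeing one class out of a block, or merging two blocks, on
#' one edge -- that most lowers the AIC, stopping when no move lowers it.
#' The two extreme scenarios (all constrained, all free) are always
#' evaluated too, and the AIC-minimal fit is returned; on AIC ties (within
#' 1e-9) the more constrained pattern wins.
#'
#' @inheritParams fit_multigroup
#' @param strategy Only `"greedy"` is implemented.
#' @return The winning `multigroup_fit`, with a `search` tibble of the moves
#'   taken attached.
#' @export
select_constraint_model <- function(f, classes, dag, strategy = "greedy",
                                    standardize = TRUE) {
  strategy <- match.arg(strategy, "greedy")
  cls <- multigroup_classes(f, classes)
  x <- path_data(f, dag, standardize)
  lv <- levels(cls)
  endo <- endogenous_nodes(dag)
  exo <- setdiff(dag$nodes, unique(dag$edges$to))
  q <- length(exo)
  g <- length(lv)
  if (any(table(cls) <= length(dag$nodes))) {
    abort("a class has too few samples for the model (need n > number of variables)")
  }

  # Constant loglik/param terms shared by every pattern.
  const_ll <- multigroup_exo_loglik(x, cls, exo)
  const_np <- g * q * (q + 1) / 2 + length(endo) * (g + 1)

  edge_of_child <- lapply(endo, function(child) {
    pa <- dag_parents(dag, child)
    stats::setNames(paste(pa, child, sep = "->"), pa)
  })
  names(edge_of_child) <- endo

  cache <- new.env(parent = emptyenv())
  eq_fit <- function(child, pat) {
    eids <- edge_of_child[[child]]
    key <- paste(child, paste(vapply(eids, function(e) paste(pat[[e]], collapse = ","),
                                     character(1)), collapse = ";"), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- fit_equation(child, names(eids), unname(eids), pat, x, cls)
    cache[[key]] <- res
    res
  }
  pattern_aic <- function(pat) {
    ll <- const_ll
    np <- const_np
    for (child in endo) {
      e <- eq_fit(child, pat)
      ll <- ll + e$loglik
      np <- np + e$n_coef
    }
    -2 * ll + 2 * np
  }

  # All single moves on one edge's block vector.
  edge_moves <- function(blocks) {
    out <- list()
    for (bl in unique(blocks)) {
      members <- names(blocks)[blocks == bl]
      if (length(members) >= 2) {
        for (m in members) {
          nb <- blocks
          nb[m] <- max(blocks) + 1L
          out[[length(out) + 1]] <- normalize_blocks(nb)
        }
      }
    }
    ub <- unique(blocks)
    if (length(ub) >= 2) {
      prs <- utils::combn(ub, 2)
      for (j in seq_len(ncol(prs))) {
        nb <- blocks
        nb[nb == prs[2, j]] <- prs[1, j]
        out[[length(out) + 1]] <- normalize_blocks(nb)
      }
    }
    unique(out)
  }

  current <- pattern_constrained(dag, lv)
  current_aic <- pattern_aic(current)
  trace <- list(tibble(step = 0L, move = "all_constrained", aic = current_aic))
  step <- 0L
  repeat {
    best_aic <- current_aic
    best_pat <- NULL
    best_move <- NULL
    for (e in names(current)) {
      for (nb in edge_moves(current[[e]])) {
        cand <- current
        cand[[e]] <- nb
        a <- pattern_aic(cand)
        if (a < best_aic - 1e-9) {
          best_aic <- a; best_pat <- cand
          best_move <- sprintf("%s: {%s}", e, paste(nb, collapse = ","))
        }
      }
    }
    if (is.null(best_pat)) break
    step <- step + 1L
    current <- best_pat
    current_aic <- best_aic
    trace[[length(trace) + 1]] <- tibble(step = step, move = best_move, aic = best_aic)
  }

  candidates <- list(
    greedy = current,
    all_constrained = pattern_constrained(dag, lv),
    all_free = pattern_free(dag, lv)
  )
  aics <- vapply(candidates, pattern_aic, numeric(1))
  nps <- vapply(candidates, pattern_n_coef, numeric(1))
  # AIC-minimal; ties (within 1e-9) go to fewer parameters
  tied <- which(aics <= min(aics) + 1e-9)
  best <- tied[which.min(nps[tied])]
  fit <- fit_multigroup(f, classes, dag, candidates[[best]], standardize = standardize)
  fit$search <- dplyr::bind_rows(trace)
  fit
}

normalize_blocks <- function(blocks) {
  u <- unique(blocks)
  stats::setNames(match(blocks, u), names(blocks))
}

## ---- class-interaction regressions ---------------------------------------

#' Confounder-adjusted class-interaction test for one pathway
#'
#' Regresses the outcome on the exposure, the backdoor adjustment set of the
#' pathway, a class factor (treatment-coded against the reference class,
#' which is the largest class by convention) and the exposure-by-class
#' interaction. Each interaction coefficient is the deviation of that class's
#' slope from the reference class.
#'
#' Significance codes follow the thresholds `* p < 0.01`, `** p < 0.001`.
#'
#' @inheritParams fit_multigroup
#' @param exposure,outcome Nodes of one directed pathway in the DAG.
#' @param reference Reference class; default the largest class.
#' @return A tibble with one row per non-reference class: `class`,
#'   `estimate`, `std_error`, `p_value`, `signif`, plus attributes
#'   `adjustment_set` and `reference`.
#' @export
interaction_regression <- function(f, classes, dag, exposure, outcome,
                                   reference = NULL, standardize = TRUE) {
  cls <- multigroup_classes(f, classes)
  z <- adjustment_set(dag, exposure, outcome)
  x <- path_data(f, dag, standardize)
  n_pred <- length(z) + 2  # intercept + exposure + adjustment
  sizes <- table(cls)
  small <- names(sizes)[sizes <= n_pred]
  if (length(small) > 0) {
    warn(sprintf("dropping class(es) with too few samples: %s", paste(small, collapse = ", ")))
    keep <- !(cls %in% small)
    x <- x[keep, , drop = FALSE]
    cls <- droplevels(cls[keep])
  }
  if (nlevels(cls) < 2) abort("need at least two usable classes")
  if (is.null(reference)) reference <- names(which.max(table(cls)))
  cls <- stats::relevel(cls, ref = reference)
  dat <- as.data.frame(x[, c(outcome, exposure, z), drop = FALSE])
  dat$class <- cls
  rhs <- c(sprintf("%s * class", exposure), z)
  fit <- stats::lm(stats::reformulate(rhs, response = outcome), data = dat)
  sm <- summary(fit)$coefficients
  rows <- grep(sprintf("^%s:class", exposure), rownames(sm))
  out <- tibble(
    class = sub(sprintf("^%s:class", exposure), "", rownames(sm)[rows]),
    estimate = sm[rows, 1],
    std_error = sm[rows, 2],
    p_value = sm[rows, 4]
  )
  out$signif <- dplyr::case_when(
    out$p_value < 0.001 ~ "**",
    out$p_value < 0.01 ~ "*",
    TRUE ~ ""
  )
  attr(out, "adjustment_set") <- z
  attr(out, "reference") <- reference
  out
}

#' Interaction report over every pathway of a DAG
#'
#' Runs [interaction_regression()] for each directed edge of the DAG and
#' binds the significant and non-significant interaction rows into one table.
#'
#' @inheritParams interaction_regression
#' @return A tibble with columns `exposure`, `outcome`, `adjustment`,
#'   `class`, `estimate`, `std_error`, `p_value`, `signif`.
#' @export
interaction_report <- function(f, classes, dag, reference = NULL,
                               standardize = TRUE) {
  rows <- lapply(seq_len(nrow(dag$edges)), function(i) {
    ex <- dag$edges$from[i]; oc <- dag$edges$to[i]
    tab <- interaction_regression(f, classes, dag, ex, oc,
                                  reference = reference, standardize = standardize)
    dplyr::bind_cols(
      tibble(exposure = ex, outcome = oc,
             adjustment = paste(attr(tab, "adjustment_set"), collapse = ",")),
      tab
    )
  })
  dplyr::bind_rows(rows)
}
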