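# Independent brute-force oracles, written straight from the defining
# formulas with no code shared with the package.

# Random symmetric dissimilarity matrix with zero diagonal.
random_dist <- function(n, ids = sprintf("s%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  v <- runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- v
  d + t(d)
}

# Euclidean distance matrix of 1-D or 2-D points, named.
point_dist <- function(x, ids = sprintf("s%02d", seq_len(NROW(x)))) {
  d <- as.matrix(dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

oracle_anosim_R <- function(d, g) {
  n <- nrow(d)
  rk <- matrix(0, n, n)
  rk[lower.tri(rk)] <- rank(d[lower.tri(d)])
  rw <- rb <- c()
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      if (g[i] == g[j]) rw <- c(rw, rk[i, j]) else rb <- c(rb, rk[i, j])
    }
  }
  (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
}

oracle_mrpp_delta <- function(d, g) {
  lev <- unique(g)
  sizes <- sapply(lev, function(l) sum(g == l))
  keep <- sizes >= 2
  lev <- lev[keep]; sizes <- sizes[keep]
  deltas <- sapply(lev, function(l) {
    m <- which(g == l)
    tot <- 0; cnt <- 0
    for (i in m) for (j in m) if (i < j) { tot <- tot + d[i, j]; cnt <- cnt + 1 }
    tot / cnt
  })
  sum(sizes / sum(sizes) * deltas)
}

oracle_permanova_F <- function(d, g) {
  n <- nrow(d)
  lev <- unique(g)
  k <- length(lev)
  ss_tot <- 0
  for (i in 2:n) for (j in 1:(i - 1)) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (l in lev) {
    m <- which(g == l)
    if (length(m) >= 2) {
      s <- 0
      for (i in m) for (j in m) if (i < j) s <- s + d[i, j]^2
      ss_w <- ss_w + s / length(m)
    }
  }
  ((ss_tot - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# Coordinate-space CH for Euclidean data (the classical definition).
oracle_ch_euclidean <- function(x, g) {
  x <- as.matrix(x)
  n <- nrow(x)
  lev <- unique(g)
  k <- length(lev)
  centroid <- colMeans(x)
  ssb <- ssw <- 0
  for (l in lev) {
    m <- which(g == l)
    cg <- colMeans(x[m, , drop = FALSE])
    ssb <- ssb + length(m) * sum((cg - centroid)^2)
    for (i in m) ssw <- ssw + sum((x[i, ] - cg)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

# ARI from explicit pair counting over all sample pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 2:n) {
    for (j in 1:(i - 1)) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Straight-line SparCC over samples-as-components (no shared code).
oracle_sparcc_rho <- function(counts_mat, pseudocount = 0.5) {
  f <- apply(counts_mat + pseudocount, 2, function(col) col / sum(col))
  n <- ncol(f)
  tmat <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) tmat[i, j] <- var(log(f[, i] / f[, j]))
  t_i <- rowSums(tmat)
  A <- matrix(1, n, n); diag(A) <- n - 1
  w <- solve(A, t_i)
  rho <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) if (i != j) {
    rho[i, j] <- min(max((w[i] + w[j] - tmat[i, j]) / (2 * sqrt(w[i] * w[j])), -1), 1)
  }
  rho
}

# Direct JSD of two probability vectors.
oracle_jsd <- function(p, q, base = 2) {
  h <- function(x) { x <- x[x > 0]; -sum(x * log(x, base = base)) }
  h((p + q) / 2) - (h(p) + h(q)) / 2
}

# Exhaustive minimal backdoor sets via the package's validity check is NOT
# used; this is an independent path-blocking oracle on small graphs.
# Enumerate all simple paths between x and y in the mixed graph (directed
# edges both ways + latent pairs), classify each node as collider or not,
# and test blocking by Z under the backdoor rules.
oracle_backdoor_valid <- function(edges_from, edges_to, bi_a, bi_b, x, y, z) {
  # expand bidirected via latents
  if (length(bi_a) > 0) {
    for (i in seq_along(bi_a)) {
      l <- paste0("..L", i)
      edges_from <- c(edges_from, l, l)
      edges_to <- c(edges_to, bi_a[i], bi_b[i])
    }
  }
  nodes <- unique(c(edges_from, edges_to, x, y, z))
  # descendants of x
  desc <- character(0); stack <- edges_to[edges_from == x]
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% desc) next
    desc <- c(desc, v); stack <- c(stack, edges_to[edges_from == v])
  }
  if (any(z %in% desc)) return(FALSE)
  # remove edges out of x, then enumerate undirected simple paths x..y
  keep <- edges_from != x
  ef <- edges_from[keep]; et <- edges_to[keep]
  adj <- list()
  for (nd in nodes) adj[[nd]] <- unique(c(et[ef == nd], ef[et == nd]))
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in adj[[v]]) if (!(w %in% path)) walk(c(path, w))
  }
  walk(x)
  blocked <- function(path) {
    if (length(path) <= 2) return(FALSE)
    for (m in 2:(length(path) - 1)) {
      v <- path[m]
      into_v_prev <- any(ef == path[m - 1] & et == v)
      into_v_next <- any(ef == path[m + 1] & et == v)
      collider <- into_v_prev && into_v_next
      if (collider) {
        dv <- v
        stackd <- v; descv <- character(0)
        while (length(stackd)) {
          u <- stackd[1]; stackd <- stackd[-1]
          if (u %in% descv) next
          descv <- c(descv, u); stackd <- c(stackd, et[ef == u])
        }
        if (!any(descv %in% z)) return(TRUE)
      } else {
        if (v %in% z) return(TRUE)
      }
    }
    FALSE
  }
  all(vapply(paths, blocked, logical(1))) || length(paths) == 0
}
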