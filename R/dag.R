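# Directed acyclic graphs over the functional variables, d-separation and
# backdoor adjustment sets. Free covariances among exogenous variables are
# represented as bidirected links, internally expanded into latent common
# causes for d-separation.

#' Build a path-model DAG
#'
#' Edges are given as strings: `"A -> B"` for a directed effect and
#' `"A ~~ B"` for a free (bidirected) covariance between exogenous variables.
#' If no `~~` links are given, all pairs of exogenous nodes (nodes with no
#' incoming directed edge) are treated as freely covarying, the usual
#' path-analysis convention.
#'
#' @param edges Character vector of edge specifications, or a single string
#'   with one edge per line (a plain-text DAG file read with `readLines()`
#'   works directly).
#' @param nodes Optional node set; defaults to the nodes mentioned in `edges`.
#' @return An object of class `path_dag` with `nodes`, `edges` (tibble
#'   `from`, `to`) and `bidirected` (tibble `a`, `b`).
#' @export
path_dag <- function(edges, nodes = NULL) {
  if (length(edges) == 1 && grepl("\n", edges)) {
    edges <- strsplit(edges, "\n")[[1]]
  }
  edges <- trimws(edges)
  edges <- edges[nzchar(edges) & !startsWith(edges, "#")]
  dir_rx <- "^(\\S+)\\s*->\\s*(\\S+)$"
  bi_rx <- "^(\\S+)\\s*~~\\s*(\\S+)$"
  from <- to <- a <- b <- character(0)
  for (e in edges) {
    if (grepl(dir_rx, e)) {
      m <- regmatches(e, regexec(dir_rx, e))[[1]]
      from <- c(from, m[2]); to <- c(to, m[3])
    } else if (grepl(bi_rx, e)) {
      m <- regmatches(e, regexec(bi_rx, e))[[1]]
      a <- c(a, m[2]); b <- c(b, m[3])
    } else {
      abort(sprintf("cannot parse edge specification: '%s'", e))
    }
  }
  if (anyDuplicated(paste(from, to))) abort("duplicated directed edge")
  all_nodes <- unique(c(nodes, from, to, a, b))
  dag <- structure(list(
    nodes = all_nodes,
    edges = tibble(from = from, to = to),
    bidirected = tibble(a = a, b = b)
  ), class = "path_dag")
  if (is.null(topological_order(dag))) abort("graph has a directed cycle")
  if (nrow(dag$bidirected) == 0) {
    exo <- exogenous_nodes(dag)
    if (length(exo) >= 2) {
      pairs <- utils::combn(sort(exo), 2)
      dag$bidirected <- tibble(a = pairs[1, ], b = pairs[2, ])
    }
  }
  dag
}

#' The default functional path DAG
#'
#' Exogenous exoenzyme activities X, G, N, P (freely covarying) drive the
#' endogenous ATP, Yield and CO2: N, G and P influence ATP; X and ATP
#' influence Yield; G, P and Yield influence CO2.
#'
#' @return A `path_dag`.
#' @export
default_path_dag <- function() {
  path_dag(c(
    "N -> ATP", "G -> ATP", "P -> ATP",
    "X -> Yield", "ATP -> Yield",
    "G -> CO2", "P -> CO2", "Yield -> CO2"
  ))
}

#' @export
print.path_dag <- function(x, ...) {
  cat(sprintf("path_dag: %d nodes, %d directed edges, %d free covariances\n",
              length(x$nodes), nrow(x$edges), nrow(x$bidirected)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s -> %s\n", x$edges$from[i], x$edges$to[i]))
  }
  invisible(x)
}

edge_ids <- function(dag) paste(dag$edges$from, dag$edges$to, sep = "->")

dag_parents <- function(dag, node) dag$edges$from[dag$edges$to == node]

exogenous_nodes <- function(dag) setdiff(dag$nodes, unique(dag$edges$to))

endogenous_nodes <- function(dag) {
  ord <- topological_order(dag)
  intersect(ord, unique(dag$edges$to))
}

# Kahn's algorithm; NULL if cyclic.
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in dag$edges$to) indeg[t] <- indeg[t] + 1
  queue <- names(indeg)[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    ch <- dag$edges$to[dag$edges$from == v]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1
      if (indeg[c] == 0) queue <- c(queue, c)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

dag_ancestors <- function(parent_map, nodes) {
  seen <- character(0)
  stack <- nodes
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, parent_map[[v]])
  }
  seen
}

# Augment bidirected links with latent common causes; returns list with node
# set and parent map over observed + latent nodes.
augmented_graph <- function(dag, drop_out_of = NULL) {
  parents <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  edges <- dag$edges
  if (!is.null(drop_out_of)) edges <- edges[edges$from != drop_out_of, , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    parents[[edges$to[i]]] <- c(parents[[edges$to[i]]], edges$from[i])
  }
  for (i in seq_len(nrow(dag$bidirected))) {
    l <- sprintf(".L_%s_%s", dag$bidirected$a[i], dag$bidirected$b[i])
    parents[[l]] <- character(0)
    parents[[dag$bidirected$a[i]]] <- c(parents[[dag$bidirected$a[i]]], l)
    parents[[dag$bidirected$b[i]]] <- c(parents[[dag$bidirected$b[i]]], l)
  }
  parents
}

# d-separation of x and y given Z via the ancestral moral graph.
d_separated <- function(parent_map, x, y, z) {
  keep <- dag_ancestors(parent_map, c(x, y, z))
  pm <- lapply(parent_map[intersect(names(parent_map), keep)],
               function(p) intersect(p, keep))
  # moralize: undirected adjacency among kept nodes
  nodes <- names(pm)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (child in nodes) {
    ps <- pm[[child]]
    for (p in ps) {
      adj[[child]] <- c(adj[[child]], p)
      adj[[p]] <- c(adj[[p]], child)
    }
    if (length(ps) >= 2) {
      prs <- utils::combn(ps, 2)
      for (j in seq_len(ncol(prs))) {
        adj[[prs[1, j]]] <- c(adj[[prs[1, j]]], prs[2, j])
        adj[[prs[2, j]]] <- c(adj[[prs[2, j]]], prs[1, j])
      }
    }
  }
  # remove Z and search for an x-y path
  avail <- setdiff(nodes, z)
  if (!(x %in% avail) || !(y %in% avail)) return(TRUE)
  seen <- x
  stack <- x
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    nb <- intersect(unique(adj[[v]]), avail)
    nb <- setdiff(nb, seen)
    if (y %in% nb) return(FALSE)
    seen <- c(seen, nb)
    stack <- c(stack, nb)
  }
  TRUE
}

#' Check a backdoor adjustment set
#'
#' `z` is valid for the effect of `exposure` on `outcome` when it contains no
#' descendant of `exposure` and blocks every backdoor path (d-separates
#' exposure and outcome in the graph with the exposure's outgoing edges
#' removed).
#'
#' @param dag A `path_dag`.
#' @param exposure,outcome Node names.
#' @param z Character vector of conditioning nodes.
#' @return Logical.
#' @export
is_valid_adjustment <- function(dag, exposure, outcome, z) {
  desc <- dag_descendants(dag, exposure)
  if (any(z %in% desc)) return(FALSE)
  pm <- augmented_graph(dag, drop_out_of = exposure)
  d_separated(pm, exposure, outcome, z)
}

dag_descendants <- function(dag, node) {
  out <- character(0)
  stack <- dag$edges$to[dag$edges$from == node]
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, dag$edges$to[dag$edges$from == v])
  }
  out
}

#' Backdoor adjustment set for a pathway
#'
#' Starts from the canonical valid set -- the observed directed parents of
#' the exposure together with observed nodes sharing a free covariance with
#' it -- then minimises it by removing, in deterministic (alphabetical)
#' order, any node whose exclusion still blocks all backdoor paths
#' (d-separation check in the graph without the exposure's outgoing edges).
#'
#' @param dag A `path_dag`.
#' @param exposure,outcome Node names (distinct, both in the DAG).
#' @return A sorted character vector of adjustment nodes (possibly empty).
#' @export
adjustment_set <- function(dag, exposure, outcome) {
  if (!all(c(exposure, outcome) %in% dag$nodes)) abort("exposure/outcome not in DAG")
  if (exposure == outcome) abort("exposure and outcome must differ")
  if (exposure %in% dag_descendants(dag, outcome)) {
    abort("outcome is an ancestor of the exposure: causal effect ill-posed")
  }
  partners <- unique(c(
    dag$bidirected$b[dag$bidirected$a == exposure],
    dag$bidirected$a[dag$bidirected$b == exposure]
  ))
  z <- sort(setdiff(unique(c(dag_parents(dag, exposure), partners)), outcome))
  if (!is_valid_adjustment(dag, exposure, outcome, z)) {
    abort("no valid backdoor adjustment set found from the exposure's parents")
  }
  for (node in sort(z)) {
    cand <- setdiff(z, node)
    if (is_valid_adjustment(dag, exposure, outcome, cand)) z <- cand
  }
  sort(z)
}
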