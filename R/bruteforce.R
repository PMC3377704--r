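# Exhaustive search for a minimum power graph on tiny graphs. Used as an
# independent optimality oracle for the greedy search: it enumerates all
# partitions of the edge set, keeps those whose blocks each form a complete
# biclique/star or a clique and whose endpoint sets satisfy the hierarchy
# condition, and returns a partition with the fewest blocks (= power edges).

# Classify an edge block: returns list(u, v, reflexive) of endpoint node
# vectors, or NULL when the block is not a clique/biclique/star.
classify_block <- function(block) {
  nodes <- sort(unique(c(block[, 1L], block[, 2L])))
  k <- length(nodes)
  keys <- edge_keys(block[, 1L], block[, 2L])
  # clique: all pairs present
  if (nrow(block) == k * (k - 1) / 2) {
    allk <- t(utils::combn(nodes, 2L))
    if (all(edge_keys(allk[, 1L], allk[, 2L]) %in% keys)) {
      if (k == 2L) return(list(u = nodes[1L], v = nodes[2L], reflexive = FALSE))
      return(list(u = nodes, v = nodes, reflexive = TRUE))
    }
  }
  # complete bipartite: 2-color by BFS, then check completeness
  color <- stats::setNames(rep(NA_integer_, k), nodes)
  adj <- split(c(block[, 2L], block[, 1L]), c(block[, 1L], block[, 2L]))
  queue <- nodes[1L]
  color[nodes[1L]] <- 0L
  while (length(queue)) {
    x <- queue[1L]; queue <- queue[-1L]
    for (y in adj[[x]]) {
      if (is.na(color[y])) {
        color[y] <- 1L - color[x]
        queue <- c(queue, y)
      } else if (color[y] == color[x]) {
        return(NULL)
      }
    }
  }
  if (anyNA(color)) return(NULL)  # disconnected block cannot be one power edge
  u <- nodes[color[nodes] == 0L]
  v <- nodes[color[nodes] == 1L]
  if (nrow(block) != length(u) * length(v)) return(NULL)
  list(u = u, v = v, reflexive = FALSE)
}

blocks_hierarchical <- function(blocks) {
  sets <- list()
  for (b in blocks) {
    sets[[length(sets) + 1L]] <- b$u
    if (!b$reflexive) sets[[length(sets) + 1L]] <- b$v
  }
  if (length(sets) < 2L) return(TRUE)
  for (i in seq_len(length(sets) - 1L)) {
    for (j in seq(i + 1L, length(sets))) {
      if (!nested_or_disjoint(sets[[i]], sets[[j]])) return(FALSE)
    }
  }
  TRUE
}

#' Minimum power graph by exhaustive search
#'
#' Enumerates every partition of the edge set into blocks, keeps the
#' partitions in which each block is a complete biclique, star, or clique
#' and whose endpoint sets form a valid hierarchy, and returns one with the
#' fewest power edges. Exponential in the number of edges; guarded to small
#' graphs. Intended as an optimality oracle for [power_graph()] in tests.
#'
#' @param g network with at most `max_edges` edges.
#' @param max_edges guard on problem size (default 10).
#' @return a `power_graph` with the minimum possible number of power edges.
#' @export
optimal_power_graph <- function(g, max_edges = 10L) {
  g <- canonical_vertex_order(g)
  m <- igraph::ecount(g)
  if (m > max_edges) {
    stop_netcompress("brute-force oracle limited to ", max_edges, " edges")
  }
  nm <- igraph::V(g)$name
  if (m == 0L) return(new_power_graph(g, list(), list()))
  el <- igraph::as_edgelist(g)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))

  best_blocks <- NULL
  best_k <- Inf
  assign_next <- function(i, labels, k) {
    if (k >= best_k) return(invisible())  # bound: cannot beat the incumbent
    if (i > m) {
      blocks <- lapply(seq_len(k), function(b) el[labels == b, , drop = FALSE])
      cls <- lapply(blocks, classify_block)
      if (any(vapply(cls, is.null, logical(1)))) return(invisible())
      if (!blocks_hierarchical(cls)) return(invisible())
      best_blocks <<- cls
      best_k <<- k
      return(invisible())
    }
    for (b in seq_len(min(k + 1L, best_k - 1L))) {
      labels[i] <- b
      assign_next(i + 1L, labels, max(k, b))
    }
    invisible()
  }
  assign_next(1L, integer(m), 0L)

  edges_out <- lapply(best_blocks, function(b) {
    list(u = match(b$u, nm), v = match(b$v, nm), reflexive = b$reflexive)
  })
  assemble_power_graph(g, nm, edges_out)
}
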