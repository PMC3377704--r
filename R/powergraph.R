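#' Jaccard similarity of two node neighborhoods
#'
#' The similarity of two nodes used to propose candidate power nodes:
#' `|N(u) ∩ N(v)| / |N(u) ∪ N(v)|`. It is 1 when both neighborhoods are
#' identical, 0 when they share no member, and 0 by convention when both are
#' empty.
#'
#' @param g network.
#' @param u,v node identifiers.
#' @return a number in `[0, 1]`.
#' @export
neighborhood_jaccard <- function(g, u, v) {
  nm <- igraph::V(g)$name
  if (!u %in% nm) stop_netcompress("unknown node: ", u)
  if (!v %in% nm) stop_netcompress("unknown node: ", v)
  nu <- names(igraph::neighbors(g, u))
  nv <- names(igraph::neighbors(g, v))
  un <- length(union(nu, nv))
  if (un == 0L) return(0)
  length(intersect(nu, nv)) / un
}

# ---------------------------------------------------------------------------
# Phase 1: candidate power nodes.
#
# Agglomerative clustering under Jaccard neighborhood similarity: clusters
# start as singletons; the neighborhood of a cluster is the union of its
# members' neighborhoods; the pair of clusters with the highest positive
# Jaccard similarity is merged and every merged set is kept as a candidate
# (no dendrogram cut). In addition, for every node v with degree >= 1 we add
# N(v) and the set of common neighbors of all members of N(v) (which always
# contains v), so that stars and strongly asymmetric bicliques are reachable
# in phase 2. All singletons are candidates implicitly.
# ---------------------------------------------------------------------------
candidate_sets_internal <- function(A) {
  n <- nrow(A)
  cands <- lapply(seq_len(n), function(i) i)
  if (n == 0L || sum(A) == 0) return(cands)

  # hierarchical merging
  NB <- A                                   # n x k cluster neighborhoods
  members <- lapply(seq_len(n), function(i) i)
  I <- crossprod(NB)
  sz <- colSums(NB)
  U <- outer(sz, sz, "+") - I
  S <- ifelse(U > 0, I / U, 0)
  diag(S) <- 0
  while (ncol(NB) > 1L) {
    best <- max(S)
    if (best <= 0) break
    hit <- which(S == best, arr.ind = TRUE)[1L, ]   # deterministic: column-major
    i <- min(hit); j <- max(hit)
    newmem <- sort(c(members[[i]], members[[j]]))
    cands[[length(cands) + 1L]] <- newmem
    newnb <- pmin(NB[, i] + NB[, j], 1)
    NB[, i] <- newnb
    NB <- NB[, -j, drop = FALSE]
    members[[i]] <- newmem
    members[[j]] <- NULL
    I <- I[-j, -j, drop = FALSE]
    S <- S[-j, -j, drop = FALSE]
    sz <- sz[-j]
    v <- as.vector(crossprod(NB, newnb))
    I[i, ] <- v; I[, i] <- v
    sz[i] <- sum(newnb)
    u <- sz + sz[i] - v
    srow <- ifelse(u > 0, v / u, 0)
    srow[i] <- 0
    S[i, ] <- srow; S[, i] <- srow
  }

  # neighborhood sets and their common-neighbor sets
  deg <- colSums(A)
  for (v in seq_len(n)) {
    if (deg[v] == 0) next
    nv <- which(A[, v] > 0)
    cands[[length(cands) + 1L]] <- nv
    cn <- which(rowSums(A[, nv, drop = FALSE]) == length(nv))
    if (length(cn)) cands[[length(cands) + 1L]] <- cn
  }

  keys <- vapply(cands, function(x) paste(x, collapse = ","), character(1))
  cands[!duplicated(keys)]
}

#' Candidate power nodes of a network
#'
#' First phase of the power-graph algorithm: collects node sets that are
#' plausible power nodes by (i) agglomerative clustering under Jaccard
#' neighborhood similarity, keeping every merged set, (ii) each node's
#' neighborhood set and the common neighbors of that neighborhood, and (iii)
#' all singletons.
#'
#' @param g network.
#' @return an object of class `candidate_set`: a list of character vectors.
#' @export
candidate_power_nodes <- function(g) {
  g <- canonical_vertex_order(g)
  A <- as_dense_adjacency(g)
  sets <- candidate_sets_internal(A)
  nm <- igraph::V(g)$name
  structure(lapply(sets, function(ix) nm[ix]), class = "candidate_set")
}

as_dense_adjacency <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  storage.mode(A) <- "double"
  A
}

# ---------------------------------------------------------------------------
# Phase 2: greedy power-edge search.
#
# Among candidate pairs (U, W) whose full biclique lies in the graph (or
# candidates U forming a clique, |U| >= 3) the pair abstracting the most
# still-uncovered edges is adopted, subject to: all its edges are uncovered
# (partition condition holds by construction) and its endpoints are disjoint
# from or nested with every already-admitted power node (hierarchy
# condition). Gains are all-or-nothing, so processing candidates in sorted
# order is equivalent to iterative best-first selection. Ties prefer cliques
# over bicliques over stars, then smaller total endpoint size, then
# lexicographic order of sorted member identifiers. Leftover edges become
# trivial singleton-singleton power edges.
# ---------------------------------------------------------------------------

#' Compress a network into a power graph
#'
#' Two-phase lossless compression: candidate power nodes are proposed by
#' neighborhood-similarity clustering ([candidate_power_nodes()]), then power
#' edges -- each representing a complete biclique, clique, or star of the
#' original graph -- are selected greedily by the number of edges they
#' abstract, under the power-node hierarchy condition and the power-edge
#' partition condition. A candidate must abstract at least two uncovered
#' edges to be adopted; every remaining edge is kept as a trivial power edge.
#'
#' @param g network.
#' @param candidates optional `candidate_set` (defaults to
#'   `candidate_power_nodes(g)`).
#' @return an object of class `power_graph` with fields `graph`,
#'   `power_nodes` (named list of member character vectors) and `power_edges`
#'   (list of `list(u, v, reflexive)` referring to power-node ids).
#' @export
power_graph <- function(g, candidates = NULL) {
  g <- canonical_vertex_order(g)
  nm <- igraph::V(g)$name
  n <- length(nm)
  m <- igraph::ecount(g)
  A <- as_dense_adjacency(g)

  if (is.null(candidates)) {
    sets <- candidate_sets_internal(A)
  } else {
    sets <- lapply(unclass(candidates), function(x) sort(match(x, nm)))
    if (any(vapply(sets, anyNA, logical(1)))) {
      stop_netcompress("candidate set contains unknown nodes")
    }
    keys <- vapply(sets, paste, character(1), collapse = ",")
    sets <- sets[!duplicated(keys)]
  }
  if (m == 0L) {
    return(new_power_graph(g, power_nodes = list(), power_edges = list()))
  }

  sizes <- lengths(sets)
  c_n <- length(sets)
  M <- matrix(0, n, c_n)
  M[cbind(unlist(sets), rep.int(seq_len(c_n), sizes))] <- 1
  P <- A %*% M
  CN <- (P == matrix(sizes, n, c_n, byrow = TRUE)) * 1  # x adjacent to all of set j
  S <- crossprod(M, CN)                                  # |members_i ∩ CN_j|
  complete <- S == matrix(sizes, c_n, c_n)               # members_i ⊆ CN_j

  # non-reflexive candidate power edges (i < j); completeness is symmetric
  # and strict adjacency forces disjoint endpoints
  idx <- which(complete & upper.tri(complete, diag = FALSE), arr.ind = TRUE)
  if (nrow(idx)) {
    gain_b <- sizes[idx[, 1L]] * sizes[idx[, 2L]]
    ok <- gain_b >= 2L
    idx <- idx[ok, , drop = FALSE]
    gain_b <- gain_b[ok]
  } else {
    gain_b <- numeric()
  }
  # reflexive candidates: cliques with >= 3 members
  within2 <- colSums(M * P)                               # 2 * edges inside set
  cliq <- which(within2 == sizes * (sizes - 1) & sizes >= 3L)

  set_key <- vapply(sets, function(ix) paste(nm[ix], collapse = ","), character(1))
  pe <- data.frame(
    i = c(idx[, 1L], cliq),
    j = c(idx[, 2L], cliq),
    reflexive = c(rep(FALSE, nrow(idx)), rep(TRUE, length(cliq))),
    gain = c(gain_b, sizes[cliq] * (sizes[cliq] - 1) / 2)
  )
  if (nrow(pe)) {
    cls <- ifelse(pe$reflexive, 0L,
                  ifelse(pmin(sizes[pe$i], sizes[pe$j]) == 1L, 2L, 1L))
    szsum <- sizes[pe$i] + ifelse(pe$reflexive, 0L, sizes[pe$j])
    key <- ifelse(pe$reflexive, set_key[pe$i],
                  paste(pmin(set_key[pe$i], set_key[pe$j]),
                        pmax(set_key[pe$i], set_key[pe$j]), sep = "|"))
    pe <- pe[order(-pe$gain, cls, szsum, key), , drop = FALSE]
  }

  COV <- matrix(FALSE, n, n)
  admitted <- list()        # non-singleton power-node member sets
  admitted_keys <- character()
  edges_out <- list()

  hier_ok <- function(set) {
    for (a in admitted) if (!nested_or_disjoint(set, a)) return(FALSE)
    TRUE
  }
  admit <- function(set) {
    if (length(set) < 2L) return(invisible())
    k <- paste(set, collapse = ",")
    if (!k %in% admitted_keys) {
      admitted[[length(admitted) + 1L]] <<- set
      admitted_keys <<- c(admitted_keys, k)
    }
    invisible()
  }

  for (r in seq_len(nrow(pe))) {
    U <- sets[[pe$i[r]]]
    if (pe$reflexive[r]) {
      sub <- COV[U, U]
      if (any(sub[upper.tri(sub)])) next
      ku <- paste(U, collapse = ",")
      if (!(ku %in% admitted_keys) && !hier_ok(U)) next
      COV[U, U] <- TRUE
      admit(U)
      edges_out[[length(edges_out) + 1L]] <- list(u = U, v = U, reflexive = TRUE)
    } else {
      W <- sets[[pe$j[r]]]
      if (any(COV[U, W])) next
      ku <- paste(U, collapse = ","); kw <- paste(W, collapse = ",")
      if (!(ku %in% admitted_keys) && !hier_ok(U)) next
      if (!(kw %in% admitted_keys) && !hier_ok(W)) next
      COV[U, W] <- TRUE; COV[W, U] <- TRUE
      admit(U); admit(W)
      edges_out[[length(edges_out) + 1L]] <- list(u = U, v = W, reflexive = FALSE)
    }
  }

  # leftover edges become trivial power edges
  left <- which(A > 0 & !COV & upper.tri(A), arr.ind = TRUE)
  if (nrow(left)) {
    for (r in seq_len(nrow(left))) {
      edges_out[[length(edges_out) + 1L]] <-
        list(u = left[r, 1L], v = left[r, 2L], reflexive = FALSE)
    }
  }

  assemble_power_graph(g, nm, edges_out)
}

# Turn integer member sets into the exported power_graph structure with
# deterministic power-node ids.
assemble_power_graph <- function(g, nm, edges_out) {
  all_sets <- list()
  keys <- character()
  get_id <- function(ix) {
    k <- paste(ix, collapse = ",")
    pos <- match(k, keys)
    if (is.na(pos)) {
      all_sets[[length(all_sets) + 1L]] <<- ix
      keys <<- c(keys, k)
      pos <- length(keys)
    }
    pos
  }
  pes <- lapply(edges_out, function(e) {
    list(u = get_id(e$u), v = get_id(e$v), reflexive = e$reflexive)
  })
  # deterministic id order: by (size, lexicographic members)
  if (length(all_sets)) {
    skey <- vapply(all_sets, function(ix) paste(nm[ix], collapse = ","), character(1))
    o <- order(lengths(all_sets), skey)
    rank <- match(seq_along(all_sets), o)
    pn <- lapply(all_sets[o], function(ix) nm[ix])
    names(pn) <- sprintf("P%d", seq_along(pn))
    pes <- lapply(pes, function(e) {
      list(u = sprintf("P%d", rank[e$u]), v = sprintf("P%d", rank[e$v]),
           reflexive = e$reflexive)
    })
  } else {
    pn <- list()
  }
  new_power_graph(g, power_nodes = pn, power_edges = pes)
}

#' Construct a power graph object
#'
#' Low-level constructor; no validity checks are performed (see
#' [validate_power_graph()]), so invalid objects can be built for testing.
#'
#' @param graph the original network.
#' @param power_nodes named list of character vectors (power-node members).
#' @param power_edges list of `list(u, v, reflexive)` with `u`, `v` power-node
#'   ids (`u == v` and `reflexive = TRUE` for a clique power edge).
#' @return an object of class `power_graph`.
#' @export
new_power_graph <- function(graph, power_nodes, power_edges) {
  structure(list(graph = graph, power_nodes = power_nodes,
                 power_edges = power_edges),
            class = "power_graph")
}

#' @export
print.power_graph <- function(x, ...) {
  m <- igraph::ecount(x$graph)
  p <- length(x$power_edges)
  cat(sprintf("power graph: %d nodes, %d edges -> %d power edges (compression rate %.3f)\n",
              igraph::vcount(x$graph), m, p, if (m > 0) (m - p) / m else NA_real_))
  invisible(x)
}

# Edges abstracted by one power edge, as a 2-column character matrix of
# canonical (lo, hi) pairs.
abstracted_edges <- function(pg, e) {
  u <- pg$power_nodes[[e$u]]
  v <- pg$power_nodes[[e$v]]
  if (e$reflexive) {
    prs <- t(utils::combn(sort(u), 2L))
  } else {
    prs <- as.matrix(expand.grid(u, v, stringsAsFactors = FALSE))
  }
  cbind(pmin(prs[, 1L], prs[, 2L]), pmax(prs[, 1L], prs[, 2L]))
}

#' Expand a power graph back into the original network
#'
#' Every power edge is expanded into the complete biclique (or clique) it
#' represents. For a valid power graph this reproduces the original network
#' exactly -- the representation is lossless.
#'
#' @param pg a `power_graph`.
#' @return network.
#' @export
decompress <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  prs <- lapply(pg$power_edges, function(e) abstracted_edges(pg, e))
  edges <- if (length(prs)) do.call(rbind, prs) else matrix(character(), ncol = 2L)
  make_network(edges, nodes = igraph::V(pg$graph)$name)
}

#' Validate a power graph
#'
#' Checks the three defining conditions: the hierarchy condition (any two
#' power nodes are disjoint or nested), the partition condition (every
#' original edge is abstracted by exactly one power edge), and losslessness
#' (the abstracted edges are exactly the original edge set). Also flags
#' singleton reflexive power edges and non-disjoint endpoints.
#'
#' @param pg a `power_graph`.
#' @return a data frame of violations with columns `condition` and `detail`;
#'   zero rows means the power graph is valid.
#' @export
validate_power_graph <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  bad <- list()
  flag <- function(condition, detail) {
    bad[[length(bad) + 1L]] <<- data.frame(condition = condition, detail = detail,
                                           stringsAsFactors = FALSE)
  }
  nodes <- igraph::V(pg$graph)$name
  for (id in names(pg$power_nodes)) {
    mem <- pg$power_nodes[[id]]
    if (length(mem) == 0L) flag("membership", sprintf("power node %s is empty", id))
    if (!all(mem %in% nodes)) {
      flag("membership", sprintf("power node %s has members outside the graph", id))
    }
  }
  ids <- names(pg$power_nodes)
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        if (!nested_or_disjoint(pg$power_nodes[[ids[i]]], pg$power_nodes[[ids[j]]])) {
          flag("hierarchy", sprintf("power nodes %s and %s overlap without nesting",
                                    ids[i], ids[j]))
        }
      }
    }
  }
  el <- igraph::as_edgelist(pg$graph)
  orig <- if (nrow(el)) edge_keys(el[, 1L], el[, 2L]) else character()
  seen <- character()
  for (k in seq_along(pg$power_edges)) {
    e <- pg$power_edges[[k]]
    u <- pg$power_nodes[[e$u]]
    v <- pg$power_nodes[[e$v]]
    if (is.null(u) || is.null(v)) {
      flag("membership", sprintf("power edge %d refers to an unknown power node", k))
      next
    }
    if (e$reflexive && length(u) < 2L) {
      flag("reflexive", sprintf("power edge %d: singleton reflexive power edge", k))
      next
    }
    if (!e$reflexive && length(intersect(u, v)) > 0L) {
      flag("endpoints", sprintf("power edge %d: endpoints are not disjoint", k))
      next
    }
    ab <- abstracted_edges(pg, e)
    kk <- edge_keys(ab[, 1L], ab[, 2L])
    if (!all(kk %in% orig)) {
      flag("losslessness", sprintf("power edge %d abstracts pairs absent from the graph", k))
    }
    dup <- intersect(kk, seen)
    if (length(dup)) {
      flag("partition", sprintf("power edge %d re-abstracts %d already-covered edge(s)",
                                k, length(dup)))
    }
    seen <- union(seen, kk)
  }
  missing <- setdiff(orig, seen)
  if (length(missing)) {
    flag("partition", sprintf("%d original edge(s) not abstracted by any power edge",
                              length(missing)))
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(condition = character(), detail = character(), stringsAsFactors = FALSE)
}

#' Remove clique content from a network
#'
#' Compresses the network, identifies the reflexive power edges (which
#' represent cliques), and deletes every interaction they abstract. Nodes are
#' kept. Used to ask how much compressibility and clustering is attributable
#' to cliques alone.
#'
#' @param g network.
#' @return network with clique edges removed.
#' @export
remove_cliques <- function(g) {
  pg <- power_graph(g)
  drop <- character()
  for (e in pg$power_edges) {
    if (e$reflexive) {
      ab <- abstracted_edges(pg, e)
      drop <- c(drop, paste(ab[, 1L], ab[, 2L], sep = "|"))
    }
  }
  g2 <- canonical_vertex_order(g)
  if (length(drop)) {
    el <- igraph::as_edgelist(g2)
    keys <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|")
    g2 <- igraph::delete_edges(g2, which(keys %in% drop))
  }
  g2
}

#' Motif spectrum of a power graph
#'
#' Tabulates power edges by endpoint sizes `(a, b)` with `a <= b` and class:
#' `clique` for reflexive power edges, `star` when one endpoint is a single
#' node, `biclique` otherwise. Trivial single-edge power edges count as
#' `(1, 1, star)`. This is the data behind disc-chart displays of motif
#' content.
#'
#' @param pg a `power_graph`.
#' @return data frame with columns `a`, `b`, `class`, `count`.
#' @export
motif_spectrum <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  if (length(pg$power_edges) == 0L) {
    return(data.frame(a = integer(), b = integer(), class = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(pg$power_edges, function(e) {
    su <- length(pg$power_nodes[[e$u]])
    sv <- length(pg$power_nodes[[e$v]])
    cls <- if (e$reflexive) "clique" else if (min(su, sv) == 1L) "star" else "biclique"
    data.frame(a = min(su, sv), b = max(su, sv), class = cls, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(tab))),
                          by = tab[c("a", "b", "class")], FUN = sum)
  agg[order(agg$a, agg$b, agg$class), , drop = FALSE]
}

#' Write a power graph in a plain-text exchange format
#'
#' One line per power node (`PN <id> parent=<id|-> : m1,m2,...`, parent being
#' the smallest power node strictly containing it) and one per power edge
#' (`PE <idU> <idV> reflexive|plain`), in deterministic order.
#'
#' @param pg a `power_graph`.
#' @param path output file path.
#' @export
write_power_graph <- function(pg, path) {
  stopifnot(inherits(pg, "power_graph"))
  lines <- sprintf("# netcompress power graph: %d nodes, %d edges, %d power edges",
                   igraph::vcount(pg$graph), igraph::ecount(pg$graph),
                   length(pg$power_edges))
  ids <- names(pg$power_nodes)
  for (id in ids) {
    mem <- pg$power_nodes[[id]]
    parent <- "-"
    best <- Inf
    for (other in ids) {
      om <- pg$power_nodes[[other]]
      if (other != id && length(om) > length(mem) && all(mem %in% om) &&
          length(om) < best) {
        parent <- other; best <- length(om)
      }
    }
    lines <- c(lines, sprintf("PN %s parent=%s : %s", id, parent,
                              paste(sort(mem), collapse = ",")))
  }
  for (e in pg$power_edges) {
    lines <- c(lines, sprintf("PE %s %s %s", e$u, e$v,
                              if (e$reflexive) "reflexive" else "plain"))
  }
  writeLines(lines, path)
  invisible(path)
}
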