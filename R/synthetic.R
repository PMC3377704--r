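#' Specification of a synthetic planted-motif network
#'
#' The generator emulates the statistical structure the compressibility
#' analyses assume in real interactomes: modules appearing as cliques
#' (protein complexes), bicliques (two groups with all-against-all
#' interactions, e.g. shared sub-complexes), and stars (hubs), embedded in a
#' background of uniformly random spurious interactions.
#'
#' @param n_nodes total number of nodes.
#' @param cliques integer vector of clique sizes (each >= 3).
#' @param bicliques list of 2-vectors `c(a, b)` of biclique side sizes (each
#'   side >= 1, `a + b >= 3`).
#' @param stars integer vector of star leaf counts (each >= 2); a star uses
#'   one extra node as the center.
#' @param noise_edges number of uniform noise edges added on top of the
#'   planted motifs (never duplicating a planted pair).
#' @param overlap when `FALSE` (default) motifs occupy disjoint node sets;
#'   when `TRUE`, each motif samples its nodes independently from the full
#'   node set, so shared sub-modules can arise.
#' @param seed integer RNG seed; the same seed reproduces the network
#'   byte-for-byte.
#' @return an object of class `plant_spec`.
#' @export
plant_spec <- function(n_nodes, cliques = integer(), bicliques = list(),
                       stars = integer(), noise_edges = 0L, overlap = FALSE,
                       seed = 1L) {
  cliques <- as.integer(cliques)
  stars <- as.integer(stars)
  if (length(cliques) && any(cliques < 3L)) {
    stop_netcompress("planted cliques need at least 3 nodes")
  }
  if (length(stars) && any(stars < 2L)) {
    stop_netcompress("planted stars need at least 2 leaves")
  }
  for (b in bicliques) {
    if (length(b) != 2L || any(b < 1L) || sum(b) < 3L) {
      stop_netcompress("bicliques must be 2-vectors c(a, b) with a + b >= 3")
    }
  }
  demand <- sum(cliques) + sum(vapply(bicliques, sum, numeric(1))) +
    sum(stars + 1L)
  if (!overlap && demand > n_nodes) {
    stop_netcompress("motifs need ", demand, " nodes but only ", n_nodes,
                     " are available (set overlap = TRUE to share nodes)")
  }
  structure(list(n_nodes = as.integer(n_nodes), cliques = cliques,
                 bicliques = bicliques, stars = stars,
                 noise_edges = as.integer(noise_edges),
                 overlap = isTRUE(overlap), seed = as.integer(seed)),
            class = "plant_spec")
}

#' Generate a planted-motif network
#'
#' Emits the union of the planted motifs plus exactly `noise_edges` uniform
#' extra edges that avoid every planted pair, together with the ground truth.
#'
#' @param spec a [plant_spec()].
#' @return `list(graph, truth)` where `truth` is a list of motifs, each a
#'   `list(id, type, nodes, ...)` with type-specific fields (`side_a`/`side_b`
#'   for bicliques, `center`/`leaves` for stars) and the planted `edges`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  nodes <- sprintf("v%04d", seq_len(spec$n_nodes))
  with_seed(spec$seed, {
    pool <- sample(nodes)
    take <- function(k) {
      if (spec$overlap) return(sample(nodes, k))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    truth <- list()
    planted <- list()
    mid <- 0L
    for (s in spec$cliques) {
      mid <- mid + 1L
      mem <- take(s)
      edges <- t(utils::combn(sort(mem), 2L))
      truth[[mid]] <- list(id = mid, type = "clique", nodes = sort(mem),
                           edges = edges)
      planted[[mid]] <- edges
    }
    for (b in spec$bicliques) {
      mid <- mid + 1L
      a_side <- take(b[1L]); b_side <- take(b[2L])
      edges <- as.matrix(expand.grid(sort(a_side), sort(b_side),
                                     stringsAsFactors = FALSE))
      truth[[mid]] <- list(id = mid, type = "biclique",
                           nodes = sort(c(a_side, b_side)),
                           side_a = sort(a_side), side_b = sort(b_side),
                           edges = edges)
      planted[[mid]] <- edges
    }
    for (s in spec$stars) {
      mid <- mid + 1L
      mem <- take(s + 1L)
      center <- mem[1L]; leaves <- sort(mem[-1L])
      edges <- cbind(rep(center, s), leaves)
      truth[[mid]] <- list(id = mid, type = "star",
                           nodes = sort(mem), center = center, leaves = leaves,
                           edges = edges)
      planted[[mid]] <- edges
    }
    planted_mat <- if (length(planted)) do.call(rbind, planted) else
      matrix(character(), ncol = 2L)
    planted_keys <- unique(edge_keys(planted_mat[, 1L], planted_mat[, 2L]))
    edges_all <- planted_mat
    if (spec$noise_edges > 0L) {
      all_pairs <- t(utils::combn(nodes, 2L))
      free <- which(!(edge_keys(all_pairs[, 1L], all_pairs[, 2L]) %in% planted_keys))
      if (length(free) < spec$noise_edges) {
        stop_netcompress("not enough free node pairs for ", spec$noise_edges,
                         " noise edges")
      }
      pick <- sample(free, spec$noise_edges)
      edges_all <- rbind(edges_all, all_pairs[pick, , drop = FALSE])
    }
    g <- make_network(edges_all, nodes = nodes)
    g$planted_keys <- planted_keys
    list(graph = g, truth = truth)
  })
}

#' Generate a scored planted-motif network
#'
#' Planted edges receive confidence scores uniform in
#' `[planted_score_min, 1]`, noise edges uniform in `[0, planted_score_min)`,
#' so the planted confidence boundary is recoverable by [slice_matrix()].
#'
#' @param spec a [plant_spec()].
#' @param planted_score_min boundary score in `(0, 1)`.
#' @return `list(graph, truth)` with a scored graph.
#' @export
generate_scored <- function(spec, planted_score_min = 0.8) {
  if (planted_score_min <= 0 || planted_score_min >= 1) {
    stop_netcompress("`planted_score_min` must be in (0, 1)")
  }
  res <- generate_network(spec)
  g <- res$graph
  el <- igraph::as_edgelist(g)
  is_planted <- edge_keys(el[, 1L], el[, 2L]) %in% g$planted_keys
  sc <- numeric(nrow(el))
  with_seed(spec$seed + 1L, {
    sc[is_planted] <- stats::runif(sum(is_planted), planted_score_min, 1)
    sc[!is_planted] <- stats::runif(sum(!is_planted), 0, planted_score_min)
  })
  igraph::E(g)$score <- sc
  res$graph <- g
  res
}

#' Generate annotations matched (or not) to planted modules
#'
#' With `informative = TRUE`, every node belonging to a planted motif is
#' labelled with that motif's id (nodes shared between motifs get several
#' labels) and background nodes get unique labels, so the annotation is
#' perfectly aligned with the planted wiring. With `informative = FALSE` the
#' same label sets are permuted uniformly across nodes, producing a null
#' annotation with the identical label distribution but no relation to the
#' topology.
#'
#' @param g graph from [generate_network()].
#' @param truth matching ground-truth motif list.
#' @param informative logical.
#' @param seed integer RNG seed (used for the permutation).
#' @param category category name in the returned set.
#' @return an [annotation_set()] with one label category.
#' @export
generate_annotations <- function(g, truth, informative = TRUE, seed = 1L,
                                 category = "module") {
  nodes <- igraph::V(g)$name
  labels <- stats::setNames(lapply(nodes, function(v) paste0("bg_", v)), nodes)
  for (mo in truth) {
    for (v in mo$nodes) {
      cur <- labels[[v]]
      cur <- cur[!startsWith(cur, "bg_")]
      labels[[v]] <- c(cur, paste0("m", mo$id))
    }
  }
  if (!informative) {
    labels <- with_seed(seed, stats::setNames(labels[sample(length(labels))], nodes))
  }
  cats <- list()
  cats[[category]] <- labels
  annotation_set(categories = cats)
}
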