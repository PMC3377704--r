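#' Configuration for degree-preserving rewiring
#'
#' @param swap_multiple positive integer; the number of attempted double-edge
#'   swaps is `swap_multiple * |E|`. The default of 10 makes it very likely
#'   that nearly every edge is rewired at least once.
#' @param seed integer RNG seed.
#' @return an object of class `rewire_config`.
#' @export
rewire_config <- function(swap_multiple = 10L, seed = 1L) {
  swap_multiple <- as.integer(swap_multiple)
  if (is.na(swap_multiple) || swap_multiple < 1L) {
    stop_netcompress("`swap_multiple` must be a positive integer")
  }
  structure(list(swap_multiple = swap_multiple, seed = as.integer(seed)),
            class = "rewire_config")
}

#' Degree-preserving random rewiring
#'
#' Null model for all relative statistics in this package: two randomly
#' chosen interactions A-B and C-D are replaced by A-C and B-D, which
#' preserves every node's number of interaction partners. Swaps that would
#' create a self-loop or duplicate an existing edge are rejected. The swap is
#' attempted `swap_multiple * |E|` times.
#'
#' @param g network with at least 2 edges.
#' @param config a [rewire_config()].
#' @return a rewired network with identical node set, edge count, and degree
#'   sequence (edge scores, no longer meaningful, are dropped).
#' @export
rewire_graph <- function(g, config = rewire_config()) {
  stopifnot(inherits(config, "rewire_config"))
  m <- igraph::ecount(g)
  if (m < 2L) stop_netcompress("rewiring needs at least 2 edges")
  g <- delete_score_attr(g)
  with_seed(config$seed, {
    igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                             niter = config$swap_multiple * m))
  })
}

#' Ensemble of rewired networks
#'
#' Chain of `n` rewired networks in which member `k + 1` is a rewiring of
#' member `k`, so correlation with the original network decays along the
#' chain. Per-step seeds are derived deterministically from `config$seed`
#' (seed + step index - 1), making the ensemble reproducible and
#' partitionable.
#'
#' @param g network.
#' @param n ensemble size (the headline protocol uses 1000; smaller values
#'   trade sampling error, which scales as `sd/sqrt(n)`, for speed).
#' @param config a [rewire_config()].
#' @return list of `n` networks.
#' @export
rewire_ensemble <- function(g, n, config = rewire_config()) {
  stopifnot(inherits(config, "rewire_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_netcompress("`n` must be >= 1")
  out <- vector("list", n)
  cur <- g
  for (k in seq_len(n)) {
    cur <- rewire_graph(cur, rewire_config(config$swap_multiple,
                                           config$seed + k - 1L))
    out[[k]] <- cur
  }
  out
}

#' Specification of a noise perturbation
#'
#' The four edge-noise models combine a sampling law with a direction:
#' `ER` (uniform over all protein pairs) or `BA` (degree-biased:
#' interaction-rich proteins get richer on addition, interaction-poor
#' proteins get poorer on removal), each either adding false positives
#' (`add_edges`) or removing true interactions (`remove_edges`). Node modes
#' (`remove_nodes`, uniform under-sampling; `add_nodes`, cloned proteins with
#' randomly rewired connections) use the uniform law only.
#'
#' @param model `"ER"` or `"BA"`.
#' @param mode one of `"add_edges"`, `"remove_edges"`, `"remove_nodes"`,
#'   `"add_nodes"`.
#' @param fraction perturbed fraction of edges (edge modes) or nodes (node
#'   modes), in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("ER", "BA"),
                       mode = c("add_edges", "remove_edges",
                                "remove_nodes", "add_nodes"),
                       fraction, seed = 1L) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop_netcompress("`fraction` must be in [0, 1]")
  }
  if (model == "BA" && !mode %in% c("add_edges", "remove_edges")) {
    stop_netcompress("the BA model is defined for edge modes only")
  }
  structure(list(model = model, mode = mode, fraction = fraction,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Apply a noise perturbation
#'
#' Dispatches to [perturb_edges()] or [perturb_nodes()] according to the
#' spec's mode.
#'
#' @param g network.
#' @param spec a [noise_spec()].
#' @return perturbed network.
#' @export
perturb <- function(g, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$mode %in% c("add_edges", "remove_edges")) {
    perturb_edges(g, spec)
  } else {
    perturb_nodes(g, spec)
  }
}

# All complement pairs of a graph as an index matrix, with per-pair weights
# under the given model (degrees taken from the unperturbed graph).
complement_pairs <- function(A) {
  which(A == 0 & upper.tri(A), arr.ind = TRUE)
}

#' Edge-level noise: false positives and false negatives
#'
#' Adds or removes exactly `k = round(fraction * |E|)` interactions
#' (half-up rounding). Under `ER` the choice is uniform: removed edges are
#' sampled uniformly from the existing edges; added edges uniformly from the
#' absent pairs. Under `BA`, addition samples each endpoint with probability
#' proportional to its degree (so an absent pair is chosen with weight
#' `deg(u) * deg(v)`) and removal picks edges with weight
#' `1/deg(u) + 1/deg(v)`. Degrees are those of the unperturbed network; the
#' node set never changes.
#'
#' @param g network.
#' @param spec a [noise_spec()] with an edge mode.
#' @return perturbed network.
#' @export
perturb_edges <- function(g, spec) {
  stopifnot(inherits(spec, "noise_spec"),
            spec$mode %in% c("add_edges", "remove_edges"))
  m <- igraph::ecount(g)
  k <- round_half_up(spec$fraction * m)
  if (k == 0L) return(g)
  g <- canonical_vertex_order(g)
  deg <- igraph::degree(g)
  if (spec$mode == "remove_edges") {
    w <- if (spec$model == "ER") {
      rep(1, m)
    } else {
      el <- igraph::as_edgelist(g)
      1 / deg[el[, 1L]] + 1 / deg[el[, 2L]]
    }
    idx <- with_seed(spec$seed, sample.int(m, k, prob = w))
    return(igraph::delete_edges(g, idx))
  }
  A <- as_dense_adjacency(g)
  comp <- complement_pairs(A)
  if (nrow(comp) < k) {
    stop_netcompress("not enough absent pairs to add ", k, " edges")
  }
  w <- if (spec$model == "ER") rep(1, nrow(comp)) else deg[comp[, 1L]] * deg[comp[, 2L]]
  if (spec$model == "BA" && all(w == 0)) {
    stop_netcompress("BA addition impossible: all absent pairs have weight zero")
  }
  pick <- with_seed(spec$seed, sample.int(nrow(comp), k, prob = w))
  nm <- igraph::V(g)$name
  new_edges <- rbind(nm[comp[pick, 1L]], nm[comp[pick, 2L]])
  g2 <- igraph::add_edges(delete_score_attr(g), as.vector(new_edges))
  g2
}

#' Node-level noise: under-sampling and cloned proteins
#'
#' `remove_nodes` deletes `k = round(fraction * |V|)` uniformly chosen nodes
#' with all their interactions. `add_nodes` introduces `k` new proteins, each
#' *cloned* from a uniformly chosen existing protein: the clone receives its
#' template's degree but its connections are rewired to uniformly chosen
#' distinct existing targets, so the degree distribution is minimally
#' perturbed while the new interactions are completely random. The clone map
#' is stored in the graph attribute `clone_map`.
#'
#' @param g network.
#' @param spec a [noise_spec()] with a node mode.
#' @return perturbed network.
#' @export
perturb_nodes <- function(g, spec) {
  stopifnot(inherits(spec, "noise_spec"),
            spec$mode %in% c("remove_nodes", "add_nodes"))
  g <- canonical_vertex_order(g)
  n <- igraph::vcount(g)
  k <- round_half_up(spec$fraction * n)
  if (spec$mode == "remove_nodes") {
    if (k >= n) stop_netcompress("removing every node would leave an empty graph")
    if (k == 0L) return(g)
    drop <- with_seed(spec$seed, sample.int(n, k))
    return(igraph::delete_vertices(g, drop))
  }
  if (k == 0L) return(g)
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  with_seed(spec$seed, {
    clones <- sample.int(n, k, replace = TRUE)
    new_names <- sprintf("added_%03d", seq_len(k))
    while (any(new_names %in% nm)) new_names <- paste0(new_names, "x")
    g2 <- igraph::add_vertices(delete_score_attr(g), k, name = new_names)
    for (i in seq_len(k)) {
      d <- deg[clones[i]]
      if (d == 0L) next
      targets <- sample.int(n, d)   # distinct original nodes
      g2 <- igraph::add_edges(g2, as.vector(rbind(new_names[i], nm[targets])))
    }
    g2$clone_map <- stats::setNames(nm[clones], new_names)
    g2
  })
}
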