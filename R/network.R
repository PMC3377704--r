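#' Build a simple undirected network
#'
#' Constructs the network container used throughout the package: a simple
#' undirected \pkg{igraph} graph over text node identifiers with an optional
#' per-edge confidence score stored in the `score` edge attribute.
#' Duplicate edges (in either orientation) collapse to one edge; when scored,
#' the last-seen score wins. Self-loops are dropped with a warning.
#'
#' @param edges two-column character matrix or data frame of endpoints; may
#'   have zero rows.
#' @param nodes optional character vector of node identifiers; endpoints are
#'   always included, so this is the way to declare isolated nodes.
#' @param scores optional numeric vector of confidence scores, one per row of
#'   `edges`.
#' @return an undirected `igraph` graph.
#' @export
make_network <- function(edges, nodes = NULL, scores = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  if (ncol(edges) < 2L) stop_netcompress("`edges` must have two columns")
  a0 <- as.character(edges[, 1L])
  b0 <- as.character(edges[, 2L])
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != length(a0)) {
      stop_netcompress("`scores` must have one entry per edge row")
    }
  }
  loops <- a0 == b0
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop edge(s)", sum(loops)), call. = FALSE)
    a0 <- a0[!loops]; b0 <- b0[!loops]
    if (!is.null(scores)) scores <- scores[!loops]
  }
  lo <- pmin(a0, b0)
  hi <- pmax(a0, b0)
  last <- !duplicated(edge_keys(lo, hi), fromLast = TRUE)  # last-seen score wins
  a <- lo[last]
  b <- hi[last]
  if (!is.null(scores)) scores <- scores[last]
  o <- order(a, b)  # canonical edge order for reproducible downstream output
  a <- a[o]; b <- b[o]
  if (!is.null(scores)) scores <- scores[o]
  all_nodes <- sort(unique(c(a, b, as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  if (!is.null(scores)) igraph::E(g)$score <- scores
  canonical_vertex_order(g)
}

#' Read a network from a delimited edge list
#'
#' Supported dialects: `tsv2` (node_a, node_b), `tsv3` (node_a, node_b,
#' numeric confidence score) and `sif` (node_a, relation, node_b; the
#' relation is ignored). Fields may be separated by tabs or spaces; lines
#' starting with `#` are comments, except `# isolated:` directives emitted by
#' [write_edge_list()] which declare edgeless nodes.
#'
#' @param path file path.
#' @param dialect one of `"tsv2"`, `"tsv3"`, `"sif"`.
#' @return an undirected `igraph` graph; for `tsv3`, edges carry a `score`
#'   attribute and the last-seen score wins for a repeated edge.
#' @export
read_edge_list <- function(path, dialect = c("tsv2", "tsv3", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_netcompress("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isolated <- character()
  iso <- grepl("^#\\s*isolated:", lines)
  if (any(iso)) {
    decl <- sub("^#\\s*isolated:\\s*", "", lines[iso])
    isolated <- unlist(strsplit(decl, "\\s+"))
    isolated <- isolated[nzchar(isolated)]
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  want <- switch(dialect, tsv2 = 2L, tsv3 = 3L, sif = 3L)
  a <- b <- character(length(rows))
  sc <- if (dialect == "tsv3") numeric(length(rows)) else NULL
  for (i in seq_along(rows)) {
    f <- strsplit(trimws(lines[rows[i]]), "[\t ]+")[[1L]]
    if (length(f) != want) {
      stop_netcompress(sprintf(
        "line %d: expected %d fields for dialect '%s', got %d",
        rows[i], want, dialect, length(f)
      ))
    }
    if (dialect == "sif") {
      a[i] <- f[1L]; b[i] <- f[3L]
    } else {
      a[i] <- f[1L]; b[i] <- f[2L]
    }
    if (dialect == "tsv3") {
      s <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(s)) {
        stop_netcompress(sprintf("line %d: non-numeric score '%s'", rows[i], f[3L]))
      }
      sc[i] <- s
    }
  }
  make_network(cbind(a, b), nodes = isolated, scores = sc)
}

#' Write a network as a delimited edge list
#'
#' Tab-delimited output with a comment header; `tsv3` writes the `score`
#' edge attribute at full precision and requires every edge to be scored.
#' Isolated nodes are recorded in a `# isolated:` header directive so that
#' the read/write round trip is the identity on nodes, edges, and scores.
#'
#' @param g network as returned by [make_network()].
#' @param path output file path.
#' @param dialect `"tsv2"` or `"tsv3"`.
#' @export
write_edge_list <- function(g, path, dialect = c("tsv2", "tsv3")) {
  dialect <- match.arg(dialect)
  el <- igraph::as_edgelist(g)
  header <- sprintf("# netcompress edge list (%s): node_a\tnode_b%s", dialect,
                    if (dialect == "tsv3") "\tscore" else "")
  lines <- header
  deg <- igraph::degree(g)
  if (any(deg == 0L)) {
    lines <- c(lines, paste("# isolated:", paste(names(deg)[deg == 0L], collapse = " ")))
  }
  if (nrow(el) > 0L) {
    a <- pmin(el[, 1L], el[, 2L])
    b <- pmax(el[, 1L], el[, 2L])
    o <- order(a, b)
    if (dialect == "tsv3") {
      sc <- igraph::E(g)$score
      if (is.null(sc) || anyNA(sc)) {
        stop_netcompress("dialect 'tsv3' requires a score on every edge")
      }
      lines <- c(lines, paste(a[o], b[o], format(sc[o], digits = 17), sep = "\t"))
    } else {
      lines <- c(lines, paste(a[o], b[o], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Local clustering coefficient of a node
#'
#' Proportion of realized interactions among the neighbors of `v` relative
#' to the maximal possible number; nodes with fewer than two neighbors get 0.
#'
#' @param g network.
#' @param v node identifier.
#' @return a number in `[0, 1]`.
#' @export
local_clustering <- function(g, v) {
  if (!v %in% igraph::V(g)$name) stop_netcompress("unknown node: ", v)
  x <- igraph::transitivity(g, type = "local", vids = v, isolates = "zero")
  unname(x)
}

#' Average clustering coefficient of a network
#'
#' Arithmetic mean of the local clustering coefficient over all nodes
#' (Watts-Strogatz average; degree < 2 nodes contribute 0).
#'
#' @param g non-empty network.
#' @return a number in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  if (igraph::vcount(g) == 0L) stop_netcompress("empty graph")
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Complement of a network
#'
#' The complement (for an interactome: the negatome) contains an edge between
#' two distinct nodes exactly when the original does not. An optional
#' `universe` of node identifiers extends the node set before complementing.
#'
#' @param g network.
#' @param universe optional character vector of node identifiers; must contain
#'   every node of `g`. Defaults to the nodes of `g`.
#' @return the complement network (unscored).
#' @export
complement_network <- function(g, universe = NULL) {
  nodes <- igraph::V(g)$name
  if (!is.null(universe)) {
    universe <- as.character(universe)
    if (!all(nodes %in% universe)) {
      stop_netcompress("`universe` must contain every node of the graph")
    }
    extra <- setdiff(universe, nodes)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  out <- igraph::complementer(delete_score_attr(g))
  canonical_vertex_order(out)
}

# Complement edges carry no meaningful confidence; strip scores first.
delete_score_attr <- function(g) {
  if ("score" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "score")
  }
  g
}

#' Bait-prey purification records
#'
#' A purification record is one affinity-purification observation: a bait and
#' the list of preys pulled down with it. Preys equal to the bait are dropped;
#' a record left with no preys is skipped with a warning by
#' [interpret_purifications()].
#'
#' @param bait node identifier.
#' @param preys character vector of prey identifiers.
#' @return an object of class `purification_record`.
#' @export
purification_record <- function(bait, preys) {
  bait <- as.character(bait)
  preys <- unique(as.character(preys))
  preys <- setdiff(preys, bait)
  structure(list(bait = bait, preys = preys), class = "purification_record")
}

#' Read purification records
#'
#' One record per row: `bait TAB prey1,prey2,...`.
#'
#' @param path file path.
#' @return list of [purification_record()] objects.
#' @export
read_purifications <- function(path) {
  if (!file.exists(path)) stop_netcompress("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\t")[[1L]]
    if (length(f) != 2L) stop_netcompress("malformed purification row: ", l)
    purification_record(f[1L], strsplit(f[2L], ",")[[1L]])
  })
}

#' Interpret purification records as a binary interaction network
#'
#' The *spoke* model adds bait-prey edges only; the *matrix* model adds all
#' pairwise edges among the bait and its preys. Unions over records are
#' deduplicated.
#'
#' @param records non-empty list of [purification_record()] objects.
#' @param model `"spoke"` or `"matrix"`.
#' @return network.
#' @export
interpret_purifications <- function(records, model = c("spoke", "matrix")) {
  model <- match.arg(model)
  if (length(records) == 0L) stop_netcompress("no purification records")
  pairs <- list()
  for (r in records) {
    if (length(r$preys) == 0L) {
      warning("skipping record with no preys after bait-self removal: ", r$bait,
              call. = FALSE)
      next
    }
    if (model == "spoke") {
      pairs[[length(pairs) + 1L]] <- cbind(r$bait, r$preys)
    } else {
      members <- c(r$bait, r$preys)
      pairs[[length(pairs) + 1L]] <- t(utils::combn(members, 2L))
    }
  }
  if (length(pairs) == 0L) stop_netcompress("no usable purification records")
  make_network(do.call(rbind, pairs))
}

#' Screening completeness of an interaction screen
#'
#' Proportion of the whole interactome search space accessible to a screen
#' with the given bait and prey ORF collections:
#' `(n_bait_orfs * n_prey_orfs) / n_protein_coding_genes^2`.
#'
#' @param n_bait_orfs number of ORFs cloned for baits.
#' @param n_prey_orfs number of ORFs cloned for preys.
#' @param n_protein_coding_genes protein-coding genes in the genome.
#' @return a number in `[0, 1]`.
#' @export
screening_completeness <- function(n_bait_orfs, n_prey_orfs, n_protein_coding_genes) {
  if (n_protein_coding_genes <= 0) stop_netcompress("gene count must be positive")
  if (n_bait_orfs <= 0 || n_prey_orfs <= 0) stop_netcompress("counts must be positive")
  if (n_bait_orfs > n_protein_coding_genes || n_prey_orfs > n_protein_coding_genes) {
    stop_netcompress("bait/prey ORF counts cannot exceed the gene count")
  }
  (n_bait_orfs * n_prey_orfs) / n_protein_coding_genes^2
}
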