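test_that("neighborhood Jaccard similarity matches set arithmetic", {
  k23 <- k_bipartite(2, 3)
  expect_equal(neighborhood_jaccard(k23, "a01", "a02"), 1)
  # opposite sides of a biclique share no neighbors
  expect_equal(neighborhood_jaccard(k23, "a01", "b01"), 0)
  # N(u) = {a,b,c}, N(v) = {b,c,d} -> 2/4
  g <- make_network(rbind(c("u", "a"), c("u", "b"), c("u", "c"),
                          c("v", "b"), c("v", "c"), c("v", "d")))
  expect_equal(neighborhood_jaccard(g, "u", "v"), 0.5)
  # symmetric, bounded, zero on two isolated nodes
  iso <- make_network(rbind(c("x", "y")), nodes = c("x", "y", "p", "q"))
  expect_equal(neighborhood_jaccard(iso, "p", "q"), 0)
  for (g in fixture_corpus(4L)) {
    nm <- igraph::V(g)$name
    pick <- nm[seq_len(min(6L, length(nm)))]
    for (u in pick) for (v in pick) {
      s <- neighborhood_jaccard(g, u, v)
      expect_true(s >= 0 && s <= 1)
      expect_equal(s, neighborhood_jaccard(g, v, u))
    }
  }
  expect_error(neighborhood_jaccard(k23, "nope", "a01"), "unknown")
})

test_that("candidate power nodes include clustered sides, neighborhoods, and singletons", {
  keys <- function(cs) vapply(cs, function(x) paste(sort(x), collapse = ","), "")
  k33 <- k_bipartite(3, 3)
  ck <- keys(candidate_power_nodes(k33))
  expect_true("a01,a02,a03" %in% ck)
  expect_true("b01,b02,b03" %in% ck)
  st <- star_network(4)
  expect_true("l01,l02,l03,l04" %in% keys(candidate_power_nodes(st)))
  # single edge: both singletons and both neighborhoods
  e <- make_network(rbind(c("A", "B")))
  expect_setequal(keys(candidate_power_nodes(e)), c("A", "B"))
})

test_that("greedy compression finds single planted motifs as one power edge", {
  pg <- power_graph(k_complete(5))
  expect_length(pg$power_edges, 1L)
  expect_true(pg$power_edges[[1]]$reflexive)
  expect_equal(compression_rate(k_complete(5), pg), 0.9)

  pg <- power_graph(k_bipartite(3, 3))
  expect_length(pg$power_edges, 1L)
  expect_false(pg$power_edges[[1]]$reflexive)

  pg <- power_graph(path_network(c("A", "B", "C")))
  expect_length(pg$power_edges, 1L)
  sizes <- sort(c(length(pg$power_nodes[[pg$power_edges[[1]]$u]]),
                  length(pg$power_nodes[[pg$power_edges[[1]]$v]])))
  expect_equal(sizes, c(1L, 2L))
})

test_that("compression is lossless and valid on a generated corpus", {
  for (g in fixture_corpus(20L)) {
    pg <- power_graph(g)
    expect_identical(nrow(validate_power_graph(pg)), 0L)
    expect_same_network(decompress(pg), g)
  }
})

test_that("abstracted edge sets partition the original edge set", {
  for (g in fixture_corpus(6L)) {
    pg <- power_graph(g)
    cov <- unlist(lapply(pg$power_edges, function(e) {
      u <- pg$power_nodes[[e$u]]; v <- pg$power_nodes[[e$v]]
      if (e$reflexive) {
        prs <- t(combn(sort(u), 2L))
      } else {
        prs <- as.matrix(expand.grid(u, v, stringsAsFactors = FALSE))
      }
      paste(pmin(prs[, 1], prs[, 2]), pmax(prs[, 1], prs[, 2]))
    }))
    expect_false(any(duplicated(cov)))
    expect_setequal(cov, sorted_edge_keys(g))
  }
})

test_that("validation flags constructed hierarchy and partition violations", {
  g <- make_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  # two power edges abstracting the same original edge
  pg_bad <- new_power_graph(
    g,
    power_nodes = list(P1 = "a", P2 = "b", P3 = "c", P4 = c("b", "c")),
    power_edges = list(list(u = "P1", v = "P4", reflexive = FALSE),
                       list(u = "P1", v = "P2", reflexive = FALSE),  # a-b twice
                       list(u = "P2", v = "P3", reflexive = FALSE))
  )
  v <- validate_power_graph(pg_bad)
  expect_true("partition" %in% v$condition)
  # overlapping, non-nested power nodes
  pg_bad2 <- new_power_graph(
    g,
    power_nodes = list(P1 = c("a", "b"), P2 = c("b", "c")),
    power_edges = list(list(u = "P1", v = "P1", reflexive = TRUE),
                       list(u = "P2", v = "P2", reflexive = TRUE))
  )
  expect_true("hierarchy" %in% validate_power_graph(pg_bad2)$condition)
  # abstracting a pair absent from the graph
  g2 <- make_network(rbind(c("a", "b"), c("a", "c")))
  pg_bad3 <- new_power_graph(
    g2,
    power_nodes = list(P1 = c("a", "b", "c")),
    power_edges = list(list(u = "P1", v = "P1", reflexive = TRUE))
  )
  expect_true("losslessness" %in% validate_power_graph(pg_bad3)$condition)
})

test_that("clique removal deletes exactly the reflexive power-edge content", {
  # triangle collapses to nothing
  expect_equal(igraph::ecount(remove_cliques(k_complete(3))), 0L)
  # bipartite graphs contain no cliques
  expect_equal(igraph::ecount(remove_cliques(k_bipartite(3, 4))), 12L)
  # two triangles joined by a bridge: only the bridge survives
  g <- make_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                          c("d", "e"), c("d", "f"), c("e", "f"), c("c", "d")))
  left <- remove_cliques(g)
  expect_identical(sorted_edge_keys(left), "c d")
  # removed edges always lie inside a reflexive power edge
  for (g in fixture_corpus(6L)) {
    pg <- power_graph(g)
    clique_edges <- unlist(lapply(pg$power_edges, function(e) {
      if (!e$reflexive) return(character())
      prs <- t(combn(sort(pg$power_nodes[[e$u]]), 2L))
      paste(prs[, 1], prs[, 2])
    }))
    removed <- setdiff(sorted_edge_keys(g), sorted_edge_keys(remove_cliques(g)))
    expect_true(all(removed %in% clique_edges))
  }
})

test_that("motif spectrum classifies power edges by endpoint sizes", {
  ms <- motif_spectrum(power_graph(k_complete(5)))
  expect_equal(ms, data.frame(a = 5L, b = 5L, class = "clique", count = 1L),
               ignore_attr = TRUE)
  ms <- motif_spectrum(power_graph(k_bipartite(3, 3)))
  expect_equal(ms$class, "biclique")
  expect_equal(c(ms$a, ms$b), c(3L, 3L))
  ms <- motif_spectrum(power_graph(star_network(4)))
  expect_equal(ms$class, "star")
  expect_equal(c(ms$a, ms$b), c(1L, 4L))
  # trivial leftover edges count as (1, 1, star)
  g <- make_network(rbind(c("a", "b")))
  ms <- motif_spectrum(power_graph(g))
  expect_equal(c(ms$a, ms$b, ms$class), c("1", "1", "star"))
})

test_that("the brute-force oracle returns minimal power graphs on small cases", {
  expect_length(optimal_power_graph(make_network(rbind(c("A", "B"))))$power_edges, 1L)
  expect_length(optimal_power_graph(path_network(c("A", "B", "C")))$power_edges, 1L)
  opt <- optimal_power_graph(k_complete(4))
  expect_length(opt$power_edges, 1L)
  expect_true(opt$power_edges[[1]]$reflexive)
  expect_error(optimal_power_graph(fixture_corpus(1L)[[1]]), "brute-force")
  # the oracle output is itself a valid power graph
  for (g in tiny_corpus()[1:8]) {
    expect_identical(nrow(validate_power_graph(optimal_power_graph(g))), 0L)
  }
})

test_that("greedy compression never beats, and often matches, the brute-force optimum", {
  for (g in tiny_corpus()) {
    if (igraph::ecount(g) > 8L || igraph::ecount(g) == 0L) next
    n_greedy <- length(power_graph(g)$power_edges)
    n_opt <- length(optimal_power_graph(g)$power_edges)
    expect_gte(n_greedy, n_opt)
  }
  # equality on single-motif graphs
  singles <- list(k_complete(3), k_complete(4), k_bipartite(2, 2),
                  k_bipartite(2, 3), star_network(4), star_network(7))
  for (g in singles) {
    expect_identical(length(power_graph(g)$power_edges),
                     length(optimal_power_graph(g)$power_edges))
  }
})

test_that("power graph text output is deterministic and self-describing", {
  f <- withr::local_tempfile(fileext = ".txt")
  pg <- power_graph(k_bipartite(2, 3))
  write_power_graph(pg, f)
  l1 <- readLines(f)
  write_power_graph(power_graph(k_bipartite(2, 3)), f)
  expect_identical(readLines(f), l1)
  expect_true(any(grepl("^PE ", l1)))
  expect_true(any(grepl("^PN ", l1)))
})
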