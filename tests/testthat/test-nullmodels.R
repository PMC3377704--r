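test_that("rewiring preserves nodes, edge count, and every degree", {
  for (g in fixture_corpus(6L)) {
    gr <- rewire_graph(g, rewire_config(seed = 42))
    expect_setequal(igraph::V(gr)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(gr), igraph::ecount(g))
    expect_equal(igraph::degree(gr)[igraph::V(g)$name], igraph::degree(g))
    expect_true(igraph::is_simple(gr))
  }
  expect_error(rewire_graph(make_network(rbind(c("a", "b")))), "at least 2")
})

test_that("forced topologies are invariant under rewiring", {
  # complete graph: every swap would duplicate an edge
  k4 <- k_complete(4)
  expect_identical(sorted_edge_keys(rewire_graph(k4, rewire_config(seed = 1))),
                   sorted_edge_keys(k4))
  # star: the degree sequence forces the shape and center
  st <- star_network(5)
  str <- rewire_graph(st, rewire_config(seed = 3))
  expect_equal(unname(igraph::degree(str)["hub"]), 5)
  expect_identical(sorted_edge_keys(str), sorted_edge_keys(st))
})

test_that("rewire ensembles are deterministic chains with preserved degrees", {
  g <- fixture_corpus(1L)[[1]]
  ens <- rewire_ensemble(g, 3L, rewire_config(seed = 11))
  expect_length(ens, 3L)
  for (e in ens) {
    expect_equal(igraph::degree(e)[igraph::V(g)$name], igraph::degree(g))
  }
  ens2 <- rewire_ensemble(g, 3L, rewire_config(seed = 11))
  for (k in 1:3) {
    expect_identical(sorted_edge_keys(ens[[k]]), sorted_edge_keys(ens2[[k]]))
  }
  # chained: consecutive members differ (with overwhelming probability)
  expect_false(identical(sorted_edge_keys(ens[[1]]), sorted_edge_keys(g)))
})

test_that("edge perturbation changes exactly k edges and nothing else", {
  g <- fixture_corpus(2L)[[2]]
  m <- igraph::ecount(g)
  for (model in c("ER", "BA")) {
    rm5 <- perturb(g, noise_spec(model, "remove_edges", 0.5, seed = 2))
    expect_equal(igraph::ecount(rm5), m - floor(0.5 * m + 0.5))
    expect_setequal(igraph::V(rm5)$name, igraph::V(g)$name)
    ad1 <- perturb(g, noise_spec(model, "add_edges", 0.1, seed = 2))
    expect_equal(igraph::ecount(ad1), m + floor(0.1 * m + 0.5))
    expect_true(all(sorted_edge_keys(g) %in% sorted_edge_keys(ad1)))
    expect_true(igraph::is_simple(ad1))
  }
  # determinism
  a <- perturb(g, noise_spec("ER", "add_edges", 0.2, seed = 9))
  b <- perturb(g, noise_spec("ER", "add_edges", 0.2, seed = 9))
  expect_identical(sorted_edge_keys(a), sorted_edge_keys(b))
  # too many additions
  expect_error(perturb(k_complete(4), noise_spec("ER", "add_edges", 1, seed = 1)),
               "not enough")
  # BA is undefined for node modes
  expect_error(noise_spec("BA", "remove_nodes", 0.1), "edge modes")
})

test_that("ER edge additions are uniform over absent pairs", {
  g <- make_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  # absent pairs: a-c and b-d
  counts <- c("a c" = 0, "b d" = 0)
  n_draws <- 2000L
  for (i in seq_len(n_draws)) {
    gp <- perturb(g, noise_spec("ER", "add_edges", 0.25, seed = i))  # k = 1
    new <- setdiff(sorted_edge_keys(gp), sorted_edge_keys(g))
    counts[new] <- counts[new] + 1L
  }
  expect_equal(sum(counts), n_draws)
  p <- stats::chisq.test(counts, p = c(0.5, 0.5))$p.value
  expect_gt(p, 0.01)
})

test_that("BA additions hit endpoints in proportion to degree", {
  # hub of degree 10 among degree-1 nodes; expected endpoint frequencies are
  # computed by exact enumeration of the weighted absent-pair distribution
  hub_edges <- cbind("hub", sprintf("l%02d", 1:10))
  chain_edges <- cbind(sprintf("z%02d", seq(1, 39, by = 2)),
                       sprintf("z%02d", seq(2, 40, by = 2)))
  g <- make_network(rbind(hub_edges, chain_edges))
  deg <- igraph::degree(g)
  nm <- igraph::V(g)$name
  pairs <- t(combn(nm, 2))
  existing <- sorted_edge_keys(g)
  keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  free <- !(keys %in% existing)
  w <- deg[pairs[, 1]] * deg[pairs[, 2]]
  w[!free] <- 0
  p_pair <- w / sum(w)
  p_hub_exact <- sum(p_pair[pairs[, 1] == "hub" | pairs[, 2] == "hub"])

  n_draws <- 4000L
  hub_hits <- 0L
  m <- igraph::ecount(g)
  for (i in seq_len(n_draws)) {
    gp <- perturb(g, noise_spec("BA", "add_edges", 1 / m, seed = 10000 + i))  # k = 1
    new <- setdiff(sorted_edge_keys(gp), existing)
    if (grepl("\\bhub\\b", new)) hub_hits <- hub_hits + 1L
  }
  p <- stats::chisq.test(c(hub_hits, n_draws - hub_hits),
                         p = c(p_hub_exact, 1 - p_hub_exact))$p.value
  expect_gt(p, 0.01)
  # and the hub is far more exposed than under uniform sampling
  expect_gt(hub_hits / n_draws, 2 * 40 / sum(free))
})

test_that("node removal and cloned addition behave as specified", {
  g <- fixture_corpus(3L)[[3]]
  n <- igraph::vcount(g)
  rm5 <- perturb(g, noise_spec("ER", "remove_nodes", 0.5, seed = 4))
  expect_equal(igraph::vcount(rm5), n - floor(0.5 * n + 0.5))
  # no dangling edges: all endpoints are retained nodes
  el <- igraph::as_edgelist(rm5)
  expect_true(all(el %in% igraph::V(rm5)$name))
  expect_error(perturb(g, noise_spec("ER", "remove_nodes", 1, seed = 1)), "empty")

  ad <- perturb(g, noise_spec("ER", "add_nodes", 0.1, seed = 4))
  k <- floor(0.1 * n + 0.5)
  expect_equal(igraph::vcount(ad), n + k)
  clone_map <- ad$clone_map
  expect_length(clone_map, k)
  for (newv in names(clone_map)) {
    expect_equal(unname(igraph::degree(ad)[newv]),
                 unname(igraph::degree(g)[clone_map[[newv]]]))
  }
})

test_that("fixed seeds fix every perturbation bit-for-bit", {
  g <- fixture_corpus(4L)[[4]]
  for (spec in list(noise_spec("ER", "remove_edges", 0.3, seed = 5),
                    noise_spec("BA", "add_edges", 0.3, seed = 5),
                    noise_spec("ER", "remove_nodes", 0.3, seed = 5),
                    noise_spec("ER", "add_nodes", 0.3, seed = 5))) {
    expect_identical(sorted_edge_keys(perturb(g, spec)),
                     sorted_edge_keys(perturb(g, spec)))
  }
})
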