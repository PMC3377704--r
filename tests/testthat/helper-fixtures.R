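# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

k_complete <- function(n, prefix = "n") {
  make_network(t(combn(sprintf("%s%02d", prefix, seq_len(n)), 2L)))
}

k_bipartite <- function(a, b) {
  make_network(as.matrix(expand.grid(sprintf("a%02d", seq_len(a)),
                                     sprintf("b%02d", seq_len(b)),
                                     stringsAsFactors = FALSE)))
}

star_network <- function(leaves) {
  make_network(cbind("hub", sprintf("l%02d", seq_len(leaves))))
}

path_network <- function(nodes) {
  make_network(cbind(nodes[-length(nodes)], nodes[-1L]))
}

# K4 minus the C-D edge: local clustering of A is 2/3, graph average 5/6.
k4_minus_edge <- function() {
  make_network(rbind(c("A", "B"), c("A", "C"), c("A", "D"),
                     c("B", "C"), c("B", "D")))
}

# A small deterministic corpus of planted-motif graphs spanning motif mixes
# and noise levels.
fixture_corpus <- function(n_graphs = 30L, seed0 = 100L) {
  specs <- list(
    function(s) plant_spec(20, cliques = c(5), noise_edges = 5, seed = s),
    function(s) plant_spec(25, bicliques = list(c(4, 4)), noise_edges = 8, seed = s),
    function(s) plant_spec(25, stars = c(6), noise_edges = 10, seed = s),
    function(s) plant_spec(35, cliques = c(5, 4), bicliques = list(c(3, 4)),
                           noise_edges = 12, seed = s),
    function(s) plant_spec(30, cliques = c(4), stars = c(5),
                           bicliques = list(c(3, 3)), noise_edges = 15, seed = s),
    function(s) plant_spec(20, noise_edges = 25, seed = s)
  )
  lapply(seq_len(n_graphs), function(i) {
    f <- specs[[(i - 1L) %% length(specs) + 1L]]
    generate_network(f(seed0 + i))$graph
  })
}

# Graphs with at most `max_edges` edges for the brute-force oracle.
tiny_corpus <- function(max_edges = 8L, n_random = 12L, seed0 = 500L) {
  fixed <- list(
    make_network(rbind(c("A", "B"))),
    path_network(c("A", "B", "C")),
    path_network(sprintf("p%d", 1:5)),
    make_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))),  # C4
    make_network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                       c("e", "a"))),                                          # C5
    k_complete(3), k_complete(4),
    k_bipartite(2, 2), k_bipartite(2, 3),
    star_network(4), star_network(7),
    make_network(rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d"),
                       c("d", "e"), c("d", "f"), c("e", "f")))  # two triangles + bridge
  )
  random <- lapply(seq_len(n_random), function(i) {
    g <- generate_network(plant_spec(8, noise_edges = sample_edges_n(i),
                                     seed = seed0 + i))$graph
    g
  })
  c(fixed, random)
}

sample_edges_n <- function(i) 3L + (i %% 6L)

expect_same_network <- function(g1, g2) {
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0L) return(character())
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(g1), key(g2))
}

sorted_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) return(character())
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}
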