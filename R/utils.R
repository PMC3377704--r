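# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up: round(0.5) in base R goes to even, which would make
# perturbation counts depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Canonical unordered-pair keys for character endpoints.
edge_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Reorder vertices of a named graph into sorted-name order so that all
# downstream tie-breaking is independent of input row order.
canonical_vertex_order <- function(g) {
  nm <- igraph::V(g)$name
  igraph::permute(g, match(nm, sort(nm)))
}

# TRUE when two sets (plain vectors) are disjoint or one contains the other.
nested_or_disjoint <- function(a, b) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}

stop_netcompress <- function(...) stop(..., call. = FALSE)
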