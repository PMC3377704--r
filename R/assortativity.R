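#' Node annotations for assortativity analysis
#'
#' Two kinds of evidence are supported. *Label categories* map a node to a
#' set of labels (cellular compartments, functional terms, module ids); two
#' interacting proteins "share" the property when their label sets intersect.
#' *Pair-score categories* assign a real-valued score to node pairs
#' (co-expression or phylogenetic-profile log-likelihoods) with a declared
#' threshold; a pair shares the property when its score reaches the
#' threshold. Nodes (or pairs) absent from a category are treated as having
#' missing information.
#'
#' @param categories named list; each element is a named list mapping a node
#'   identifier to a character vector of labels.
#' @param pair_scores named list; each element is a
#'   `list(scores = data.frame(a, b, score), threshold = <numeric>)`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(categories = list(), pair_scores = list()) {
  stopifnot(is.list(categories), is.list(pair_scores))
  for (nmc in names(pair_scores)) {
    ps <- pair_scores[[nmc]]
    if (!is.list(ps) || is.null(ps$scores) || is.null(ps$threshold)) {
      stop_netcompress("pair-score category '", nmc,
                       "' must be list(scores = <data.frame>, threshold = <numeric>)")
    }
  }
  structure(list(categories = categories, pair_scores = pair_scores),
            class = "annotation_set")
}

#' Read a node annotation table
#'
#' Format: `node TAB category TAB label`, one label per row; `#` comments
#' allowed.
#'
#' @param path file path.
#' @return an [annotation_set()] with one label category per distinct
#'   category value.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_netcompress("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 3L)) stop_netcompress("annotation rows must have 3 fields")
  df <- data.frame(node = vapply(parts, `[`, "", 1L),
                   category = vapply(parts, `[`, "", 2L),
                   label = vapply(parts, `[`, "", 3L),
                   stringsAsFactors = FALSE)
  cats <- lapply(split(df, df$category), function(d) {
    lapply(split(d$label, d$node), unique)
  })
  annotation_set(categories = cats)
}

#' Read a node-pair score table
#'
#' Format: `node_a TAB node_b TAB score`.
#'
#' @param path file path.
#' @param threshold score at or above which a pair is called shared.
#' @return a pair-score category suitable for [annotation_set()].
#' @export
read_pair_scores <- function(path, threshold) {
  if (!file.exists(path)) stop_netcompress("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 3L)) stop_netcompress("pair-score rows must have 3 fields")
  sc <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(sc)) stop_netcompress("non-numeric pair score")
  list(scores = data.frame(a = vapply(parts, `[`, "", 1L),
                           b = vapply(parts, `[`, "", 2L),
                           score = sc, stringsAsFactors = FALSE),
       threshold = threshold)
}

#' Assortativity ratio of a network for one annotation category
#'
#' Fraction of interacting pairs sharing the annotated property among the
#' interacting pairs with complete information about both partners. For a
#' label category, complete information means both endpoints are annotated
#' and sharing means at least one common label; for a pair-score category it
#' means the pair is scored, and sharing means `score >= threshold`
#' (inclusive). Each unordered interacting pair counts once. Pairs with
#' missing information are excluded from numerator and denominator.
#'
#' @param g network.
#' @param ann an [annotation_set()].
#' @param category category name.
#' @return a number in `[0, 1]`.
#' @export
assortativity_ratio <- function(g, ann, category) {
  stopifnot(inherits(ann, "annotation_set"))
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) stop_netcompress("the network has no edges")
  if (category %in% names(ann$categories)) {
    cat_map <- ann$categories[[category]]
    known <- names(cat_map)
    ok <- el[, 1L] %in% known & el[, 2L] %in% known
    if (!any(ok)) stop_netcompress("no interacting pair is fully annotated")
    share <- vapply(which(ok), function(r) {
      length(intersect(cat_map[[el[r, 1L]]], cat_map[[el[r, 2L]]])) > 0L
    }, logical(1))
    return(sum(share) / sum(ok))
  }
  if (category %in% names(ann$pair_scores)) {
    ps <- ann$pair_scores[[category]]
    key <- edge_keys(ps$scores$a, ps$scores$b)
    sc <- ps$scores$score[!duplicated(key, fromLast = TRUE)]
    key <- key[!duplicated(key, fromLast = TRUE)]
    ek <- edge_keys(el[, 1L], el[, 2L])
    hit <- match(ek, key)
    ok <- !is.na(hit)
    if (!any(ok)) stop_netcompress("no interacting pair has a score")
    return(sum(sc[hit[ok]] >= ps$threshold) / sum(ok))
  }
  stop_netcompress("unknown annotation category: ", category)
}

#' Relative assortativity against the rewired null ensemble
#'
#' Normalizes the assortativity ratio the same way as the relative
#' compression rate: the annotation is held fixed on the nodes while the
#' network is rewired `n_random` times preserving all degrees, and the mean
#' ensemble ratio is subtracted. Label assignments independent of the
#' topology score about zero; annotations aligned with the wiring score
#' positive.
#'
#' @inheritParams assortativity_ratio
#' @param n_random ensemble size.
#' @param config a [rewire_config()].
#' @return an object of class `relative_assortativity` with fields `value`
#'   (ratio minus ensemble mean), `ratio`, `ensemble_mean`, `ensemble_sd`,
#'   `n_random`.
#' @export
relative_assortativity <- function(g, ann, category, n_random = 100L,
                                   config = rewire_config()) {
  ratio <- assortativity_ratio(g, ann, category)
  ens <- rewire_ensemble(g, n_random, config)
  ratios <- vapply(ens, assortativity_ratio, numeric(1), ann = ann,
                   category = category)
  structure(list(value = ratio - mean(ratios), ratio = ratio,
                 ensemble_mean = mean(ratios), ensemble_sd = stats::sd(ratios),
                 n_random = as.integer(n_random), seed = config$seed),
            class = "relative_assortativity")
}

#' @export
print.relative_assortativity <- function(x, ...) {
  cat(sprintf(
    "assortativity ratio %.4f | random ensemble %.4f +/- %.4f (n = %d) | relative %.4f\n",
    x$ratio, x$ensemble_mean, x$ensemble_sd, x$n_random, x$value))
  invisible(x)
}

#' Kendall rank correlation
#'
#' Convenience wrapper used when relating relative compressibility to other
#' per-network statistics: Kendall's tau (tau-b under ties) with a two-sided
#' p-value, delegated to [stats::cor.test()].
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return `list(tau, p)`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_netcompress("`x` and `y` must have equal length")
  if (length(x) < 3L) stop_netcompress("need at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}
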