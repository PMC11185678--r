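#' Detectable-IBD graph at a locus
#'
#' Nodes are haplotypes; an edge joins two haplotypes that share a detectable
#' IBD segment at the focal point. Duplicate records collapse to one edge.
#'
#' @param segments a pairwise segment table ([detectable_segments()] with
#'   `m = 2`), or a 2-column matrix of node pairs.
#' @param n_nodes number of haplotypes.
#' @return an object of class `locus_graph`: list with `n_nodes` and `edges`
#'   (2-column integer matrix, `i < j`, unique rows).
#' @export
build_graph <- function(segments, n_nodes) {
  if (is.data.frame(segments)) {
    if (!all(c("id1", "id2") %in% names(segments)))
      stop("pairwise (m = 2) segment records are required")
    if (any(grepl("^id3$", names(segments))))
      stop("pairwise (m = 2) segment records are required")
    e <- cbind(segments$id1, segments$id2)
  } else {
    e <- as.matrix(segments)
    if (ncol(e) != 2) stop("edge input must have two columns")
  }
  storage.mode(e) <- "integer"
  if (nrow(e)) {
    if (any(e < 1L | e > n_nodes)) stop("node ids must lie in [1, n_nodes]")
    if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = e),
            class = "locus_graph")
}

#' @export
print.locus_graph <- function(x, ...) {
  cat("<locus_graph> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

#' Connected-component features of a locus graph
#'
#' Union-find extraction of the five summary features: edge count, number of
#' trees of order 2 (2 nodes, 1 edge) and order 3 (3 nodes, 2 edges), number
#' of complete components of order >= 3 (cliques), and the node count of the
#' largest component.
#'
#' @param g a `locus_graph`.
#' @return named numeric vector `edges`, `tree2`, `tree3`, `complete3plus`,
#'   `largest`.
#' @export
#' @examples
#' g <- build_graph(rbind(c(1, 2), c(3, 4), c(5, 6), c(5, 7), c(6, 7)), 7)
#' graph_features(g)
graph_features <- function(g) {
  stopifnot(inherits(g, "locus_graph"))
  f <- cpp_graph_features(g$n_nodes, g$edges[, 1] - 1L, g$edges[, 2] - 1L)
  names(f) <- c("edges", "tree2", "tree3", "complete3plus", "largest")
  f
}

#' Edge probability matched to detectable IBD sharing
#'
#' The uniform success probability for the comparison Erdos-Renyi graph is
#' the probability that a random haplotype pair shares a detectable segment
#' overlapping the focal point. The default `"discrete"` model sums the
#' geometric coalescent-time distribution against the Gamma(2, 2t) width
#' survival, `sum_{t>=1} (1/N)(1-1/N)^(t-1) (1+2wt) e^(-2wt)` (evaluated in
#' closed form as a geometric series); `"continuous"` uses the Exponential
#' limit, `(4Nw+1)/(2Nw+1)^2`.
#'
#' @param n_h haploid population size (> 1).
#' @param w Morgans threshold (> 0).
#' @param model `"discrete"` (default) or `"continuous"`.
#' @return an edge probability.
#' @export
#' @examples
#' er_probability(2e5, 0.03)                  # ~1.641e-4
#' er_probability(2e5, 0.03, "continuous")    # ~1.666e-4
er_probability <- function(n_h, w, model = c("discrete", "continuous")) {
  model <- match.arg(model)
  if (!is.numeric(n_h) || n_h <= 1) stop("`n_h` must exceed 1")
  if (!is.numeric(w) || w <= 0) stop("`w` must be positive")
  if (model == "continuous") return(e2_overlap(n_h * w))
  r <- (1 - 1 / n_h) * exp(-2 * w)
  (1 / (n_h - 1)) * (r / (1 - r) + 2 * w * r / (1 - r)^2)
}

#' Simulate a sparse Erdos-Renyi graph
#'
#' Draws the edge count from Binomial(choose(n, 2), p), then samples that
#' many distinct unordered pairs uniformly — efficient when `p` is small.
#'
#' @param n_nodes number of nodes.
#' @param p edge probability in `[0, 1]`.
#' @return a `locus_graph`.
#' @export
simulate_er <- function(n_nodes, p) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (p == 1) {
    e <- t(utils::combn(n_nodes, 2))
    return(build_graph(e, n_nodes))
  }
  sim <- cpp_simulate_er(as.integer(n_nodes), p)
  e <- cbind(sim$i + 1L, sim$j + 1L)
  structure(list(n_nodes = as.integer(n_nodes), edges = e),
            class = "locus_graph")
}

#' Expected number of isolated trees of order k in G(n, p)
#'
#' Standard closed form used as the simulation oracle:
#' `choose(n, k) k^(k-2) p^(k-1) (1-p)^(k(n-k) + choose(k,2) - (k-1))`.
#'
#' @param n_nodes number of nodes.
#' @param p edge probability.
#' @param k tree order (>= 2).
#' @return an expected count.
#' @export
expected_er_tree_count <- function(n_nodes, p, k) {
  if (k < 2) stop("`k` must be >= 2")
  choose(n_nodes, k) * k^(k - 2) * p^(k - 1) *
    (1 - p)^(k * (n_nodes - k) + choose(k, 2) - (k - 1))
}

#' Write a graph as an edge-list TSV
#'
#' @param g a `locus_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(g, path) {
  write.table(data.frame(i = g$edges[, 1], j = g$edges[, 2]), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
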