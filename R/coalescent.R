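#' Simulate a single-locus coalescent genealogy
#'
#' Simulates the binary genealogy of `n_hap` haplotypes at one locus under a
#' piecewise-constant demography. In continuous time this is the Kingman
#' coalescent: while k lineages remain the waiting time has hazard
#' C(k,2)/N_h(t) per generation, inverted exactly across epochs. In discrete
#' time the wait to the next (single) merger is geometric with per-generation
#' success probability min(1, C(k,2)/N_h(t)) and a uniformly chosen pair
#' merges; simultaneous multi-mergers are ignored, which leaves pairwise
#' marginals exact.
#'
#' Node times are stored in generations; leaves are nodes `1..n_hap` at time
#' 0 and internal nodes `n_hap+1 .. 2*n_hap-1` follow in merger order, the
#' last being the root. Randomness comes from R's global stream; seed with
#' [set.seed()] (see [substream_seed()] for replicate streams).
#'
#' @param n_hap number of sampled haplotypes (>= 2).
#' @param demography a [demography] object.
#' @param time_model `"continuous"` (Kingman) or `"discrete"` (geometric
#'   waits on integer generations).
#' @return an object of class `coalescent_tree`: list with `n_leaves`,
#'   `parent` (integer vector of length `2*n_hap - 1`, `NA` at the root) and
#'   `time` (generations).
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(4, constant_demography(1000))
#' tr$time[tr$n_leaves + 1:3]   # merger times in generations
simulate_tree <- function(n_hap, demography,
                          time_model = c("continuous", "discrete")) {
  time_model <- match.arg(time_model)
  if (!is.numeric(n_hap) || length(n_hap) != 1 || n_hap < 2 ||
      n_hap != floor(n_hap))
    stop("`n_hap` must be a single integer >= 2")
  if (!inherits(demography, "demography"))
    stop("`demography` must be a demography object (possibly empty input?)")
  if (n_hap > min(demography$size))
    warning("sample size exceeds the smallest population size; ",
            "the coalescent approximation is poor in that regime")
  sim <- cpp_simulate_tree(as.integer(n_hap), demography$start_gen,
                           demography$size, time_model == "discrete")
  parent <- sim$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(n_leaves = as.integer(n_hap), parent = parent,
                 time = sim$time),
            class = "coalescent_tree")
}

#' @export
print.coalescent_tree <- function(x, ...) {
  cat("<coalescent_tree> ", x$n_leaves, " leaves, root at ",
      format(max(x$time), digits = 6), " generations\n", sep = "")
  invisible(x)
}

#' Validate a coalescent tree
#'
#' Checks the structural invariants: one root, binary internal nodes, parent
#' times never below child times. Ties (zero-length branches) are accepted;
#' the continuous-time simulator never produces them but annotated trees must
#' be able to represent them.
#'
#' @param tree a `coalescent_tree`.
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "coalescent_tree"))
  n <- tree$n_leaves
  total <- 2L * n - 1L
  if (length(tree$parent) != total || length(tree$time) != total)
    stop("parent/time must have length 2*n_leaves - 1")
  if (sum(is.na(tree$parent)) != 1L) stop("exactly one root is required")
  kids <- tabulate(tree$parent[!is.na(tree$parent)], nbins = total)
  if (any(kids[seq_len(n)] != 0)) stop("leaves cannot have children")
  if (any(kids[(n + 1L):total] != 2L))
    stop("internal nodes must have exactly two children")
  ok <- is.na(tree$parent) | tree$time[tree$parent] >= tree$time
  if (!all(ok)) stop("parent times must not precede child times")
  invisible(tree)
}

#' Most recent common ancestor of a set of leaves
#'
#' @param tree a `coalescent_tree`.
#' @param leaves leaf ids (a singleton set returns the leaf itself).
#' @return the node id of the MRCA.
#' @export
mrca <- function(tree, leaves) {
  stopifnot(inherits(tree, "coalescent_tree"))
  leaves <- unique(as.integer(leaves))
  if (any(leaves < 1L | leaves > tree$n_leaves))
    stop("unknown leaf id")
  if (length(leaves) == 1L) return(leaves)
  cnt <- integer(length(tree$parent))
  for (v in leaves) {
    while (!is.na(v)) {
      cnt[v] <- cnt[v] + 1L
      v <- tree$parent[v]
    }
  }
  full <- which(cnt == length(leaves))
  full[which.min(tree$time[full])]
}

#' Convert to an ape phylo object / export Newick
#'
#' Debugging aids: `as_phylo()` renumbers nodes to ape's convention and
#' `write_tree_newick()` writes a Newick string with branch lengths in
#' generations via `ape::write.tree`.
#'
#' @param tree a `coalescent_tree`.
#' @return `as_phylo()` returns an `ape::phylo`; `write_tree_newick()`
#'   returns `path` invisibly.
#' @export
as_phylo <- function(tree) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for phylo conversion")
  validate_tree(tree)
  n <- tree$n_leaves
  total <- 2L * n - 1L
  # ape: tips 1..n, root n+1; map our internal id x -> n + 1 + (total - x)
  remap <- function(x) ifelse(x <= n, x, n + 1L + (total - x))
  child <- which(!is.na(tree$parent))
  edge <- cbind(remap(tree$parent[child]), remap(child))
  len <- tree$time[tree$parent[child]] - tree$time[child]
  phy <- structure(list(edge = edge, edge.length = len,
                        tip.label = paste0("h", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  phy
}

#' @rdname as_phylo
#' @param path output file path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}
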