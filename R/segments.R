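#' Annotate a genealogy with nearest-crossover distances
#'
#' Crossovers along the genome form a Poisson process per meiosis, so from a
#' focal point the Morgans distance to the nearest crossover accumulated over
#' a branch of length `l` generations is Exponential with rate `l` on each
#' side, independently. Zero-length branches receive `+Inf` (no constraint).
#'
#' @param tree a `coalescent_tree`.
#' @return a `crossover_annotation`: numeric matrix with one row per node and
#'   columns `d_left`, `d_right` (Morgans; `NA` for the root).
#' @export
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(3, constant_demography(500))
#' ann <- annotate_crossovers(tr)
annotate_crossovers <- function(tree) {
  validate_tree(tree)
  parent0 <- tree$parent - 1L
  parent0[is.na(parent0)] <- -1L
  d <- cpp_annotate(parent0, tree$time)
  colnames(d) <- c("d_left", "d_right")
  structure(d, class = c("crossover_annotation", class(d)))
}

#' Shared segment extents for a tuple of haplotypes
#'
#' The segment shared identically by all members survives to the right of the
#' focal point up to the nearest crossover on any branch of the spanning
#' subtree (all paths from the members up to their MRCA); the left side is
#' analogous. Conditional on a pair's MRCA at `t` generations, each side is
#' Exponential(2t); in general `P(R >= w | tree) = exp(-w G)` with `G` the
#' spanning subtree's total branch length in generations.
#'
#' @param tree a `coalescent_tree`.
#' @param ann a `crossover_annotation` for `tree`.
#' @param members two or more distinct leaf ids.
#' @return `c(L =, R =)` extents in Morgans.
#' @export
tuple_extents <- function(tree, ann, members) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stop("`members` must be distinct leaves")
  if (length(members) < 2L) stop("`members` must have length >= 2")
  if (any(members < 1L | members > tree$n_leaves)) stop("unknown leaf id")
  m <- length(members)
  cnt <- integer(length(tree$parent))
  for (v in members) {
    while (!is.na(v)) {
      cnt[v] <- cnt[v] + 1L
      v <- tree$parent[v]
    }
  }
  inside <- cnt >= 1L & cnt < m
  c(L = min(ann[inside, "d_left"]), R = min(ann[inside, "d_right"]))
}

#' Enumerate detectable IBD segments
#'
#' Returns the m-tuples of haplotypes whose shared segment meets the
#' detection criterion: right-extent `R >= w` (`mode = "right"`, the form the
#' distribution theory is stated for) or total width `L + R >= w`
#' (`mode = "overlap"`, the form used in the simulation studies).
#'
#' The default method processes the tree bottom-up, carrying per-node
#' candidate lists pruned by the detection criterion; extents only shrink
#' toward the root so the pruning is exact, and each tuple is emitted once at
#' its MRCA. `method = "brute"` scans all `choose(n, m)` tuples via
#' [tuple_extents()] and is the reference implementation.
#'
#' @param tree a `coalescent_tree`.
#' @param ann a `crossover_annotation`.
#' @param w detection threshold in Morgans (> 0).
#' @param mode `"right"` or `"overlap"`.
#' @param m tuple order (>= 2; keep m much smaller than n).
#' @param method `"pruned"` (fast path) or `"brute"` (reference scan).
#' @return a data frame with columns `id1..idm` (leaf ids, ascending within
#'   each child-block ordering), `L`, `R`, `W = L + R`.
#' @export
detectable_segments <- function(tree, ann, w, mode = c("right", "overlap"),
                                m = 2L, method = c("pruned", "brute")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!is.numeric(w) || length(w) != 1 || w <= 0)
    stop("`w` must be a positive Morgans threshold")
  if (m < 2L) stop("`m` must be >= 2")
  if (method == "brute") {
    combos <- utils::combn(tree$n_leaves, m)
    rec <- apply(combos, 2, function(mem) tuple_extents(tree, ann, mem))
    keepv <- if (mode == "right") rec["R", ] >= w
             else rec["L", ] + rec["R", ] >= w
    mem <- t(combos[, keepv, drop = FALSE])
    L <- rec["L", keepv]
    R <- rec["R", keepv]
  } else {
    parent0 <- tree$parent - 1L
    parent0[is.na(parent0)] <- -1L
    det <- cpp_detect(parent0, tree$time, ann[, "d_left"], ann[, "d_right"],
                      w, if (mode == "right") 0L else 1L, as.integer(m))
    mem <- det$members + 1L
    L <- det$L
    R <- det$R
  }
  out <- as.data.frame(matrix(as.integer(mem), ncol = m,
                              dimnames = list(NULL, paste0("id", seq_len(m)))))
  out$L <- as.numeric(L)
  out$R <- as.numeric(R)
  out$W <- out$L + out$R
  # canonical order: sorted members, then lexicographic rows
  if (nrow(out)) {
    ids <- t(apply(out[, seq_len(m), drop = FALSE], 1, sort))
    out[, seq_len(m)] <- ids
    out <- out[do.call(order, as.list(out[, seq_len(m), drop = FALSE])), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write segments as TSV
#'
#' Long-format segment table: members comma-joined, extents in Morgans, plus
#' an optional replicate id column.
#'
#' @param segments output of [detectable_segments()].
#' @param path output path.
#' @param replicate optional replicate id recycled across rows.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path, replicate = NULL) {
  idcols <- grep("^id", names(segments))
  members <- if (nrow(segments))
    apply(segments[, idcols, drop = FALSE], 1, paste, collapse = ",")
  else character(0)
  out <- data.frame(
    members = members,
    L = segments$L, R = segments$R, W = segments$W,
    indicator = rep(1L, nrow(segments)))
  if (!is.null(replicate)) out <- cbind(replicate = replicate, out)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
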