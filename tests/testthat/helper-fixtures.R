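# Fixtures and independent oracles, built in code.

# construct a coalescent_tree directly (bypasses the simulator)
make_tree <- function(parent, time, n_leaves) {
  structure(list(n_leaves = as.integer(n_leaves),
                 parent = as.integer(parent), time = as.numeric(time)),
            class = "coalescent_tree")
}

# balanced 4-leaf tree ((1,2)5,(3,4)6)7 with merger times t5 <= t6 <= t7
balanced4 <- function(t5 = 10, t6 = 20, t7 = 30) {
  make_tree(parent = c(5, 5, 6, 6, 7, 7, NA),
            time = c(0, 0, 0, 0, t5, t6, t7), n_leaves = 4)
}

# a crossover_annotation with hand-set distances (rows follow node ids)
make_ann <- function(d_left, d_right) {
  d <- cbind(d_left = d_left, d_right = d_right)
  structure(d, class = c("crossover_annotation", class(d)))
}

# Independent brute-force segment oracle: explicit ancestor chains, explicit
# spanning-subtree branch union. Never calls the package's detection code.
brute_segments <- function(tree, ann, w, mode, m = 2) {
  combos <- utils::combn(tree$n_leaves, m)
  rows <- list()
  for (j in seq_len(ncol(combos))) {
    mem <- combos[, j]
    anc <- lapply(mem, function(x) {
      path <- integer()
      v <- x
      while (!is.na(v)) {
        path <- c(path, v)
        v <- tree$parent[v]
      }
      path
    })
    common <- Reduce(intersect, anc)
    mr <- common[which.min(tree$time[common])]
    branches <- unique(unlist(lapply(anc, function(p) {
      p[seq_len(which(p == mr) - 1)]
    })))
    L <- min(ann[branches, "d_left"])
    R <- min(ann[branches, "d_right"])
    if (if (mode == "right") R >= w else L + R >= w)
      rows[[length(rows) + 1]] <- c(sort(mem), L, R)
  }
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), ncol = m + 3))
  } else {
    out <- as.data.frame(do.call(rbind, rows))
    out[, m + 3] <- out[, m + 1] + out[, m + 2]
    out <- out[do.call(order, as.list(out[, seq_len(m), drop = FALSE])), ]
  }
  names(out) <- c(paste0("id", seq_len(m)), "L", "R", "W")
  rownames(out) <- NULL
  for (k in seq_len(m)) out[[k]] <- as.integer(out[[k]])
  out
}

# igraph reference for component features
igraph_features <- function(g) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges[, 1], to = g$edges[, 2]),
    directed = FALSE, vertices = data.frame(name = seq_len(g$n_nodes)))
  comp <- igraph::components(ig)
  memb <- comp$membership
  edge_comp <- memb[as.character(g$edges[, 1])]
  ne <- tabulate(edge_comp, nbins = comp$no)
  nn <- comp$csize
  c(edges = nrow(g$edges),
    tree2 = sum(nn == 2 & ne == 1),
    tree3 = sum(nn == 3 & ne == 2),
    complete3plus = sum(nn >= 3 & ne == nn * (nn - 1) / 2),
    largest = max(nn))
}

# Monte-Carlo indicators for fixed leaf tuples on fresh small trees
tuple_mc <- function(n_leaves, dem, w, mode, tuples, reps, seed) {
  set.seed(seed)
  ibdclt:::cpp_tuple_mc(n_leaves, dem$start_gen, dem$size, w,
                        if (mode == "right") 0L else 1L,
                        lapply(tuples, function(t) as.integer(t - 1L)),
                        as.integer(reps), FALSE)$indicators
}

mc_se <- function(x) stats::sd(x) / sqrt(length(x))
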