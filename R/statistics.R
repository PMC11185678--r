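#' Standardize a detectable-segment count
#'
#' The sum of variances of the `choose(n, m)` identically distributed
#' detection indicators is `Omega = choose(n, m) p (1 - p)`; the standardized
#' statistic is the mean-centered count scaled by `Omega^{-1/2}`,
#' `z = (count - choose(n, m) p) / sqrt(Omega)`, which has unit variance
#' under independence and is the quantity the central limit theorem drives to
#' standard normal. (Scaling the *mean* rather than the sum by `Omega^{-1/2}`
#' degenerates to zero; the sum form is used throughout.)
#'
#' @param count observed number of detectable m-tuples.
#' @param n_hap haploid sample size.
#' @param m tuple order.
#' @param p theoretical tuple detection probability in (0, 1).
#' @return an object of class `rate_statistics` with fields `n_hap`, `m`,
#'   `count`, `rate`, `p`, `omega`, `z`.
#' @export
#' @examples
#' standardize(10, n_hap = 100, m = 2, p = 0.002)
standardize <- function(count, n_hap, m, p) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  C <- choose(n_hap, m)
  if (count < 0 || count > C) stop("`count` must lie in [0, choose(n, m)]")
  omega <- C * p * (1 - p)
  structure(list(n_hap = n_hap, m = m, count = count, rate = count / C,
                 p = p, omega = omega,
                 z = (count - C * p) / sqrt(omega)),
            class = "rate_statistics")
}

#' @export
print.rate_statistics <- function(x, ...) {
  cat(sprintf(
    "<rate_statistics> n=%d m=%d count=%g rate=%.4g p=%.4g omega=%.4g z=%.4f\n",
    x$n_hap, x$m, x$count, x$rate, x$p, x$omega, x$z))
  invisible(x)
}

#' CLT condition diagnostics
#'
#' Finite-sample evaluation of the conditions under which the standardized
#' detectable IBD rate is approximately normal: the total 3-share covariance
#' (about `n^3 * cov3`) and 4-share covariance (about `n^4 * cov4 / 4`) must
#' be small relative to `Omega`, and the size ratios `Nw / n^2` (enough
#' detectable segments) and `n / (Nw)` (no large clusters) must be small.
#' Under varying population size the covariances are evaluated at the
#' smallest size `N2` (their upper bound) and the first size ratio at the
#' largest size `N1`, mirroring the sandwich bounds.
#'
#' @param n_hap haploid sample size.
#' @param demography a [demography] object.
#' @param w Morgans threshold.
#' @return a list with `omega`, `cov3_total`, `cov4_total`, ratios, the size
#'   ratios, and booleans for the two size conditions.
#' @export
clt_condition_report <- function(n_hap, demography, w) {
  stopifnot(inherits(demography, "demography"))
  rng <- pop_size_range(demography)
  p <- e2_right_demography(demography, w)
  n <- n_hap
  omega <- choose(n, 2) * p * (1 - p)
  cov3_total <- n^3 * cov3_right(rng[["n2"]] * w)
  cov4_total <- n^4 * cov4_right(rng[["n2"]] * w) / 4
  ratio_nw_n2 <- rng[["n1"]] * w / n^2
  ratio_n_nw <- n / (rng[["n2"]] * w)
  list(n_hap = n, w = w, p = p, omega = omega,
       cov3_total = cov3_total, cov4_total = cov4_total,
       cov3_ratio = cov3_total / omega, cov4_ratio = cov4_total / omega,
       ratio_nw_n2 = ratio_nw_n2, ratio_n_nw = ratio_n_nw,
       cond_many_segments = ratio_nw_n2 < 1,
       cond_small_clusters = ratio_n_nw < 1)
}

#' Monte-Carlo check of the conditional-covariance condition
#'
#' The third CLT condition requires
#' `E[Z_ab * Zbar_-ab | Zbar_-ab] >= 0` for every value of the leave-one-out
#' centered sum. Given per-replicate samples of the designated pair's
#' centered indicator and the remainder sum, replicates are binned by the
#' remainder sum and the product is averaged within bins; no bin should be
#' significantly negative.
#'
#' @param z_pair centered indicator of the designated pair, per replicate.
#' @param z_rest centered remainder sum, per replicate.
#' @param n_bins number of quantile bins.
#' @param min_per_bin bins smaller than this are merged with a neighbor
#'   (reported via a message).
#' @return data frame with per-bin `center`, `n`, `estimate`, `se`.
#' @export
condition3_check <- function(z_pair, z_rest, n_bins = 10, min_per_bin = 30) {
  if (length(z_pair) != length(z_rest)) stop("inputs must have equal length")
  if (length(z_pair) < 1000) stop("at least 1000 replicates are required")
  br <- unique(quantile(z_rest, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(z_rest, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- tabulate(bin, nbins = max(bin))
  while (any(tab < min_per_bin) && length(tab) > 1) {
    i <- which(tab < min_per_bin)[1]
    j <- if (i == 1) 2L else i - 1L
    message("merging bin ", i, " (n=", tab[i], ") into neighbor ", j)
    bin[bin == i] <- j
    bin <- match(bin, sort(unique(bin)))
    tab <- tabulate(bin, nbins = max(bin))
  }
  prod <- z_pair * z_rest
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- prod[bin == b]
    data.frame(center = mean(z_rest[bin == b]), n = length(v),
               estimate = mean(v), se = sd(v) / sqrt(length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Multivariate rates over disjoint subsamples
#'
#' Splits the leaves into disjoint, equally sized subsets, computes each
#' subset's standardized detectable rate using only within-subset pairs, and
#' returns every pairwise difference of standardized rates (asymptotically
#' normal with variance 2 when the subsets decorrelate).
#'
#' @param tree a `coalescent_tree`.
#' @param ann a `crossover_annotation`.
#' @param subsets list of disjoint, equal-length leaf-id vectors.
#' @param w Morgans threshold.
#' @param mode `"right"` or `"overlap"`.
#' @param p theoretical pair detection probability used to standardize (for
#'   constant size N_h use `e2_right(N_h w)` / `e2_overlap(N_h w)`).
#' @return list with `rates` (list of `rate_statistics`) and `differences`
#'   (data frame of subset pairs and `diff = z_i - z_j`).
#' @export
multi_sample_rates <- function(tree, ann, subsets, w,
                               mode = c("right", "overlap"), p) {
  mode <- match.arg(mode)
  ids <- unlist(subsets)
  if (anyDuplicated(ids)) stop("subsets must be disjoint")
  sizes <- lengths(subsets)
  if (length(unique(sizes)) != 1) stop("subsets must be equally sized")
  seg <- detectable_segments(tree, ann, w, mode = mode, m = 2L)
  memb <- rep(NA_integer_, tree$n_leaves)
  for (l in seq_along(subsets)) memb[subsets[[l]]] <- l
  g1 <- memb[seg$id1]
  g2 <- memb[seg$id2]
  rates <- lapply(seq_along(subsets), function(l) {
    cnt <- sum(!is.na(g1) & !is.na(g2) & g1 == l & g2 == l)
    standardize(cnt, n_hap = sizes[1], m = 2L, p = p)
  })
  pairs <- utils::combn(length(subsets), 2)
  differences <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    diff = vapply(seq_len(ncol(pairs)), function(k) {
      rates[[pairs[1, k]]]$z - rates[[pairs[2, k]]]$z
    }, numeric(1)))
  list(rates = rates, differences = differences)
}
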