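#' Closed-form moments of detectable IBD indicators
#'
#' All moments are functions of the dimensionless scaled population size
#' `Nw` (haploid size times the Morgans threshold). For a pair, the
#' right-extent given the coalescent time `T2 ~ Exp(1)` (units of N
#' generations) is Exponential(2 N w T2), giving
#' `E2 = P(R >= w) = 1/(2Nw + 1)`. The overlapping width is Gamma(2, 2t),
#' giving `P(W >= w) = (4Nw + 1)/(2Nw + 1)^2`. For an m-way segment the first
#' crossover on the spanning subtree must fall beyond `w` while stage k holds
#' k branches for `T_k ~ Exp(C(k,2))`, giving the product form of
#' [em_right()]; note this forces `E_m <= E_{m-1}`, which rules out any
#' candidate expression with an extra multiplicative constant.
#'
#' @param scaled_size `Nw >= 0` (vectorized).
#' @return a probability (vector).
#' @export
#' @examples
#' e2_right(6000)              # ~ 8.33e-5 at N_h = 2e5, w = 0.03
#' e2_overlap(6000)
#' em_right(3, 1)              # 1/6
e2_right <- function(scaled_size) {
  if (any(scaled_size < 0)) stop("`scaled_size` must be nonnegative")
  1 / (2 * scaled_size + 1)
}

#' @rdname e2_right
#' @export
e2_overlap <- function(scaled_size) {
  if (any(scaled_size < 0)) stop("`scaled_size` must be nonnegative")
  (4 * scaled_size + 1) / (2 * scaled_size + 1)^2
}

#' @rdname e2_right
#' @param m tuple order (integer >= 2).
#' @export
em_right <- function(m, scaled_size) {
  if (length(m) != 1 || m < 2 || m != floor(m)) stop("`m` must be >= 2")
  if (any(scaled_size < 0)) stop("`scaled_size` must be nonnegative")
  out <- rep(1, length(scaled_size))
  for (k in 2:m) out <- out * (k - 1) / ((k - 1) + 2 * scaled_size)
  out
}

# expectation of g(t) * density of pairwise TMRCA under piecewise demography,
# by exact per-epoch exponential integrals. kind: "right" uses
# g(t) = exp(-2wt), "overlap" uses (1 + 2wt) exp(-2wt).
piecewise_pair_expectation <- function(dem, w, kind) {
  K <- nrow(dem)
  S <- 1          # survival (no coalescence) up to current epoch start
  total <- 0
  for (i in seq_len(K)) {
    g <- dem$start_gen[i]
    N <- dem$size[i]
    len <- if (i < K) dem$start_gen[i + 1] - g else Inf
    a <- 2 * w + 1 / N
    ea <- if (is.finite(len)) exp(-a * len) else 0
    I0 <- (1 - ea) / a
    I1 <- (1 - (1 + a * ifelse(is.finite(len), len, 0)) * ea) / a^2
    base <- S * exp(-2 * w * g) / N
    total <- total + switch(kind,
      right = base * I0,
      overlap = base * ((1 + 2 * w * g) * I0 + 2 * w * I1))
    if (i < K) S <- S * exp(-len / N)
  }
  total
}

#' Pair detection probability under piecewise demography
#'
#' Integrates the detection survival function against the exact pairwise
#' TMRCA density of the piecewise-constant demography (per-epoch analytic
#' exponential integrals). The result always lies between the constant-size
#' values at the largest (`N1`) and smallest (`N2`) sizes.
#'
#' @param demography a [demography] object.
#' @param w Morgans threshold (> 0).
#' @return a probability; `e2_overlap_demography()` is the analogue for
#'   segments overlapping the focal point.
#' @export
#' @examples
#' dem <- demography(c(0, 50), c(100, 10000))
#' e2_right_demography(dem, 0.01)
e2_right_demography <- function(demography, w) {
  stopifnot(inherits(demography, "demography"))
  if (!is.numeric(w) || length(w) != 1 || w <= 0) stop("`w` must be > 0")
  piecewise_pair_expectation(demography, w, "right")
}

#' @rdname e2_right_demography
#' @export
e2_overlap_demography <- function(demography, w) {
  stopifnot(inherits(demography, "demography"))
  if (!is.numeric(w) || length(w) != 1 || w <= 0) stop("`w` must be > 0")
  piecewise_pair_expectation(demography, w, "overlap")
}

# numeric E[exp(-Nw * sum_j coef_j T_j)] for independent stage durations
# T_j ~ Exp(rate_j) (coalescent units), by adaptive quadrature per stage.
stage_survival_numeric <- function(coefs, rates, scaled_size,
                                   rel_tol = 1e-8) {
  out <- 1
  for (j in seq_along(coefs)) {
    r <- rates[j]
    a <- coefs[j] * scaled_size
    # finite-range adaptive quadrature: the integrand is e^{-45} at the cap,
    # so truncation is far below the requested tolerance even after the
    # E[joint] - E2^2 cancellation at large Nw
    upper <- 45 / (r + a)
    out <- out * stats::integrate(function(t) r * exp(-(r + a) * t), 0,
                                  upper, rel.tol = rel_tol,
                                  abs.tol = 0)$value
  }
  out
}

# all 18 labeled merger histories of 4 leaves, as the (t4, t3, t2)
# coefficients of the length of path(a,b) union path(c,d): a branch belongs
# to the union iff its descendant-leaf set contains exactly one of {a,b} or
# exactly one of {c,d}.
four_leaf_union_coefs <- function() {
  leaves <- c("a", "b", "c", "d")
  in_union <- function(set) {
    xor("a" %in% set, "b" %in% set) || xor("c" %in% set, "d" %in% set)
  }
  res <- list()
  first <- utils::combn(4, 2)
  for (f in seq_len(ncol(first))) {
    l3 <- c(list(leaves[first[, f]]),
            as.list(leaves[-first[, f]]))
    second <- utils::combn(3, 2)
    for (s in seq_len(ncol(second))) {
      l2 <- c(list(unlist(l3[second[, s]])), l3[-second[, s]])
      coefs <- c(
        sum(vapply(as.list(leaves), in_union, logical(1))),
        sum(vapply(l3, in_union, logical(1))),
        sum(vapply(l2, in_union, logical(1))))
      res[[length(res) + 1]] <- coefs
    }
  }
  res
}

#' Covariances between detectable right-extent indicators
#'
#' `cov3_right()` is `Cov(X_ab, X_ac)` (pairs sharing one haplotype) and
#' `cov4_right()` is `Cov(X_ab, X_cd)` (disjoint pairs), computed by numeric
#' integration over the enumerated coalescent topologies of three and four
#' leaves: conditional on the tree, the joint survival is
#' `exp(-w * length of the union of the two paths)`, which is linear in the
#' stage durations. These are `O((Nw)^-2)` and `O((Nw)^-3)` respectively and
#' nonnegative.
#'
#' @param scaled_size `Nw > 0`.
#' @return a covariance (scalar; vectorized over `scaled_size`).
#' @export
#' @examples
#' cov3_right(100) * 100^2   # order-stable in Nw
cov3_right <- function(scaled_size) {
  if (any(scaled_size <= 0)) stop("`scaled_size` must be positive")
  vapply(scaled_size, function(nw) {
    # every 3-leaf topology's path union is the whole spanning subtree:
    # 3 branches during T3 ~ Exp(3), 2 during T2 ~ Exp(1)
    e12 <- stage_survival_numeric(c(3, 2), c(3, 1), nw)
    e2 <- stage_survival_numeric(2, 1, nw)
    e12 - e2^2
  }, numeric(1))
}

#' @rdname cov3_right
#' @export
cov4_right <- function(scaled_size) {
  if (any(scaled_size <= 0)) stop("`scaled_size` must be positive")
  hist_coefs <- four_leaf_union_coefs()
  vapply(scaled_size, function(nw) {
    terms <- vapply(hist_coefs, stage_survival_numeric,
                    rates = c(6, 3, 1), scaled_size = nw, numeric(1))
    e2 <- stage_survival_numeric(2, 1, nw)
    mean(terms) - e2^2
  }, numeric(1))
}

#' Moment table over a grid
#'
#' Convenience builder for the TSV moment interface: closed-form marginals
#' and numeric covariances keyed by `(m, Nw)`.
#'
#' @param scaled_sizes vector of `Nw` values.
#' @param m_max largest tuple order for [em_right()].
#' @return a data frame.
#' @export
moment_table <- function(scaled_sizes, m_max = 4) {
  do.call(rbind, lapply(scaled_sizes, function(nw) {
    data.frame(m = 2:m_max, scaled_size = nw,
               e2_right = e2_right(nw), e2_overlap = e2_overlap(nw),
               em_right = vapply(2:m_max, em_right, numeric(1),
                                 scaled_size = nw),
               cov3_right = cov3_right(nw), cov4_right = cov4_right(nw))
  }))
}
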