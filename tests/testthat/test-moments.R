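# rate_statistics: closed-form moments, demography integrals, covariances

test_that("pair moment closed forms", {
  expect_equal(e2_right(0), 1)
  expect_equal(e2_right(0.5), 0.5)
  expect_equal(e2_right(6000), 1 / 12001)
  expect_equal(e2_overlap(0), 1)
  expect_equal(e2_overlap(6000), 24001 / 144024001)
  nw <- c(0.1, 1, 10, 100, 5000)
  expect_true(all(e2_overlap(nw) >= e2_right(nw)))   # W >= R pointwise
  expect_true(all(diff(e2_right(nw)) < 0))           # strictly decreasing
  expect_error(e2_right(-1), "nonnegative")
})

test_that("m-way product form and its consistency", {
  expect_equal(em_right(2, 0.5), e2_right(0.5))
  expect_equal(em_right(3, 1), 1 / 6)
  expect_equal(em_right(4, 1), 0.1)
  # m-way sharing implies pairwise sharing: E_m <= E_{m-1}
  for (nw in c(0.5, 5, 500))
    expect_true(em_right(4, nw) <= em_right(3, nw) &&
                  em_right(3, nw) <= em_right(2, nw))
  expect_error(em_right(1, 1), ">= 2")
})

test_that("demography integrals reduce, sandwich, and match quadrature", {
  w <- 0.01
  cd <- constant_demography(2000)
  expect_equal(e2_right_demography(cd, w), e2_right(2000 * w),
               tolerance = 1e-12)
  expect_equal(e2_overlap_demography(cd, w), e2_overlap(2000 * w),
               tolerance = 1e-12)
  # randomized demographies: sandwich bounds + independent quadrature oracle
  for (i in 1:20) {
    set.seed(substream_seed(71, i))
    K <- sample(1:4, 1)
    starts <- c(0, sort(sample(1:400, K - 1)))
    sizes <- 10^runif(K, 1, 4)
    dem <- demography(starts, sizes)
    got <- e2_right_demography(dem, w)
    rng <- pop_size_range(dem)
    expect_gte(got, e2_right(rng[["n1"]] * w) - 1e-12)
    expect_lte(got, e2_right(rng[["n2"]] * w) + 1e-12)
    # quadrature oracle: integrate survival * TMRCA density directly, with
    # the cumulative hazard written as plain epoch-overlap arithmetic
    haz <- function(t) 1 / dem$size[findInterval(t, dem$start_gen)]
    ends <- c(dem$start_gen[-1], Inf)
    cumhaz <- function(t) {
      vapply(t, function(tt) {
        sum(pmax(0, pmin(tt, ends) - dem$start_gen) / dem$size)
      }, numeric(1))
    }
    f <- function(t) exp(-2 * w * t) * vapply(t, haz, numeric(1)) *
      exp(-cumhaz(t))
    # integrate epoch by epoch; truncate the last epoch where the integrand
    # has decayed by e^{-40}
    pieces <- c(dem$start_gen,
                max(dem$start_gen) + 40 / (2 * w + 1 / dem$size[K]))
    oracle <- sum(vapply(seq_len(length(pieces) - 1), function(j) {
      stats::integrate(f, pieces[j], pieces[j + 1], rel.tol = 1e-8)$value
    }, numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-5)
  }
})

test_that("two-epoch demography mean matches Monte-Carlo simulation", {
  dem <- demography(c(0, 30), c(200, 2000))
  w <- 0.01
  mc <- tuple_mc(2, dem, w, "right", list(c(1, 2)), reps = 50000, seed = 73)
  p <- e2_right_demography(dem, w)
  expect_lt(abs(mean(mc) - p), 3 * sqrt(p * (1 - p) / nrow(mc)))
})

test_that("cov3/cov4 numeric integrals: bounds, order stability, closed form",
{
  for (nw in c(10, 100, 1000)) {
    c3 <- cov3_right(nw)
    expect_gt(c3, 0)
    expect_lt(c3, e2_right(nw))
    # every 3-leaf topology's union is the whole spanning subtree, giving
    # the closed form E3 - E2^2 (independent algebraic oracle)
    expect_equal(c3, em_right(3, nw) - e2_right(nw)^2, tolerance = 1e-7)
  }
  grid <- c(1e2, 1e3, 1e4)
  s3 <- grid^2 * cov3_right(grid)
  s4 <- grid^3 * cov4_right(grid)
  expect_lt(max(s3) / min(s3), 2)
  expect_lt(max(s4) / min(s4), 2)
  expect_true(all(cov4_right(grid) > 0))
  expect_error(cov3_right(0), "positive")
})

test_that("standardize is the exact affine map of the count", {
  rs <- standardize(0, n_hap = 50, m = 2, p = 0.1)
  C <- choose(50, 2)
  expect_equal(rs$omega, C * 0.1 * 0.9)
  expect_equal(rs$z, -sqrt(C * 0.1 / 0.9))
  expect_equal(standardize(3 * 0.5, n_hap = 3, m = 2, p = 0.5)$omega, 0.75)
  expect_equal(standardize(3 * 0.5, n_hap = 3, m = 2, p = 0.5)$z, 0)
  # invertible: recover the count from z
  rs2 <- standardize(37, n_hap = 100, m = 2, p = 0.004)
  expect_equal(rs2$z * sqrt(rs2$omega) + choose(100, 2) * rs2$p, 37)
  expect_equal(rs2$rate, 37 / choose(100, 2))
  expect_error(standardize(1, 10, 2, 0), "in \\(0, 1\\)")
  expect_error(standardize(-1, 10, 2, 0.5), "count")
})

test_that("clt_condition_report diagnostics behave as expected", {
  dem <- constant_demography(1e4 / 0.01)   # N_h w = 1e4 at w = 0.01
  rep1 <- clt_condition_report(100, dem, 0.01)
  expect_lt(rep1$cov3_ratio, 1)
  expect_lt(rep1$cov4_ratio, 1)
  # Nw/n^2 sits exactly at the boundary here; the cluster condition holds
  expect_equal(rep1$ratio_nw_n2, 1)
  expect_true(rep1$cond_small_clusters)
  # violating n = o(Nw) inflates the 3-share ratio
  nw <- 1000
  bad <- clt_condition_report(10 * nw, constant_demography(nw / 0.01), 0.01)
  good <- clt_condition_report(round(nw / 10),
                               constant_demography(nw / 0.01), 0.01)
  expect_gt(bad$cov3_ratio, good$cov3_ratio)
  expect_false(bad$cond_small_clusters)
  # Nw -> infinity with n fixed: omega -> 0, ratios approach constants
  r1 <- clt_condition_report(100, constant_demography(1e6), 0.01)
  r2 <- clt_condition_report(100, constant_demography(1e8), 0.01)
  expect_lt(r2$omega, r1$omega)
  expect_equal(r2$cov3_ratio / r1$cov3_ratio, 1e-2, tolerance = 0.05)
})

test_that("condition3_check separates independence from correlation", {
  set.seed(substream_seed(79, 0))
  n <- 20000
  p <- 0.2
  z_pair <- rbinom(n, 1, p) - p
  z_rest <- rowSums(matrix(rbinom(n * 30, 1, p), n)) - 30 * p
  res <- condition3_check(z_pair, z_rest, n_bins = 8)
  # simultaneous band over 8 bins; a bin at z_rest == 0 is identically zero
  expect_true(all(abs(res$estimate) <= 4 * res$se + 1e-12))
  # duplicate the pair indicator into the remainder: positive everywhere
  z_rest2 <- 10 * z_pair + rnorm(n, sd = 0.05)
  res2 <- condition3_check(z_pair, z_rest2, n_bins = 8)
  expect_true(all(res2$estimate > -3 * res2$se))
  expect_gt(mean(res2$estimate), 0)
  expect_error(condition3_check(1:10, 1:10), "1000")
})

test_that("small bins are merged with a neighbor", {
  set.seed(substream_seed(83, 0))
  z_rest <- rnorm(2000)
  z_pair <- rnorm(2000, sd = 0.1)
  # 64 quantile bins of ~31 each, all below the floor: merging must cascade
  expect_message(res <- condition3_check(z_pair, z_rest, n_bins = 64,
                                         min_per_bin = 40),
                 "merging bin")
  expect_gte(min(res$n), 40)
})

test_that("multi_sample_rates: symmetry, decorrelation, variance 2", {
  dem <- constant_demography(2e4)
  w <- 0.05                       # Nw = 1000
  p <- e2_overlap(2e4 * w)
  n <- 200
  reps <- 400
  z0 <- z1 <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(substream_seed(89, i))
    tr <- simulate_tree(n, dem)
    ann <- annotate_crossovers(tr)
    ms <- multi_sample_rates(tr, ann, list(1:100, 101:200), w,
                             mode = "overlap", p = p)
    z0[i] <- ms$rates[[1]]$z
    z1[i] <- ms$rates[[2]]$z
    if (i == 1) {
      expect_equal(ms$differences$diff, z0[1] - z1[1])
      expect_error(multi_sample_rates(tr, ann, list(1:100, 100:199), w,
                                      p = p), "disjoint")
      expect_error(multi_sample_rates(tr, ann, list(1:100, 101:150), w,
                                      p = p), "equally sized")
    }
  }
  d <- z0 - z1
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(reps))
  expect_lt(abs(cor(z0, z1)), 0.2)
  expect_lt(abs(var(d) - 2), 0.45)
})

test_that("moment_table is keyed by (m, Nw) and consistent", {
  tab <- moment_table(c(1, 10), m_max = 3)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$em_right[tab$m == 2], e2_right(tab$scaled_size[tab$m == 2]))
})
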