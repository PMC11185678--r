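# experiments: batteries, upper bounds, two-sample study, CLI

test_that("experiment_config validates and resolves sizes", {
  dem <- constant_demography(1e4)
  cfg <- experiment_config(n_diploid = 50, demography = dem, reps = 10,
                           n_batches = NULL)
  expect_equal(cfg$n_hap, 100)
  expect_equal(cfg$reps, 10)
  cfg2 <- experiment_config(n_haploid = 40, demography = dem,
                            batch_size = 20, n_batches = 3)
  expect_equal(cfg2$reps, 60)
  expect_error(experiment_config(demography = dem), "exactly one")
  expect_error(experiment_config(n_haploid = 10, demography = dem,
                                 reps = 10, n_batches = NULL, alpha = 1),
               "alpha")
  expect_error(experiment_config(n_haploid = 10, demography = dem,
                                 reps = 5, batch_size = 10, n_batches = 2),
               "cover")
})

test_that("shapiro_battery: nominal level, gross non-normality, batching", {
  set.seed(substream_seed(109, 0))
  res <- shapiro_battery(rnorm(40 * 500), 500, 40, alpha = 0.05)
  # binomial 99% envelope around the nominal level
  env <- qbinom(c(0.005, 0.995), 40, 0.05) / 40
  expect_gte(res$rejection_proportion, env[1])
  expect_lte(res$rejection_proportion, env[2])
  set.seed(substream_seed(109, 1))
  expect_equal(shapiro_battery(rexp(20 * 500), 500, 20)$rejection_proportion,
               1)
  # deterministic in-order batching
  v <- c(rnorm(500), rexp(500) * 100)
  expect_identical(shapiro_battery(v, 500, 2)$p_values,
                   c(shapiro.test(v[1:500])$p.value,
                     shapiro.test(v[501:1000])$p.value))
  expect_error(shapiro_battery(rnorm(10), 500, 1), "at least")
})

test_that("zero-variance batches count as rejections with a warning", {
  set.seed(substream_seed(127, 0))
  v <- c(rnorm(10), rep(1, 10))
  expect_warning(res <- shapiro_battery(v, 10, 2), "zero-variance")
  expect_equal(res$p_values[2], 0)
  expect_gte(res$rejection_proportion, 0.5)
})

test_that("upper_bound_study recovers known ratios", {
  set.seed(substream_seed(113, 0))
  resn <- upper_bound_study(rnorm(100 * 500), k_sd = 3, batch_size = 500)
  expect_equal(resn$ratio, 1, tolerance = 0.06)
  set.seed(substream_seed(113, 1))
  rese <- upper_bound_study(rexp(100 * 500), k_sd = 3, batch_size = 500)
  expect_equal(rese$ratio, 4 / -log(1 - stats::pnorm(3)), tolerance = 0.05)
  expect_equal(100 * stats::pnorm(3), 99.86501, tolerance = 1e-6)
  expect_equal(100 * stats::pnorm(4), 99.99683, tolerance = 1e-6)
  expect_error(upper_bound_study(1:10, batch_size = 500), "too few")
})

test_that("feature battery bookkeeping and reproducibility", {
  dem <- constant_demography(500)
  cfg <- experiment_config(n_haploid = 30, demography = dem, w = 0.02,
                           reps = 10, n_batches = NULL, seed = 5)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_feature_battery(cfg, out_dir = out1)
  expect_equal(nrow(res$features), 10)
  # summary matches recomputation from the raw table
  expect_equal(res$summary$avg, colMeans(res$features)[res$summary$feature],
               ignore_attr = TRUE)
  expect_equal(res$summary$max, apply(res$features, 2,
                                      max)[res$summary$feature],
               ignore_attr = TRUE)
  # same seed + config => byte-identical outputs
  run_feature_battery(cfg, out_dir = out2)
  expect_identical(readLines(file.path(out1, "features.tsv")),
                   readLines(file.path(out2, "features.tsv")))
  # replicates are order-independent: replicate i alone reproduces row i
  set.seed(substream_seed(5, 4))
  row5 <- ibd_replicate_stats(30, dem, 0.02)
  expect_equal(unlist(res$features[5, ]), row5[colnames(res$features)],
               ignore_attr = TRUE)
})

test_that("two_sample_study is centered and standardized", {
  dem <- constant_demography(2e4)
  cfg <- experiment_config(n_haploid = 200, demography = dem, w = 0.05,
                           batch_size = 100, n_batches = 4, seed = 9)
  res <- two_sample_study(cfg)
  expect_equal(nrow(res$stats), 400)
  d <- res$stats$diff
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  expect_equal(res$stats$diff, res$stats$z0 - res$stats$z1)
  cfg_odd <- experiment_config(n_haploid = 7, demography = dem, reps = 2,
                               n_batches = NULL)
  expect_error(two_sample_study(cfg_odd), "even")
})

test_that("batch driver half counts agree with multi_sample_rates", {
  dem <- constant_demography(3000)
  w <- 0.02
  p <- e2_overlap(3000 * w)
  for (i in 1:5) {
    set.seed(substream_seed(131, i))
    row <- ibd_replicate_stats(60, dem, w, mode = "overlap")
    # identical RNG consumption: replay the replicate at the R level
    set.seed(substream_seed(131, i))
    tr <- simulate_tree(60, dem)
    ann <- annotate_crossovers(tr)
    ms <- multi_sample_rates(tr, ann, list(1:30, 31:60), w,
                             mode = "overlap", p = p)
    expect_equal(unname(row["count0"]), ms$rates[[1]]$count)
    expect_equal(unname(row["count1"]), ms$rates[[2]]$count)
    expect_equal(unname(row["count"]),
                 nrow(detectable_segments(tr, ann, w, mode = "overlap")))
  }
})

test_that("demography JSON config round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(epochs = data.frame(start_gen = c(0, 100),
                             size_diploid = c(500, 5000))),
    path)
  dem <- read_demography(path)
  expect_equal(dem$size, c(1000, 10000))
  expect_equal(dem$start_gen, c(0, 100))
})

test_that("CLI subcommands run end to end", {
  out <- withr::local_tempdir()
  # moments
  tab <- ibd_cli(c("moments", "--scaled-size", "10", "--out", out))
  expect_true(file.exists(file.path(out, "moments.tsv")))
  expect_equal(tab$e2_right[1], e2_right(10))
  # simulate (tiny battery)
  suppressMessages(res <- ibd_cli(c(
    "simulate", "--haploid", "20", "--size-haploid", "500", "--w", "0.02",
    "--reps", "6", "--seed", "3", "--out", file.path(out, "sim"))))
  expect_equal(nrow(res$features), 6)
  expect_true(file.exists(file.path(out, "sim", "features.tsv")))
  # er battery
  suppressMessages(res_er <- ibd_cli(c(
    "er", "--haploid", "50", "--size-haploid", "1000", "--w", "0.02",
    "--reps", "6", "--seed", "3", "--out", file.path(out, "er"))))
  expect_equal(nrow(res_er$features), 6)
  # sw-battery on a written values file
  vpath <- file.path(out, "values.tsv")
  set.seed(1)
  write.table(data.frame(z = rnorm(200)), vpath, sep = "\t",
              row.names = FALSE)
  res_sw <- ibd_cli(c("sw-battery", "--values", vpath, "--batch-size", "50",
                      "--n-batches", "4"))
  expect_length(res_sw$p_values, 4)
  # clt-report
  suppressMessages(rep <- ibd_cli(c(
    "clt-report", "--haploid", "100", "--size-haploid", "1e6",
    "--w", "0.01", "--out", out)))
  expect_true(file.exists(file.path(out, "clt_report.json")))
  expect_true(rep$cond_small_clusters)
  expect_error(ibd_cli(character(0)), "usage")
  expect_error(ibd_cli("nope"), "unknown subcommand")
})
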