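#' Experiment configuration
#'
#' Bundles the knobs shared by the simulation batteries. Sample and
#' population sizes may be given as diploid counts (doubled internally, the
#' haploid model with twice the diploid count) or directly as haploid counts.
#'
#' @param n_diploid,n_haploid sample size (give exactly one).
#' @param demography a [demography] object.
#' @param w Morgans detection threshold.
#' @param mode `"overlap"` (the simulation studies) or `"right"` (the form
#'   the theory is stated for).
#' @param reps total replicates; defaults to `batch_size * n_batches`.
#' @param batch_size observations per Shapiro-Wilk test.
#' @param n_batches number of Shapiro-Wilk tests.
#' @param alpha significance level in (0, 1).
#' @param seed master seed; replicate i uses `substream_seed(seed, i)`.
#' @param time_model passed to [simulate_tree()].
#' @param verbose log progress to stderr every 1000 replicates.
#' @return a list of class `experiment_config`.
#' @export
#' @examples
#' experiment_config(n_diploid = 50, demography = constant_demography(1e4),
#'                   w = 0.02, reps = 10, n_batches = NULL)
experiment_config <- function(n_diploid = NULL, n_haploid = NULL, demography,
                              w = 0.03, mode = c("overlap", "right"),
                              reps = NULL, batch_size = 500L,
                              n_batches = 50L, alpha = 0.05, seed = 1L,
                              time_model = c("continuous", "discrete"),
                              verbose = FALSE) {
  mode <- match.arg(mode)
  time_model <- match.arg(time_model)
  if (is.null(n_haploid) == is.null(n_diploid))
    stop("give exactly one of `n_diploid`, `n_haploid`")
  n_hap <- if (is.null(n_haploid)) 2L * n_diploid else n_haploid
  stopifnot(inherits(demography, "demography"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (is.null(reps)) {
    if (is.null(n_batches)) stop("give `reps` or `n_batches`")
    reps <- batch_size * n_batches
  }
  if (!is.null(n_batches) && reps < batch_size * n_batches)
    stop("`reps` must cover batch_size * n_batches")
  structure(list(n_hap = as.integer(n_hap), demography = demography, w = w,
                 mode = mode, reps = as.integer(reps),
                 batch_size = as.integer(batch_size),
                 n_batches = if (is.null(n_batches)) NULL
                             else as.integer(n_batches),
                 alpha = alpha, seed = as.integer(seed),
                 time_model = time_model, verbose = verbose),
            class = "experiment_config")
}

#' One full IBD replicate's summary statistics
#'
#' Simulates tree, crossover annotation and detectable pairs, and returns the
#' pair count, the indicator for the designated pair (1,2), within-half pair
#' counts (leaves split at `n_hap/2`), and the five graph features. Uses the
#' current RNG state.
#'
#' @inheritParams experiment_config
#' @param demography a [demography] object.
#' @param w Morgans threshold.
#' @param mode detection mode.
#' @param time_model time model.
#' @return named numeric vector.
#' @export
ibd_replicate_stats <- function(n_haploid, demography, w,
                                mode = c("overlap", "right"),
                                time_model = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  time_model <- match.arg(time_model)
  cpp_ibd_replicate(as.integer(n_haploid), demography$start_gen,
                    demography$size, w, if (mode == "right") 0L else 1L,
                    time_model == "discrete")
}

feature_summary <- function(tab) {
  cols <- c("edges", "tree2", "tree3", "complete3plus", "largest")
  cols <- intersect(cols, names(tab))
  do.call(rbind, lapply(cols, function(cl) {
    v <- tab[[cl]]
    data.frame(feature = cl, avg = mean(v), var = var(v), min = min(v),
               max = max(v))
  }))
}

run_battery_core <- function(config, simulate_row) {
  reps <- config$reps
  first <- simulate_row(0L)
  tab <- matrix(NA_real_, nrow = reps, ncol = length(first),
                dimnames = list(NULL, names(first)))
  tab[1, ] <- first
  for (i in seq_len(reps - 1L)) {
    tab[i + 1L, ] <- simulate_row(i)
    if (config$verbose && (i + 1L) %% 1000L == 0L)
      message("replicate ", i + 1L, "/", reps)
  }
  as.data.frame(tab)
}

#' Run the graph-feature battery
#'
#' Per replicate: genealogy, crossover annotation, detectable pairs, graph
#' features. Summaries (avg/var/min/max) and Shapiro-Wilk rejection
#' proportions are computed per feature over deterministic, in-order batches.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for `features.tsv` and `summary.json`.
#' @return list with `features` (per-replicate data frame), `summary`,
#'   `sw` (per-feature rejection proportions, when `n_batches` is set) and
#'   the `config`.
#' @export
run_feature_battery <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  tab <- run_battery_core(config, function(i) {
    set.seed(substream_seed(config$seed, i))
    ibd_replicate_stats(config$n_hap, config$demography, config$w,
                        mode = config$mode, time_model = config$time_model)
  })
  res <- list(features = tab, summary = feature_summary(tab),
              config = config)
  if (!is.null(config$n_batches)) {
    cols <- c("edges", "tree2", "tree3", "complete3plus", "largest")
    res$sw <- vapply(cols, function(cl) {
      shapiro_battery(tab[[cl]], config$batch_size, config$n_batches,
                      config$alpha)$rejection_proportion
    }, numeric(1))
  }
  maybe_write_battery(res, out_dir)
  res
}

#' Run the matched Erdos-Renyi battery
#'
#' Same bookkeeping as [run_feature_battery()] but on G(n, p) graphs with the
#' matched edge probability.
#'
#' @param n_nodes number of nodes.
#' @param p edge probability (see [er_probability()]).
#' @param config an [experiment_config()] (its sample size and demography are
#'   ignored; reps/batching/seed apply).
#' @param out_dir optional output directory.
#' @return as [run_feature_battery()].
#' @export
er_feature_battery <- function(n_nodes, p, config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  tab <- run_battery_core(config, function(i) {
    set.seed(substream_seed(config$seed, i))
    graph_features(simulate_er(n_nodes, p))
  })
  res <- list(features = tab, summary = feature_summary(tab),
              config = config)
  if (!is.null(config$n_batches)) {
    res$sw <- vapply(names(tab), function(cl) {
      shapiro_battery(tab[[cl]], config$batch_size, config$n_batches,
                      config$alpha)$rejection_proportion
    }, numeric(1))
  }
  maybe_write_battery(res, out_dir)
  res
}

maybe_write_battery <- function(res, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cbind(replicate = seq_len(nrow(res$features)), res$features)
  write.table(tab, file.path(out_dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = res$summary, sw = as.list(res$sw)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

#' Shapiro-Wilk battery
#'
#' Splits `values` into `n_batches` consecutive batches of `batch_size` (in
#' input order — no shuffling, so results are seed-stable), tests each batch
#' for normality, and reports the proportion of p-values below `alpha`.
#' Zero-variance batches cannot be tested and are counted as rejections with
#' a warning (a degenerate distribution is maximally non-normal).
#'
#' @param values numeric vector, at least `batch_size * n_batches` long.
#' @param batch_size observations per test (3..5000).
#' @param n_batches number of tests.
#' @param alpha significance level.
#' @return list with `rejection_proportion` and per-batch `p_values`.
#' @export
shapiro_battery <- function(values, batch_size, n_batches, alpha = 0.05) {
  if (length(values) < batch_size * n_batches)
    stop("need at least batch_size * n_batches values")
  pv <- vapply(seq_len(n_batches), function(b) {
    v <- values[((b - 1) * batch_size + 1):(b * batch_size)]
    if (var(v) == 0) {
      warning("zero-variance batch ", b, " counted as rejection")
      return(0)
    }
    shapiro.test(v)$p.value
  }, numeric(1))
  list(rejection_proportion = mean(pv < alpha), p_values = pv)
}

#' Relative upper bound study
#'
#' For each consecutive batch, computes the estimated upper bound
#' `mean + k_sd * sd`; pools all values for the empirical percentile matching
#' the normal `k_sd`-sigma tail, and returns the averaged batch bound divided
#' by that percentile. Values below 1 mean the k-sigma bound understates the
#' tail.
#'
#' @param values numeric vector.
#' @param k_sd 3 or 4 standard deviations.
#' @param batch_size observations per batch; all complete batches are used.
#' @param q tail percentile (defaults to `100 * pnorm(k_sd)`:
#'   99.86501 for 3, 99.99683 for 4).
#' @return list with `ratio`, `mean_bound`, `percentile`.
#' @export
upper_bound_study <- function(values, k_sd = 3, batch_size = 500,
                              q = 100 * stats::pnorm(k_sd)) {
  n_batches <- length(values) %/% batch_size
  if (n_batches < 1) stop("too few values for one batch")
  bounds <- vapply(seq_len(n_batches), function(b) {
    v <- values[((b - 1) * batch_size + 1):(b * batch_size)]
    mean(v) + k_sd * sd(v)
  }, numeric(1))
  pct <- as.numeric(quantile(values[seq_len(n_batches * batch_size)],
                             q / 100, type = 7))
  list(ratio = mean(bounds) / pct, mean_bound = mean(bounds),
       percentile = pct)
}

#' Two-sample difference study
#'
#' Per replicate, one shared genealogy is simulated, its leaves are split
#' into two fixed equal halves, each half's standardized detectable rate
#' (within-half pairs only) is computed with the theoretical `p` for the
#' demography, and the difference of the two standardized rates is recorded.
#' A Shapiro-Wilk battery is applied to the differences.
#'
#' @param config an [experiment_config()]; `n_hap` must be even.
#' @param out_dir optional directory for `two_sample.tsv` / `summary.json`.
#' @return list with `stats` (per-replicate `z0`, `z1`, `diff`),
#'   `rejection_proportion` and `config`.
#' @export
two_sample_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$n_hap %% 2L != 0L) stop("`n_hap` must be even for a half split")
  n_half <- config$n_hap %/% 2L
  p <- if (config$mode == "overlap")
    e2_overlap_demography(config$demography, config$w)
  else e2_right_demography(config$demography, config$w)
  tab <- run_battery_core(config, function(i) {
    set.seed(substream_seed(config$seed, i))
    r <- ibd_replicate_stats(config$n_hap, config$demography, config$w,
                             mode = config$mode,
                             time_model = config$time_model)
    c(count0 = unname(r["count0"]), count1 = unname(r["count1"]))
  })
  C <- choose(n_half, 2)
  omega <- C * p * (1 - p)
  tab$z0 <- (tab$count0 - C * p) / sqrt(omega)
  tab$z1 <- (tab$count1 - C * p) / sqrt(omega)
  tab$diff <- tab$z0 - tab$z1
  res <- list(stats = tab, config = config)
  if (!is.null(config$n_batches))
    res$rejection_proportion <- shapiro_battery(
      tab$diff, config$batch_size, config$n_batches,
      config$alpha)$rejection_proportion
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(cbind(replicate = seq_len(nrow(tab)), tab),
                file.path(out_dir, "two_sample.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(rejection_proportion = res$rejection_proportion,
           mean_diff = mean(tab$diff)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
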