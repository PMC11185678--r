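# ibdclt

Coalescent models and normality diagnostics for identity-by-descent (IBD)
rates around a genomic locus.

## The problem

When two haplotypes descend from a recent common ancestor, they share a long
haplotype tract — an IBD segment — around any locus inside it, bounded by
crossovers on the descending lineages. Genome scans and demographic
inference routinely use the *detectable IBD rate*: the fraction of haplotype
pairs whose shared segment at a focal point exceeds a detection threshold
`w` Morgans. Those pair indicators are **correlated** through the shared
genealogy and shared recombinations, so the usual iid central limit theorem
does not apply, and tests that assume normality can be anti-conservative.

`ibdclt` implements the generative model behind this statistic and the
simulation machinery to study when normality holds, for statisticians and
population geneticists building IBD-based tests:

* **Genealogy**: Kingman coalescent at a single locus, continuous or
  discrete time, piecewise-constant demography `N(t)`; waiting times with
  hazard `C(k,2)/N(t)` per generation while `k` lineages remain.
* **Recombination**: crossovers as a Poisson process; from the focal point,
  the distance to the nearest crossover on a branch of `ℓ` generations is
  `Exp(ℓ)` Morgans per side. For a pair with common ancestor `t`
  generations back, the right extent is `R | t ~ Exp(2t)` and the width
  `W = L + R | t ~ Gamma(2, 2t)`.
* **Moments** (scaled size `Nw = N_h × w`):
  `E2 = P(R ≥ w) = 1/(2Nw+1)`, `P(W ≥ w) = (4Nw+1)/(2Nw+1)²`,
  m-way `E_m = Π_{k=2..m} (k−1)/((k−1)+2Nw)`; covariance classes
  `Cov(X_ab, X_ac) = O((Nw)⁻²)` and `Cov(X_ab, X_cd) = O((Nw)⁻³)` by
  numeric integration over enumerated topologies.
* **Statistic**: `z = (count − C(n,2)p) / sqrt(C(n,2)p(1−p))`, approximately
  standard normal when `n = o(Nw)` and `Nw = o(n²)`.
* **Batteries**: detectable-IBD graphs at a locus (edges, order-2/3 trees,
  cliques, largest component) vs matched sparse Erdős–Rényi graphs;
  Shapiro-Wilk normality batteries; upper-percentile ("relative upper
  bound") studies; two-sample rate-difference tests.

The heavy loops (tree simulation, segment enumeration, union-find) are C++
via Rcpp; the segment enumerator is an exact pruned bottom-up algorithm
tested against a brute-force all-tuples scan. See the methods vignette
(`vignettes/ibd-rates-methods.Rmd`) for the model, assumptions, and design
decisions.

## Worked example

```r
library(ibdclt)
set.seed(7)
tr  <- simulate_tree(n_hap = 8, constant_demography(5000))
ann <- annotate_crossovers(tr)
seg <- detectable_segments(tr, ann, w = 0.01, mode = "overlap")
seg
#>   id1 id2         L          R          W
#> 1   2   6 0.0460107 0.03998967 0.08600037
```

One haplotype pair (2, 6) shares a segment of width 0.086 Morgans
overlapping the focal point — detectable at `w = 0.01`. The matching graph
and standardized rate:

```r
graph_features(build_graph(seg, 8))
#>         edges         tree2         tree3 complete3plus       largest
#>             1             1             0             0             2

standardize(nrow(seg), n_hap = 8, m = 2, p = e2_overlap(5000 * 0.01))
#> <rate_statistics> n=8 m=2 count=1 rate=0.03571 p=0.0197 omega=0.5408 z=0.6096
```

`p = 0.0197` is the theoretical pair probability at `Nw = 50`; observing 1
detectable pair among `C(8,2) = 28` gives `z = 0.61`, unremarkable under the
normal approximation. Diagnostics for when that approximation is trustworthy:

```r
rep <- clt_condition_report(200, constant_demography(1e6), w = 0.03)
rep$cov3_ratio   # 0.0067  : 3-share covariance ≪ Omega
rep$ratio_n_nw   # 0.0067  : n / (Nw) small => no large IBD clusters
```

Batteries at study scale are one call each, e.g. the detectable-IBD graph
battery (2000 diploids, constant population of 1e5 diploids, `w = 0.03`,
50 Shapiro-Wilk batches of 500 replicates):

```r
cfg <- experiment_config(n_diploid = 2000,
                         demography = constant_demography(1e5, diploid = TRUE),
                         w = 0.03, batch_size = 500, n_batches = 50, seed = 1)
res <- run_feature_battery(cfg)   # ~3 minutes
res$sw                            # rejection proportions per graph feature
```

## Command line

```sh
Rscript -e 'ibdclt::ibd_cli()' simulate \
    --config inst/configs/feature-battery-scaled.json --seed 1 --out out/
Rscript -e 'ibdclt::ibd_cli()' er --haploid 4000 --size-haploid 200000 \
    --w 0.03 --reps 2000 --seed 1 --out out-er/
Rscript -e 'ibdclt::ibd_cli()' moments --out out/
```

Subcommands: `simulate`, `er`, `moments`, `sw-battery`, `upper-bound`,
`two-sample`, `condition3`, `clt-report`. JSON configs ship in
`inst/configs/` (scaled-down presets alongside full study-scale ones, the
latter documented as long-running).

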