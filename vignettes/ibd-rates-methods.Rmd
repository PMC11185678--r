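---
title: "Methods: detectable IBD rates around a locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detectable IBD rates around a locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdclt)
```

## The model

`ibdclt` models identity-by-descent (IBD) sharing at a single focal genomic
position in a sample of $n$ haplotypes drawn from a population of haploid
size $N_h$ (all sizes are haploid internally; user-facing entry points accept
diploid counts and double them).

Two ingredients generate the data:

1. **Genealogy.** The ancestry of the sample at the locus is a Kingman
   coalescent: while $k$ lineages remain, the waiting time to the next
   pairwise merger has hazard $\binom{k}{2}/N_h(t)$ per generation, with
   $N_h(t)$ a piecewise-constant demography. In coalescent units
   ($\times N_h$, constant size) the stage durations are
   $T_k \sim \mathrm{Exp}\!\left(\binom{k}{2}\right)$. Times are stored in
   generations throughout; coalescent units appear only inside moment
   formulas. This avoids unit bugs when the demography varies.
2. **Recombination.** Crossovers along the genome form a Poisson process
   with no interference, so from the focal point the Morgans distance to the
   nearest crossover accumulated along a branch of length $\ell$ generations
   is $\mathrm{Exp}(\ell)$ on each side of the locus, independently per side
   and per branch. The chromosome is treated as infinite in both directions
   (no edge truncation).

For a haplotype pair $(a,b)$ whose most recent common ancestor sits $t$
generations back, the shared segment's right extent is the minimum of the
crossover distances over the two descending paths,
$R_{a,b}\mid t \sim \mathrm{Exp}(2t)$, the left extent $L_{a,b}$ likewise,
and the width $W_{a,b} = L_{a,b} + R_{a,b} \mid t \sim \Gamma(2, 2t)$. A
segment is *detectable* at threshold $w$ Morgans when $R_{a,b} \ge w$
(`mode = "right"`, the form the distribution theory is stated in) or
$W_{a,b} \ge w$ (`mode = "overlap"`, the form the simulation studies use).
For an $m$-tuple, the shared extent is the minimum over all branches of the
spanning subtree up to the tuple's MRCA, so conditional on the tree
$P(R \ge w \mid \text{tree}) = e^{-wG}$ with $G$ the spanning subtree's
total length in generations.

## Moments

With $Nw$ the scaled population size ($N_h \times w$, dimensionless):

* $E_2 = P(R_{a,b} \ge w) = (2Nw+1)^{-1}$ — integrate $e^{-2Nwt}$ against
  the $\mathrm{Exp}(1)$ coalescent density.
* $P(W_{a,b} \ge w) = (4Nw+1)/(2Nw+1)^2$ — same integral with the
  $\Gamma(2,2t)$ survival $(1+2Nwt)e^{-2Nwt}$.
* $E_m = \prod_{k=2}^{m} \frac{k-1}{(k-1) + 2Nw}$ — during stage $k$ the
  spanning subtree has $k$ live branches for
  $T_k \sim \mathrm{Exp}\!\left(\binom{k}{2}\right)$, so the stage
  contributes $\binom{k}{2} / \left(\binom{k}{2} + kNw\right)$.

A note on the three-way constant: one sometimes sees the three-way
probability quoted with an extra leading factor of 3,
$3(2Nw+1)^{-1}(Nw+1)^{-1}$. That cannot be right — sharing among three
haplotypes implies sharing within each pair, so $E_3 \le E_2$ must hold, and
the factor-3 expression violates it already at $Nw = 1$ ($1/2 > 1/3$). The
product form above satisfies the inequality and is what the package's
Monte-Carlo oracle reproduces (`test-acceptance.R`, criterion 1, which
additionally asserts the simulated mean is more than ten standard errors
away from the factor-3 variant). `em_right()` therefore implements the
product form.

**Covariances.** For the central-limit behaviour the two covariance classes
are $\mathrm{Cov}(X_{a,b}, X_{a,c})$ (three distinct haplotypes) and
$\mathrm{Cov}(X_{a,b}, X_{c,d})$ (four). Conditional on the genealogy, joint
survival is $e^{-w \cdot |{\rm path}(a,b)\,\cup\,{\rm path}(c,d)}|$, and the
union length is linear in the stage durations, so each enumerated labeled
topology contributes a product of one-dimensional exponential integrals.
`cov3_right()`/`cov4_right()` evaluate those integrals by adaptive
quadrature (relative tolerance $10^{-8}$, finite range capped where the
integrand reaches $e^{-45}$) with topology probabilities enumerated exactly
(each of the 18 four-leaf labeled histories has probability $1/18$). Two
independent checks cover them: for three leaves every topology's path union
is the whole spanning subtree, giving the closed form
$\mathrm{cov}_3 = E_3 - E_2^2 = Nw\,(1+Nw)^{-1}(1+2Nw)^{-2}$, and both
integrals are compared against brute-force Monte-Carlo covariance over
annotated three- and four-leaf trees. They scale as $(Nw)^{-2}$ and
$(Nw)^{-3}$, the rates that make the total covariance negligible against
$\Omega$ when $n = o(Nw)$.

**Demography.** Under piecewise-constant $N_h(t)$ the pair moment becomes a
sum of per-epoch exponential integrals, evaluated analytically epoch by
epoch (`e2_right_demography()`, `e2_overlap_demography()`); this is more
stable than blind quadrature near epoch boundaries and is validated against
`stats::integrate` and a Monte-Carlo oracle in the tests. The result is
always sandwiched between the constant-size values at
$N_1 = \max_t N_h(t)$ and $N_2 = \min_t N_h(t)$.

## Standardization

The standardized statistic is the mean-centered **sum** of indicators scaled
by $\Omega^{-1/2}$ where $\Omega = \binom{n}{m} p (1-p)$:

$$ z = \frac{\text{count} - \binom{n}{m} p}{\sqrt{\binom{n}{m} p (1-p)}}. $$

Scaling the *mean* by $\Omega^{-1/2}$ (a reading one could take from a terse
display of the definition) degenerates to zero as $n$ grows; only the sum
form has unit variance under independence and matches the limit statement,
so `standardize()` implements the sum form — stated here prominently because
the two readings differ by the factor $\binom{n}{2}$. For non-constant
demography the standardizing $p$ is the numeric demography moment, not a
plug-in empirical mean, so $z$ remains a statistic of a single replicate.

## Condition diagnostics

`clt_condition_report()` reports $\Omega$, the 3-share covariance total
$\approx n^3\,\mathrm{cov}_3$ and 4-share total
$\approx n^4\,\mathrm{cov}_4/4$ (the asymptotic combinatorial counts of each
class), their ratios to $\Omega$, and the finite-sample size ratios
$Nw/n^2$ (want: small, i.e. many detectable segments) and $n/(Nw)$ (want:
small, i.e. no large IBD clusters). Under varying size the covariances are
evaluated at $N_2$ (their upper bound) and the first ratio at $N_1$.

The third, conditional-covariance condition —
$E[Z_{a,b}\,\bar Z_{-a,b} \mid \bar Z_{-a,b}] \ge 0$ — is not analytically
tractable; `condition3_check()` estimates it by binning replicates on the
leave-one-out sum and averaging the product within bins, merging underfull
bins into a neighbor (logged). iid indicators give flat-zero profiles;
positive dependence gives nonnegative ones.

## The simulation engine

The generator is the package's own single-locus coalescent (continuous time
by default; a discrete-geometric variant exists for checking the
continuous-time approximation). The detectable-segment enumerator is exact,
not a heuristic: processing the tree bottom-up, each node carries
`(leaf, L, R)` running path minima, pruned by the detection criterion —
valid because extents only shrink toward the root — and every tuple is
emitted once, at its MRCA. Its output is tested for equality against an
independent all-tuples brute-force scan on randomized trees. Expected output
size is small ($E_2 \approx (2Nw+1)^{-1}$ per pair), so the enumeration is
near-linear in practice; the hot path is C++ (Rcpp), as is the union-find
component-feature extraction.

Design choices worth recording:

* **Discrete-time clamp.** The geometric per-generation merger probability
  $\binom{k}{2}/N_h$ exceeds 1 when $k$ is large relative to $N_h$; it is
  clamped at 1 (wait of one generation). Only pairwise marginals are used by
  the formulas, and those are exact under the single-merger scheme. The
  simulator warns when `n_hap` exceeds the smallest epoch size.
* **Epoch-boundary ties** go to the later (more ancient) epoch.
* **Zero-length branches** get crossover distance $+\infty$ (no
  constraint); the tree validator therefore tolerates time ties, although
  the continuous-time simulator never produces them.
* **Seeding.** One master seed; replicate $i$ re-seeds R's RNG with
  `substream_seed(seed, i)`, a fixed integer mixing map staying below
  $2^{31}$. Replicates are therefore reproducible independently of
  execution order or chunking, and battery outputs are byte-identical for a
  given (seed, config) — asserted in the tests.

## Batteries and what the synthetic world does (and does not) establish

`run_feature_battery()` simulates detectable-IBD graphs (an edge per
detectable pair), extracts the five component features — edges, trees of
order 2 and 3, complete components of order $\ge 3$, largest component
size — and applies per-feature Shapiro-Wilk batteries over deterministic,
in-order batches (no shuffling: seed-stable). Zero-variance batches count as
rejections with a warning, because a degenerate distribution is maximally
non-normal. `er_feature_battery()` runs the matched sparse Erdős–Rényi
ensemble, whose edge probability (`er_probability()`) defaults to the
discrete geometric-coalescent sum
$\sum_{t\ge 1} N^{-1}(1-N^{-1})^{t-1}(1+2wt)e^{-2wt}$: at $N_h = 2\times
10^5$, $w = 0.03$ it gives $p = 1.6415\times 10^{-4}$ and reproduces the
reference ensemble means (edges $\approx 1313$, order-2 trees $\approx
353$, order-3 trees $\approx 120$) to a fraction of a percent, whereas the
continuous closed form is about 1.5% high. `two_sample_study()` splits one
shared genealogy's leaves into two fixed halves and batteries the
difference of the two standardized within-half overlap rates.

The defaults of the shipped configurations are the stated study conditions:
threshold $w = 0.03$ Morgans, constant population of $10^5$ diploids,
samples of 2000 diploids (graph batteries) and 5000 diploids (two-sample),
Shapiro-Wilk batches of 500 at level 0.05. Scaled-down replicate counts
(50 and 30 batches) keep the desk runs in minutes; the full-scale studies
(125 000 replicates, populations to $10^7$) are documented as long-running
and are not reproduced at desk scale.

What a green battery establishes: that *this* generative model — neutral
single-locus coalescent, no interference, infinite chromosome, exact
detection at threshold $w$ — produces the claimed distributional behaviour.
What it does not establish: behaviour under detection error of real IBD
callers, gene conversion, crossover interference, selection, or genome-wide
dependence between loci; none of these are modeled. Because reference
ensembles for the IBD graphs were produced by an external generator whose
discretization details are not public, IBD edge-count and tree-count means
are compared *directionally* against the matched Erdős–Rényi ensemble (IBD
edges overdispersed, more order-2 trees, smaller largest component), while
our continuous-time means sit a few percent above the reference IBD row —
the expected direction, since the discrete-time pair probability is
strictly below the continuous one. One published reference cell, the
Erdős–Rényi "complete components" mean, cannot be reconciled with counting
isolated cliques at the matched $p$ (the literal expectation is
$\approx 0.05$, and our simulations produce 0); the package implements the
literal clique-count definition and excludes that cell from acceptance.

## Numerical and degenerate-input policy

* Quadrature: relative tolerance $10^{-8}$, integration capped where the
  integrand reaches $e^{-45}$ — keeps `cov4_right()` positive through the
  $E[\text{joint}] - E_2^2$ cancellation up to $Nw = 10^4$.
* `shapiro_battery()` requires $3 \le$ batch size $\le 5000$ (the test's
  own domain); batches are consecutive index ranges.
* `upper_bound_study()` pools all complete batches for the empirical
  percentile (type-7 quantile) and divides the averaged per-batch
  mean-plus-$k$-SD bound by it; $k \in \{3, 4\}$ pairs with the 99.86501 and
  99.99683 percentiles ($100\,\Phi(k)$).
* Empty graphs report `largest = 1` (an isolated node), 0 for all counts.
* `er_probability()`'s geometric series is summed in closed form and
  verified against direct partial summation in the tests.

## Known limitations

* Single locus only: no ancestral recombination graph, no genome-wide scan.
* The discrete-time model ignores simultaneous multi-mergers, so only its
  pairwise marginals are exact at small $N_h$.
* Multi-way enumeration is exponential in $m$ through candidate-list
  combinations; intended for $m \ll n$ (tested to $m = 4$).
* Unequal-size two-sample theory is not implemented (only conjectured in
  the literature); `multi_sample_rates()` requires equal subsets.
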