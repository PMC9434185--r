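---
title: "Coestimating crossover and gene conversion from diploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coestimating crossover and gene conversion from diploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhogc)
```

## The model

Recombination happens by two mechanisms: crossover (CO), a reciprocal
exchange that separates everything on either side of the break point, and
gene conversion (GC), the non-reciprocal copying of a short tract from one
chromatid to the other. LD-based estimators that only model CO fold the GC
signal into a distance-dependent bias. `rhogc` coestimates both, plus the
mean GC tract length, from a single unphased diploid genome (or several
pooled), using only the positions of heterozygous sites.

For one diploid and a pair of sites $d$ bp apart, the observable is the
zygosity state: $H_0$ (neither site heterozygous), $H_1$ (exactly one),
$H_2$ (both). Under a neutral Wright–Fisher model with scaled per-site
mutation rate $\theta = 4N\mu$ and total scaled recombination rate $\rho$
between the sites,

$$
\mathbb{E}[H_0] = \frac{1 + \Delta\theta}{(1+\theta)^2},\qquad
\mathbb{E}[H_2] = \frac{\theta^2 + \Delta\theta}{(1+\theta)^2},\qquad
\mathbb{E}[H_1] = 1 - \mathbb{E}[H_0] - \mathbb{E}[H_2],
$$

where the zygosity correlation

$$
\Delta(\theta,\rho) =
\frac{\theta\,(18 + \rho + 18\theta + \rho\theta + 4\theta^2)}
     {18 + 13\rho + \rho^2 + 54\theta + 40\theta^2 + 8\theta^3
      + \rho(\rho\theta + 19\theta + 6\theta^2)}
$$

measures the excess of $H_0$ and $H_2$ over the independence products that
tight linkage induces. $\Delta$ decreases strictly in $\rho$, from
$\theta/(1+2\theta)$ at complete linkage to $0$ at free recombination
(`zygosity_correlation()`, `two_locus_probs()`).

A conversion tract recombines the two sites only when it covers exactly one
of them. With CO rate $\kappa = 4Nc$ per bp, GC initiation rate
$\gamma = 4Ng$ per bp and exponentially distributed tract lengths with mean
$L$,

$$
\rho(d) = \kappa d + 2\gamma L\,\bigl(1 - e^{-d/L}\bigr),
$$

so the per-bp rate $\rho(d)/d$ decays from $\kappa + 2\gamma$ between
adjacent sites to $\kappa$ at large $d$ (`rho_total()`). This decay *is*
the signal that separates the three parameters.

Counting, for every distance $d$, the pairs $n_{d,0}, n_{d,1}, n_{d,2}$ in
each state gives a per-distance trinomial log-likelihood, and summing over
distances the composite likelihood

$$
\ln \mathrm{CL}(\kappa,\gamma,L)
 = \sum_{d=d_{\min}}^{d_{\max}} \sum_i n_{d,i} \ln \mathbb{E}_d[H_i],
$$

maximised by `fit_chromosome()`. Pairs are heavily reused and shared
between individuals, so this is a composite, not a true, likelihood: point
estimates are consistent in practice, but the curvature must not be read as
Fisher information. Uncertainty comes from `parametric_bootstrap()`.

$\theta$ is not coestimated: it is plugged in from the observed
heterozygous fraction via $\theta = H/(1-H)$ (`marginal_het()`,
`theta_from_het()`), per chromosome. This mirrors how the estimator is
meant to be used, keeps the optimisation 3-dimensional, and makes the
estimates of $\kappa/\theta$, $\gamma/\theta$ robust to proportional
rescaling of the population size. Note one pitfall we encountered in
testing: for data dominated by few independent genealogies the *realised*
diversity can sit far from any externally supplied $\theta$, and the fit
then misreads the discrepancy as recombination — always plug in the
heterozygosity observed in the analysed intervals themselves.

## Counting pairs

`prepare_intervals()` implements the interval policy for intronic scans:
drop intervals of length $\le$ `min_len` (default 1000 bp, strict) and
keep only the first `dmax` bases of each survivor (default 1000 bp,
5'-aware when a strand column is present). Truncation stops very long —
selectively atypical — introns from dominating the counts.

`count_pairs()` turns per-individual heterozygous positions into the
per-distance tables. Pairs never span two intervals. For each interval and
distance, $n_2$ counts het–het pairs by sorted-difference tabulation, the
mixed count comes from rank arithmetic
($n_1 = B - 2n_2$, where $B$ sums, over het sites, the in-interval
indicators of partners at $\pm d$), and $n_0$ is the remainder of the
$N_d = \sum_\text{intervals} \max(0, \ell - d)$ available pairs. All sites
inside the intervals absent from the VCF are treated as homozygous —
callability of the input region is the user's responsibility. The
implementation is validated against an exhaustive $O(\ell \cdot d_{max})$
enumeration oracle on randomised small instances. An empty het set returns
the pure-$H_0$ table rather than nothing, which keeps pooling identities
exact.

Pooling across individuals (`pool_counts()`) sums tables; the composite
likelihood deliberately ignores the non-independence from shared ancestry,
which is one more reason to bootstrap rather than invert curvature.

## Distance thresholds

Defaults are $d_{\min} = 100$ and $d_{\max} = 1000$. Real short-distance
rows are contaminated by variant-calling artefacts (clustered-SNP filters,
complex mutations), which depress $\hat\rho$ below ~50 bp; $d_{\min}$
excises them at the cost of some GC information. $d_{\max}$ matches the
interval truncation. Count tables are always built on the full grid
$d \in [1, d_{\max}]$ and thresholds applied at fit time, so one table
serves any $d_{\min}$ sensitivity sweep. On simulated data, where no
artefacts exist, fitting from $d_{\min} = 1$ uses all the signal and is
what the recovery experiments do.

## Optimisation

The composite likelihood has a pronounced curved ridge: $\kappa$ trades
off against $\gamma$ and $L$, and $\gamma$ against $L$ (visible with
`cl_surface()`; both ridge correlations are negative). When
$d_{\min} \gg L$ the data constrain mainly the product $2\gamma L$, so the
surface flattens along $\gamma L = \text{const}$ and estimates can run
along it under noise. The optimiser therefore works on $\log_{10}$
parameters inside the box $\kappa,\gamma \in [10^{-8}, 1]$,
$L \in [1, 10^5]$ with:

* 8 Latin-hypercube starting points (`lhs`), plus one start on the
  crossover-only boundary ($\gamma$ at its lower bound, $\kappa$ from a
  1-D fit) so the nested CO-only solution is always reachable;
* Nelder–Mead with relative tolerance $10^{-12}$, restarted at the
  incumbent until the composite likelihood is stable to $10^{-10}$
  relative;
* a final bounded quasi-Newton (`L-BFGS-B`) polish. The simplex alone
  stalls roughly $10^{-5}$ above the optimum on these surfaces, which is
  enough to violate model nesting numerically; the polish restores
  $\ln\mathrm{CL}_{\text{3-par}} \ge \ln\mathrm{CL}_{\text{CO-only}}$ to
  machine precision.

Ties between starts break by composite likelihood, then by smaller $L$,
for determinism. Convergence status, restart counts and bounds are kept in
the returned object (`glance()`).

The per-distance profile (`fit_rho_profile()`, the diagnostic that shows
the GC decay directly) does not use a likelihood search at all: with
$p_1 = 2\theta(1-\Delta)/(1+\theta)^2$ the trinomial score in $\Delta$ is
strictly decreasing, so the single-distance MLE solves a bounded 1-D root
problem in $\Delta$ and maps back to $\rho$ through the inverse of the
rational correlation function (a quadratic in $\rho$). This reaches machine
precision where golden-section search on the raw likelihood hits the
floating-point noise floor of the big log-likelihood sums (~$10^{-4}$
relative error at short distances).

The joint multi-chromosome fit (`fit_joint_shared_L()`) exploits
separability: given $L$, chromosomes decouple into independent 2-parameter
fits. The outer problem is a 1-D profile over $\log_{10} L$ — a coarse
24-point grid followed by Brent refinement of the bracketed maximum — with
inner fits warm-started between neighbouring $L$ values and fully
multi-started + polished only at the final $\hat L$. This turns a
$2K{+}1$-parameter problem into seconds per chromosome.

## Synthetic data and what it does (not) show

`expected_counts()` is the model's deterministic twin
($n_{d,i} = N_d\,\mathbb{E}_d[H_i]$); fitting it back must recover the
generating parameters, and does so to $\lesssim 10^{-4}$ relative — this
is the main correctness check of the estimator, independent of any
simulator. `sample_counts()` adds seeded trinomial noise for power
experiments.

`simulate_genomes()` runs a neutral constant-size coalescent with CO and
GC (msprime through Python; the package degrades with a clear error when
the engine is absent, and the multinomial mode covers everything else).
Only scaled parameters matter; internally a reference diploid size
$N_e = 10^4$ sets $\mu = \theta/4N_e$, $c = \kappa/4N_e$,
$g = \gamma/4N_e$, recorded in the output metadata. The default mutation
model is the engine's finite-sites default: recurrent mutation can mask a
heterozygous site, which biases short-distance $\hat\rho/d$ slightly
upward relative to the infinite-sites expectations; an
`infinite_alleles` option is exposed for bias-free estimator tests. The
recovery experiments here use the default and absorb the small bias within
their stochastic tolerance.

What the simulations emulate: pooled counts across 10 unphased diploids,
intronic-scale interval lengths, mouse-like diversity
($\theta \approx 0.0071$; note that a typo-prone alternative reading
$\theta = 0.071$ circulates for the same data set — this package treats
0.0071 as the working value throughout). What they do not emulate:
sequencing error and filtering artefacts (the reason $d_{\min} = 100$
exists), demographic non-equilibrium (bottlenecks, growth, admixture,
structure — all known to bias LD-based recombination estimates), and
fine-scale rate variation. Passing recovery tests on these simulations
therefore validates the estimator under its own assumptions, not the
assumptions themselves.

One subtlety worth keeping: the zygosity correlation is an *ensemble*
property over genealogies. A single non-recombining simulated block is one
genealogy, under which sites are independent Poisson mutations and no
$H_2$ excess need appear. The "no recombination implies maximal
correlation" expectation is only realised after pooling many independent
blocks, which is how the corresponding test is built.

## Problem sizes used in the shipped experiments

Chosen as the smallest sizes at which the checks are statistically clean:
noise-free self-consistency at $N_d = 10^6$ per distance; the
19-chromosome shared-$L$ joint fit at $N_d = 2\times10^5$; coalescent
recovery with 10 diploids $\times$ 5 Mb $\times$ 3 seeds; bootstrap
power comparisons with 12 replicates at 1 Mb per individual. The
full-scale analyses the package targets (whole-genome intronic scans) are
larger by one to two orders of magnitude but change nothing structurally.

## Degenerate inputs and numerical choices

* $\theta = 0$ returns the exact state distribution $(1,0,0)$ by a guarded
  branch, avoiding $0/0$ in $\Delta$.
* $\Delta$ is evaluated exactly as the rational function is written, in
  double precision, with no rearrangement — the regime of use
  ($\theta < 0.1$, $\rho < 10^4$) is benign and this keeps results
  reproducible against the formula.
* $1 - e^{-d/L}$ uses `expm1`, which matters for $d \ll L$ where the GC
  signal lives.
* $0\cdot\ln 0 = 0$: empty rows and zero counts contribute nothing; a
  positive count on a zero-probability state yields $-\infty$, never an
  exception, so optimisers treat it as a rejected point.
* Distances are integer bp, differences of 0-based positions; intervals
  are 0-based half-open throughout (BED convention).
* Fractional (expected) tables tolerate $10^{-9}$ relative slack in the
  row-sum invariant; integer tables must satisfy it exactly.

## Known limitations

The method needs large amounts of sequence: the rarest state $H_2$ has
frequency of order $\theta^2$, so windowed estimates (say 100 kb) are out
of reach. Composite-likelihood curvature is not usable for standard
errors. Demographic non-equilibrium biases estimates in ways the model
cannot see (growth mimics GC with short tracts; old admixture hides GC).
The infinite-sites mutation assumption slightly inflates short-distance
estimates for highly heterozygous genomes. Finally, when
$d_{\min} \gg L$, $\gamma$ and $L$ are identified mainly through their
product; report and interpret $2\gamma L$ in that regime.
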