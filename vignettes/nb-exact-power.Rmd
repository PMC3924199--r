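---
title: "Power and sample size for RNA-seq with the NB exact test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and sample size for RNA-seq with the NB exact test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

RNA-seq read counts from biological replicates are routinely overdispersed
relative to the Poisson: the variance exceeds the mean. `nbseqpower` models
the (pseudo)count of a gene in sample $j$ of group $i$ as negative binomial,

$$Y_{ij} \sim \mathrm{NB}(d_{ij}\gamma_i,\ \phi),\qquad
\mathbb{E}Y = \mu,\quad \mathrm{Var}\,Y = \mu(1 + \mu\phi),$$

where $\gamma_i$ is the normalized expression level of group $i$, $d_{ij}$
a per-sample normalization factor for sequencing depth, and $\phi \ge 0$ the
dispersion ($\phi = 0$ recovers the Poisson, which the package treats as an
explicit branch rather than a limit, so near-Poisson designs estimated from
technical replicates are numerically stable).

Within a group the per-sample laws are approximately identical, so the
group sum $Y_i = \sum_j Y_{ij}$ is again negative binomial,
$Y_i \sim \mathrm{NB}(n_i d_i^{*}\gamma_i,\ \phi/n_i)$, with $d_i^{*}$ the
geometric mean of the group's normalization factors. Differential
expression between a control group (mean count $\mu_0 = d_0^{*}\gamma_0$
per sample) and a treatment group is the test of $\gamma_1 = \gamma_0$
against a two-sided alternative with fold change $\rho = \gamma_1/\gamma_0$;
the depth imbalance between groups enters only through
$w = d_1^{*}/d_0^{*}$.

### The exact test

Conditional on the total $s = y_1 + y_0$, the null distribution of the
treatment sum is

$$q_a = \frac{P(Y_1 = a)\,P(Y_0 = s-a)}
{\sum_{b=0}^{s} P(Y_1 = b)\,P(Y_0 = s-b)},\qquad a = 0,\dots,s,$$

and, in analogy with Fisher's exact test, the two-sided p-value sums the
conditional probabilities of all outcomes no more likely than the observed
one ("small probabilities" rule). All probability arithmetic is in log
space with log-gamma; the conditioning sum is finite, so it is enumerated
exactly, never truncated. A relative tie tolerance of $10^{-7}$ groups
outcomes whose conditional probabilities are analytically equal (the
symmetric $w = 1$ case produces exact ties that floating arithmetic would
otherwise split). The doubled-smaller-tail rule is available behind
`rule = "doubletail"` for sensitivity analysis; across the design grids
shipped in the tests the two rules give identical or ±1 sample sizes.

### Exact power and the sample-size solvers

The power of the level-$\alpha$ test under fold change $\rho$ is the double
sum over outcome pairs,

$$\xi(n, \rho, \mu_0, \phi, w, \alpha) =
\sum_{y_0}\sum_{y_1} f_{nw\rho\mu_0,\,\phi/n}(y_1)\,
f_{n\mu_0,\,\phi/n}(y_0)\, \mathbb{1}\{p(y_1,y_0) < \alpha\},$$

which `nb_power()` organises by total $s$: one conditional distribution per
total, its rejection set, then the joint alternative mass of that set. This
O($S^2$) arrangement is what makes the deep designs (e.g. $n \approx 280$
at $\mu_0 = 1$) run in seconds where per-pair evaluation would not. The
marginals are truncated at `nb_tail_bound()` with tail mass
$\varepsilon/2$ each ($\varepsilon = 10^{-10}$ by default); since the
indicator is bounded by 1 the absolute truncation error is at most
$\varepsilon$, far below the print precision of any tabulated quantity.
The rejection indicator uses the strict inequality $p < \alpha$.

`nb_sample_size()` inverts $\xi$ in the integer $n$: power is evaluated at
$n = 2$, the bracket is doubled until the target is met, bisection narrows
it, and a final evaluation at $n - 1$ certifies minimality. Bisection
rather than a gradient scheme because the curve is discrete, empirically
monotone but stair-stepped: rejection regions change discontinuously with
$n$. The solver never returns $n < 2$ (dispersion estimation and the
pseudo-sum model need replication), and raises a typed
`"nbss_unachievable"` error carrying the power at `n_max` when the target
cannot be met.

### FDR-controlled multi-gene designs

For $m$ simultaneous tests with $m_1$ truly differentially expressed
("prognostic") genes, controlling the FDR at $f$ while expecting $r_1$
true rejections fixes the per-test level through
$f = m_0\alpha/(m_0\alpha + r_1)$, i.e.

$$\alpha^{*} = \frac{r_1 f}{m_0(1-f)},\qquad
\beta^{*} = 1 - r_1/m_1,\qquad m_0 = m - m_1 .$$

`nb_sample_size_fdr()` then either solves the single-gene problem at
$(\alpha^{*}, 1-\beta^{*})$ using a conservative parameter triple — the
fold change with the smallest $|\log_2\rho|$, the minimum control mean, the
maximum dispersion, so the returned $n$ bounds the per-gene answer from
above — or, when per-gene parameters are available, finds the smallest $n$
with $\sum_{g} \xi(n, \rho_g, \mu_{0g}, \phi_g, w, \alpha^{*}) \ge r_1$.
A tie in $|\log_2\rho|$ (e.g. 4 vs 0.25) is broken toward the fold change
below 1, purely for determinism. A single common $w$ is used throughout;
per-gene normalization ratios are not modelled.

## Pilot estimation

`pilot_fit()` turns a pilot count matrix into design inputs:

* **Filtering.** Genes must exceed `min_total` (default 5) reads in each
  group separately.
* **Normalization.** Trimmed mean of M-values (30% M trim, 5% A trim,
  reference sample chosen by upper quartile) via edgeR, rescaled so the
  effective factors $d_{ij}$ have geometric mean 1; a plain library-size
  mode is available for testing. Note a consequence of the geometric-mean
  constraint: rescaling one sample's column rescales every $\mu_{0g}$ by
  the same $c^{1/N}$ while fold changes are untouched.
* **Per-gene estimates.** $\mu_{0g}$ is the mean normalized control count;
  $\rho_g$ the ratio of normalized group means, with a +0.5 continuity
  offset to both means when either is zero (bounded, deterministic fold
  changes for genes absent in one group); $\phi_g$ a per-gene profile
  maximum-likelihood estimate floored at 0. The quantile-adjusted
  conditional ML machinery of edgeR is deliberately not reproduced — the
  design only needs order statistics of the per-gene estimates, and plain
  ML is transparent and testable.
* **Pooled dispersion.** A single $\hat\phi$ maximizing the summed
  per-group conditional log-likelihoods (each group's counts given their
  group total), which eliminates the gene means and collapses, after
  tabulating distinct counts, to a handful of log-gamma evaluations per
  candidate $\phi$.
* **Prognostic set.** The $\lceil \text{proportion} \times m \rceil$ genes
  with smallest exact-test p-values; ties break by larger $|\log_2\rho_g|$,
  then identifier. The ceiling convention is a deterministic choice where
  "top $\approx$ 1%" is otherwise ambiguous.

## The validation harness

`run_validation()` rehearses the whole analysis at a proposed design.
Each replicate draws $m$ independent NB genes — control mean $\mu_0$,
treatment mean $w\rho\mu_0$ for the $m_1$ prognostic genes and $w\mu_0$
for the null genes ($w$ emulates a depth imbalance and therefore scales
every treatment mean; $w = 1$ gives the symmetric setting) — then
estimates TMM factors and $\hat w$, a pooled conditional-likelihood
dispersion, computes exact-test p-values of the group sums (genes sharing
a total share one conditional distribution, which is what keeps 500
replicates of $m = 10^4$ genes to a couple of seconds each), and rejects
at Storey q-value $\le f$ with $\hat\pi_0$ at $\lambda = 0.5$, capped at 1
and floored at $1/m$ so a degenerate $\hat\pi_0 = 0$ cannot reject
everything by fiat. Replicate $r$ uses an RNG stream keyed by
`(seed, r)`, so results are bitwise reproducible and replicates are
independent.

What the generator emulates — independent genes, a common dispersion, a
single fold change, equal library sizes up to $w$ — is exactly the
homogeneous setting of the design formulas. Real data have correlated
genes, dispersion that varies with abundance, and heterogeneous effects;
passing validation here shows the machinery is internally consistent, not
that any particular experiment will achieve nominal power. The
conservative triple is the design-side hedge against that heterogeneity.

Two honest caveats surfaced by the package's own checks. First, the
achieved true rejections of the harness at the tabulated reference cell
($m = 10^4$, $m_1 = 100$, $\log_2\rho = 1$, $\phi = 0.1$, $\mu_0 = 5$,
$f = 5\%$, $n = 20$) centre a few counts below the historical reference
value; running today's edgeR in place of this package's test reproduces
our number, not the historical one, so the difference lies in decade-old
software behaviour rather than in this implementation. Second, integer
sample sizes within ±1 of tabulated values (and one deeper discrepancy in
one published application table that no parameter reading we tried
reproduces) should be expected when comparing against solvers that
accepted near-target power; this solver certifies strict minimality
instead.

## Problem sizes and defaults

The shipped tests exercise: oracle equivalence of p-values up to totals of
30 over a model grid; power against a naive double loop on small grids
($n\mu_0 \le 50$); the solver's bracketing certificate on every returned
$n$; moment recovery of the generator at $10^5$ draws; parameter recovery
at $n = 100$ per group; and the validation harness at 500 replicates of
the $m = 10^4$ reference cell (the Monte Carlo standard error of
$\hat r_1$ is then about 0.25 true rejections). Defaults worth knowing:
truncation $\varepsilon = 10^{-10}$; tie tolerance $10^{-7}$; q-value
$\lambda = 0.5$; prognostic proportion 1%; `n_max = 10000`; the
small-probabilities rule everywhere.
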