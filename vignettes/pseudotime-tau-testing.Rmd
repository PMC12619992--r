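---
title: "Testing differential expression along pseudotime with the sign covariance tau-star"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential expression along pseudotime with the sign covariance tau-star}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotau)
```

## The problem and the model

After a single-cell RNA-seq trajectory analysis assigns each cell a
pseudotime — a scalar ordering cells along a developmental process — the
next question is which genes change along that ordering. Regression-based
answers model expression as a function of pseudotime; `pseudotau` instead
treats the question as what it literally is: a test of *independence*
between the pseudotime $X$ and the expression $Y_g$ of each gene, both
viewed as random variables over cells.

The test statistic is the Bergsma–Dassios sign covariance $\tau^*$, a
quartet-based extension of Kendall's tau with the property that
$\tau^* \ge 0$ always and $\tau^* = 0$ *if and only if* $X$ and $Y_g$ are
independent. It is estimated by the U-statistic

$$\tau^*_n = \frac{(n-4)!}{n!} \sum_{i,j,k,l\ \text{distinct}}
  a(X_i, X_j, X_k, X_l)\, a(Y_{gi}, Y_{gj}, Y_{gk}, Y_{gl}),
\qquad
a(z_1,z_2,z_3,z_4) = \mathrm{sign}\left(|z_1-z_2| + |z_3-z_4| - |z_1-z_3| -
|z_2-z_4|\right).$$

The kernel $a$ classifies four points on the line: it is $+1$ when
$\{z_1,z_3\}$ and $\{z_2,z_4\}$ are strictly separated (one pair entirely
below the other), $-1$ when $\{z_1,z_2\}$ and $\{z_3,z_4\}$ are, and $0$
otherwise. This characterization is not just intuition — it is how the
package *evaluates* the kernel, because the naive absolute-value expression
is an exact mathematical zero for the two unseparated pairings of any
quartet, and floating-point rounding of that zero would otherwise inject
spurious $\pm 1$s. Being a function of ranks only, $\tau^*_n$ is invariant
under strictly increasing transformations of either margin, so it is
insensitive to normalization choices that preserve order.

Because the statistic is estimated without modelling how expression depends
on pseudotime, it detects monotone, unimodal, switch-like, or any other
dependence shape, at the cost of some power against purely monotone
alternatives compared to a test specialized for them.

## Exact computation at three costs

Grouping the ordered quadruples of the U-statistic by their underlying
4-subset shows that each subset contributes $+16$ when the *same* pair
split is strictly separated in both margins (a *concordant* quartet),
$-8$ when *different* splits are separated in the two margins
(*discordant*), and $0$ otherwise, giving
$\tau^*_n = (16 N_c - 8 N_d) / n(n-1)(n-2)(n-3)$. The three tiers all
compute this exactly:

* `tau_star_brute()` sums the defining formula over all ordered quadruples
  in $O(n^4)$; it exists to be the oracle the other tiers are tested
  against.
* `tau_star_pairwise()` counts, for every pair of cells, how many partner
  pairs complete a concordant or discordant quartet with it, using Fenwick
  trees over expression ranks for the dominance counts; $O(n^2 \log n)$,
  exact under arbitrary ties in both margins. A subtlety worth recording:
  a candidate partner pair with *equal* expression values can never
  complete a discordant quartet (the mixed split cannot be strictly
  separated), so the counting structure also tracks within-level pair
  counts to subtract them.
* `tau_star_fast()` is the production path. Cells are sorted by pseudotime
  (assumed tie-free; see below), after which the pseudotime-separated
  split of any quadruple of positions $i<j<k<l$ is always
  $\{i,j\}|\{k,l\}$. Concordant quadruples are counted by about $4M$
  linear threshold sweeps — the $O(Mn)$ core step, where $M$ is the number
  of unique expression values — while the total number of
  expression-separated quadruples depends only on the level multiplicities
  and costs $O(M)$. Sparse scRNA-seq genes have $M \ll n$, which is what
  makes the near-linear total $O(n \log n + Mn)$ possible.

Counts are accumulated as integers in double precision and divided once at
the end, so for integer-valued margins the result is a ratio of exact
integer counts whenever those counts stay below $2^{53}$ (n up to several
thousand), and within $\sim 10^{-15}$ relative error beyond.

Ties in *pseudotime* are rare (inferred pseudotime is continuous) but
possible. The fast path never approximates: when it detects tied
pseudotime it delegates to the pairwise tier with a message, which handles
ties exactly.

## The asymptotic null and p-values

Under independence the first projection of the (symmetrized) kernel
vanishes, so $\tau^*_n$ is a degenerate U-statistic and $n\,\tau^*_n$
converges to a centered quadratic form in independent standard normals.
For this kernel the second projection factorizes over the margins. Writing
$\phi(s,t)$ for the difference between the probability that the split
pairing $s$ and $t$ *across* two independent copies is strictly separated
and the probability that the split pairing them *together* is, one obtains

$$h_2 = \tfrac{2}{3}\,\phi_X(x_1,x_2)\,\phi_Y(y_1,y_2),
\qquad\text{hence}\qquad
n\,\tau^*_n \;\xrightarrow{d}\; 4 \sum_{u,v} \alpha_u \beta_v\,(Z_{uv}^2-1),$$

where $\alpha_u$ and $\beta_v$ are the eigenvalues of the $\phi$ integral
operator on the pseudotime and expression margins. This product structure
is what makes a tie-adapted null practical:

* an expression margin with $M$ levels contributes an *exact* $M\times M$
  kernel matrix built from the level probabilities (the kernel depends on
  the margin only through its CDF), so sparse genes get an exactly
  tie-adapted null;
* a tie-free pseudotime margin is rank-equivalent to Uniform(0,1) and is
  handled once by Nyström midpoint quadrature with $K = 256$ nodes (the
  eigenvalues decay like $u^{-2}$; $K$ is far past the point where the
  retained spectrum is stable), with the constant function projected out
  to enforce the exact degeneracy the quadrature slightly breaks.

Two finite checks on this derivation are built into the test suite: for
Bernoulli(½) margins the law collapses to the single hand-computable
coefficient $\tfrac14(Z^2-1)$, and at $n$ in the thousands the permutation
distribution of $n\,\tau^*_n$ matches the derived law in variance and
upper quantiles.

The one-sided upper-tail p-value $P(\text{limit} \ge n\,\tau^*_n)$ — upper
because the population $\tau^*$ is nonnegative and zero exactly at
independence — is evaluated deterministically: Gil-Pelaez
characteristic-function inversion in the body of the distribution, with a
Lugannani–Rice saddlepoint taking over when the inverted value falls below
$10^{-4}$ or the observed statistic sits more than 8 standard deviations
into the tail, where the oscillatory integral is cancellation-limited. The
~100 largest coefficients $4\alpha_u\beta_v$ are kept exactly; the many
small remaining terms are absorbed into a Gaussian component with their
summed variance, a central-limit substitution whose variance share is
negligible. Below the saddlepoint's representable range p-values are
floored at $10^{-300}$ rather than returned as 0.

Null distributions are memoized across genes keyed by $(n,$ level
probabilities quantized to $10^{-4})$, and the null is *built from* the
quantized profile so the cache key identifies the law exactly. A
permutation null (`build_null_permutation()`, add-one p-value estimator)
is retained both as a user-selectable mode and as the validation oracle
for the asymptotic route.

## The synthetic benchmark generator

`simulate_null_dataset()` and `simulate_de_dataset()` emulate the features
of trajectory scRNA-seq that this test must survive: zero-inflated
negative-binomial counts with gene-specific mean (log-uniform on
$[0.1, 2]$) and dispersion (NB size uniform on $[0.5, 2]$), 20% extra
zeros, and a Uniform(0,1) pseudotime. These defaults put the median gene
near $M \approx 6$ unique values at $n = 1000$ — the sparse regime. DE
genes (default fraction 0.2) carry a smooth log-mean trend
$\log\mu_g(t) = \log\mu_{0g} + \gamma_g\, s_g(t)$ with $s_g$ drawn equally
among monotone, unimodal and sigmoidal shapes — the non-monotone shapes
are there deliberately, because a quartet statistic must be exercised on
signals a rank correlation would miss — and amplitude $|\gamma_g|$ uniform
on $[0.5, 2.5]$ (up to ~12-fold swings across the trajectory, a realistic
range for developmental genes).

What the generator does *not* emulate: library-size variation, batch
structure, gene–gene correlation, and pseudotime estimation error (the
pseudotime handed to the test is the true one). Passing calibration here
therefore shows the test and its null are correct *given* pseudotime; it
does not address the double-dipping distortion that arises when pseudotime
is inferred from the same counts, which is out of scope.

## Study conditions and numerical choices

The packaged benchmarks run at desk scale: calibration on 2000 null genes
at $n = 1000$ across 10 seeds (KS uniformity of raw p-values, expected to
pass in at least 8), FDR/power on 500 genes with 20% DE at $n = 1000$
(Benjamini–Hochberg at 0.05; empirical FDR at or below 0.10 and power at
least 0.5 on the strongest-effect tercile), runtime scaling measured at
fixed $M = 8$ over $n \in \{1000, 4000, 16000\}$ for the fast path (log–log
slope below 1.4) against $n \in \{1000, 2000, 4000\}$ for the pairwise
tier (slope near 2), and asymptotic-vs-permutation agreement within 0.03
on 50 null genes. `scripts/acceptance.R` re-runs the calibration study
from scratch and reports the median KS p-value and the mean $\tau^*$
across null genes.

Other decisions a maintainer should know:

* **Filtering.** Genes constant across cells carry no information
  ($\tau^*_n \equiv 0$) and are reported untested with reason `"constant"`;
  genes with fewer than `min_nonzero_cells = 3` nonzero cells are reported
  `"too sparse"`. Rows are never dropped, so output row count equals input
  gene count.
* **Alignment.** Cells are matched by identifier whenever both inputs
  carry identifiers; positional alignment is used otherwise and warned
  about, since silent misalignment is the classic failure mode of this
  kind of pipeline.
* **Determinism.** Asymptotic mode contains no randomness; permutation
  mode derives one seed per gene from the run seed, so results are
  identical for any thread count.
* **Sidedness.** Only the right tail is tested; a large negative
  $n\,\tau^*_n$ is evidence of nothing under this alternative family.
* **Known limitations.** No covariate adjustment (depth, batch): confounders
  must be removed upstream, and a conditional form of the sign covariance
  would be needed to handle them natively. P-values for genes with very
  few distinct values at small $n$ inherit the discreteness of the
  statistic and are conservative rather than exact. The asymptotic null is
  an $n \to \infty$ law; below a few hundred cells the permutation mode is
  the safer choice.
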