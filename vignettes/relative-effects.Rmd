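---
title: "Rank-based relative effects: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based relative effects: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvrelef)
```

## The statistical problem

Two experimental groups A and B (say, controls and cases) are observed
on $d$ numeric coordinates per subject. In the motivating application
the coordinates are DNA-methylation $\beta$-values at $d$ CpG loci:
bounded in $[0,1]$, frequently skewed or bimodal, and dependent across
loci both through genomic proximity (co-methylation decaying with
distance) and through shared cell-type composition. Parametric models
for such data are hard to justify, and coordinate-wise testing without
a dependence-aware multiplicity correction either inflates the
family-wise error rate (FWER) or, with Bonferroni-type corrections,
wastes power exactly when dependence is strong.

`mvrelef` treats the problem nonparametrically. All subjects are
assumed independent; within each group the $d$-vectors are i.i.d. with
arbitrary (non-degenerate) distributions. Nothing else is assumed — in
particular no continuity, so ties are legitimate data.

## Relative effects and their rank estimator

The effect measure per coordinate is the relative effect
$p^{(\ell)} = P(X_A^{(\ell)} < X_B^{(\ell)}) + \tfrac12 P(X_A^{(\ell)}
= X_B^{(\ell)})$, the probability that a random group-B subject exceeds
a random group-A subject, with ties split evenly; $p^{(\ell)} = 1/2$
means no stochastic tendency. The coordinate hypotheses are
$H_\ell' : p^{(\ell)} = 1/2$ against two-sided alternatives.

`relative_effects()` estimates $p^{(\ell)}$ from pooled mid-ranks:
$\hat p^{(\ell)} = (\bar R_B^{(\ell)} - (n_B+1)/2)/n_A$. Mid-ranks
realize the *normalized* (mid-) empirical cdf, which makes the
estimator well defined on tied data and equal to the pairwise-kernel
double sum $\frac{1}{n_A n_B}\sum_{j,k}\{\mathbb 1(x_{Aj} < x_{Bk}) +
\tfrac12 \mathbb 1(x_{Aj} = x_{Bk})\}$ exactly (the test suite asserts
this equivalence by brute force over small tied samples). The
Mann–Whitney functional is reported with the same $\tfrac12$-tie
kernel, so $\hat u = 1 - \hat p$ identically; the package therefore
keeps two statistic *names* (`relative_effect`, `wmw`, corresponding
to the relative-effect and marginal-homogeneity hypothesis families)
over one numerical engine. The tie convention is a deliberate choice:
an indicator kernel without the tie term would make $\hat u$ and
$1-\hat p$ drift apart on rounded data, and $\beta$-values are rounded
in practice.

## Studentization by placements

The covariance of $\sqrt N(\hat{\mathbf p} - \mathbf p)$ is estimated
from *placements*: the cross-group normalized ecdf transforms
$y_{Ak}^{(\ell)} = \hat F_B^{(\ell)}(x_{Ak}^{(\ell)})$ and vice versa,
computed from rank differences. The estimator is

$$\hat v(\ell, r) = \frac{N}{n_A}\,\hat c_A(\ell,r) +
  \frac{N}{n_B}\,\hat c_B(\ell,r),$$

with $\hat c_i$ the unbiased (divisor $n_i - 1$) sample covariance of
the placement columns in group $i$. The divisor is conventional and
asymptotically irrelevant; $n_i - 1$ was fixed once and not revisited.
Studentization makes the statistic asymptotically pivotal even when
the dependence structure differs between the groups, which is the
well-known obstacle ("null dilemma") to naive permutation inference on
unstudentized statistics.

The global and subset statistics are quadratic forms
$W = N(\hat{\mathbf p}_S - \tfrac12 \mathbf 1)^\top
\hat V_S^{+} (\hat{\mathbf p}_S - \tfrac12 \mathbf 1)$,
referred to $\chi^2$ with $|S|$ degrees of freedom.

**Degenerate covariances.** With constant coordinates, $d \ge N$, or
complete separation, $\hat V_S$ can be singular. The package uses the
spectral (Moore–Penrose) pseudoinverse with eigenvalues below
$10^{-10} \cdot \lambda_{\max}$ treated as zero, and the numerical
rank as *effective* degrees of freedom of the $\chi^2$ reference. Flat
directions are thereby projected out rather than inverted, keeping the
statistic defined and conservative; a rank-0 submatrix yields
statistic 0 with $p = 1$ ("no evidence computable"), never an
exception — permutations with degenerate covariance must stay in the
null set, since dropping them would bias permutation p-values.

## Permutation calibration

The $\chi^2$ approximation of $W$ converges slowly and from the
liberal side: in the simulations below its type-I error reaches 21% at
$d = 10$ with $n_A = 20$, $n_B = 30$. The package therefore calibrates
$W$ against the distribution of studentized statistics recomputed on
random relabellings of the pooled sample into pseudo-groups of sizes
$n_A$ and $n_B$ (`permutation_plan()`: $B$ uniform random
permutations, drawn with replacement, plus the identity).

For a permutation $\pi$, let $\tau$ be the fraction of original
group-B subjects among the first $n_A$ positions. The permuted
estimate $\hat{\mathbf p}^\pi$ is conditionally centered not at
$\tfrac12$ but at the mixture
$c(\tau) = \tau(1 + n_A/n_B)\tfrac12 \mathbf 1 +
(1 - \tau(1+n_A/n_B))\,\hat{\mathbf p}$
(`permutation_centering()`), and the asymptotic theory shows that the
permutation distribution of the $c(\tau)$-centered studentized
quadratic form converges to $\chi^2_{|S|}$. Under that *estimated*
centering the identity permutation's statistic is exactly 0.

**Choice of centering (a genuinely open design point).** The package
implements both centerings and defaults to `center = "null"`, which
centers every permuted statistic at the hypothesized value $\tfrac12$
— the fixed point of the mixture under the tested hypothesis:

* Under marginal homogeneity ($P = Q$) the null-centered permuted
  statistic is a pure function of the relabelled data, so the
  resulting Monte-Carlo permutation test is *finite-sample exact*
  (p-values are super-uniform for any $N$ and $B$).
* In our Model-1 experiments at $n_A = 20$, $n_B = 30$, the
  estimated-centering variant is measurably anti-conservative
  (empirical type-I error up to about 0.07 at the 5% level at
  $d = 5$, $\rho = 0.4$), because the centering itself is estimated
  with $O_p(N^{-1/2})$ error of the same order as the quantity being
  centered. The null-centered variant stays at or below the nominal
  level in the same settings, matching the operating characteristics
  published for this class of tests.
* Both variants share the same asymptotics under the tested null;
  under $H_S'$ the tested subvector of $\hat{\mathbf p}$ converges to
  $\tfrac12\mathbf 1$, so the two centerings coincide in the limit.

`center = "estimated"` remains available (and is what
`permuted_statistic()`'s identity-zero property refers to); the
distributional convergence tests in the suite exercise it explicitly.

**p-value convention.** For a plan of $B$ random permutations plus the
identity, $p = (1 + \#\{\pi : W^\pi \ge W_{\mathrm{obs}}\})/(B+1)$,
counting only the random draws in the exceedance and the identity slot
as the guaranteed $+1$. This keeps $p \in (0, 1]$ with granularity
$1/(B+1)$, is valid for permutations drawn with replacement, and never
returns 0. Rejection uses $p \le \alpha$. A plain numeric vector
passed to `permutation_pvalue()` is instead treated as a complete null
distribution with a direct exceedance count.

## Closed testing

`closed_test()` tests every non-empty $H_S'$ at full level $\alpha$
with the subvector statistic and rejects coordinate $\ell$ iff every
$S \ni \ell$ is rejected; the adjusted p-value of $\ell$ is
$\max_{S \ni \ell} p_S$, the smallest FWER level at which $\ell$ would
be rejected. Two implementation decisions:

* **One shared permutation plan for all $2^d - 1$ subsets.** This cuts
  the permutation work by a factor $2^d$ and induces positive
  dependence among subset p-values, which the closure tolerates (it
  needs each $\varphi_S$ to be a valid level-$\alpha$ test
  marginally).
* **Dimension cap** `d_max = 15` (32 767 subsets): full closure is
  exponential; larger panels should be reduced first, e.g. by the
  two-stage pipeline. Step-down shortcuts are out of scope.

The $\chi^2$-calibrated closure uses the effective (rank) degrees of
freedom per subset.

## The Model-1 generator

`generate_model1()` draws each subject as a $d$-variate standard
Gaussian with AR(1) correlation $R_{\ell r} = \rho^{|\ell - r|}$,
pushes each coordinate through the standard normal cdf and then
through a beta quantile. Coordinates $1..d_0$ are true nulls,
Beta($3, 4$) in both groups; the remaining $d_1 = d - d_0$ coordinates
are Beta($3, 4$) in A and Beta($3 + \delta, 4$) in B. These defaults
(shapes $3$ and $4$, $\delta \in [0.5, 3]$, $\rho \in [0, 0.8]$,
moderate $n = 20 + 30$ and large $n = 100 + 150$ regimes) *are* the
study conditions of the simulation experiments; they emulate unimodal
methylation-like marginals on $[0,1]$ with dependence decaying in
coordinate distance. One wording ambiguity was resolved on
mathematical grounds: a Gaussian copula is scale-free, so the copula
parameter is the correlation matrix $R$ itself — marginal variances
cannot enter. The correlation for the power experiments is not
determined by the published tables; the package defaults to
$\rho = 0.2$ and exposes it.

What the generator does **not** emulate: bimodal or zero/one-inflated
$\beta$-value distributions, block (rather than AR) dependence,
batch effects, or covariate confounding (age being the notorious one
for methylation). Passing simulation checks therefore demonstrates
correct operating characteristics under smooth unimodal marginals with
banded dependence — not robustness to those real-data features; the
rank machinery is invariant to all monotone marginal distortions,
which covers a good part of the gap but not dependence misspecification.

Seeding: each experiment pre-draws one sub-seed per replicate from the
master seed, so replicates are independent, order-insensitive and
bit-reproducible from `(seed, cfg)`; the permutation plan of a
replicate continues that replicate's stream.

## Experiments and problem sizes

`type1_experiment()`, `power_experiment()` and `fwer_experiment()`
report empirical rejection rates with binomial standard errors
$\sqrt{\hat r(1-\hat r)/K}$. The FWER experiment counts a replicate as
a family-wise error when the closure rejects at least one *true null*
coordinate. The acceptance script runs the headline cells at
$K = 10{,}000$ ($\chi^2$ type-I), $K = 5{,}000$ (power, closed-$\chi^2$
FWER), $K = 2{,}000$ with $B = 999$ (permutation type-I) and
$K = 1{,}000$ with $B = 499$ (closed-permutation FWER); the test suite
re-runs the same cells at $K$ between 250 and 1 500 with the tolerance
scaled as $3\sqrt{\hat r(1-\hat r)/K}$. These sizes give standard
errors between 0.002 and 0.014 on rates near 5%, which is tight enough
to separate correct calibration from the $\chi^2$ liberality being
demonstrated.

## Two-stage screening and confirmation

For panels far beyond `d_max`, `split_sample()` partitions the
subjects within groups once (fractions rounded per group, or explicit
per-group counts to mirror a published design); `screen_loci()` ranks
loci by two-sided Wilcoxon rank-sum p-values on the screening
sub-sample (R's implementation: exact enumeration when the smaller
group has at most 10 untied observations, otherwise the normal
approximation with tie and continuity correction — the variant only
matters through the ranking, and ties in ranking are broken by
coordinate index for determinism); `confirm_loci()` runs the closed
permutation test on the selected loci using only the disjoint
confirmation subjects, so the data-driven selection does not
invalidate the confirmation p-values.

## Known limitations

* Two groups only; multi-sample extensions are out of scope.
* FWER control by full closure is exponential in $d$; no step-down
  shortcut and no FDR-type error rates.
* The permutation test's finite-sample exactness holds under marginal
  homogeneity; under the broader relative-effect null with $P \neq Q$
  its validity is asymptotic (as is the $\chi^2$ calibration's).
* No confidence intervals for $\hat p$, and no adjustment for
  covariates/confounders.
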