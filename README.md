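# mvrelef

Nonparametric two-group comparison of multivariate outcomes via
rank-based **relative effects**, with studentized permutation
calibration and **closed testing** for strong family-wise error rate
(FWER) control.

The package is aimed at two-group studies that measure several
dependent, non-normally distributed quantities per subject — the
motivating case is differential DNA methylation, where each subject
contributes a vector of β-values (methylation ratios in [0, 1]) at d
CpG loci, with pronounced and unknown dependence between loci — but
nothing in the machinery is specific to methylation: any N × d numeric
table with a two-level group label works.

## The method

For groups A and B and coordinate ℓ, the *relative effect*

&nbsp;&nbsp;&nbsp;&nbsp;p<sub>AB</sub><sup>(ℓ)</sup> = P(X<sub>A</sub><sup>(ℓ)</sup> < X<sub>B</sub><sup>(ℓ)</sup>) + ½ P(X<sub>A</sub><sup>(ℓ)</sup> = X<sub>B</sub><sup>(ℓ)</sup>) = ∫ F<sub>A</sub><sup>(ℓ)</sup> dF<sub>B</sub><sup>(ℓ)</sup>

quantifies the stochastic tendency of group B towards larger values;
p = ½ means no tendency. The coordinate-wise hypotheses are
H<sub>ℓ</sub>′: p<sub>AB</sub><sup>(ℓ)</sup> = ½. The estimator p̂ is a
pure rank statistic (mid-ranks handle ties), and

&nbsp;&nbsp;&nbsp;&nbsp;W<sub>N</sub> = N (p̂ − ½ 1)ᵀ V̂<sub>N</sub><sup>−1</sup> (p̂ − ½ 1)

is a Wald-type quadratic form studentized by a placement-based
covariance estimator V̂<sub>N</sub>, asymptotically χ²<sub>d</sub> under
the global null. Because the χ² approximation is liberal at realistic
sample sizes (empirically up to 20% type-I error at d = 10, n = 50),
the statistic is calibrated instead against its **studentized
permutation distribution**; restricted to any coordinate subset S the
same construction tests the intersection hypothesis H<sub>S</sub>′ with
|S| degrees of freedom, and the **closure principle** over all 2ᵈ − 1
subsets yields multiplicity-adjusted p-values with strong FWER control.

For locus discovery on large panels, a **two-stage pipeline** splits
the subjects once: univariate Wilcoxon screening ranks loci on one
sub-sample, and the closed multivariate permutation test confirms the
top-m loci on the disjoint remainder.

A Model-1 simulation harness (beta marginals coupled by an AR(1)
Gaussian copula, coordinate-wise shape shifts δ) reproduces the
method's operating characteristics: empirical type-I error, power and
FWER.

## Worked example

A small synthetic β-value table ships with the package (30 subjects,
3 CpG loci; locus `cg0003` carries a genuine group shift):

```r
library(mvrelef)
path <- system.file("extdata", "methylation_betas_synthetic.csv",
                    package = "mvrelef")
s <- read_two_group_table(path, levels = c("control", "case"),
                          coords = c("cg0001", "cg0002", "cg0003"))
relative_effects(s)
#> Relative effects p_AB ( 14 vs 16 units):
#> cg0001 cg0002 cg0003
#> 0.7277 0.4821 0.7991

plan <- permutation_plan(s$n_A + s$n_B, B = 9999, seed = 42)
relef_test(s, calibration = "both", plan = plan)
#> Studentized rank Wald test for relative effects
#>   coordinates: { 1, 2, 3 }
#>   W = 26.8327 on 3 df
#>   p (asymptotic chi-square) = 6.383e-06
#>   p (studentized permutation) = 0.003

closed_test(s, calibration = "permutation", plan = plan)
#> Closed permutation multiple test, FWER level 0.05
#>  coordinate  raw_p adjusted_p rejected
#>      cg0001 0.0324     0.0937    FALSE
#>      cg0002 0.8546     0.8546    FALSE
#>      cg0003 0.0029     0.0107     TRUE
```

Reading: cases tend towards higher methylation at `cg0001` and
`cg0003` (p̂ ≈ 0.73, 0.80). The global test rejects decisively. At the
locus level, only `cg0003` survives the closure (adjusted p = 0.0107);
the borderline raw p = 0.0324 at `cg0001` is absorbed by the
intersection hypotheses — exactly the false-positive protection the
closed procedure buys. With permutation calibration, p-values have
granularity 1/(B+1).

A command-line wrapper covers the same flows
(`test`, `closed-test`, `pipeline`, `simulate`):

```sh
Rscript inst/cli/mvrelef closed-test --input betas.csv \
    --levels control,case --perms 9999 --seed 42 --output out.csv
```

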