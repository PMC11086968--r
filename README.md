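# npparallel

Nonparametric parallelism testing for paired curves via smoothing spline
ANOVA.

## The problem

Many case–control designs observe a response along a continuous coordinate —
DNA-methylation M-values along genomic position, BOLD signal along scan time
— once per subject, in two groups. The scientific question is rarely "do the
groups differ at all?" (a vertical shift between groups is usually
uninteresting nuisance) but "do the two group **curves have different
shapes**?", i.e. are they *parallel*?

`npparallel` models the response surface in a tensor-product reproducing
kernel Hilbert space and decomposes it as in a two-way functional ANOVA,

```
f(x, g) = f00 + f10(x) + f01(g) + f11(x, g) ,
```

where `x ∈ [0,1]` is the (rescaled) position, `g ∈ {0,1}` the group, `f10`
the shared curve shape, `f01` the group shift and `f11` the **nonparallel
(interaction) effect**. The curves are parallel exactly when `f11 = 0`, and
the package tests

```
H0 : f11 = 0    vs    H1 : f11 ≠ 0 .
```

## The test

The continuous margin uses the m-th order homogeneous (periodic) Sobolev
kernel built from scaled Bernoulli polynomials, `(-1)^(m-1) k_{2m}(z - x)`;
the binary margin uses the averaging decomposition with contrast kernel
`1(x2 = z2) - 1/2`. The interaction component is estimated by penalized
least squares; in closed form, with `M = Ξ + λI` the regularized penalty
Gram and `S` the design of the unpenalized subspace,

```
f̂11 = K11 M⁻¹ (I − S (SᵀM⁻¹S)⁻¹ SᵀM⁻¹) y ,
```

and the Wald-type statistic is its squared empirical norm
`T = ‖f̂11‖² / (ns)`. Because the projector annihilates every parallel mean
structure exactly, the null distribution of `T` is free of the nuisance
components (a Wilks-type phenomenon): its null mean and variance are the
exact trace formulas

```
μ = σ² tr(Δ)/(ns),   σ_T² = 2 σ⁴ tr(Δ²)/(ns)²,   Δ = M⁻¹ K11² M⁻¹ ,
```

and the decision compares `z = (T − μ̂)/σ̂_T` with a standard normal. The
smoothing parameter is chosen by a *testing-optimal* (not
estimation-optimal) rule: `λ*` is the grid point at the crossing
`λ ≈ σ_{n,λ}`, balancing the squared bias of `f̂11` against the standard
deviation of `T`. No resampling is needed; a permutation benchmark with the
same statistic is included for comparison.

## Worked example

```r
library(npparallel)
set.seed(42)
n <- 250
x <- runif(2 * n)
g <- rep(0:1, each = n)
y <- 1.8 * sin(2 * pi * x) + 0.6 * g +          # shared curve + group shift
     0.9 * g * sin(pi * x) +                    # nonparallel effect
     rnorm(2 * n, sd = 0.8)
d <- design_points(x, g, y)
parallelism_test(d)
```

```
Nonparametric parallelism test (Wald-type, SSANOVA)
  ns = 500 obs, 2 subject(s); m = 2; lambda* = 0.000373; sigma^2 = 0.6118
  T = 0.004138, null mean 0.001325, null sd 0.0005585
  z = 5.037, p = 4.729e-07  ->  REJECT parallelism (H0: f11 = 0) at alpha = 0.05
```

The fitted noise variance (truth: 0.64) and the selected `λ*` are reported;
`T` is more than five null standard deviations above its null mean, so the
shape difference `0.9 sin(πx)` is detected, while the shift `0.6 g` alone
would not excite the statistic at all (try `y - 0.9*g*sin(pi*x)`: the same
call gives a z-score near 0).

Region-wise scanning with FDR control, e.g. for methylation tracks:

```r
scan <- scan_regions("methylation.tsv", "promoters.bed", alpha = 0.01)
write_region_results(scan, "dmr_results.tsv")
```

A command-line interface wraps the same functions
(`inst/exec/npparallel test|scan|simulate ...`).

## Simulation engine

`sim_setting(1..7)` defines the package's built-in study conditions (curve
`2.5 sin(3πx)(1−x)` with magnitude / frequency / non-constant-magnitude /
shift perturbations, AR(1) noise, and a non-smooth piecewise truth);
`simulate_setting()` draws data and `empirical_power()` /`power_table()`
estimate rejection rates with Monte-Carlo standard errors.

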