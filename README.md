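# mfeeg — monofractal and multifractal features for EEG-like time series

Quantitative EEG pipelines summarize recordings epoch by epoch, and
fractal descriptors are popular epoch features: the Higuchi fractal
dimension, the DFA scaling exponent, and the width Δα and height Δf of
the multifractal singularity spectrum f(α). This package is built for the
practitioner who wants those features *without* silently re-measuring
signal variance, and with an estimator that is stable over time:

* **Monofractal estimators** — `higuchi_fd()` (curve-length scaling,
  `<L(d)> ∝ d^-FD`) and `dfa()` (detrended fluctuation analysis,
  `F(l) ∝ l^H`), with full log–log fit diagnostics.
* **Multifractal estimators** — the direct Chhabra-Jensen method
  (`chhabra_jensen()`), which estimates α(q) and f(q) as regression
  slopes of the q-weighted box statistics
  `Mα = Σ μ_i log P_i`, `Mf = Σ μ_i log μ_i` on `log l`
  with a per-q `R² ≥ 0.9` retention rule, and the Legendre-transform
  estimators `mfdfa()` and `mfdma()` for comparison.
* **The variance-decoupling pipeline** — `standardize_epoch()` (per-epoch
  zero mean / unit sd), then `sigmoid_transform()`
  (`σ(X) = 1/(1 + e^{vX})`, mapping signed data to a positive measure),
  then the direct estimator. The resulting `cj_width_std` feature is
  decorrelated from epoch variance; the raw-epoch variant is not.
* **Ground-truth simulators** — exact fractional Gaussian noise / fBm by
  circulant embedding (`fgn_sim()`, `fbm_sim()`), variance-modulated fBm
  (`modfbm_sim()`), the binomial p-model cascade (`pmodel_sim()`, exactly
  multifractal with `τ(q) = -log2(p1^q + p2^q)`), and surrogates.
* **Feature engineering & redundancy** — `epoch_features()` (band powers,
  line length, fractal features), `pearson_matrix()`,
  `gc_mutual_information()` (Gaussian-copula MI, nats),
  `redundancy_report()`.
* **Experiment drivers** — `run_experiment1()` (variance confound of the
  monofractal estimators), `run_experiment2()` (estimator stability on a
  cascade), `effect_size_scan()` (Cohen's D of ictal vs interictal
  spectrum width over a sampling-rate × epoch-length grid).

A thin command-line wrapper is installed as `exec/mfeeg`
(`mfeeg simulate ...`, `mfeeg features ...`, `mfeeg scan ...`) over the
same functions, with a one-line `fs=<Hz>` CSV interchange format.

## Worked example

Estimate the spectrum of an exactly multifractal cascade and compare the
three estimators' stability over epochs:

```r
library(mfeeg)

m <- pmodel_sim(levels = 10, p1 = 0.4, seed = 7)   # 1,024-sample cascade
s <- chhabra_jensen(m)
s
#> <mf_spectrum> chhabra-jensen: width 0.4488, height 0.4812 (41 of 41 q retained)
round(s$alpha[s$q == 1], 4)
#> [1] 0.971
```

The width 0.4488 is the spread of singularity strengths across
q ∈ [−5, 5]; α(1) = 0.971 equals the binary entropy of p₁ = 0.4 — the
closed-form value for this cascade — to three decimals (machine precision
internally; the estimator is exact on pure cascades).

```r
r <- run_experiment2(levels = 15, seed = 9)
r
#> Estimator stability on p-model cascade (p1 = 0.4, 2^15 samples)
#>       estimator var_width var_height mean_width mean_height max_height
#>  chhabra-jensen 1.571e-31  8.887e-32     0.2746      0.1892     0.1892
#>           mfdfa 5.971e-03  1.468e-02     0.4416      0.6724     0.9498
#>           mfdma 3.130e-03  1.854e-02     0.3724      0.8480     1.1454
#>   most stable (lowest width variance): chhabra-jensen
```

Every epoch of a cascade is a subtree — the same leaf multiset up to
permutation and scale — so a permutation-invariant estimator must return
identical widths on all epochs: the Chhabra-Jensen variance (~1e-31) is
floating-point noise, 28 orders of magnitude below the Legendre
estimators.

Decoupling the width from variance on an EEG-like signal:

```r
env <- modulator("triangular", peak = 2, baseline = 0.25)
x <- modulator_eval(env, 40960) * fgn_sim(40960, 0.7, seed = 3)
tab <- epoch_features(x, fs = 512, q = seq(-3, 3, 0.5))
pr <- pearson_matrix(tab)
pr["cj_width", "std"]       #  0.98   raw width ~ epoch sd: redundant
pr["cj_width_std", "std"]   # -0.318  standardized width: decoupled
```

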