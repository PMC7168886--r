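# poolrna

Design and evaluation of RNA sample pooling strategies for bulk RNA-seq
experiments.

## Why

RNA-seq budgets are spent on three things: RNA sample preparation,
library preparation, and sequencing reads. When money (or input material)
is short, the usual levers are fewer replicates or shallower sequencing.
A third option is *pooling*: mixing the RNA of `q` biological samples into
one library. Pooling keeps the biological breadth of many samples while
paying for fewer libraries, and it shrinks the within-group variance of
each measurement — at the price of fewer replicates for the downstream
test. Whether that trade is worth it depends on the pool size, the number
of pools, the sequencing depth, and how variable the biology is.

`poolrna` is a toolkit for making that decision quantitatively. It is
aimed at statisticians and genomics core facilities planning two-group
differential-expression (DGE) studies.

## What it implements

**The pooling model.** The observed value of pool `k` for one gene is

    Y_k = sum_j A_jk W_jk U_j + e_k

where `U_j` are the (unobservable) per-sample counts with means `mu_j` and
variances `sigma2_j`, `A` is a uniformly random partition of the `n`
samples into pools, `W_k ~ Dirichlet(1, ..., 1)` are the random RNA mixing
fractions, and `e_k` is optional technical noise. The pooled mean is the
average of the member means (pooling is unbiased), and the marginal
variance has the closed form

    Var(Y_k) = 2*S2/(n(q+1)) + (q-1)/(q+1) * (M1^2 - M2)/(n(n-1))
               - M1^2/n^2 + sigma2_eps

with `M1 = sum(mu)`, `M2 = sum(mu^2)`, `S2 = sum(mu^2 + sigma2)` — for
homogeneous means this is `2*sigma2/(q+1)`: pooling divides biological
variance by `(q+1)/2`.

**Power and cost.** The log2 fold-change estimate from a pooled design has
its variance inflated by `2q/(q+1)` (or `(2n/m^2) * sum 1/(1+q_k)` for
unequal pools), which yields an analytic power bound for the two-sided
negative binomial likelihood-ratio test (`nb_lrt_power()`), and a linear
cost model `S*20 + L*100 + R*7.5` (`total_cost()`, unit costs
overridable). `tradeoff_grid()` evaluates pooling, fewer-samples and
shallower-depth strategies against a full-budget reference.

**Simulation benchmarking.** A negative binomial simulator with built-in
truth (`simulate_counts()`), an in-silico scenario engine that pools and
binomially thins a source count matrix into any of 17 built-in design
scenarios (`builtin_scenarios()`, `apply_scenario()`), an internal
quasi-likelihood-moderated per-gene NB test (`nb_lrt_test()`), and an
evaluation pipeline (`evaluate_scenarios()`) that scores designs by LFC
bias, signal-to-noise, concordance with the reference, realized FDR and
sensitivity, then ranks them by a composite z-score.

## Worked example

Power versus cost for a low-abundance gene (relative abundance `1e-7`,
|LFC| = 1, dispersion 2) under a reference design of 60 samples per group
at 20M reads:

```r
library(poolrna)
ref <- power_spec(n1 = 60, theta = 1, phi = 2, rho = 1e-7, depth = 20e6)
grid <- tradeoff_grid(ref)
grid[c(1, 2, 6, 10), c("strategy", "parameter", "libraries_per_group",
                       "power", "cost", "relative_cost")]
#> # A tibble: 4 x 6
#>   strategy        parameter libraries_per_group power  cost relative_cost
#>   <chr>           <chr>                   <dbl> <dbl> <dbl>         <dbl>
#> 1 reference       reference                  60 0.699 32400         1
#> 2 pooling         q=2                        30 0.576 17400         0.537
#> 3 fewer_samples   n=60                       30 0.420 16200         0.5
#> 4 shallower_depth L=10M                      60 0.640 23400         0.722
```

Pooling pairs of samples keeps 0.58 power at 54% of the cost; simply
halving the samples to the same 30 libraries costs slightly less but drops
power to 0.42. The variance mechanics behind this, for a gene with mean 20
and variance 820 across 40 samples:

```r
pop <- gene_population(mu = rep(20, 40), sigma2 = rep(820, 40))
pooled_variance(pop, q = 1:4)
#> [1] 820.0000 546.6667 410.0000 328.0000
```

A small simulation benchmark (2000 genes, 10% DE at |LFC| = 1, 5
replicates) of the full-budget reference A0 against A1 (half the samples)
and B1 (same libraries as A1 but each a pool of two):

```r
sc <- builtin_scenarios("1a")[c(1, 2, 6), ]
ev <- evaluate_scenarios(sc, sim_config(genes = 2000, lfc_mode = "fixed"),
                         replicates = 5, seed = 1)
tidy(ev)[, c("scenario", "mad", "concordance", "fdr", "tpr", "cost",
             "score", "rank")]
#> # A tibble: 3 x 8
#>   scenario   mad concordance    fdr   tpr  cost   score  rank
#>   <chr>    <dbl>       <dbl>  <dbl> <dbl> <dbl>   <dbl> <int>
#> 1 A0       0           1     0.0565 0.802 21600  0.949      1
#> 2 A1       0.201       0.941 0.0700 0.521 10800 -0.938      3
#> 3 B1       0.120       0.946 0.0668 0.694 11600 -0.0113     2
```

B1 recovers most of the sensitivity A1 loses (0.69 vs 0.52), with smaller
LFC bias, for 800 currency units more. `autoplot(ev)` draws the ranking;
`autoplot(ev$curves)` the FDR–TPR curves.

## Command line

A thin CLI ships in `exec/poolrna` with subcommands `power`, `cost`,
`tradeoff`, `simulate`, `pool`, `dge`, `evaluate`, `rank`; every
file-writing command records a `manifest.json` with flags, seed and
versions. For example:

```sh
poolrna cost --samples 40 --libraries 40 --mreads 800
# 10800
poolrna simulate --genes 5000 --seed 1 --out-dir sim/
poolrna pool --counts sim/counts.tsv --groups sim/samples.tsv \
        --scenario B1 --table 1a --seed 2 --out-dir pooled/
```

## Documentation

The methods vignette (`vignettes/pooling-design.Rmd`) documents the model
and its assumptions, the power derivation, the simulator's presets and
what they do and do not emulate, the calibration of the internal test, and
the deliberate design choices (pool-then-thin order, thinning by a common
fraction, ranking conventions).
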