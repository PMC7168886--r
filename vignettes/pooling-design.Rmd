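---
title: "Designing pooled RNA-seq experiments: model, power, cost and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing pooled RNA-seq experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolrna)
```

## The problem

Bulk RNA-seq experiments are constrained by budget: each RNA sample costs
money to prepare, each library costs more, and sequencing reads cost by the
million. The usual cost-saving levers are sequencing fewer samples or
sequencing each library less deeply. A third lever is *pooling*: mixing the
RNA of several biological samples into one library before sequencing. A pool
of `q` samples yields one library whose reads represent the average of its
members, so pooling trades the number of replicates against the
within-group variability of each replicate.

`poolrna` provides the machinery to reason about this trade quantitatively:
a stochastic model of what a pooled library measures, closed-form variance
and power expressions, a linear cost model, and a simulation pipeline that
benchmarks whole experimental designs by the operating characteristics of
the downstream differential-expression (DGE) analysis.

## The pooling model

For one gene, let \(U_j\) be the *virtual count* of biological sample
\(j = 1, \dots, n\): the reads it would yield if sequenced individually,
with mean \(\mu_j\) and variance \(\sigma_j^2\). The observed value of pool
\(k\) is

\[ Y_k = \sum_{j=1}^n A_{jk}\, W_{jk}\, U_j + \epsilon_k, \]

where \(A_{jk}\) indicates membership of sample \(j\) in pool \(k\)
(a uniformly random partition of the \(n\) samples into pools of the design
sizes, realised as a random permutation cut into blocks), \(W_{k}\) is a
symmetric Dirichlet vector of mixing weights — the random fractions of RNA
mass each member contributes — and
\(\epsilon_k \sim N(0, \sigma^2_\epsilon)\) is additive technical noise.
\(A\), \(W\) and \(U\) are mutually independent, which random allocation
and RNA-level mixing justify.

Unit Dirichlet concentration is the default: it is the worst case
(maximum mixing variability subject to uniform marginal weights), so every
downstream statement errs on the conservative side. The concentration is
exposed for sensitivity analyses; infinite concentration models exact
proportional mixing. The technical noise defaults to
\(\sigma^2_\epsilon = 0\); its effect on power is negligible relative to
biological variability unless it rivals the pooled biological variance, and
no published quantification of its magnitude exists to anchor a different
default. When it is positive, negative pooled values are clipped at zero —
the model itself is silent on this corner, and clipping is the only option
that keeps counts interpretable.

Conditional on membership, \(E\{Y_k \mid J_k\}\) is the plain average of
the member means, and marginally \(\bar Y\) is an unbiased estimate of the
population mean expression \(\tfrac1n\sum_j \mu_j\) — pooling does not bias
expression estimates. The marginal variance has the closed form implemented
in `pooled_variance()`: with \(M_1 = \sum_j \mu_j\),
\(M_2 = \sum_j \mu_j^2\) and \(S_2 = \sum_j (\mu_j^2 + \sigma_j^2)\),

\[ \mathrm{Var}(Y_k) = \frac{2 S_2}{n(q+1)}
   + \frac{q-1}{q+1} \cdot \frac{M_1^2 - M_2}{n(n-1)}
   - \frac{M_1^2}{n^2} + \sigma^2_\epsilon. \]

We derived this expression from the model above by direct moment
calculation, using \(E\{W_{jk}^2\} = 2/(q(q+1))\) and
\(E\{W_{ik}W_{jk}\} = 1/(q(q+1))\) for the symmetric Dirichlet and the
without-replacement membership probabilities \(q/n\) and
\(q(q-1)/(n(n-1))\). Three properties make us confident in it:

* with homogeneous means it reduces to
  \(2\bar\sigma^2/(q+1) + \sigma^2_\epsilon\) — the biological variance
  shrinks by \(2/(q+1)\), which is exactly the factor that produces the
  \(2q/(q+1)\) variance inflation of the log-fold-change estimate below;
* at \(q = 1\) it reduces to the total variance of one uniformly drawn
  sample, \(S_2/n - M_1^2/n^2\);
* it agrees with brute-force Monte-Carlo pooling to within Monte-Carlo
  error at every parameter combination we test (the test suite checks
  \(q \in \{2,3,4\}\), dispersions 0.5 and 2, library sizes uniform on
  15–25 million reads, at \(10^5\) draws).

Treatments of this model elsewhere sometimes print a simpler second term;
any form whose cross-moment term is dropped fails the Monte-Carlo check by
dozens of standard errors under heterogeneous means, so the exact derivation
is used throughout. Pool sizes of one are accepted by the function (the
expression remains meaningful) but the pooling model is intended for
\(q \ge 2\).

```{r variance}
L <- runif(40, 15e6, 25e6)
mu <- 1e-6 * L
pop <- gene_population(mu, mu + 2 * mu^2)
pooled_variance(pop, q = 1:4)
```

## Power and the cost of a design

Pooling lowers per-library variance but also the number of libraries, and
the net effect on the log2 fold change (LFC) estimate
\(\hat\theta = \log_2 \hat\rho_2/\hat\rho_1\) is adverse: its variance is
inflated by \(2q/(q+1)\) relative to sequencing all \(n\) samples
individually, or by \((2n/m^2)\sum_k 1/(1+q_k)\) for unequal pools
(`variance_inflation()`, `variance_inflation_unequal()`).

`nb_lrt_power()` turns this into an analytic power bound for the two-sided
negative binomial likelihood-ratio test of no differential expression:

\[ \text{power} \le \Phi\!\left\{ \frac{\sqrt{n_1(q+1)}\,|\theta|
   - Z_{\alpha/2}\sqrt{2qV_0}}{\sqrt{2qV_A}} \right\}. \]

\(V_0\) and \(V_A\) are delta-method variances of the LFC under the null
and alternative. We use the canonical negative binomial form: per group
with mean count \(\mu = \rho L\) (relative abundance times depth) and
dispersion \(\phi\), the contribution is \((1/\ln 2)^2 (1/\mu + \phi)\);
\(V_0\) evaluates both groups at the pooled null mean, \(V_A\) at the
group-specific means. This choice is validated, not assumed: the package's
own per-gene test, run on data simulated under the model at the bound's
parameter settings, rejects at a rate that matches the bound to within
Monte-Carlo error at every grid point checked (effect sizes 0.5 and 1,
dispersions 0.5 and 2, pooled and unpooled), and never exceeds it by more
than sampling noise. Values are clamped to \([\alpha/2, 1]\); at
\(\theta = 0\) the expression equals \(\alpha/2\), the one-tail rejection
probability. Library-size variability is deliberately not modelled here —
the simulation pipeline covers it.

Costs are linear: `total_cost()` charges per RNA sample (default 20), per
library (default 100) and per million reads (default 7.5), computed in
integer cents so currency comparisons are exact. `tradeoff_grid()` combines
both into the design picture: a full-budget reference (120 samples at 20M
reads each by default) against pooling (\(q \in \{2,3,4,6\}\)), fewer
samples (120 down to 20) and shallower depth (10M down to 0.5M):

```{r tradeoff}
ref <- power_spec(n1 = 60, theta = 1, phi = 2, rho = 1e-7, depth = 20e6)
grid <- tradeoff_grid(ref)
grid[, c("strategy", "parameter", "power", "relative_cost")]
```

At matched library counts, pooling always costs slightly more than simply
dropping samples (the extra RNA preparations) but retains more power,
because the pooled libraries are less variable; both cost less than the
reference. `autoplot()` on the grid draws the power-versus-cost scatter.

## The count simulator

`simulate_counts()` generates two-group count matrices with known truth:
gene-wise relative abundances drawn log-uniformly over `1e-8`–`1e-4` and
normalised to sum to one (so a sample's expected total equals its library
size), library sizes uniform on 15–25 million reads, negative binomial
counts with gene-wise dispersion, and a chosen fraction of DE genes whose
group-2 abundances are scaled by \(2^{\theta_g}\) (group 2 renormalised so
totals stay interpretable). Signs are balanced; magnitudes are either
fixed at `lfc_min` or `lfc_min` plus an exponential excess (rate 2), so
that "at least" a given effect size means exactly that.

Two dispersion presets stand in for the two kinds of source material the
design tables target. `"tissue"` draws \(\phi_g\) log-normally with median
0.5 and sdlog 0.8 — squared biological coefficients of variation mostly
between 0.1 and 2, typical of heterogeneous tumour cohorts. `"cellline"`
uses median 0.05 and sdlog 0.5, typical of homogeneous cultured cells.
These presets are calibration choices of this package, not estimates from
any particular dataset: the evaluation machinery needs a realistic
mean–dispersion structure and known truth, not a replica of one cohort.
The simulator is parametric by design; it does not emulate batch effects,
outlier genes, zero-inflation beyond the negative binomial, or gene–gene
correlation. Conclusions from it therefore speak to the *relative* merits
of designs under clean negative binomial biology, not to absolute
performance on any real dataset.

`thin_depth()` emulates shallower sequencing by binomial thinning, which
preserves relative abundances in expectation and maps a negative binomial
count to a negative binomial count with the same dispersion.

## The scenario engine

`builtin_scenarios()` carries two design families for a two-group
comparison. Family "1a" (tissue-scale): a reference with 40 samples and 40
libraries per group at ~20M reads, plus twelve test designs combining
halved samples, halved or quartered depth, and pool sizes 2 or 4. Family
"1b" (cell-line-scale): a 9-library reference and three 3-library designs
with pool sizes 1, 2, 3. Catalogue prices are stored alongside; every row
except the 1a reference agrees exactly with `total_cost()` under default
unit costs (the 1a reference's catalogued price is 200 units above the
formula; we keep the catalogued value and exclude that row from exact
cost checks).

`apply_scenario()` derives a scenario's dataset from a source matrix:
per group it subsamples the scenario's number of samples uniformly without
replacement, assigns them to pools, draws mixing weights (one weight
vector per pool, shared by all genes — weights are a property of the
physical pool), computes the weighted pooled counts, rounds half-to-even
(rounding is deferred to this point because DGE tests need integers while
the model is continuous), and finally thins. Two deliberate choices:

* **Pool first, then thin.** When a scenario both pools and reduces depth,
  the pooled library is constructed at full information and the sequencing
  budget cut is applied to it — mirroring a real pooled library sequenced
  less deeply. The output manifest of the command-line `pool` tool records
  this order.
* **Thinning by a common fraction, not to a hard per-library target.** The
  retention fraction is `scenario depth / reference depth`, applied to all
  libraries of the scenario. Realised library sizes then keep their natural
  spread while their mean matches the scenario depth, which is how
  depth-reduced designs behave in practice (a hard per-library cap would
  shrink the mean below target and clip the spread asymmetrically).
  Scenarios asking for more depth than the source carries warn and keep
  the achievable depth; thinning never up-samples.

`filter_expressed()` applies the standard expression filter — a non-zero
count in at least 3 libraries — before testing.

## The internal DGE test

Evaluating designs needs a per-gene two-group test that runs thousands of
times; the package ships its own rather than depending on an external
pipeline, so that the evaluation is self-contained and its calibration is
under our control. `nb_lrt_test()` fits, per gene, negative binomial
models with log link and effective-library-size offsets — a common
abundance under the null, one per group under the alternative — and forms
the likelihood-ratio statistic. Calibration rests on three components,
each of which earned its place by measurement during development:

* **Median-of-ratios offsets.** With asymmetric differential expression,
  raw total counts carry a composition bias: every null gene appears
  shifted by a common factor. Offsets from the median of per-gene ratios
  to a geometric-mean reference (the standard size-factor construction)
  remove it. On simulated data with 10% DE genes this alone moved the
  null rejection rate at \(p < 0.01\) from ~2.2% back to ~1.1%. A
  `libsize` mode and a `lib_sizes` override exist for data whose depths
  are known by construction.
* **Trended working dispersion.** Gene-wise method-of-moments dispersion
  estimates (residuals around the group means, small-sample corrected,
  shrunk toward the across-gene median) are reduced to a running-median
  trend along abundance. The trend captures the mean–variance relationship;
  deliberately, gene-level scatter is *not* plugged in here, because a
  noisy plug-in dispersion makes the chi-squared reference anti-
  conservative exactly for the genes most likely to be called.
* **Moderated quasi-likelihood F-test.** Gene-level departures from the
  trend go into a quasi-dispersion (Pearson statistic over residual
  degrees of freedom), moderated towards a common value with an
  empirical-Bayes prior whose degrees of freedom are estimated from the
  across-gene scatter of log quasi-dispersions (trigamma moment matching),
  and the scaled statistic is referred to \(F(1, d_{res} + d_{prior})\).
  This is the standard quasi-likelihood architecture for finite-sample
  FDR control in count models.

With a *known* dispersion supplied, the plain likelihood-ratio test against
\(\chi^2_1\) is used instead — it is exactly calibrated in that case, and
it is the right comparator for the analytic power bound. Under the default
estimated path, the realized FDR of Benjamini–Hochberg calls at 5% nominal
stays below 8% in every design of the simulation study below, including
5-library-per-group designs, and the null rejection rate on matched
negative binomial simulations sits within Monte-Carlo error of nominal.

Fold changes are `log2` ratios of the fitted group abundances; a gene with
a zero group total gets 0.5 added to both group mean CPM values before the
ratio, which keeps the estimate finite without dominating non-degenerate
genes. Standard errors come from the group Fisher informations scaled by
the moderated quasi-dispersion.

## Evaluation metrics and ranking

`evaluate_scenarios()` runs the full loop: simulate a source cohort,
derive every scenario from it, test, and score. Per scenario and replicate:

* **LFC bias** (`mad_lfc()`): mean absolute difference to the reference
  scenario's per-gene LFC estimates — the risk of losing signal the full
  budget would recover.
* **Standardized LFC** (`standardized_lfc()`): mean \(|LFC/\widehat{se}|\)
  over the truly DE genes — the simulation stand-in for a gene set known
  to differ between groups; grows with replicates and falls with
  within-group variance.
* **Concordance** (`concordance()`): the fraction of the scenario's DE
  calls that the reference also calls. An empty call set is scored 1 — it
  cannot disagree — and the event is logged; this convention only matters
  for designs too weak to call anything.
* **Actual FDR and TPR** (`fdr_tpr()`) against the simulator's truth, at
  5% nominal and on a 0–40% nominal grid for curves.

`performance_score()` z-scores five metrics across scenarios — inverse
bias, standardized LFC, concordance, one minus FDR, sensitivity — and
averages them; scenarios are ranked by the composite, ties broken in
favour of the cheaper design. z-scoring (rather than min–max scaling) is
used because it does not let a single outlying scenario compress every
other difference to zero; a metric constant across scenarios contributes
zero. The reference compares to itself with zero bias, so its infinite
inverse bias is replaced by the largest finite value before standardizing
— keeping the reference best-in-class on that metric without breaking the
arithmetic.

```{r evaluate, eval = FALSE}
ev <- evaluate_scenarios(builtin_scenarios("1a"),
                         sim_config(lfc_mode = "fixed"),
                         replicates = 20, seed = 1)
tidy(ev)[, c("scenario", "fdr", "tpr", "concordance", "score", "rank")]
autoplot(ev)
```

The study conditions for this benchmark are part of the protocol: 5000
genes, 10% DE, fixed |LFC| = 1, tissue-like dispersion, 20 replicates.
The fixed-effect mode is used so that "DE gene" means one precise effect
size; 20 replicates keep the full 13-scenario study at around a minute of
compute while leaving replicate-level standard errors of the TPR around
one percentage point. Under these conditions the pooling designs that
keep 10 or more libraries per group (B1, B3, C1, C3) dominate the
sample-reduced ones (B2, B4, C2, C4) in the composite ranking, and the
pooled designs B1/B3 reach higher sensitivity than the unpooled A1/A2
with the same or fewer libraries — the central design insight the package
exists to quantify.

## Numerical notes and limitations

* Mean fits use Newton iterations on the log scale with expected
  information, damped to ±5 per step; likelihood tolerances are `1e-10`.
  Dispersions are floored at `1e-8`; the trigamma inversion for the prior
  degrees of freedom runs 50 Newton steps from the asymptotic start.
* All randomness flows through explicit seeds; sub-streams (per replicate,
  per group) are derived with an integer congruential hash kept below
  \(2^{31}\), so parallel or partial re-runs reproduce exactly.
* Currency is unit-agnostic; default unit costs match the built-in
  catalogue prices.
* The engine pools within groups only, with non-overlapping pools and
  independent samples; paired designs, confounders, and pooling across
  conditions are out of scope. Because pooling physically averages RNA
  *before* measurement, sample-level covariates cannot be recovered from a
  pooled design — a fundamental limitation of pooling, not of this
  implementation.
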