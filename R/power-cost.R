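#' Variance inflation of the log-fold-change estimate under pooling
#'
#' Pooling `n` samples per group into `n/q` pools of size `q` reduces the
#' per-library variance but also the number of libraries; the net effect on
#' the variance of the log2 fold-change estimate is an inflation by
#' `2q / (q + 1)` relative to sequencing all `n` samples individually. The
#' factor is 1 at `q = 1` and approaches 2 as pools grow.
#'
#' @param q Pool size(s), `>= 1`.
#' @return Numeric vector `2 * q / (q + 1)`.
#' @examples
#' variance_inflation(c(1, 2, 4))
#' @export
variance_inflation <- function(q) {
  stop_if_not(is.numeric(q) && all(q >= 1), "`q` must be >= 1",
    class = "poolrna_parameter_error")
  2 * q / (q + 1)
}

#' Variance inflation with unequal pool sizes
#'
#' Generalisation of [variance_inflation()] to a group of `n` samples split
#' into `m` pools of sizes `q_k`: the log-fold-change variance is inflated by
#' `(2n / m^2) * sum(1 / (1 + q_k))`. With equal pools (`q_k = q`,
#' `n = m q`) it reduces exactly to `2q / (q + 1)`.
#'
#' @param n Number of RNA samples in the group.
#' @param pool_sizes Integer vector of pool sizes summing to `n`.
#' @return A single number, the inflation factor.
#' @examples
#' variance_inflation_unequal(6, c(2, 4))  # (12/4) * (1/3 + 1/5) = 1.6
#' @export
variance_inflation_unequal <- function(n, pool_sizes) {
  pool_sizes <- as.integer(pool_sizes)
  stop_if_not(all(pool_sizes >= 1), "all pool sizes must be >= 1",
    class = "poolrna_design_error")
  stop_if_not(sum(pool_sizes) == n,
    sprintf("pool sizes sum to %d but n = %d", sum(pool_sizes), as.integer(n)),
    class = "poolrna_design_error")
  m <- length(pool_sizes)
  (2 * n / m^2) * sum(1 / (1 + pool_sizes))
}

#' Build a table of power-calculation settings
#'
#' One row per design to evaluate with [nb_lrt_power()]. Scalar arguments are
#' recycled, so grids are easy to build.
#'
#' @param n1,n2 RNA samples per group (`n2` defaults to `n1`).
#' @param q Common pool size (1 = no pooling). For unequal pools use the
#'   effective value `n1 / m` (samples per group over pools per group).
#' @param theta Log2 fold change to detect.
#' @param phi Negative binomial over-dispersion, `>= 0`.
#' @param rho Relative abundance of the gene in group 1 (fraction of reads).
#' @param depth Sequencing depth per library, in reads.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble with one row per setting, class `"power_spec"`.
#' @export
power_spec <- function(n1, n2 = n1, q = 1, theta, phi, rho, depth,
                       alpha = 0.05) {
  out <- tibble(n1 = as.double(n1), n2 = as.double(n2), q = as.double(q),
                theta = as.double(theta), phi = as.double(phi),
                rho = as.double(rho), depth = as.double(depth),
                alpha = as.double(alpha))
  with(out, {
    stop_if_not(all(n1 >= 1) && all(n2 >= 1), "group sizes must be >= 1",
      class = "poolrna_parameter_error")
    stop_if_not(all(q >= 1), "`q` must be >= 1",
      class = "poolrna_parameter_error")
    stop_if_not(all(phi >= 0), "`phi` must be >= 0",
      class = "poolrna_parameter_error")
    stop_if_not(all(rho > 0) && all(depth > 0),
      "`rho` and `depth` must be positive", class = "poolrna_parameter_error")
    stop_if_not(all(alpha > 0 & alpha < 1), "`alpha` must be in (0, 1)",
      class = "poolrna_parameter_error")
  })
  class(out) <- c("power_spec", class(out))
  out
}

# delta-method variances of the log2 fold-change, per paired sample
# (both groups combined): V = (1/ln2)^2 * sum over groups of (1/mu + phi).
# V0 evaluates both groups at the pooled null mean, VA at the group means.
lfc_variances <- function(theta, phi, rho, depth) {
  l2 <- 1 / log(2)^2
  mu1 <- rho * depth
  mu2 <- rho * 2^abs(theta) * depth
  mub <- (mu1 + mu2) / 2
  list(V0 = l2 * 2 * (1 / mub + phi),
       VA = l2 * ((1 / mu1 + phi) + (1 / mu2 + phi)))
}

#' Analytic power of the negative binomial likelihood-ratio test
#'
#' Upper bound on the power of the two-sided per-gene NB likelihood-ratio
#' test of no differential expression, for a design with `n1 = n2` RNA
#' samples per group pooled into libraries of pool size `q` (q = 1 is the
#' standard unpooled design):
#' \deqn{power \le \Phi\left\{ \frac{\sqrt{n_1 (q+1)}\,|\theta|
#'   - Z_{\alpha/2}\sqrt{2 q V_0}}{\sqrt{2 q V_A}} \right\},}
#' where `V0` and `VA` are delta-method variances of the log2 fold-change
#' estimate under the null and the alternative. Per group with mean count
#' `mu = rho * depth`, the per-sample contribution is
#' `(1/ln 2)^2 (1/mu + phi)`; `V0` evaluates both groups at the pooled null
#' mean, `VA` at the group-specific means. The `2q/(q+1)` variance inflation
#' of pooling enters through the `q` terms, so at `q = 1` the expression is
#' the standard two-group normal-approximation power. Library-size
#' variability is not modelled here; the simulation pipeline covers it.
#'
#' Values are clamped to `[alpha/2, 1]`; at `theta = 0` (where `V0 = VA`)
#' the bound equals `alpha/2`, the one-tail rejection probability.
#'
#' @param spec A [power_spec()] table (or any data frame with its columns).
#' @return The input tibble with an added `power` column.
#' @examples
#' nb_lrt_power(power_spec(n1 = 60, q = 2, theta = 1, phi = 2,
#'                         rho = 1e-7, depth = 20e6))
#' @export
nb_lrt_power <- function(spec) {
  stop_if_not(is.data.frame(spec) && all(
    c("n1", "n2", "q", "theta", "phi", "rho", "depth", "alpha") %in%
      names(spec)),
    "`spec` must be a power_spec() table")
  v <- lfc_variances(spec$theta, spec$phi, spec$rho, spec$depth)
  z <- qnorm(1 - spec$alpha / 2)
  p <- pnorm((sqrt(spec$n1 * (spec$q + 1)) * abs(spec$theta) -
                z * sqrt(2 * spec$q * v$V0)) / sqrt(2 * spec$q * v$VA))
  out <- as_tibble(spec)
  out$power <- pmin(1, pmax(spec$alpha / 2, p))
  out
}

#' Unit costs of an RNA-seq experiment
#'
#' Three linear cost components: RNA sample preparation, library preparation,
#' and sequencing per million reads. Defaults are typical European service
#' prices (EUR 20 per sample, EUR 100 per library, EUR 7.50 per million
#' reads); the currency is treated as a plain number.
#'
#' @param cost_per_sample,cost_per_library,cost_per_mread Non-negative unit
#'   costs.
#' @return A list of class `"cost_model"`.
#' @export
cost_model <- function(cost_per_sample = 20, cost_per_library = 100,
                       cost_per_mread = 7.5) {
  check_scalar(cost_per_sample, "cost_per_sample", 0)
  check_scalar(cost_per_library, "cost_per_library", 0)
  check_scalar(cost_per_mread, "cost_per_mread", 0)
  structure(list(cost_per_sample = cost_per_sample,
                 cost_per_library = cost_per_library,
                 cost_per_mread = cost_per_mread),
            class = "cost_model")
}

#' Total data-generation cost of a design
#'
#' `samples * cost_per_sample + libraries * cost_per_library +
#' mreads * cost_per_mread`, computed in integer cents so that currency
#' comparisons are exact.
#'
#' @param samples Number of RNA samples prepared.
#' @param libraries Number of sequencing libraries.
#' @param mreads Total sequencing reads, in millions.
#' @param model A [cost_model()].
#' @return Numeric vector of costs (currency units). Arguments are recycled.
#' @examples
#' total_cost(40, 40, 800)  # 10800
#' @export
total_cost <- function(samples, libraries, mreads, model = cost_model()) {
  stop_if_not(inherits(model, "cost_model"), "`model` must be a cost_model")
  stop_if_not(all(samples >= 0) && all(libraries >= 0) && all(mreads >= 0),
    "counts of samples, libraries and reads must be non-negative",
    class = "poolrna_parameter_error")
  cents <- round(samples * model$cost_per_sample * 100) +
    round(libraries * model$cost_per_library * 100) +
    round(mreads * model$cost_per_mread * 100)
  cents / 100
}

#' Default cost-saving strategy grids
#'
#' The three families compared against a full-budget reference design:
#' pooling (`q` in 2, 3, 4, 6 at unchanged depth per library), reducing the
#' total number of samples (to 60, 40, 30, 20 by default, i.e. half per
#' group), and reducing the depth per library (to 10M, 5M, 1M, 0.5M reads).
#'
#' @param reference A one-row [power_spec()] describing the reference design
#'   (`q = 1`).
#' @param q Pool sizes for the pooling strategy.
#' @param n_total Total sample numbers for the fewer-samples strategy.
#' @param depth Depths (reads/library) for the shallower-depth strategy.
#' @return A tibble with columns `strategy`, `parameter`, `n1`, `q`, `depth`.
#' @export
default_strategies <- function(reference, q = c(2, 3, 4, 6),
                               n_total = c(60, 40, 30, 20),
                               depth = c(10e6, 5e6, 1e6, 0.5e6)) {
  dplyr::bind_rows(
    tibble(strategy = "pooling", parameter = paste0("q=", q),
           n1 = reference$n1, q = q, depth = reference$depth),
    tibble(strategy = "fewer_samples", parameter = paste0("n=", n_total),
           n1 = n_total / 2, q = 1, depth = reference$depth),
    tibble(strategy = "shallower_depth",
           parameter = paste0("L=", depth / 1e6, "M"),
           n1 = reference$n1, q = 1, depth = depth)
  )
}

#' Power-versus-cost trade-off grid
#'
#' Evaluates analytic power ([nb_lrt_power()]) and total cost
#' ([total_cost()]) for a reference design and a grid of cost-saving
#' strategies, reporting cost relative to the reference. Sample, library and
#' read counts follow from the design: a group of `n1` samples with pool
#' size `q` yields `n1 / q` libraries per group, each sequenced at `depth`
#' reads.
#'
#' @param reference A one-row [power_spec()] with `q = 1`; its `n1`, `depth`,
#'   `theta`, `phi`, `rho`, `alpha` define the reference design.
#' @param strategies A strategy grid as from [default_strategies()] (the
#'   default); must be non-empty with columns `strategy`, `parameter`, `n1`,
#'   `q`, `depth`.
#' @param model A [cost_model()].
#' @return A tibble of class `"pool_tradeoff"`, one row per design:
#'   `strategy`, `parameter`, `n1`, `q`, `depth`, `libraries_per_group`,
#'   `power`, `cost`, `relative_cost` (reference row first,
#'   `relative_cost = 1`).
#' @examples
#' ref <- power_spec(n1 = 60, theta = 1, phi = 2, rho = 1e-7, depth = 20e6)
#' tradeoff_grid(ref)
#' @export
tradeoff_grid <- function(reference, strategies = default_strategies(reference),
                          model = cost_model()) {
  stop_if_not(is.data.frame(reference) && nrow(reference) == 1,
    "`reference` must be a one-row power_spec()")
  stop_if_not(is.data.frame(strategies) && nrow(strategies) > 0,
    "`strategies` must be a non-empty strategy grid",
    class = "poolrna_parameter_error")
  grid <- dplyr::bind_rows(
    tibble(strategy = "reference", parameter = "reference",
           n1 = reference$n1, q = 1, depth = reference$depth),
    as_tibble(strategies)
  )
  spec <- power_spec(n1 = grid$n1, q = grid$q, theta = reference$theta,
                     phi = reference$phi, rho = reference$rho,
                     depth = grid$depth, alpha = reference$alpha)
  grid$libraries_per_group <- grid$n1 / grid$q
  grid$power <- nb_lrt_power(spec)$power
  grid$cost <- total_cost(2 * grid$n1, 2 * grid$libraries_per_group,
                          2 * grid$libraries_per_group * grid$depth / 1e6,
                          model)
  grid$relative_cost <- grid$cost / grid$cost[1]
  class(grid) <- c("pool_tradeoff", class(grid))
  grid
}
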