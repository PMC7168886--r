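#' Describe the per-sample count distribution of one gene
#'
#' A gene population holds, for one gene, the expected count `mu` and count
#' variance `sigma2` of every biological sample that could be sequenced. These
#' are the moments of the *virtual counts*: the reads each sample would yield
#' had it been sequenced individually. They drive the closed-form moments of
#' pooled libraries ([expected_pool_mean()], [pooled_variance()]).
#'
#' @param mu Numeric vector of per-sample expected counts (one per sample,
#'   all `>= 0`).
#' @param sigma2 Numeric vector of per-sample count variances, same length
#'   as `mu`, all `>= 0`. For a negative binomial sample with mean `m` and
#'   over-dispersion `phi` this is `m + phi * m^2`.
#' @return A tibble with columns `sample`, `mu`, `sigma2` and class
#'   `"gene_population"`.
#' @examples
#' gene_population(mu = c(10, 20), sigma2 = c(30, 60))
#' @export
gene_population <- function(mu, sigma2) {
  stop_if_not(length(mu) == length(sigma2) && length(mu) >= 1,
    "`mu` and `sigma2` must be non-empty vectors of equal length")
  stop_if_not(all(is.finite(mu)) && all(mu >= 0), "`mu` must be non-negative")
  stop_if_not(all(is.finite(sigma2)) && all(sigma2 >= 0),
    "`sigma2` must be non-negative")
  out <- tibble(sample = seq_along(mu), mu = as.double(mu),
                sigma2 = as.double(sigma2))
  class(out) <- c("gene_population", class(out))
  out
}

#' Read gene population parameters from a TSV file
#'
#' Expects three columns: `sample_id`, `mu`, `sigma2`.
#'
#' @param path Path to a tab-separated file.
#' @return A [gene_population()] tibble.
#' @export
read_population <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stop_if_not(all(c("sample_id", "mu", "sigma2") %in% names(d)),
    "population file must have columns sample_id, mu, sigma2")
  out <- gene_population(d$mu, d$sigma2)
  out$sample_id <- d$sample_id
  out
}

#' Randomly assign biological samples to pools
#'
#' Partitions samples `1..n` uniformly at random into ordered pools of the
#' requested sizes. The assignment is a uniformly random permutation split
#' into consecutive blocks, which realises the constrained multinomial
#' allocation of the pooling model exactly: every sample lands in exactly one
#' pool, pool `k` receives exactly `pool_sizes[k]` samples, and each sample is
#' equally likely to land in any pool of a given size.
#'
#' @param n Number of biological samples.
#' @param pool_sizes Integer vector of pool sizes `q_k`; must sum to `n`,
#'   all `>= 1`.
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A tibble with one row per sample, columns `sample`, `pool` and
#'   `member` (position within the pool, matching the `member` index of
#'   [draw_mixing_weights()]), ordered by pool. Class `"pool_assignment"`,
#'   with attribute `pool_sizes`.
#' @examples
#' assign_samples_to_pools(6, c(2, 2, 2), seed = 1)
#' @export
assign_samples_to_pools <- function(n, pool_sizes, seed = NULL) {
  n <- as.integer(n)
  pool_sizes <- as.integer(pool_sizes)
  stop_if_not(length(pool_sizes) >= 1 && all(pool_sizes >= 1),
    "all pool sizes must be >= 1", class = "poolrna_design_error")
  stop_if_not(sum(pool_sizes) == n,
    sprintf("pool sizes sum to %d but n = %d", sum(pool_sizes), n),
    class = "poolrna_design_error")
  perm <- with_seed_if(seed, sample.int(n))
  out <- tibble(
    sample = perm,
    pool   = rep(seq_along(pool_sizes), pool_sizes),
    member = unlist(lapply(pool_sizes, seq_len), use.names = FALSE)
  )
  attr(out, "pool_sizes") <- pool_sizes
  class(out) <- c("pool_assignment", class(out))
  out
}

#' Draw Dirichlet mixing weights for each pool
#'
#' The fractions of RNA mass the samples of a pool contribute are modelled as
#' a symmetric Dirichlet vector: for a pool of size `q`, the weight vector has
#' mean `1/q` per sample and component variance `(q - 1) / (q^2 (q + 1))` at
#' the default unit concentration. Concentration 1 is the worst case (maximum
#' mixing variability under uniform marginals); larger concentrations model
#' more accurate pipetting, and `concentration = Inf` gives exact equal
#' weights `1/q`.
#'
#' @param pool_sizes Integer vector of pool sizes `q_k`, all `>= 1`.
#' @param concentration Positive scalar Dirichlet concentration (default 1).
#'   `Inf` yields deterministic equal weights.
#' @param seed Optional integer seed.
#' @return A tibble with columns `pool`, `member`, `weight`; weights within a
#'   pool sum to one. Class `"pool_weights"`.
#' @examples
#' draw_mixing_weights(c(2, 2), seed = 1)
#' draw_mixing_weights(3, concentration = Inf)  # equal thirds
#' @export
draw_mixing_weights <- function(pool_sizes, concentration = 1, seed = NULL) {
  pool_sizes <- as.integer(pool_sizes)
  stop_if_not(all(pool_sizes >= 1), "all pool sizes must be >= 1",
    class = "poolrna_design_error")
  stop_if_not(is.numeric(concentration) && length(concentration) == 1 &&
    concentration > 0, "`concentration` must be a positive scalar",
    class = "poolrna_parameter_error")
  total <- sum(pool_sizes)
  pool <- rep(seq_along(pool_sizes), pool_sizes)
  if (is.infinite(concentration)) {
    w <- rep(1 / pool_sizes, pool_sizes)
  } else {
    g <- with_seed_if(seed, rgamma(total, shape = concentration))
    # gamma normalisation per pool == Dirichlet; guard an all-zero pool
    # (possible only at tiny concentrations through underflow)
    sums <- tapply(g, pool, sum)[pool]
    zero <- sums == 0
    g[zero] <- 1
    sums[zero] <- tapply(g, pool, sum)[pool][zero]
    w <- g / sums
  }
  out <- tibble(pool = pool,
                member = unlist(lapply(pool_sizes, seq_len), use.names = FALSE),
                weight = as.double(w))
  attr(out, "pool_sizes") <- pool_sizes
  attr(out, "concentration") <- concentration
  class(out) <- c("pool_weights", class(out))
  out
}

#' Generate pooled expression values from virtual counts
#'
#' Realises the pooled data-generating model for one gene: the observed value
#' of pool `k` is the mixing-weight-weighted sum of the virtual counts of the
#' samples assigned to that pool, plus an optional Gaussian technical error
#' with variance `sigma2_eps`. Negative values (possible only when
#' `sigma2_eps > 0`) are clipped at zero. Values are returned on the
#' continuous scale; rounding to integer counts is deferred to the scenario
#' engine ([apply_scenario()]), where it is done half-to-even.
#'
#' @param u Numeric vector of virtual counts, one per sample.
#' @param assignment A [assign_samples_to_pools()] result covering
#'   `length(u)` samples.
#' @param weights A [draw_mixing_weights()] result with matching pool sizes.
#' @param sigma2_eps Variance of the additive technical error (default 0:
#'   pooling itself adds no measurement noise).
#' @param seed Optional integer seed for the error term.
#' @return A tibble with columns `pool` and `count`.
#' @examples
#' a <- assign_samples_to_pools(2, 2)
#' w <- draw_mixing_weights(2, concentration = Inf)
#' pool_counts(c(10, 30), a, w)  # 0.5 * 10 + 0.5 * 30 = 20
#' @export
pool_counts <- function(u, assignment, weights, sigma2_eps = 0, seed = NULL) {
  stop_if_not(inherits(assignment, "pool_assignment"),
    "`assignment` must come from assign_samples_to_pools()")
  stop_if_not(inherits(weights, "pool_weights"),
    "`weights` must come from draw_mixing_weights()")
  stop_if_not(length(u) == nrow(assignment),
    sprintf("`u` has length %d but the assignment covers %d samples",
            length(u), nrow(assignment)))
  stop_if_not(identical(attr(assignment, "pool_sizes"),
                        attr(weights, "pool_sizes")),
    "assignment and weights have different pool sizes")
  check_scalar(sigma2_eps, "sigma2_eps", lower = 0)
  m <- length(attr(assignment, "pool_sizes"))
  y <- as.double(tapply(weights$weight * u[assignment$sample],
                        assignment$pool, sum))
  if (sigma2_eps > 0) {
    y <- y + with_seed_if(seed, rnorm(m, 0, sqrt(sigma2_eps)))
    y <- pmax(y, 0)
  }
  tibble(pool = seq_len(m), count = y)
}

# dense n x m matrix with W[j, k] = mixing weight of sample j in pool k
# (zero if j not in pool k); used to pool whole count matrices at once
pool_weight_matrix <- function(assignment, weights) {
  sizes <- attr(assignment, "pool_sizes")
  W <- matrix(0, nrow(assignment), length(sizes))
  W[cbind(assignment$sample, assignment$pool)] <- weights$weight
  W
}

#' Expected expression of one pool
#'
#' The conditional mean of a pooled library, given which samples it contains,
#' is the plain average of the member samples' expected counts.
#'
#' @param pop A [gene_population()].
#' @param members Integer vector of member sample indices (non-empty).
#' @return A single number: `mean(mu[members])`.
#' @export
expected_pool_mean <- function(pop, members) {
  stop_if_not(inherits(pop, "gene_population"),
    "`pop` must be a gene_population")
  members <- as.integer(members)
  stop_if_not(length(members) >= 1, "pool membership must be non-empty")
  stop_if_not(all(members >= 1 & members <= nrow(pop)),
    "member indices out of range")
  mean(pop$mu[members])
}

#' Closed-form variance of a pooled expression value
#'
#' Marginal variance of the pooled value `Y_k` under the pooling model: a
#' uniformly random pool of `q` of the `n` samples, symmetric Dirichlet
#' mixing weights, and additive technical noise. With
#' \eqn{M_1 = \sum_j \mu_j}, \eqn{M_2 = \sum_j \mu_j^2} and
#' \eqn{S_2 = \sum_j (\mu_j^2 + \sigma_j^2)},
#' \deqn{Var(Y_k) = \frac{2 S_2}{n(q+1)}
#'   + \frac{q-1}{q+1}\,\frac{M_1^2 - M_2}{n(n-1)}
#'   - \frac{M_1^2}{n^2} + \sigma^2_\epsilon .}
#' When all samples share the same mean this reduces to
#' \eqn{2\bar\sigma^2/(q+1) + \sigma^2_\epsilon}: pooling shrinks the
#' biological variance by the factor \eqn{2/(q+1)}, so the variance is
#' decreasing in the pool size. At `q = 1` the expression reduces to the
#' variance of a single uniformly drawn sample (total variance
#' \eqn{S_2/n - M_1^2/n^2}); note the pooling model itself is meant for
#' pools of two or more samples.
#'
#' @param pop A [gene_population()] describing all `n` candidate samples.
#' @param q Pool size (may be a vector; `1 <= q <= n`).
#' @param sigma2_eps Technical error variance (default 0).
#' @return Numeric vector of variances, one per element of `q`.
#' @seealso [variance_inflation()] for the downstream effect on log-fold-
#'   change estimates.
#' @export
pooled_variance <- function(pop, q, sigma2_eps = 0) {
  stop_if_not(inherits(pop, "gene_population"),
    "`pop` must be a gene_population")
  check_scalar(sigma2_eps, "sigma2_eps", lower = 0)
  q <- as.integer(q)
  n <- nrow(pop)
  stop_if_not(all(q >= 1), "pool size must be >= 1")
  stop_if_not(all(q <= n), "pool size cannot exceed the number of samples")
  M1 <- sum(pop$mu)
  M2 <- sum(pop$mu^2)
  S2 <- M2 + sum(pop$sigma2)
  cross <- if (n > 1) (M1^2 - M2) / (n * (n - 1)) else 0
  2 * S2 / (n * (q + 1)) + (q - 1) / (q + 1) * cross - M1^2 / n^2 + sigma2_eps
}
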