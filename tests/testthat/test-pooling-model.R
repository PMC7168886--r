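test_that("pool assignment is always a valid partition", {
  for (seed in 1:40) {
    sizes <- withr::with_seed(seed, sample(1:4, sample(1:4, 1), replace = TRUE))
    n <- sum(sizes)
    a <- assign_samples_to_pools(n, sizes, seed = seed)
    expect_setequal(a$sample, seq_len(n))              # each sample once
    expect_equal(as.integer(table(a$pool)), sizes)     # pool sizes exact
  }
  # forced cases
  a <- assign_samples_to_pools(2, 2)
  expect_equal(a$pool, c(1L, 1L))
  a <- assign_samples_to_pools(4, c(2, 2), seed = 3)
  expect_equal(sort(a$sample), 1:4)
  expect_equal(as.integer(table(a$pool)), c(2L, 2L))
  # determinism
  expect_identical(assign_samples_to_pools(6, c(3, 3), seed = 11),
                   assign_samples_to_pools(6, c(3, 3), seed = 11))
  expect_error(assign_samples_to_pools(5, c(2, 2)), class = "poolrna_design_error")
  expect_error(assign_samples_to_pools(4, c(4, 0)), class = "poolrna_design_error")
})

test_that("assignment is uniform over pools", {
  draws <- 10000
  hits <- integer(3)
  for (i in seq_len(draws)) {
    a <- assign_samples_to_pools(6, c(2, 2, 2), seed = i)
    hits[a$pool[a$sample == 1]] <- hits[a$pool[a$sample == 1]] + 1L
  }
  freq <- hits / draws
  se <- sqrt((1 / 3) * (2 / 3) / draws)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("mixing weights follow the symmetric Dirichlet law", {
  # singleton pools are degenerate
  expect_equal(draw_mixing_weights(1, seed = 1)$weight, 1)
  # normalisation holds for every pool on random configurations
  for (seed in 1:25) {
    sizes <- withr::with_seed(seed, sample(1:5, 4, replace = TRUE))
    w <- draw_mixing_weights(sizes, seed = seed)
    sums <- tapply(w$weight, w$pool, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(w$weight >= 0 & w$weight <= 1))
  }
  # q = 3 component moments: mean 1/3, variance (q-1)/(q^2 (q+1)) = 2/36
  n_pools <- 30000
  w <- draw_mixing_weights(rep(3, n_pools), seed = 42)
  first <- w$weight[w$member == 1]
  v_true <- 2 / 36
  expect_lt(abs(mean(first) - 1 / 3), 3 * sqrt(v_true / n_pools))
  expect_lt(abs(var(first) - v_true), 3 * se_of_var(first))
  # infinite concentration = exact proportional mixing
  expect_equal(draw_mixing_weights(c(4, 2), concentration = Inf)$weight,
               c(rep(0.25, 4), rep(0.5, 2)))
  expect_error(draw_mixing_weights(3, concentration = 0),
               class = "poolrna_parameter_error")
})

test_that("pool_counts realises the weighted-sum model", {
  # pool of one is the identity
  a1 <- assign_samples_to_pools(3, c(1, 1, 1), seed = 2)
  w1 <- draw_mixing_weights(c(1, 1, 1))
  u <- c(5, 17, 40)
  y <- pool_counts(u, a1, w1)
  expect_equal(y$count, u[a1$sample[match(1:3, a1$pool)]])
  # forced arithmetic: equal weights on (10, 30) give 20
  a <- assign_samples_to_pools(2, 2)
  w <- draw_mixing_weights(2, concentration = Inf)
  expect_equal(pool_counts(c(10, 30), a, w)$count, 20)
  # unbiasedness over repeated assignment/weight draws (fixed virtual counts)
  u <- withr::with_seed(7, rnbinom(8, mu = 50, size = 2))
  vals <- numeric(0)
  for (i in 1:2000) {
    ai <- assign_samples_to_pools(8, c(4, 4), seed = 5000 + i)
    wi <- draw_mixing_weights(c(4, 4), seed = 9000 + i)
    vals <- c(vals, pool_counts(u, ai, wi)$count)
  }
  expect_lt(abs(mean(vals) - mean(u)), 3 * sd(vals) / sqrt(length(vals)))
  # technical noise is clipped at zero and seeded
  y1 <- pool_counts(c(0, 0), a, w, sigma2_eps = 4, seed = 3)
  expect_true(all(y1$count >= 0))
  expect_identical(y1, pool_counts(c(0, 0), a, w, sigma2_eps = 4, seed = 3))
  expect_error(pool_counts(c(1, 2, 3), a, w), class = "poolrna_error")
})

test_that("expected pool mean is the average of member means", {
  pop <- gene_population(mu = c(10, 20), sigma2 = c(1, 1))
  expect_equal(expected_pool_mean(pop, c(1, 2)), 15)
  expect_equal(expected_pool_mean(pop, 2), 20)
  pop5 <- gene_population(mu = rep(5, 4), sigma2 = rep(2, 4))
  expect_equal(expected_pool_mean(pop5, c(1, 3)), 5)
  expect_error(expected_pool_mean(pop, integer(0)), class = "poolrna_error")
})

test_that("pooled variance has the right limits and structure", {
  # degenerate population
  z <- gene_population(mu = rep(0, 6), sigma2 = rep(0, 6))
  expect_equal(pooled_variance(z, 2), 0)
  expect_equal(pooled_variance(z, 3, sigma2_eps = 1.5), 1.5)
  # homogeneous means: biological variance shrinks by 2/(q+1)
  pop <- gene_population(mu = rep(20, 10), sigma2 = rep(840, 10))
  for (q in 1:5) {
    expect_equal(pooled_variance(pop, q), 2 * 840 / (q + 1))
  }
  # q = 1 equals the variance of one uniformly drawn sample
  mu <- c(3, 8, 15, 24); s2 <- c(5, 10, 20, 40)
  pop2 <- gene_population(mu, s2)
  n <- 4
  single <- sum(mu^2 + s2) / n - (sum(mu) / n)^2
  expect_equal(pooled_variance(pop2, 1), single)
  # non-increasing in q
  v <- pooled_variance(pop2, 1:4)
  expect_true(all(diff(v) <= 1e-12))
  expect_error(pooled_variance(pop2, 5), class = "poolrna_error")
})

test_that("closed-form pooled variance matches a Monte-Carlo oracle", {
  # iid resampling oracle, independent of pool_counts / assignment code
  n <- 40; q <- 2; phi <- 2; rho <- 1e-6
  L <- withr::with_seed(1, runif(n, 15e6, 25e6))
  mu <- rho * L
  pop <- gene_population(mu, mu + phi * mu^2)
  draws <- 30000
  y <- withr::with_seed(2, {
    idx <- vapply(seq_len(draws), function(i) sample.int(n, q), integer(q))
    U <- matrix(rnbinom(q * draws, mu = mu[idx], size = 1 / phi), q, draws)
    W <- matrix(rgamma(q * draws, 1), q, draws)
    colSums(U * W) / colSums(W)
  })
  expect_lt(abs(pooled_variance(pop, q) - var(y)), 3 * se_of_var(y))
})
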