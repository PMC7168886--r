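# small fixture builders shared across test files

# NB count matrix with gene names; constant mean and dispersion
make_counts <- function(G, J, mu = 80, phi = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(G * J, mu = mu, size = 1 / phi), G, J)
    storage.mode(m) <- "integer"
    rownames(m) <- sprintf("g%03d", seq_len(G))
    colnames(m) <- sprintf("s%02d", seq_len(J))
    m
  })
}

# a custom one-row scenario tibble (same columns as builtin_scenarios())
make_scenario <- function(name, samples_per_group, libraries_per_group,
                          pool_size, depth, reference = FALSE) {
  tibble::tibble(
    table = "custom", scenario = name, reference = reference,
    samples_per_group = samples_per_group,
    libraries_per_group = libraries_per_group,
    pool_size = pool_size, depth = depth, pooling = pool_size > 1,
    samples_total = 2 * samples_per_group,
    libraries_total = 2 * libraries_per_group,
    mreads_total = 2 * libraries_per_group * depth / 1e6,
    cost_printed = NA_real_
  )
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  q
}

# standard error of a sample variance from the fourth central moment
se_of_var <- function(x) {
  n <- length(x)
  v <- var(x)
  m4 <- mean((x - mean(x))^4)
  sqrt((m4 - v^2 * (n - 3) / (n - 1)) / n)
}
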