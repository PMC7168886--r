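test_that("fold changes and q-values are computed exactly", {
  # forced LFC: equal library sizes, fourfold difference
  y <- rbind(target = c(100L, 100L, 400L, 400L),
             flat = c(200L, 200L, 200L, 200L),
             other = c(50L, 60L, 55L, 55L))
  fit <- nb_lrt_test(y, c("g1", "g1", "g2", "g2"),
                     lib_sizes = rep(1e6, 4))
  expect_equal(fit$lfc[fit$gene == "target"], 2, tolerance = 1e-6)
  expect_equal(fit$lfc[fit$gene == "flat"], 0, tolerance = 1e-6)

  # BH adjustment equals the brute-force step-up on the fit's own p-values
  m <- make_counts(200, 12, mu = 120, phi = 0.3, seed = 20)
  fit2 <- nb_lrt_test(m, rep(c("a", "b"), each = 6))
  expect_equal(fit2$q_value, bh_brute(fit2$p_value))
  expect_true(all(fit2$q_value >= fit2$p_value - 1e-12))
  expect_true(all(fit2$q_value >= 0 & fit2$q_value <= 1))
  expect_equal(fit2$de, fit2$q_value <= 0.05)
  # the reference example for the step-up
  expect_equal(bh_brute(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))

  # broom-style accessors
  expect_s3_class(tidy(fit2), "tbl_df")
  expect_false(inherits(tidy(fit2), "nb_dge"))
  g <- glance(fit2)
  expect_equal(g$n_genes, 200)

  # input validation
  expect_error(nb_lrt_test(m, rep("a", 12)), class = "poolrna_design_error")
  expect_error(nb_lrt_test(m[, 1:3], c("a", "a", "b")),
               class = "poolrna_design_error")
  expect_error(nb_lrt_test(m * 0.5, rep(c("a", "b"), each = 6)),
               class = "poolrna_input_error")
  # all-zero genes are excluded with a message
  m0 <- rbind(m, zero = rep(0L, 12))
  expect_message(fit0 <- nb_lrt_test(m0, rep(c("a", "b"), each = 6)),
                 "all-zero")
  expect_false("zero" %in% fit0$gene)
})

test_that("type-I error is controlled on a matched null simulation", {
  G <- 5000
  m <- make_counts(G, 40, mu = 80, phi = 0.2, seed = 21)
  fit <- nb_lrt_test(m, rep(c("a", "b"), each = 20))
  rej <- mean(fit$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / G)
  expect_lt(abs(rej - 0.05), 3 * se)
  # permuted labels leave the null property intact
  perm <- withr::with_seed(22, sample(rep(c("a", "b"), each = 20)))
  rej_p <- mean(nb_lrt_test(m, perm)$p_value < 0.05)
  expect_lt(abs(rej_p - 0.05), 3 * se)
})

test_that("LFC bias metric equals the brute-force mean absolute difference", {
  m <- make_counts(150, 8, mu = 150, phi = 0.2, seed = 23)
  fit <- nb_lrt_test(m, rep(c("a", "b"), each = 4))
  expect_equal(mad_lfc(fit, fit), 0)
  shifted <- fit
  shifted$lfc <- fit$lfc + 0.7
  expect_equal(mad_lfc(shifted, fit), 0.7)
  noisy <- fit
  noisy$lfc <- withr::with_seed(24, fit$lfc + rnorm(nrow(fit)))
  brute <- mean(abs(noisy$lfc - fit$lfc))
  expect_equal(mad_lfc(noisy, fit), brute)
  # intersection semantics
  sub <- fit[1:50, ]
  expect_message(v <- mad_lfc(sub, noisy), "shared")
  expect_equal(v, mean(abs(sub$lfc - noisy$lfc[1:50])))
  empty <- fit; empty$gene <- paste0("x", seq_len(nrow(fit)))
  expect_error(mad_lfc(empty, fit), class = "poolrna_input_error")
})

test_that("standardized LFC is the signal-to-noise ratio", {
  m <- make_counts(100, 8, mu = 150, phi = 0.2, seed = 25)
  fit <- nb_lrt_test(m, rep(c("a", "b"), each = 4))
  unit <- fit; unit$se <- rep(1, nrow(fit))
  s <- standardized_lfc(unit)
  expect_equal(s$slfc, unit$lfc)
  doubled <- fit; doubled$se <- fit$se * 2
  expect_equal(standardized_lfc(doubled)$slfc,
               standardized_lfc(fit)$slfc / 2)
  expect_equal(attr(standardized_lfc(fit), "mean_abs"),
               mean(abs(fit$lfc / fit$se)))
  # zero-SE genes are skipped, empty gene sets rejected
  broken <- fit; broken$se[1] <- 0
  expect_message(sb <- standardized_lfc(broken), "skipping 1 gene")
  expect_equal(nrow(sb), nrow(fit) - 1)
  expect_error(standardized_lfc(fit, geneset = "nope"),
               class = "poolrna_input_error")
})

test_that("concordance is the overlap fraction of DE calls", {
  m <- make_counts(60, 8, mu = 150, phi = 0.2, seed = 26)
  fit <- nb_lrt_test(m, rep(c("a", "b"), each = 4))
  mk <- function(de_genes) {
    f <- fit
    f$q_value <- ifelse(f$gene %in% de_genes, 0.01, 0.5)
    f
  }
  ref <- mk(paste0("g", sprintf("%03d", 1:20)))
  # subset of the reference calls
  expect_equal(concordance(mk(paste0("g", sprintf("%03d", 5:10))), ref), 1)
  # disjoint calls
  expect_equal(concordance(mk(paste0("g", sprintf("%03d", 30:40))), ref), 0)
  # brute-force on random call sets
  for (seed in 1:5) {
    tg <- withr::with_seed(seed, sample(fit$gene, 15))
    rg <- withr::with_seed(seed + 100, sample(fit$gene, 25))
    expect_equal(concordance(mk(tg), mk(rg)),
                 length(intersect(tg, rg)) / length(tg))
  }
  expect_message(v <- concordance(mk(character(0)), ref), "no genes DE")
  expect_equal(v, 1)
})

test_that("FDR/TPR curves behave at the extremes and under scrambling", {
  m <- make_counts(300, 8, mu = 150, phi = 0.2, seed = 27)
  fit <- nb_lrt_test(m, rep(c("a", "b"), each = 4))
  truth <- setNames(rep(FALSE, nrow(fit)), fit$gene)
  truth[1:30] <- TRUE
  # a perfect test
  perfect <- fit
  perfect$q_value <- ifelse(truth[perfect$gene], 0, 1)
  pc <- fdr_tpr(perfect, truth, nominal_grid = c(0.05, 0.2))
  expect_equal(pc$fdr, c(0, 0))
  expect_equal(pc$tpr, c(1, 1))
  # no calls at all: guarded division
  none <- fit; none$q_value <- rep(1, nrow(fit))
  nc <- fdr_tpr(none, truth, nominal_grid = 0.05)
  expect_equal(nc$fdr, 0)
  expect_equal(nc$tpr, 0)
  # scrambled evidence: TPR tracks the DE fraction at the matched call count
  scr <- fit
  scr$q_value <- withr::with_seed(28, runif(nrow(fit)) * 0.4)
  sc <- fdr_tpr(scr, truth, nominal_grid = 0.1)
  expected_tpr <- sc$n_called * mean(truth) / sum(truth)
  expect_lt(abs(sc$tpr - expected_tpr),
            3 * sqrt(sc$n_called * 0.1 * 0.9) / sum(truth) + 0.05)
  # TPR is monotone along the nominal grid
  curve <- fdr_tpr(fit, truth)
  expect_true(all(diff(curve$tpr) >= 0))
  expect_error(fdr_tpr(fit, unname(truth)), class = "poolrna_mode_error")
})

test_that("performance scores average the five z-scored metrics", {
  met <- tibble::tibble(
    scenario = c("X", "Y", "Z"),
    mad = c(0.1, 0.3, 0.2), slfc = c(5, 2, 3),
    concordance = c(0.9, 0.5, 0.7), fdr = c(0.03, 0.10, 0.06),
    tpr = c(0.8, 0.4, 0.6), cost = c(300, 100, 200))
  ps <- performance_score(met)
  # X dominates every metric
  expect_equal(ps$rank[ps$scenario == "X"], 1L)
  expect_equal(sort(ps$rank), 1:3)
  # brute-force recomputation of the composite
  z <- function(x) (x - mean(x)) / sd(x)
  manual <- (z(1 / met$mad) + z(met$slfc) + z(met$concordance) +
               z(1 - met$fdr) + z(met$tpr)) / 5
  expect_equal(ps$score, manual)
  # identical scenarios tie; the cheaper one ranks first
  met2 <- met[c(1, 1, 2), ]
  met2$scenario <- c("exp", "cheap", "other")
  met2$cost[2] <- 50
  ps2 <- performance_score(met2)
  expect_lt(ps2$rank[ps2$scenario == "cheap"],
            ps2$rank[ps2$scenario == "exp"])
  # constant metric gets z-score zero
  met3 <- met; met3$concordance <- 0.5
  expect_message(ps3 <- performance_score(met3), "constant")
  expect_equal(ps3$z_concordance, rep(0, 3))
  # zero bias (reference vs itself) handled finitely
  met4 <- met; met4$mad[1] <- 0
  expect_message(ps4 <- performance_score(met4), "zero LFC bias")
  expect_true(all(is.finite(ps4$score)))
  expect_error(performance_score(met[1, ]), class = "poolrna_input_error")
})

test_that("more libraries and pooling both raise the signal-to-noise", {
  sim <- simulate_counts(sim_config(genes = 1200, n1 = 20, n2 = 20,
                                    lfc_mode = "fixed"), seed = 29)
  de <- sim$genes$gene[sim$genes$de]
  run <- function(sc) {
    ds <- apply_scenario(sim$counts, sim$samples$group, sc, seed = 3,
                         reference_depth = 20e6)
    fit <- suppressMessages(
      nb_lrt_test(ds$counts[filter_expressed(ds$counts), , drop = FALSE],
                  ds$samples$group))
    attr(suppressMessages(standardized_lfc(fit, de)), "mean_abs")
  }
  full <- run(make_scenario("full", 20, 20, 1, 20e6))
  small <- run(make_scenario("small", 5, 5, 1, 20e6))
  pooled <- run(make_scenario("pooled", 20, 10, 2, 20e6))
  expect_gt(full, small)    # more replicates sharpen the signal
  expect_gt(pooled, small)  # pooling recovers part of it at half the libraries
})
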