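# align two nb_dge results on their shared gene universe
shared_genes <- function(test, reference) {
  g <- intersect(test$gene, reference$gene)
  stop_if_not(length(g) > 0, "no shared genes between the two results",
    class = "poolrna_input_error")
  dropped <- (nrow(test) - length(g)) + (nrow(reference) - length(g))
  if (dropped > 0) {
    inform(sprintf("restricting to %d shared genes (%d dropped)",
                   length(g), dropped))
  }
  g
}

#' Log-fold-change bias of a test scenario
#'
#' Mean absolute difference between a scenario's per-gene log2 fold-change
#' estimates and the reference scenario's, over the shared gene universe. It
#' measures the risk of losing, under a cheaper design, differential-
#' expression signal that the full-budget design would recover.
#'
#' @param test,reference [nb_lrt_test()] results.
#' @return A single non-negative number.
#' @export
mad_lfc <- function(test, reference) {
  g <- shared_genes(test, reference)
  lt <- test$lfc[match(g, test$gene)]
  lr <- reference$lfc[match(g, reference$gene)]
  mean(abs(lt - lr))
}

#' Standardized log-fold-change (signal-to-noise ratio)
#'
#' `lfc / se` per gene over a gene set of interest (for instance, the truly
#' differential genes of a simulation, or a pathway known to differ between
#' the groups). Its mean absolute value increases with sample size and with
#' decreasing within-group variability, so it gauges how well a design
#' resolves the biological effect. Genes with a zero or non-finite standard
#' error are skipped with a message.
#'
#' @param test An [nb_lrt_test()] result.
#' @param geneset Optional character vector of gene ids; default all genes.
#' @return A tibble (`gene`, `lfc`, `se`, `slfc`) with attribute
#'   `"mean_abs"`, the mean of `|slfc|`.
#' @export
standardized_lfc <- function(test, geneset = NULL) {
  d <- as_tibble(test)[, c("gene", "lfc", "se")]
  if (!is.null(geneset)) d <- d[d$gene %in% geneset, ]
  stop_if_not(nrow(d) > 0, "gene set is empty after intersection",
    class = "poolrna_input_error")
  bad <- !is.finite(d$se) | d$se == 0
  if (any(bad)) {
    inform(sprintf("skipping %d gene%s with zero or non-finite SE", sum(bad),
                   if (sum(bad) == 1) "" else "s"))
    d <- d[!bad, ]
  }
  d$slfc <- d$lfc / d$se
  attr(d, "mean_abs") <- mean(abs(d$slfc))
  d
}

#' Concordance of differential-expression calls with a reference
#'
#' Fraction of the genes called differential in the test scenario that are
#' also called differential in the reference scenario, both at the same
#' nominal FDR level. When the test scenario calls nothing the concordance
#' is defined as 1 (with a message): an empty call set cannot disagree.
#'
#' @param test,reference [nb_lrt_test()] results.
#' @param level Nominal FDR level for both call sets (default 0.05).
#' @return A number in `[0, 1]`.
#' @export
concordance <- function(test, reference, level = 0.05) {
  g <- shared_genes(test, reference)
  de_t <- g[test$q_value[match(g, test$gene)] <= level]
  de_r <- g[reference$q_value[match(g, reference$gene)] <= level]
  if (length(de_t) == 0) {
    inform("test scenario calls no genes DE; concordance defined as 1")
    return(1)
  }
  length(intersect(de_t, de_r)) / length(de_t)
}

#' Actual FDR and TPR against simulation truth
#'
#' Evaluates the realized false-discovery proportion and sensitivity of a
#' differential-expression result over a grid of nominal FDR levels, using
#' the simulator's ground-truth DE indicator. `FDR = FP / max(1, FP + TP)`
#' (0 when nothing is called) and `TPR = TP / (number of truly DE genes)`.
#'
#' @param test An [nb_lrt_test()] result.
#' @param truth Logical DE indicator named by gene, or a data frame with
#'   columns `gene` and `de` (as in `sim$genes`).
#' @param nominal_grid Nominal FDR levels (default 0 to 0.4 in steps of
#'   0.01).
#' @return A tibble of class `"pool_fdr_tpr"`: `nominal`, `n_called`, `fdr`,
#'   `tpr`.
#' @export
fdr_tpr <- function(test, truth, nominal_grid = seq(0, 0.4, by = 0.01)) {
  if (is.data.frame(truth)) {
    stop_if_not(all(c("gene", "de") %in% names(truth)),
      "`truth` data frame needs columns gene and de",
      class = "poolrna_input_error")
    truth <- setNames(as.logical(truth$de), truth$gene)
  }
  stop_if_not(!is.null(names(truth)),
    "`truth` must be named by gene (or be a data frame)",
    class = "poolrna_mode_error")
  g <- intersect(test$gene, names(truth))
  stop_if_not(length(g) > 0, "no genes shared with the truth table",
    class = "poolrna_input_error")
  qv <- test$q_value[match(g, test$gene)]
  tr <- truth[g]
  n_pos <- sum(tr)
  stop_if_not(n_pos > 0, "truth table flags no DE genes",
    class = "poolrna_mode_error")
  rows <- lapply(nominal_grid, function(lvl) {
    called <- qv <= lvl
    tp <- sum(called & tr)
    fp <- sum(called & !tr)
    tibble(nominal = lvl, n_called = tp + fp,
           fdr = fp / max(1, fp + tp), tpr = tp / n_pos)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pool_fdr_tpr", class(out))
  out
}

#' Composite performance score and ranking of scenarios
#'
#' Summarises five evaluation metrics per scenario - the inverse of the LFC
#' bias, the mean absolute standardized LFC, the concordance with the
#' reference, one minus the actual FDR, and the sensitivity - by
#' standardizing each across scenarios (z-scores) and averaging; scenarios
#' are then ranked by decreasing average z-score, with ties broken in favour
#' of the cheaper design. A metric that is constant across scenarios gets
#' z-score 0 (with a message); an infinite inverse bias (the reference
#' compares to itself with bias 0) is replaced by the largest finite value
#' before standardizing.
#'
#' @param metrics A data frame with one row per scenario and columns
#'   `scenario`, `mad`, `slfc`, `concordance`, `fdr`, `tpr`, `cost`.
#' @return The input with added columns `z_inv_mad`, `z_slfc`,
#'   `z_concordance`, `z_one_minus_fdr`, `z_tpr`, `score`, `rank` (1 =
#'   best), class `"pool_ranking"`.
#' @export
performance_score <- function(metrics) {
  need <- c("scenario", "mad", "slfc", "concordance", "fdr", "tpr", "cost")
  stop_if_not(is.data.frame(metrics) && all(need %in% names(metrics)),
    paste("`metrics` needs columns", paste(need, collapse = ", ")),
    class = "poolrna_input_error")
  stop_if_not(nrow(metrics) >= 2, "ranking needs at least two scenarios",
    class = "poolrna_input_error")
  inv_mad <- 1 / metrics$mad
  if (any(is.infinite(inv_mad))) {
    finite <- inv_mad[is.finite(inv_mad)]
    stop_if_not(length(finite) > 0, "all scenarios have zero LFC bias",
      class = "poolrna_input_error")
    inform("zero LFC bias treated as the best finite inverse bias")
    inv_mad[is.infinite(inv_mad)] <- max(finite)
  }
  zscore <- function(x, label) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) {
      inform(sprintf("metric %s is constant across scenarios; z-score 0",
                     label))
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  out <- as_tibble(metrics)
  out$z_inv_mad <- zscore(inv_mad, "1/MAD")
  out$z_slfc <- zscore(out$slfc, "standardized LFC")
  out$z_concordance <- zscore(out$concordance, "concordance")
  out$z_one_minus_fdr <- zscore(1 - out$fdr, "1 - FDR")
  out$z_tpr <- zscore(out$tpr, "TPR")
  out$score <- rowMeans(out[, c("z_inv_mad", "z_slfc", "z_concordance",
                                "z_one_minus_fdr", "z_tpr")])
  ord <- order(-out$score, out$cost)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  class(out) <- c("pool_ranking", class(out))
  out
}
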