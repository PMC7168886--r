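#' Simulation-based evaluation and ranking of design scenarios
#'
#' Runs the full benchmarking loop: for each replicate a fresh two-group
#' count matrix with known truth is simulated ([simulate_counts()]); every
#' scenario - including the reference - is derived from it in silico
#' ([apply_scenario()]), filtered for sufficiently expressed genes
#' ([filter_expressed()]) and tested for differential expression
#' ([nb_lrt_test()]); per-scenario metrics are computed against the
#' reference result and the ground truth. Metrics are averaged over
#' replicates and summarised into a composite score and ranking
#' ([performance_score()]).
#'
#' The standardized-LFC metric is evaluated over the truly differential
#' genes (the simulation analogue of a gene set known to differ between the
#' groups). Scenario costs come from [total_cost()] under `model`.
#'
#' @param scenarios A scenario table, e.g. [builtin_scenarios()]; must
#'   contain exactly one row flagged `reference`.
#' @param config A [sim_config()] whose group sizes cover the largest
#'   scenario.
#' @param replicates Number of independent simulation replicates.
#' @param nominal_fdr Nominal FDR for calls and the FDR/TPR point metrics.
#' @param nominal_grid Grid of nominal levels for the FDR-TPR curves.
#' @param seed Optional integer seed; replicate sub-seeds are derived from
#'   it deterministically.
#' @param model A [cost_model()].
#' @return A list of class `"pool_eval"`: `metrics` (per-scenario means),
#'   `ranking` ([performance_score()] output), `replicates` (per-replicate,
#'   per-scenario metrics), `curves` (mean FDR-TPR curve per scenario, class
#'   `"pool_fdr_tpr"`), and the call settings.
#' @examples
#' \donttest{
#' sc <- builtin_scenarios("1a")[c(1, 2, 6), ]
#' ev <- evaluate_scenarios(sc, sim_config(genes = 500), replicates = 2,
#'                          seed = 1)
#' tidy(ev)
#' }
#' @export
evaluate_scenarios <- function(scenarios = builtin_scenarios("1a"),
                               config = sim_config(),
                               replicates = 20,
                               nominal_fdr = 0.05,
                               nominal_grid = seq(0, 0.4, by = 0.02),
                               seed = NULL,
                               model = cost_model()) {
  stop_if_not(is.data.frame(scenarios) && nrow(scenarios) >= 1,
    "`scenarios` must be a scenario table")
  stop_if_not(sum(scenarios$reference) == 1,
    "`scenarios` must flag exactly one reference row",
    class = "poolrna_design_error")
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  need <- max(scenarios$samples_per_group)
  stop_if_not(min(config$n1, config$n2) >= need,
    sprintf("config provides %d+%d samples but scenarios need %d per group",
            config$n1, config$n2, need),
    class = "poolrna_design_error")
  check_scalar(replicates, "replicates", 1)

  ref_name <- scenarios$scenario[scenarios$reference]
  per_rep <- vector("list", replicates)
  curve_acc <- vector("list", replicates)

  for (r in seq_len(replicates)) {
    rs <- child_seed(seed, 1000 + r)
    sim <- simulate_counts(config, seed = rs)
    truth <- sim$genes
    de_genes <- truth$gene[truth$de]

    fits <- vector("list", nrow(scenarios))
    names(fits) <- scenarios$scenario
    for (i in seq_len(nrow(scenarios))) {
      ds <- apply_scenario(sim$counts, sim$samples$group, scenarios[i, ],
                           seed = child_seed(rs, i),
                           reference_depth = scenarios$depth[
                             scenarios$reference])
      keep <- filter_expressed(ds$counts)
      fits[[i]] <- suppressMessages(
        nb_lrt_test(ds$counts[keep, , drop = FALSE], ds$samples$group,
                    nominal_fdr = nominal_fdr))
    }
    ref_fit <- fits[[ref_name]]

    rows <- vector("list", nrow(scenarios))
    crows <- vector("list", nrow(scenarios))
    for (i in seq_len(nrow(scenarios))) {
      fit <- fits[[i]]
      point <- fdr_tpr(fit, truth, nominal_grid = nominal_fdr)
      curve <- fdr_tpr(fit, truth, nominal_grid = nominal_grid)
      rows[[i]] <- tibble(
        replicate = r,
        scenario = scenarios$scenario[i],
        n_genes = nrow(fit),
        mad = suppressMessages(mad_lfc(fit, ref_fit)),
        slfc = attr(suppressMessages(standardized_lfc(fit, de_genes)),
                    "mean_abs"),
        concordance = suppressMessages(
          concordance(fit, ref_fit, level = nominal_fdr)),
        fdr = point$fdr, tpr = point$tpr, n_called = point$n_called
      )
      crows[[i]] <- dplyr::mutate(curve, replicate = r,
                                  scenario = scenarios$scenario[i])
    }
    per_rep[[r]] <- dplyr::bind_rows(rows)
    curve_acc[[r]] <- dplyr::bind_rows(crows)
  }

  rep_tbl <- dplyr::bind_rows(per_rep)
  metrics <- rep_tbl |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(dplyr::across(c("n_genes", "mad", "slfc", "concordance",
                                     "fdr", "tpr", "n_called"), mean),
                     .groups = "drop")
  cost_tbl <- tibble(
    scenario = scenarios$scenario,
    cost = total_cost(scenarios$samples_total, scenarios$libraries_total,
                      scenarios$mreads_total, model)
  )
  metrics <- dplyr::left_join(metrics, cost_tbl, by = "scenario")
  metrics <- metrics[match(scenarios$scenario, metrics$scenario), ]
  ranking <- if (nrow(metrics) >= 2) {
    suppressMessages(performance_score(metrics))
  } else {
    NULL
  }
  curves <- dplyr::bind_rows(curve_acc) |>
    dplyr::group_by(.data$scenario, .data$nominal) |>
    dplyr::summarise(fdr = mean(.data$fdr), tpr = mean(.data$tpr),
                     n_called = mean(.data$n_called), .groups = "drop")
  class(curves) <- c("pool_fdr_tpr", class(curves))

  structure(list(metrics = metrics, ranking = ranking,
                 replicates = rep_tbl, curves = curves,
                 reference = ref_name,
                 settings = list(replicates = replicates,
                                 nominal_fdr = nominal_fdr,
                                 config = config, seed = seed)),
            class = "pool_eval")
}

#' @export
print.pool_eval <- function(x, ...) {
  cat(sprintf("<pool_eval> %d scenarios x %d replicates (reference %s)\n",
              nrow(x$metrics), x$settings$replicates, x$reference))
  print(if (!is.null(x$ranking)) {
    dplyr::arrange(as_tibble(x$ranking)[, c("scenario", "mad", "slfc",
                                            "concordance", "fdr", "tpr",
                                            "cost", "score", "rank")],
                   .data$rank)
  } else {
    x$metrics
  })
  invisible(x)
}

#' @rdname evaluate_scenarios
#' @param x A `"pool_eval"` object.
#' @param ... Unused.
#' @export
tidy.pool_eval <- function(x, ...) {
  if (!is.null(x$ranking)) as_tibble(x$ranking) else x$metrics
}

#' @rdname evaluate_scenarios
#' @export
glance.pool_eval <- function(x, ...) {
  best <- if (!is.null(x$ranking)) {
    x$ranking$scenario[x$ranking$rank == 1]
  } else {
    NA_character_
  }
  tibble(n_scenarios = nrow(x$metrics),
         replicates = x$settings$replicates,
         genes = x$settings$config$genes,
         nominal_fdr = x$settings$nominal_fdr,
         reference = x$reference,
         best_scenario = best)
}
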