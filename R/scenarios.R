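#' Built-in experimental design scenarios
#'
#' Two families of designs for a two-group comparison, spanning the typical
#' cost-saving strategies: reducing samples, reducing depth, pooling, and
#' combinations. Table `"1a"` holds a full-budget reference (80 tumour
#' samples, 40 libraries per group, ~20M reads each) plus 12 test scenarios;
#' table `"1b"` holds a small cell-line family (reference with 9 libraries
#' per group plus three 3-library designs with pool sizes 1, 2 and 3).
#'
#' `pool_size = 1` marks unpooled designs. `cost_printed` is the catalogue
#' cost of each design; all rows except the table-1a reference agree exactly
#' with [total_cost()] under the default [cost_model()] (the 1a reference
#' row's catalogue value is 200 currency units above the formula; it is kept
#' as catalogued).
#'
#' @param table `"1a"` (tissue family, 13 rows) or `"1b"` (cell-line family,
#'   4 rows).
#' @return A tibble with one row per scenario: `table`, `scenario`,
#'   `reference`, `samples_per_group`, `libraries_per_group`, `pool_size`,
#'   `depth` (reads per library), `pooling`, `samples_total`,
#'   `libraries_total`, `mreads_total`, `cost_printed`.
#' @examples
#' builtin_scenarios("1a")
#' @export
builtin_scenarios <- function(table = c("1a", "1b")) {
  table <- tryCatch(match.arg(table),
    error = function(e) abort("unknown scenario table; use \"1a\" or \"1b\"",
                              class = "poolrna_parameter_error"))
  if (table == "1a") {
    d <- tibble(
      scenario = c("A0", "A1", "A2", "A3", "A4",
                   "B1", "B2", "B3", "B4", "C1", "C2", "C3", "C4"),
      samples_total   = c(80, 40, 40, 80, 80, 80, 40, 80, 40, 80, 40, 80, 40),
      libraries_total = c(80, 40, 40, 80, 80, 40, 20, 40, 20, 20, 10, 20, 10),
      mreads_total    = c(1600, 800, 400, 800, 400, 800, 400, 400, 200,
                          400, 200, 200, 100),
      cost_printed    = c(21800, 10800, 7800, 15600, 12600, 11600, 5800,
                          8600, 4300, 6600, 3300, 5100, 2550),
      libraries_per_group = c(40, 20, 20, 40, 40, 20, 10, 20, 10,
                              10, 5, 10, 5),
      pool_size = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 4, 4, 4, 4)
    )
  } else {
    d <- tibble(
      scenario = c("A0", "A", "B", "C"),
      samples_total   = c(18, 6, 12, 18),
      libraries_total = c(18, 6, 6, 6),
      mreads_total    = c(270, 90, 90, 90),
      cost_printed    = c(4185, 1395, 1515, 1635),
      libraries_per_group = c(9, 3, 3, 3),
      pool_size = c(1, 1, 2, 3)
    )
  }
  d$table <- table
  d$reference <- d$scenario == "A0"
  d$samples_per_group <- d$samples_total / 2L
  d$depth <- d$mreads_total / d$libraries_total * 1e6
  d$pooling <- d$pool_size > 1
  d[, c("table", "scenario", "reference", "samples_per_group",
        "libraries_per_group", "pool_size", "depth", "pooling",
        "samples_total", "libraries_total", "mreads_total", "cost_printed")]
}

#' Derive one scenario's dataset from a source count matrix
#'
#' Emulates running a cheaper design on the population that produced the
#' source data. Within each group the engine (1) uniformly subsamples the
#' scenario's number of RNA samples, (2) randomly assigns them to pools of
#' the scenario's pool size, (3) draws Dirichlet mixing weights (one weight
#' vector per pool, shared by all genes), (4) computes weighted pooled counts
#' and rounds them half-to-even to integers, and (5) binomially thins all
#' libraries by a common fraction when the scenario's depth per library is
#' below the source's average depth. Pooling happens before thinning, which
#' mirrors reducing the sequencing budget of an already-pooled library.
#'
#' Thinning uses one retention fraction per scenario
#' (`depth / reference_depth`), not a per-library hard target, so realised
#' library sizes keep their natural spread while their mean matches the
#' scenario depth; a scenario asking for more depth than the source has
#' triggers a warning and keeps the achievable depth.
#'
#' @param counts Integer gene x sample source matrix.
#' @param groups Group label per column (two levels).
#' @param scenario A one-row scenario, e.g. one row of
#'   [builtin_scenarios()].
#' @param seed Optional integer seed controlling subsampling, pool
#'   assignment, mixing weights and thinning.
#' @param concentration Dirichlet concentration for the mixing weights
#'   (default 1; `Inf` = exact equal mixing).
#' @param reference_depth Average depth per library of the source design, in
#'   reads; defaults to `mean(colSums(counts))`.
#' @return A list of class `"pooled_dataset"`: `counts` (gene x library
#'   integer matrix), `samples` (tibble: `library`, `group`, `lib_size`),
#'   `provenance` (tibble: `library`, `group`, `pool`, `source_sample`,
#'   `weight`), and `scenario`.
#' @export
apply_scenario <- function(counts, groups, scenario, seed = NULL,
                           concentration = 1, reference_depth = NULL) {
  stop_if_not(is_count_matrix(counts),
    "`counts` must be a non-negative integer matrix",
    class = "poolrna_input_error")
  stop_if_not(is.data.frame(scenario) && nrow(scenario) == 1,
    "`scenario` must be a single scenario row")
  groups <- as.factor(groups)
  stop_if_not(length(groups) == ncol(counts),
    "`groups` must have one label per column of `counts`",
    class = "poolrna_input_error")
  lev <- levels(groups)
  stop_if_not(length(lev) == 2, "exactly two groups are required",
    class = "poolrna_design_error")
  S <- scenario$samples_per_group
  m <- scenario$libraries_per_group
  q <- scenario$pool_size
  stop_if_not(S == m * q,
    "scenario samples per group must equal libraries x pool size",
    class = "poolrna_design_error")
  stop_if_not(all(tabulate(groups) >= S),
    sprintf("scenario needs %d samples per group; source has %s", S,
            paste(tabulate(groups), collapse = ", ")),
    class = "poolrna_design_error")
  reference_depth <- reference_depth %||% mean(colSums(counts))
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }

  one_group <- function(g, gseed) {
    cols <- which(groups == lev[g])
    pick <- with_seed_if(gseed, sort(sample(cols, S)))
    assign <- assign_samples_to_pools(S, rep(q, m),
                                      seed = child_seed(gseed, 1))
    w <- draw_mixing_weights(rep(q, m), concentration = concentration,
                             seed = child_seed(gseed, 2))
    U <- counts[, pick, drop = FALSE]
    Y <- U %*% pool_weight_matrix(assign, w)
    lib_ids <- sprintf("%s_p%02d", lev[g], seq_len(m))
    colnames(Y) <- lib_ids
    prov <- tibble(
      library = lib_ids[assign$pool],
      group = lev[g],
      pool = assign$pool,
      source_sample = colnames(counts)[pick[assign$sample]],
      weight = w$weight  # both tibbles are pool-major, member-ascending
    )
    list(Y = Y, prov = prov)
  }

  g1 <- one_group(1, child_seed(seed, 101))
  g2 <- one_group(2, child_seed(seed, 202))
  Y <- cbind(g1$Y, g2$Y)
  Y <- round(Y)  # round() is round-half-to-even
  storage.mode(Y) <- "integer"
  rownames(Y) <- rownames(counts)

  p <- scenario$depth / reference_depth
  if (p < 1) {
    Y <- thin_depth(Y, p * colSums(Y), seed = child_seed(seed, 303))
  } else if (p > 1.02) {
    warn(sprintf(
      "scenario depth (%.3g) exceeds the source depth (%.3g); keeping the achievable depth",
      scenario$depth, reference_depth))
  }

  structure(list(
    counts = Y,
    samples = tibble(library = colnames(Y),
                     group = rep(lev, each = m),
                     lib_size = colSums(Y)),
    provenance = dplyr::bind_rows(g1$prov, g2$prov),
    scenario = as_tibble(scenario)
  ), class = "pooled_dataset")
}

#' @export
print.pooled_dataset <- function(x, ...) {
  cat(sprintf(
    "<pooled_dataset> scenario %s: %d genes x %d libraries (pool size %d, mean depth %.2gM)\n",
    x$scenario$scenario %||% "?", nrow(x$counts), ncol(x$counts),
    x$scenario$pool_size, mean(x$samples$lib_size) / 1e6))
  invisible(x)
}

#' Genes with sufficient expression
#'
#' Keeps genes with a non-zero count in at least `min_samples` libraries
#' (groups combined); the boundary is inclusive.
#'
#' @param counts Gene x library count matrix.
#' @param min_samples Minimum number of libraries with a non-zero count
#'   (default 3).
#' @return Integer vector of row indices of the retained genes (named when
#'   `counts` has rownames).
#' @export
filter_expressed <- function(counts, min_samples = 3) {
  check_scalar(min_samples, "min_samples", 1)
  which(rowSums(counts > 0) >= min_samples)
}
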