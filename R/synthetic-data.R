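#' Configuration of the negative binomial count simulator
#'
#' Describes a two-group bulk RNA-seq experiment with known differential-
#' expression truth. Defaults emulate a tumour-tissue experiment: 5000
#' genes, 40 samples per group, library sizes uniform on 15-25 million
#' reads, 10% of genes differentially expressed with |log2 fold change|
#' at least 1, and gene-wise dispersions drawn log-normally around a
#' tissue-like median.
#'
#' Two dispersion presets are built in. `"tissue"` (median over-dispersion
#' 0.5, sdlog 0.8) emulates heterogeneous tumour material, where squared
#' biological coefficients of variation of 0.1-2 are typical; `"cellline"`
#' (median 0.05, sdlog 0.5) emulates homogeneous cultured cells. A numeric
#' value gives every gene that constant dispersion (0 = Poisson).
#'
#' @param genes Number of genes `G`.
#' @param n1,n2 Samples per group.
#' @param frac_de Fraction of genes differentially expressed (0-1); the
#'   number of DE genes is `floor(frac_de * genes)`.
#' @param lfc_min Minimum absolute log2 fold change of DE genes.
#' @param lfc_mode `"exponential"`: |LFC| = `lfc_min` + Exponential(rate 2);
#'   `"fixed"`: |LFC| = `lfc_min` exactly.
#' @param dispersion `"tissue"`, `"cellline"`, or a non-negative number.
#' @param lib_range Lower and upper bound of the uniform library-size law,
#'   in reads.
#' @param rho_range Range of the log-uniform law for baseline relative
#'   abundances (normalised to sum to 1 across genes, so a sample's expected
#'   total count equals its library size).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(genes = 5000, n1 = 40, n2 = 40, frac_de = 0.1,
                       lfc_min = 1, lfc_mode = c("exponential", "fixed"),
                       dispersion = "tissue",
                       lib_range = c(15e6, 25e6),
                       rho_range = c(1e-8, 1e-4)) {
  lfc_mode <- match.arg(lfc_mode)
  check_scalar(genes, "genes", 1)
  check_scalar(n1, "n1", 1); check_scalar(n2, "n2", 1)
  stop_if_not(frac_de >= 0 && frac_de <= 1, "`frac_de` must be in [0, 1]",
    class = "poolrna_parameter_error")
  check_scalar(lfc_min, "lfc_min", 0)
  stop_if_not(length(lib_range) == 2 && all(lib_range > 0) &&
    lib_range[1] <= lib_range[2], "`lib_range` must be positive and ordered",
    class = "poolrna_parameter_error")
  stop_if_not(length(rho_range) == 2 && all(rho_range > 0) &&
    rho_range[1] <= rho_range[2], "`rho_range` must be positive and ordered",
    class = "poolrna_parameter_error")
  if (is.character(dispersion)) {
    stop_if_not(dispersion %in% c("tissue", "cellline"),
      "dispersion preset must be \"tissue\" or \"cellline\"",
      class = "poolrna_parameter_error")
  } else {
    check_scalar(dispersion, "dispersion", 0)
  }
  structure(list(genes = as.integer(genes), n1 = as.integer(n1),
                 n2 = as.integer(n2), frac_de = frac_de, lfc_min = lfc_min,
                 lfc_mode = lfc_mode, dispersion = dispersion,
                 lib_range = lib_range, rho_range = rho_range),
            class = "sim_config")
}

disp_presets <- list(
  tissue   = c(meanlog = log(0.5),  sdlog = 0.8),
  cellline = c(meanlog = log(0.05), sdlog = 0.5)
)

#' Simulate a two-group RNA-seq count matrix with built-in truth
#'
#' Draws virtual counts `U_gj ~ NB(mean = rho_g * L_j * 2^(theta_g * [j in
#' group 2]), dispersion = phi_g)`, with group-2 abundances renormalised so
#' that every sample's expected total equals its library size. DE genes are
#' sampled uniformly; half are up- and half down-regulated in group 2.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical config + seed reproduce the
#'   counts exactly.
#' @return A list of class `"sim_dataset"`: `counts` (gene x sample integer
#'   matrix), `samples` (tibble: `sample`, `group`, `lib_size`), `genes`
#'   (tibble: `gene`, `rho`, `theta`, `de`, `phi`), and `config`.
#' @examples
#' sim <- simulate_counts(sim_config(genes = 100, n1 = 4, n2 = 4), seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(config = sim_config(), seed = NULL) {
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  with_seed_if(seed, {
    G <- config$genes
    n <- config$n1 + config$n2
    group <- rep(c(1L, 2L), c(config$n1, config$n2))
    L <- runif(n, config$lib_range[1], config$lib_range[2])
    rho <- exp(runif(G, log(config$rho_range[1]), log(config$rho_range[2])))
    rho <- rho / sum(rho)
    n_de <- floor(config$frac_de * G)
    if (config$frac_de > 0 && n_de < config$frac_de * G) {
      inform(sprintf("frac_de * genes is not an integer; using %d DE genes",
                     n_de))
    }
    theta <- numeric(G)
    de <- rep(FALSE, G)
    if (n_de > 0) {
      idx <- sample.int(G, n_de)
      de[idx] <- TRUE
      mag <- if (config$lfc_mode == "fixed") rep(config$lfc_min, n_de) else
        config$lfc_min + rexp(n_de, rate = 2)
      sign <- rep(c(1, -1), length.out = n_de)[sample.int(n_de)]
      theta[idx] <- sign * mag
    }
    phi <- if (is.character(config$dispersion)) {
      p <- disp_presets[[config$dispersion]]
      exp(rnorm(G, p["meanlog"], p["sdlog"]))
    } else {
      rep(config$dispersion, G)
    }
    rho2 <- rho * 2^theta
    rho2 <- rho2 / sum(rho2)
    mu <- cbind(rho %o% L[group == 1L], rho2 %o% L[group == 2L])
    counts <- matrix(0L, G, n)
    pois <- phi == 0
    if (any(pois)) {
      counts[pois, ] <- rpois(sum(pois) * n, mu[pois, , drop = FALSE])
    }
    if (any(!pois)) {
      counts[!pois, ] <- rnbinom(sum(!pois) * n,
                                 mu = mu[!pois, , drop = FALSE],
                                 size = 1 / phi[!pois])
    }
    storage.mode(counts) <- "integer"
    gene_ids <- sprintf("gene_%0*d", nchar(G), seq_len(G))
    sample_ids <- sprintf("s%0*d", nchar(n), seq_len(n))
    dimnames(counts) <- list(gene_ids, sample_ids)
    structure(list(
      counts = counts,
      samples = tibble(sample = sample_ids, group = group, lib_size = L),
      genes = tibble(gene = gene_ids, rho = rho, theta = theta, de = de,
                     phi = phi),
      config = config
    ), class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d genes x %d samples (%d + %d), %d DE genes, %s dispersion\n",
    nrow(x$counts), ncol(x$counts), x$config$n1, x$config$n2,
    sum(x$genes$de),
    if (is.character(x$config$dispersion)) x$config$dispersion else "constant"
  ))
  invisible(x)
}

#' Binomial thinning of a count matrix to a target depth
#'
#' Downsamples each library independently: every read is kept with
#' probability `target_depth / current total`, so the expected thinned total
#' equals the target and gene-wise relative abundances are preserved in
#' expectation. Libraries already at or below their target are returned
#' unchanged (thinning never up-samples), with a warning.
#'
#' @param counts Non-negative integer gene x sample matrix.
#' @param target_depth Target total reads per sample; length 1 or one value
#'   per column.
#' @param seed Optional integer seed.
#' @return An integer matrix of the same shape.
#' @examples
#' m <- matrix(rpois(200, 50), 20, 10)
#' colSums(thin_depth(m, 250, seed = 1))
#' @export
thin_depth <- function(counts, target_depth, seed = NULL) {
  stop_if_not(is_count_matrix(counts),
    "`counts` must be a non-negative integer matrix",
    class = "poolrna_input_error")
  totals <- colSums(counts)
  target <- rep_len(as.double(target_depth), ncol(counts))
  stop_if_not(all(target >= 0), "`target_depth` must be non-negative",
    class = "poolrna_parameter_error")
  p <- ifelse(totals > 0, target / totals, 1)
  if (any(p > 1)) {
    warn(sprintf(
      "%d librar%s already at or below the target depth; left unchanged",
      sum(p > 1), if (sum(p > 1) == 1) "y is" else "ies are"))
    p <- pmin(p, 1)
  }
  if (all(p == 1)) return(counts)
  out <- with_seed_if(seed, {
    thinned <- counts
    redo <- which(p < 1)
    for (j in redo) {
      thinned[, j] <- rbinom(nrow(counts), counts[, j], p[j])
    }
    thinned
  })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(counts)
  out
}
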