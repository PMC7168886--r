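# Readers and writers for the plain-text formats the package exchanges:
# TSV count matrices (first column = gene id), MatrixMarket matrices with
# .rows/.cols sidecar files, and sample/group annotation tables.

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV files must carry gene ids in the first column and one column per
#' library. A `.mtx` file is read with the `Matrix` package and expects
#' sidecar files `<stem>.rows` and `<stem>.cols` holding the gene and
#' library ids, one per line.
#'
#' @param path Path to a `.tsv`/`.txt` or `.mtx` file.
#' @return An integer gene x library matrix with dimnames.
#' @export
read_counts <- function(path) {
  stop_if_not(file.exists(path), sprintf("file not found: %s", path),
    class = "poolrna_input_error")
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rows <- paste0(stem, ".rows")
    cols <- paste0(stem, ".cols")
    if (file.exists(rows)) rownames(m) <- readLines(rows)
    if (file.exists(cols)) colnames(m) <- readLines(cols)
  } else {
    d <- readr::read_tsv(path, show_col_types = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix
#'
#' @param counts Gene x library matrix with dimnames.
#' @param path Output path; a `.mtx` suffix selects MatrixMarket (with
#'   `.rows`/`.cols` sidecars), anything else tab-separated text with the
#'   gene ids in a `gene` column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))),
               paste0(stem, ".rows"))
    writeLines(colnames(counts) %||% as.character(seq_len(ncol(counts))),
               paste0(stem, ".cols"))
  } else {
    d <- as_tibble(counts, rownames = "gene")
    readr::write_tsv(d, path)
  }
  invisible(path)
}

#' Read a sample annotation table
#'
#' A TSV with at least columns `sample` and `group` (optionally
#' `lib_size`).
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_groups <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stop_if_not(all(c("sample", "group") %in% names(d)),
    "groups file must have columns sample and group",
    class = "poolrna_input_error")
  d
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `counts.tsv`, `counts.mtx` (+ sidecars), `samples.tsv` and
#' `truth.tsv` into a directory, so the ground truth round-trips with the
#' counts.
#'
#' @param sim A [simulate_counts()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stop_if_not(inherits(sim, "sim_dataset"), "`sim` must be a sim_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.mtx"))
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$genes, file.path(dir, "truth.tsv"))
  invisible(dir)
}
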