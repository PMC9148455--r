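#' Count matrix container
#'
#' Light container for a genes x samples matrix of non-negative integer
#' counts, carrying library sizes (column sums) and, once computed,
#' median-of-ratios size factors.
#'
#' @param counts Integer matrix (genes in rows, samples in columns).
#' @param gene_ids,sample_ids Optional dimension names; taken from `counts`
#'   when present.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(counts))
    stop(sprintf("counts must be non-negative integers; offending entry at row %d, column %d: %s",
                 ij[1], ij[2], format(counts[bad[1]])))
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (nrow(counts) > 0) rownames(counts) <- gene_ids
  if (ncol(counts) > 0) colnames(counts) <- sample_ids
  structure(list(
    counts = counts,
    gene_ids = gene_ids,
    sample_ids = sample_ids,
    library_sizes = colSums(counts),
    size_factors = NULL
  ), class = "count_matrix")
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      "median library size", format(stats::median(x$library_sizes), big.mark = ","), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix from TSV/CSV or MatrixMarket files
#'
#' TSV/CSV files must have gene ids in the first column and one column per
#' sample. MatrixMarket (`.mtx`) input additionally requires sidecar files
#' `<stem>.genes.txt` and `<stem>.samples.txt` (one id per line), or explicit
#' `genes_path`/`samples_path`.
#'
#' @param path Path to the counts file.
#' @param genes_path,samples_path Optional row/column name files for MTX input.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, genes_path = NULL, samples_path = NULL) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(genes_path)) genes_path <- paste0(stem, ".genes.txt")
    if (is.null(samples_path)) samples_path <- paste0(stem, ".samples.txt")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(samples_path)
    return(count_matrix(m))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts file must have a gene-id column plus sample columns")
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- gene_ids
  count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' @param x A [count_matrix()] or plain matrix.
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  x <- as_count_matrix(x)
  df <- data.frame(gene = x$gene_ids, x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata and build a study design
#'
#' Expects a TSV with columns `sample`, `subject`, `group`, `time`. Rows are
#' kept in file order; when `counts` is supplied, rows are aligned to its
#' sample columns and unknown/missing samples raise an error.
#'
#' @param path Path to the metadata TSV.
#' @param counts Optional [count_matrix()] to align sample order against.
#' @param group_ref Optional reference group label (default: first
#'   alphabetically).
#' @return A `study_design`.
#' @export
read_metadata <- function(path, counts = NULL, group_ref = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    counts <- as_count_matrix(counts)
    missing <- setdiff(counts$sample_ids, df$sample)
    if (length(missing))
      stop("metadata is missing sample(s): ", paste(missing, collapse = ", "))
    df <- df[match(counts$sample_ids, df$sample), ]
  }
  new_study_design(df, group_ref = group_ref)
}

#' Write study-design metadata as TSV
#' @param design A `study_design`.
#' @param path Output path.
#' @export
write_metadata <- function(design, path) {
  utils::write.table(design$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
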