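#' Construct a labelled expression dataset
#'
#' The canonical container used throughout the package: a numeric matrix of
#' expression values in samples-by-genes orientation, gene identifiers, and
#' an integer class label per sample. Labels are remapped to the contiguous
#' range `1..c`; the original label values are retained in the
#' `label_levels` attribute so reports can echo them.
#'
#' @param values Numeric matrix, `n_samples` rows by `n_genes` columns.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column of `values`.
#' @param labels Vector of class labels, one per row of `values`. Coerced to
#'   integers `1..c` in order of first appearance of the sorted unique values.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `gene_ids`, `labels` (integer in `1..c`), `n_classes` and `sample_ids`.
#'
#' @details Invariants enforced at construction: all values finite, every
#'   class has at least two samples (per-class standard deviations are needed
#'   by the IIC statistic), and gene identifiers are unique.
#' @export
expression_dataset <- function(values, gene_ids = colnames(values),
                               labels, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != ncol(values)) {
    stop_scipso("data", "gene_ids length (", length(gene_ids),
                ") does not match number of genes (", ncol(values), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop_scipso("data", "gene identifiers must be unique; duplicated: ",
                paste(unique(gene_ids[duplicated(gene_ids)])[1:3], collapse = ", "))
  }
  if (length(labels) != nrow(values)) {
    stop_scipso("data", "labels length does not match number of samples")
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_scipso("data", "non-finite expression value at sample ", bad[1, 1],
                ", gene '", gene_ids[bad[1, 2]], "'")
  }
  label_levels <- sort(unique(labels))
  labels_int <- match(labels, label_levels)
  counts <- tabulate(labels_int, nbins = length(label_levels))
  if (length(label_levels) < 2L) {
    stop_scipso("data", "need at least 2 classes, got ", length(label_levels))
  }
  if (any(counts < 2L)) {
    k <- which(counts < 2L)[1]
    stop_scipso("data", "class '", label_levels[k], "' has ", counts[k],
                " sample(s); every class needs at least 2")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  dimnames(values) <- NULL
  structure(
    list(values = values, gene_ids = gene_ids,
         labels = as.integer(labels_int), n_classes = length(label_levels),
         sample_ids = as.character(sample_ids),
         label_levels = label_levels),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", nrow(x$values), "samples x", ncol(x$values),
      "genes,", x$n_classes, "classes\n")
  cat("  class sizes:", paste(tabulate(x$labels, x$n_classes), collapse = "/"),
      "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Load a labelled expression matrix from delimited text
#'
#' Reads a CSV/TSV file with a header row into an [expression_dataset].
#' Orientation is explicit -- the loader never guesses whether rows are
#' samples or genes, because a silently transposed matrix is the classic
#' failure mode with microarray tables.
#'
#' @param path Path to a delimited text file with a header row. The first
#'   column holds sample identifiers (samples-by-genes) or gene identifiers
#'   (genes-by-samples).
#' @param label_column Name of the column (samples-by-genes) or row
#'   (genes-by-samples) holding the class labels.
#' @param orientation `"samples_by_genes"` (canonical) or
#'   `"genes_by_samples"`, in which case the table is transposed on load.
#' @param sep Field separator; defaults to tab for `.tsv`/`.txt`, comma
#'   otherwise.
#' @param na_action `"error"` (default) rejects any missing or non-numeric
#'   expression cell, naming its position; `"impute_mean"` replaces missing
#'   values by the gene's mean across samples with observed values.
#' @return An [expression_dataset].
#' @seealso [write_dataset()] for the inverse operation.
#' @export
load_dataset <- function(path, label_column = "label",
                         orientation = c("samples_by_genes", "genes_by_samples"),
                         sep = NULL, na_action = c("error", "impute_mean")) {
  orientation <- match.arg(orientation)
  na_action <- match.arg(na_action)
  if (!file.exists(path)) stop_scipso("data", "file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2L) stop_scipso("data", "table has fewer than 2 columns")
  ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]

  if (orientation == "genes_by_samples") {
    # rows are genes (plus one label row); transpose to canonical orientation
    row_is_label <- ids == label_column
    if (!any(row_is_label)) {
      stop_scipso("data", "label row '", label_column, "' not found")
    }
    labels <- unlist(body[row_is_label, , drop = TRUE], use.names = FALSE)
    mat <- t(as.matrix(body[!row_is_label, , drop = FALSE]))
    values <- matrix(suppressWarnings(as.numeric(mat)), nrow = nrow(mat))
    gene_ids <- ids[!row_is_label]
    sample_ids <- colnames(body)
  } else {
    col_is_label <- names(body) == label_column
    if (!any(col_is_label)) {
      stop_scipso("data", "label column '", label_column, "' not found")
    }
    labels <- body[[which(col_is_label)[1]]]
    expr <- body[, !col_is_label, drop = FALSE]
    values <- matrix(suppressWarnings(as.numeric(as.matrix(expr))),
                     nrow = nrow(expr))
    gene_ids <- names(expr)
    sample_ids <- ids
  }

  labels <- suppressWarnings(as.integer(labels))
  if (anyNA(labels)) stop_scipso("data", "labels not castable to integers")

  miss <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    if (na_action == "error") {
      stop_scipso("data", "missing or non-numeric expression value at sample ",
                  sample_ids[miss[1, 1]], ", gene '", gene_ids[miss[1, 2]], "'")
    }
    for (j in unique(miss[, 2])) {
      col <- values[, j]
      col[!is.finite(col)] <- mean(col[is.finite(col)])
      values[, j] <- col
    }
  }
  expression_dataset(values, gene_ids, labels, sample_ids)
}

#' Write a dataset as delimited text
#'
#' Writes the canonical samples-by-genes layout (sample identifier column,
#' one column per gene, plus the label column) with enough digits that
#' [load_dataset()] reproduces the values to full double precision.
#'
#' @param ds An [expression_dataset].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, label_column = "label") {
  stopifnot(inherits(ds, "expression_dataset"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  header <- paste(c("sample_id", ds$gene_ids, label_column), collapse = sep)
  # original label values, not the remapped 1..c codes
  orig_labels <- ds$label_levels[ds$labels]
  rows <- vapply(seq_len(nrow(ds$values)), function(i) {
    paste(c(ds$sample_ids[i], sprintf("%.17g", ds$values[i, ]),
            as.character(orig_labels[i])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits samples into disjoint training and testing sets, stratified by
#' class so the training split contains every class. Within each class,
#' `round(train_fraction * n_class)` samples (at least one) are assigned to
#' training.
#'
#' @param ds An [expression_dataset].
#' @param train_fraction Fraction of samples to train on, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return An object of class `split_spec` with integer vectors
#'   `train_indices` and `test_indices` (a partition of `1..n`) and the seed.
#' @examples
#' ds <- generate_synthetic(synth_spec(n_per_class = c(6, 6), n_genes = 20,
#'                                     n_informative = 2, seed = 1))$dataset
#' sp <- split_dataset(ds, 0.5, seed = 7)
#' length(sp$train_indices) + length(sp$test_indices) == nrow(ds$values)
#' @export
split_dataset <- function(ds, train_fraction, seed) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop_scipso("data", "train_fraction must be strictly inside (0, 1)")
  }
  n <- nrow(ds$values)
  train <- integer(0)
  with_seed(seed, {
    for (k in seq_len(ds$n_classes)) {
      idx <- which(ds$labels == k)
      n_tr <- max(1L, min(length(idx), as.integer(round(train_fraction * length(idx)))))
      train <- c(train, sample(idx)[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  if (length(test) == 0L) {
    stop_scipso("data", "split leaves no testing samples; lower train_fraction")
  }
  structure(list(train_indices = train, test_indices = test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Write a ranked gene list as TSV
#'
#' Serializes a ranking produced by the pipeline (columns: rank, 1-based gene
#' serial number, gene identifier, score) in the layout used by all reports.
#' Serial numbers are 1-based column positions in the input matrix, matching
#' the numbering conventionally used to report microarray gene subsets.
#'
#' @param ranking Data frame with columns `rank`, `serial`, `gene_id`,
#'   `score` (additional columns are carried through).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_ranking <- function(ranking, path) {
  stopifnot(is.data.frame(ranking),
            all(c("rank", "serial", "gene_id", "score") %in% names(ranking)))
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
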