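# Synthetic microarray generator: Gaussian expression matrices with a
# planted set of class-informative genes, shaped like the public microarray
# benchmarks this method targets (tens of samples, thousands of genes,
# 2-5 classes). Used by the tests and the acceptance experiments so every
# stage is exercisable without external downloads.

#' Specification for a synthetic expression dataset
#'
#' @param n_per_class Integer vector of per-class sample counts (length =
#'   number of classes, each >= 2).
#' @param n_genes Total number of genes `G`.
#' @param n_informative Number of planted informative genes `k <= G`.
#' @param effect_size Class-mean separation `delta`, in units of the
#'   within-class standard deviation: class `j` shifts an informative gene's
#'   mean by `(j - 1) * delta * sigma`.
#' @param sigma Within-class standard deviation of every gene.
#' @param log_normal If `TRUE`, expression values are exponentiated
#'   (log-normal intensities) for a heavier-tailed, strictly positive matrix.
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_per_class = c(30L, 30L), n_genes = 2000L,
                       n_informative = 10L, effect_size = 2,
                       sigma = 1, log_normal = FALSE, seed = 1L) {
  stopifnot(length(n_per_class) >= 2L, all(n_per_class >= 2L),
            n_informative <= n_genes, effect_size >= 0, sigma > 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, sigma = sigma,
                 log_normal = isTRUE(log_normal), seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic labelled expression dataset with planted genes
#'
#' Non-informative genes are `Normal(0, sigma^2)` independent of class;
#' each informative gene receives class-specific mean offsets spaced
#' `effect_size * sigma` apart across the classes. The informative genes are
#' shuffled into random column positions so positional bookkeeping bugs
#' surface in recovery tests; their positions are returned as the ground
#' truth.
#'
#' @param spec A [synth_spec()].
#' @return List with `dataset` (an [expression_dataset]) and `truth`
#'   (1-based column indices of the planted informative genes, sorted).
#' @examples
#' out <- generate_synthetic(synth_spec(n_per_class = c(10, 10), n_genes = 50,
#'                                      n_informative = 3, seed = 42))
#' out$truth
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- sum(spec$n_per_class)
  g <- spec$n_genes
  labels <- rep(seq_along(spec$n_per_class), spec$n_per_class)
  with_seed(spec$seed, {
    values <- matrix(stats::rnorm(n * g, 0, spec$sigma), n, g)
    truth <- sort(sample.int(g, spec$n_informative))
    for (j in truth) {
      values[, j] <- values[, j] +
        (labels - 1) * spec$effect_size * spec$sigma
    }
    if (spec$log_normal) values <- exp(values)
    ds <- expression_dataset(values,
                             gene_ids = sprintf("g%05d", seq_len(g)),
                             labels = labels)
    list(dataset = ds, truth = truth)
  })
}

#' Generate a deceptive landscape with one true optimum and decoy gene sets
#'
#' Plants one fully predictive informative gene set (as in
#' [generate_synthetic()]) plus `n_decoys` partially predictive decoy sets.
#' A decoy gene carries the class signal only for a fixed random fraction of
#' the samples and is pure noise elsewhere, so subsets built from decoys
#' classify part of the data well and create local optima for subset search.
#'
#' @param spec A [synth_spec()]; `n_informative` is the size of the true set
#'   and of each decoy set.
#' @param n_decoys Number of decoy sets (>= 1).
#' @param decoy_coverage Fraction of samples (per class) a decoy explains;
#'   default 0.6.
#' @return List with `dataset`, `truth` (true set column indices) and
#'   `decoys` (list of decoy-set column indices).
#' @export
deceptive_landscape <- function(spec, n_decoys = 3L, decoy_coverage = 0.6) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n_decoys < 1L) {
    out <- generate_synthetic(spec)
    out$decoys <- list()
    return(out)
  }
  k <- spec$n_informative
  need <- (n_decoys + 1L) * k
  stopifnot(need <= spec$n_genes)
  n <- sum(spec$n_per_class)
  labels <- rep(seq_along(spec$n_per_class), spec$n_per_class)
  with_seed(spec$seed, {
    values <- matrix(stats::rnorm(n * spec$n_genes, 0, spec$sigma),
                     n, spec$n_genes)
    cols <- sample.int(spec$n_genes, need)
    truth <- sort(cols[seq_len(k)])
    decoys <- lapply(seq_len(n_decoys), function(d) {
      sort(cols[(d * k + 1L):((d + 1L) * k)])
    })
    shift <- (labels - 1) * spec$effect_size * spec$sigma
    for (j in truth) values[, j] <- values[, j] + shift
    for (d in seq_len(n_decoys)) {
      covered <- unlist(lapply(split(seq_len(n), labels), function(idx) {
        sample(idx, max(1L, round(decoy_coverage * length(idx))))
      }), use.names = FALSE)
      mask <- seq_len(n) %in% covered
      for (j in decoys[[d]]) {
        values[mask, j] <- values[mask, j] + shift[mask]
      }
    }
    if (spec$log_normal) values <- exp(values)
    ds <- expression_dataset(values,
                             gene_ids = sprintf("g%05d", seq_len(spec$n_genes)),
                             labels = labels)
    list(dataset = ds, truth = truth, decoys = decoys)
  })
}
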