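# Three-level filter cascade that shrinks the gene universe before the
# swarm search: (1) per-gene IIC ranking, (2) randomized gene subsets
# screened by ELM cross-validation accuracy, (3) rank-based gene scoring.

new_gene_pool <- function(level, gene_indices, scores = NULL, iic = NULL) {
  stopifnot(level %in% 1:3, !anyDuplicated(gene_indices))
  structure(list(level = level, gene_indices = as.integer(gene_indices),
                 scores = scores, iic = iic),
            class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat("Gene pool (level ", x$level, "): ", length(x$gene_indices),
      " genes\n", sep = "")
  invisible(x)
}

#' Information index to classification (IIC) for every gene
#'
#' For each gene `g`, sums over all ordered class pairs `(j, k)`, `j != k`,
#' the quantity
#' \deqn{\frac{1}{2}\frac{|\mu_j - \mu_k|}{\sigma_j + \sigma_k} +
#'       \frac{1}{2}\ln\frac{\sigma_j^2 + \sigma_k^2}{2\sigma_j\sigma_k}}
#' where the means and standard deviations are computed per class on the
#' training samples only. Each unordered class pair therefore contributes
#' twice, which matches the double sum as conventionally written for this
#' index. The first term rewards separated class means, the second rewards
#' unequal class variances; both are invariant under positive affine
#' rescaling of the gene, and `d(g) >= 0` with equality when all class
#' distributions share mean and standard deviation.
#'
#' Standard deviations are floored at
#' `max(1e-6 * sd_global(g), 1e-12)` so genes constant within a class keep a
#' finite score; a warning reports how many genes were floored.
#'
#' @param ds An [expression_dataset].
#' @param split A `split_spec`; statistics use `split$train_indices` only.
#' @return Numeric vector of IIC values `d(g)`, one per gene.
#' @export
iic_scores <- function(ds, split) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(split, "split_spec"))
  x <- ds$values[split$train_indices, , drop = FALSE]
  y <- ds$labels[split$train_indices]
  c_n <- ds$n_classes
  counts <- tabulate(y, c_n)
  if (any(counts < 2L)) {
    stop_scipso("filters", "every class needs >= 2 training samples for ",
                "per-class standard deviations")
  }
  mu <- rowsum(x, y) / counts                       # c x G class means
  sumsq <- rowsum(x * x, y)
  sdev <- sqrt(pmax(sumsq - counts * mu^2, 0) / (counts - 1))
  g_sd <- apply(x, 2L, stats::sd)
  floor_at <- pmax(1e-6 * g_sd, 1e-12)
  n_floored <- sum(apply(sdev, 2L, min) < floor_at)
  if (n_floored > 0L) {
    warning(sprintf("iic_scores: variance floor applied to %d gene(s) with a near-constant class",
                    n_floored), call. = FALSE)
  }
  sdev <- pmax(sdev, rep(floor_at, each = c_n))
  d <- numeric(ncol(x))
  for (j in seq_len(c_n - 1L)) {
    for (k in seq((j + 1L), c_n)) {
      term <- 0.5 * abs(mu[j, ] - mu[k, ]) / (sdev[j, ] + sdev[k, ]) +
        0.5 * log((sdev[j, ]^2 + sdev[k, ]^2) / (2 * sdev[j, ] * sdev[k, ]))
      d <- d + 2 * term                             # both orderings (j,k), (k,j)
    }
  }
  unname(d)
}

#' IIC of a single gene
#'
#' @inheritParams iic_scores
#' @param gene 1-based column index of the gene.
#' @return The scalar `d(g)`.
#' @export
iic_score <- function(ds, split, gene) {
  stopifnot(gene >= 1L, gene <= length(ds$gene_ids))
  sub <- ds
  sub$values <- ds$values[, gene, drop = FALSE]
  sub$gene_ids <- ds$gene_ids[gene]
  iic_scores(sub, split)[1L]
}

#' Build the first-level gene pool by IIC ranking
#'
#' Keeps the `n_top` genes with the highest IIC on the training split
#' (typically 200-400 for microarray-sized inputs). Ties break to the lower
#' gene index.
#'
#' @inheritParams iic_scores
#' @param n_top Pool size, between 1 and the number of genes.
#' @return A level-1 `gene_pool`, ordered by decreasing IIC, with the IIC
#'   values attached as `scores`.
#' @export
build_first_level_pool <- function(ds, split, n_top = 300L) {
  n_genes <- length(ds$gene_ids)
  if (n_top < 1L || n_top > n_genes) {
    stop_scipso("filters", "n_top must be in [1, ", n_genes, "]")
  }
  d <- iic_scores(ds, split)
  ord <- order(-d, seq_along(d))[seq_len(n_top)]
  new_gene_pool(1L, ord, scores = d[ord], iic = d[ord])
}

#' Randomly draw candidate gene subsets from a pool
#'
#' Each subset's size is drawn uniformly from `size_range`, and its genes
#' are sampled without replacement from the pool. Distinct draws may repeat
#' the same subset; draws are deterministic given the seed.
#'
#' @param pool A `gene_pool` (level 1).
#' @param n_subsets Number of subsets to draw.
#' @param size_range Integer vector `c(min, max)` of subset sizes.
#' @param seed Integer seed.
#' @return List of `gene_subset` objects (fields `gene_indices`,
#'   `cv_accuracy`, `rank`, the latter two unset).
#' @export
generate_candidate_subsets <- function(pool, n_subsets,
                                       size_range = c(5L, 15L), seed = 1L) {
  stopifnot(inherits(pool, "gene_pool"))
  p <- length(pool$gene_indices)
  if (p == 0L) stop_scipso("filters", "empty gene pool")
  if (size_range[1] < 1L || size_range[2] > p || size_range[1] > size_range[2]) {
    stop_scipso("filters", "size_range must satisfy 1 <= min <= max <= |pool|")
  }
  with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_subsets, replace = TRUE)
    lapply(sizes, function(s) {
      structure(list(gene_indices = pool$gene_indices[sample.int(p, s)],
                     cv_accuracy = NA_real_, rank = NA_integer_),
                class = "gene_subset")
    })
  })
}

#' Screen candidate subsets by CV accuracy and rank the survivors
#'
#' Evaluates every candidate subset by stratified `k`-fold ELM
#' cross-validation on the training split and deletes subsets whose accuracy
#' falls below the threshold `theta_ac`. Survivors are ranked 1..l_se by
#' decreasing accuracy (rank 1 = most accurate); accuracy ties break to the
#' smaller subset, then to draw order.
#'
#' @param subsets List of `gene_subset`s from [generate_candidate_subsets()].
#' @param ds An [expression_dataset] (values already standardized if the
#'   pipeline is configured to do so).
#' @param split A `split_spec`.
#' @param theta_ac Accuracy threshold in `[0, 1]`.
#' @param elm_control List of ELM settings: `n_hidden`, `activation`, `k`.
#' @param seed Seed fixing the fold assignment shared by all evaluations.
#' @return List of surviving `gene_subset`s in rank order, each with
#'   `cv_accuracy` and `rank` filled in.
#' @export
screen_and_rank_subsets <- function(subsets, ds, split, theta_ac = 0.8,
                                    elm_control = list(), seed = 1L) {
  if (length(subsets) == 0L) stop_scipso("filters", "no candidate subsets")
  if (!is.numeric(theta_ac) || theta_ac < 0 || theta_ac > 1) {
    stop_scipso("filters", "theta_ac must lie in [0, 1]")
  }
  ctl <- elm_defaults(elm_control)
  x <- ds$values[split$train_indices, , drop = FALSE]
  y <- ds$labels[split$train_indices]
  d_max <- max(vapply(subsets, function(s) length(s$gene_indices), integer(1)))
  ctx <- cv_context(x, y, ctl$k, seed, ctl$n_hidden, ctl$activation,
                    ds$n_classes, d_max)
  acc <- vapply(subsets, function(s) {
    cv_accuracy_ctx(ctx, s$gene_indices)
  }, numeric(1))
  keep <- which(acc >= theta_ac)
  if (length(keep) == 0L) {
    stop_scipso("filters", "no subset reached theta_ac = ", theta_ac,
                " (best was ", sprintf("%.3f", max(acc)),
                "); lower theta_ac")
  }
  sizes <- vapply(subsets, function(s) length(s$gene_indices), integer(1))
  ord <- keep[order(-acc[keep], sizes[keep], keep)]
  out <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    s <- subsets[[ord[r]]]
    s$cv_accuracy <- acc[ord[r]]
    s$rank <- r
    out[[r]] <- s
  }
  out
}

elm_defaults <- function(ctl) {
  list(n_hidden = ctl$n_hidden %||% NULL,
       activation = ctl$activation %||% "sigmoid",
       k = ctl$k %||% 5L)
}

#' Score genes from the ranks of the surviving subsets
#'
#' A gene's raw score is the sum over surviving subsets containing it of the
#' reversed rank `l_se - R_j + 1`, so membership in highly ranked subsets
#' counts most. Raw scores are then min-max normalized to `[0, 1]` over the
#' genes appearing in at least one surviving subset; genes in no surviving
#' subset score 0. When all member genes share one raw score the degenerate
#' normalization maps them to 1.
#'
#' The scoring kernel is pluggable: `weight_fn(rank, l_se)` defaults to the
#' reversed rank above; e.g. `function(r, l) 1 / r` gives reciprocal-rank
#' scoring.
#'
#' @param ranked List of ranked surviving `gene_subset`s from
#'   [screen_and_rank_subsets()].
#' @param pool The level-1 `gene_pool` the subsets were drawn from.
#' @param weight_fn Function of (rank, number of survivors) giving the
#'   weight a subset contributes to its member genes.
#' @return Numeric vector of normalized scores aligned to
#'   `pool$gene_indices`.
#' @export
score_genes <- function(ranked, pool,
                        weight_fn = function(rank, l_se) l_se - rank + 1) {
  if (length(ranked) == 0L) stop_scipso("filters", "empty ranked subset list")
  stopifnot(inherits(pool, "gene_pool"))
  l_se <- length(ranked)
  raw <- numeric(length(pool$gene_indices))
  names(raw) <- as.character(pool$gene_indices)
  member <- logical(length(raw))
  for (s in ranked) {
    w <- weight_fn(s$rank, l_se)
    pos <- match(s$gene_indices, pool$gene_indices)
    raw[pos] <- raw[pos] + w
    member[pos] <- TRUE
  }
  scores <- numeric(length(raw))
  if (any(member)) {
    lo <- min(raw[member]); hi <- max(raw[member])
    scores[member] <- if (hi > lo) (raw[member] - lo) / (hi - lo) else 1
  }
  scores
}

#' Build the third-level gene pool from normalized gene scores
#'
#' Keeps the `pool_size` highest-scoring genes among those with a positive
#' normalized score. Score ties break to the higher IIC, then to the lower
#' gene index. If fewer than `pool_size` genes have positive scores, all of
#' them are kept with a warning.
#'
#' @param scores Normalized scores aligned to `pool$gene_indices`
#'   (from [score_genes()]).
#' @param pool The level-1 `gene_pool` (carries IIC values for tie-breaks).
#' @param pool_size Target pool size (40 by default, the setting used across
#'   microarray-scale runs).
#' @return A level-3 `gene_pool` with `scores` and `iic` attached.
#' @export
build_third_level_pool <- function(scores, pool, pool_size = 40L) {
  stopifnot(inherits(pool, "gene_pool"),
            length(scores) == length(pool$gene_indices))
  if (pool_size < 1L) stop_scipso("filters", "pool_size must be >= 1")
  pos <- which(scores > 0)
  if (length(pos) == 0L) stop_scipso("filters", "no gene has a positive score")
  if (length(pos) < pool_size) {
    warning(sprintf("only %d genes have positive scores; third-level pool truncated from %d",
                    length(pos), pool_size), call. = FALSE)
    pool_size <- length(pos)
  }
  iic <- pool$iic %||% rep(0, length(scores))
  ord <- pos[order(-scores[pos], -iic[pos], pool$gene_indices[pos])]
  keep <- ord[seq_len(pool_size)]
  new_gene_pool(3L, pool$gene_indices[keep], scores = scores[keep],
                iic = iic[keep])
}
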