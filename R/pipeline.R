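# End-to-end orchestration of the four-stage hybrid selection: IIC pool ->
# randomized subset screening -> rank-based scoring -> improved PSO, with
# repeated runs, per-gene selection frequencies, held-out test evaluation
# and parameter sweeps.

#' Full run configuration
#'
#' Collects every tunable of the pipeline in one serializable object.
#' Defaults mirror the protocol the method was developed under wherever that
#' protocol pins a value (swarm size 60, 20 generations,
#' `c1 = c2 = 1.49445`, inertia 0.9 to 0.4, third-level pool of 40 genes,
#' `n_mu = 3`); the remaining knobs (threshold `theta_ac`, number of random
#' subsets, subset size range, ELM width, annealing constants) are explicit
#' package choices documented in the methods vignette.
#'
#' @param train_fraction Fraction of samples in the training split.
#' @param standardize Per-gene z-scoring using training-split statistics
#'   (frozen and applied to the test split) before ELM evaluation.
#' @param n_top Level-1 pool size (IIC ranking), typically 200-400.
#' @param n_subsets Number of random candidate subsets screened in level 2;
#'   `NULL` means `20 * n_top`.
#' @param subset_size_range Candidate subset sizes, drawn uniformly.
#' @param theta_ac CV-accuracy survival threshold in level 2.
#' @param pool3_size Level-3 pool size.
#' @param n_select Number of genes the optimizer selects (particle
#'   dimension).
#' @param swarm_size,max_iter,c1,c2,w_ini,w_end,v_max,t0,t_end,epsilon,n_mu,gbest_update
#'   Passed to [ipso_config()].
#' @param elm_n_hidden Hidden neurons for fitness ELMs; `NULL` means
#'   `min(ceiling(n_train_fold / 2), 20)`.
#' @param elm_activation Activation function name.
#' @param cv_k Cross-validation folds for the fitness.
#' @param n_repeats Number of independent repeats of stages 2-4.
#' @param master_seed Master seed; fans out deterministically to all stages
#'   and repeats.
#' @return A list of class `scipso_config`.
#' @export
scipso_config <- function(train_fraction = 0.6, standardize = TRUE,
                          n_top = 300L, n_subsets = NULL,
                          subset_size_range = c(5L, 15L), theta_ac = 0.8,
                          pool3_size = 40L, n_select = 5L,
                          swarm_size = 60L, max_iter = 20L,
                          c1 = 1.49445, c2 = 1.49445,
                          w_ini = 0.9, w_end = 0.4, v_max = NULL,
                          t0 = 0.1, t_end = 0.001, epsilon = 0.01,
                          n_mu = 3L, gbest_update = "metropolis",
                          elm_n_hidden = NULL, elm_activation = "sigmoid",
                          cv_k = 5L, n_repeats = 100L, master_seed = 1L) {
  cfg <- list(train_fraction = train_fraction, standardize = standardize,
              n_top = n_top, n_subsets = n_subsets,
              subset_size_range = subset_size_range, theta_ac = theta_ac,
              pool3_size = pool3_size, n_select = n_select,
              swarm_size = swarm_size, max_iter = max_iter, c1 = c1, c2 = c2,
              w_ini = w_ini, w_end = w_end, v_max = v_max,
              t0 = t0, t_end = t_end, epsilon = epsilon, n_mu = n_mu,
              gbest_update = gbest_update, elm_n_hidden = elm_n_hidden,
              elm_activation = elm_activation, cv_k = cv_k,
              n_repeats = n_repeats, master_seed = master_seed)
  class(cfg) <- "scipso_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' The file is a flat mapping of [scipso_config()] argument names; unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `scipso_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_scipso("pipeline", "the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(scipso_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop_scipso("pipeline", "unknown config key(s): ",
                paste(unknown, collapse = ", "))
  }
  do.call(scipso_config, vals)
}

# Freeze training-split per-gene statistics and z-score the whole matrix
# with them, so nothing about the test rows leaks into the transform.
standardize_by_train <- function(ds, split) {
  tr <- ds$values[split$train_indices, , drop = FALSE]
  mu <- colMeans(tr)
  sdev <- apply(tr, 2L, stats::sd)
  sdev[sdev < 1e-12] <- 1
  out <- ds
  out$values <- sweep(sweep(ds$values, 2L, mu), 2L, sdev, "/")
  out
}

# One repeat of stages 2-4 (level-1 pool is shared across repeats since it
# is deterministic given the split).
run_single_repeat <- function(ds, split, pool1, cfg, seed) {
  seeds <- derive_seeds(seed, 3L)
  elm_control <- list(n_hidden = cfg$elm_n_hidden,
                      activation = cfg$elm_activation, k = cfg$cv_k)
  n_subsets <- cfg$n_subsets %||% (20L * length(pool1$gene_indices))
  subsets <- generate_candidate_subsets(pool1, n_subsets,
                                        cfg$subset_size_range, seed = seeds[1])
  ranked <- screen_and_rank_subsets(subsets, ds, split, cfg$theta_ac,
                                    elm_control, seed = seeds[2])
  scores <- score_genes(ranked, pool1)
  pool3 <- build_third_level_pool(scores, pool1, cfg$pool3_size)
  icfg <- ipso_config(swarm_size = cfg$swarm_size, n_select = cfg$n_select,
                      max_iter = cfg$max_iter, c1 = cfg$c1, c2 = cfg$c2,
                      w_ini = cfg$w_ini, w_end = cfg$w_end, v_max = cfg$v_max,
                      t0 = cfg$t0, t_end = cfg$t_end, epsilon = cfg$epsilon,
                      n_mu = cfg$n_mu, gbest_update = cfg$gbest_update,
                      seed = seeds[3])
  res <- run_ipso(pool3, ds, split, icfg, elm_control)
  list(result = res, pool3 = pool3, l_se = length(ranked))
}

# Held-out evaluation: ELM trained on the full training split projected on
# the subset, scored on the untouched test split.
test_accuracy <- function(ds, split, genes, cfg, seed) {
  xtr <- ds$values[split$train_indices, genes, drop = FALSE]
  xte <- ds$values[split$test_indices, genes, drop = FALSE]
  ytr <- ds$labels[split$train_indices]
  yte <- ds$labels[split$test_indices]
  n_hidden <- cfg$elm_n_hidden %||% default_n_hidden(nrow(xtr))
  m <- train_elm(xtr, ytr, n_hidden = n_hidden,
                 activation = cfg$elm_activation, seed = seed,
                 n_classes = ds$n_classes)
  mean(predict(m, xte) == yte)
}

#' Run the full hybrid gene-selection pipeline
#'
#' Executes the four stages end to end: stratified train/test split,
#' (optional) training-statistics z-scoring, level-1 IIC pool, then
#' `n_repeats` independent repeats of randomized subset screening,
#' rank-based gene scoring and the improved PSO. Each repeat's best subset
#' is evaluated by its fitness (stratified k-fold CV accuracy on the
#' training split) and by held-out accuracy on the test split. Nothing in
#' the selection stages reads the test rows.
#'
#' @param ds An [expression_dataset], or a path accepted by
#'   [load_dataset()].
#' @param cfg A [scipso_config()].
#' @param label_column Label column name, used when `ds` is a path.
#' @return An object of class `scipso_report`: `config`, `split`,
#'   per-repeat `repeats` (selected 1-based serials, gene identifiers, CV
#'   and test accuracy, level-2 survivor count), `pool1` serials,
#'   `frequency` (per-gene selection counts, see [frequency_table()]), and
#'   summary means. Reproducible byte-for-byte from `(cfg, master_seed)`.
#' @export
run_scipso <- function(ds, cfg = scipso_config(), label_column = "label") {
  if (is.character(ds)) ds <- load_dataset(ds, label_column = label_column)
  stopifnot(inherits(ds, "expression_dataset"), inherits(cfg, "scipso_config"))
  seeds <- derive_seeds(cfg$master_seed, 2L + 2L * cfg$n_repeats)
  split <- split_dataset(ds, cfg$train_fraction, seed = seeds[1])
  work <- if (isTRUE(cfg$standardize)) standardize_by_train(ds, split) else ds
  n_top <- cfg$n_top
  if (n_top > ncol(ds$values)) {
    message("n_top (", n_top, ") exceeds the gene count; using all ",
            ncol(ds$values), " genes in the level-1 pool")
    n_top <- ncol(ds$values)
    cfg$n_top <- n_top
  }
  pool1 <- build_first_level_pool(work, split, n_top)

  repeats <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    rep_out <- run_single_repeat(work, split, pool1, cfg, seeds[2L + r])
    genes <- sort(rep_out$result$best_genes)
    acc_test <- test_accuracy(work, split, genes, cfg,
                              seeds[2L + cfg$n_repeats + r])
    repeats[[r]] <- list(
      serials = genes,                       # 1-based column serial numbers
      gene_ids = ds$gene_ids[genes],
      cv_accuracy = rep_out$result$best_fitness,
      test_accuracy = acc_test,
      l_se = rep_out$l_se,
      pool3_serials = rep_out$pool3$gene_indices,
      pool3_scores = rep_out$pool3$scores
    )
  }
  report <- structure(
    list(config = unclass(cfg),
         n_samples = nrow(ds$values), n_genes = ncol(ds$values),
         n_classes = ds$n_classes,
         split = list(train = split$train_indices, test = split$test_indices),
         pool1_serials = pool1$gene_indices,
         repeats = repeats,
         mean_cv_accuracy = mean(vapply(repeats, `[[`, numeric(1), "cv_accuracy")),
         mean_test_accuracy = mean(vapply(repeats, `[[`, numeric(1), "test_accuracy"))),
    class = "scipso_report"
  )
  report$frequency <- frequency_table(report, ds$gene_ids)
  report
}

#' Per-gene selection frequencies over repeats
#'
#' Counts how often each gene appears in the repeats' selected subsets
#' (frequencies sum to `n_repeats * n_select`). Genes are ranked by
#' frequency; ties break by the gene's mean level-3 score over the repeats
#' where it entered the pool, then by serial number.
#'
#' @param report A `scipso_report`.
#' @param gene_ids Optional gene identifiers (taken from the report's
#'   frequency table if already attached).
#' @return Data frame with columns `rank`, `serial`, `gene_id`, `frequency`,
#'   `score` (mean level-3 score), restricted to genes selected at least
#'   once.
#' @export
frequency_table <- function(report, gene_ids = NULL) {
  stopifnot(inherits(report, "scipso_report"))
  if (is.null(gene_ids)) {
    all_ids <- unlist(lapply(report$repeats, `[[`, "gene_ids"))
    all_ser <- unlist(lapply(report$repeats, `[[`, "serials"))
    gene_ids <- character(report$n_genes)
    gene_ids[all_ser] <- all_ids
  }
  counts <- numeric(report$n_genes)
  score_sum <- numeric(report$n_genes)
  score_n <- numeric(report$n_genes)
  for (rp in report$repeats) {
    counts[rp$serials] <- counts[rp$serials] + 1
    score_sum[rp$pool3_serials] <- score_sum[rp$pool3_serials] + rp$pool3_scores
    score_n[rp$pool3_serials] <- score_n[rp$pool3_serials] + 1
  }
  mean_score <- ifelse(score_n > 0, score_sum / pmax(score_n, 1), 0)
  sel <- which(counts > 0)
  ord <- sel[order(-counts[sel], -mean_score[sel], sel)]
  data.frame(rank = seq_along(ord), serial = ord,
             gene_id = gene_ids[ord], frequency = counts[ord],
             score = mean_score[ord], stringsAsFactors = FALSE)
}

#' @export
print.scipso_report <- function(x, ...) {
  cat("Hybrid gene-selection report\n")
  cat(sprintf("  data: %d samples x %d genes, %d classes (%d train / %d test)\n",
              x$n_samples, x$n_genes, x$n_classes,
              length(x$split$train), length(x$split$test)))
  cat(sprintf("  repeats: %d; mean 5-fold CV accuracy %.2f%%; mean test accuracy %.2f%%\n",
              length(x$repeats), 100 * x$mean_cv_accuracy,
              100 * x$mean_test_accuracy))
  top <- utils::head(x$frequency, 10L)
  cat("  top selected genes (serial:frequency):",
      paste(sprintf("%d:%d", top$serial, top$frequency), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to a directory
#'
#' Emits `report.json` (full report), `frequency.tsv` (ranked gene list:
#' rank, 1-based serial, gene identifier, score and selection frequency)
#' and `config.json`.
#'
#' @param report A `scipso_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  write_gene_ranking(report$frequency, file.path(dir, "frequency.tsv"))
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Sweep one pipeline parameter
#'
#' Runs the full pipeline once per value of the swept parameter and reports
#' the mean CV and test accuracies over the configured repeats -- the
#' standard way to choose the survival threshold `theta_ac` or the number
#' of selected genes for a new dataset.
#'
#' @param ds An [expression_dataset].
#' @param cfg Base [scipso_config()].
#' @param parameter `"theta_ac"` or `"n_select"`.
#' @param values Numeric vector of parameter values (non-empty).
#' @return Data frame with columns `value`, `mean_cv_accuracy`,
#'   `mean_test_accuracy`.
#' @export
sweep_parameter <- function(ds, cfg, parameter = c("theta_ac", "n_select"),
                            values) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop_scipso("pipeline", "values must be non-empty")
  rows <- lapply(values, function(v) {
    cfg2 <- cfg
    cfg2[[parameter]] <- if (parameter == "n_select") as.integer(v) else v
    rep <- run_scipso(ds, cfg2)
    data.frame(value = v, mean_cv_accuracy = rep$mean_cv_accuracy,
               mean_test_accuracy = rep$mean_test_accuracy)
  })
  do.call(rbind, rows)
}
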