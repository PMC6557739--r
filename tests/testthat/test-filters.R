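make_two_class_ds <- function(values_by_class) {
  # values_by_class: list of per-class matrices (samples x genes)
  vals <- do.call(rbind, values_by_class)
  labels <- rep(seq_along(values_by_class),
                vapply(values_by_class, nrow, integer(1)))
  expression_dataset(vals, paste0("g", seq_len(ncol(vals))), labels)
}

full_split <- function(ds) {
  # degenerate split helper: train on all but one sample per class
  n <- nrow(ds$values)
  structure(list(train_indices = seq_len(n), test_indices = integer(0),
                 seed = 0L), class = "split_spec")
}

test_that("IIC vanishes for identical class distributions and matches the hand case", {
  # two classes with the same values -> same mean and sd -> d(g) = 0
  block <- matrix(c(0, 1, 2, 3), 4, 1)
  ds <- make_two_class_ds(list(block, block))
  sp <- full_split(ds)
  expect_equal(iic_score(ds, sp, 1), 0)

  # mu1 = 0, mu2 = 1, sd1 = sd2 = 1: each ordered pair contributes
  # 1/2 * 1/2 + 1/2 * ln(1) = 1/4; both orderings sum to 1/2
  base <- c(-1.5, -0.5, 0.5, 1.5) / sd(c(-1.5, -0.5, 0.5, 1.5))
  ds <- make_two_class_ds(list(matrix(base, 4, 1), matrix(base + 1, 4, 1)))
  expect_equal(iic_score(ds, full_split(ds), 1), 0.5, tolerance = 1e-12)
})

test_that("IIC grows strictly with mean separation at fixed spread", {
  base <- scale(c(-1.5, -0.5, 0.5, 1.5))[, 1]
  d_at_shift <- vapply(c(0.5, 1, 2, 4), function(shift) {
    ds <- make_two_class_ds(list(matrix(base, 4, 1),
                                 matrix(base + shift, 4, 1)))
    iic_score(ds, full_split(ds), 1)
  }, numeric(1))
  expect_true(all(diff(d_at_shift) > 0))
})

test_that("IIC is invariant under positive affine rescaling of a gene", {
  out <- make_separable(n_per_class = c(8, 8), n_genes = 10)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.75, seed = 2)
  d0 <- iic_scores(ds, sp)
  for (case in list(c(2.5, 0), c(0.3, -7), c(10, 100))) {
    ds2 <- ds
    ds2$values <- ds$values * case[1] + case[2]
    expect_equal(iic_scores(ds2, sp), d0, tolerance = 1e-9)
  }
})

test_that("variance floor keeps constant-in-class genes finite, with a warning", {
  vals <- cbind(c(1, 1, 1, 1, 5, 5, 5, 5), rnorm(8))
  ds <- expression_dataset(vals, c("flat", "noise"), rep(1:2, each = 4))
  sp <- full_split(ds)
  expect_warning(d <- iic_scores(ds, sp), "variance floor")
  expect_true(all(is.finite(d)))
  expect_gt(d[1], d[2])  # separated flat gene still ranks above noise
})

test_that("multi-class IIC counts every ordered class pair", {
  # three classes; the double sum over j, k != j has 6 ordered pairs
  set.seed(5)
  base <- scale(rnorm(6))[, 1]
  ds <- make_two_class_ds(list(matrix(base, 6, 1), matrix(base + 1, 6, 1),
                               matrix(base + 2, 6, 1)))
  got <- iic_score(ds, full_split(ds), 1)
  pairs <- rbind(c(0, 1), c(0, 2), c(1, 2))
  manual <- sum(apply(pairs, 1, function(p) {
    2 * (0.5 * abs(p[1] - p[2]) / 2 + 0.5 * log((1 + 1) / 2))
  }))
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("first-level pool keeps the top-IIC genes and handles boundaries", {
  out <- make_separable(n_per_class = c(10, 10), n_genes = 40,
                        n_informative = 5, effect = 4)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.7, seed = 3)
  pool <- build_first_level_pool(ds, sp, 10)
  expect_s3_class(pool, "gene_pool")
  expect_true(all(out$truth %in% pool$gene_indices))
  expect_equal(pool$scores, sort(iic_scores(ds, sp), decreasing = TRUE)[1:10])

  all_pool <- build_first_level_pool(ds, sp, 40)
  expect_setequal(all_pool$gene_indices, 1:40)
  expect_error(build_first_level_pool(ds, sp, 0), "n_top")
  expect_error(build_first_level_pool(ds, sp, 41), "n_top")
})

test_that("tied IIC values fall back to gene order", {
  # all genes identical -> identical d(g); pool must be the first indices
  vals <- matrix(rep(c(1, 2, 3, 4, 8, 9, 10, 11), 6), 8, 6)
  ds <- expression_dataset(vals, paste0("g", 1:6), rep(1:2, each = 4))
  pool <- suppressWarnings(build_first_level_pool(ds, full_split(ds), 3))
  expect_equal(pool$gene_indices, 1:3)
})

test_that("candidate subset generation honors its contract", {
  pool <- make_pool(11:40)
  subs <- generate_candidate_subsets(pool, 50, c(3L, 7L), seed = 9)
  expect_length(subs, 50L)
  sizes <- vapply(subs, function(s) length(s$gene_indices), integer(1))
  expect_true(all(sizes >= 3 & sizes <= 7))
  for (s in subs) {
    expect_false(anyDuplicated(s$gene_indices) > 0)
    expect_true(all(s$gene_indices %in% 11:40))
  }
  # determinism and singleton boundary
  expect_identical(generate_candidate_subsets(pool, 50, c(3L, 7L), seed = 9),
                   subs)
  singles <- generate_candidate_subsets(pool, 5, c(1L, 1L), seed = 1)
  expect_true(all(lengths(lapply(singles, `[[`, "gene_indices")) == 1L))
  expect_error(generate_candidate_subsets(pool, 5, c(0L, 3L), seed = 1),
               "size_range")
})

test_that("screening keeps everything at threshold zero and validates inputs", {
  out <- make_separable(n_per_class = c(8, 8), n_genes = 20,
                        n_informative = 4, effect = 4)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.75, seed = 4)
  pool <- build_first_level_pool(ds, sp, 15)
  subs <- generate_candidate_subsets(pool, 30, c(2L, 5L), seed = 5)
  ranked <- screen_and_rank_subsets(subs, ds, sp, theta_ac = 0,
                                    seed = 6)
  expect_length(ranked, 30L)
  expect_equal(vapply(ranked, `[[`, integer(1), "rank"), 1:30)
  accs <- vapply(ranked, `[[`, numeric(1), "cv_accuracy")
  expect_true(all(diff(accs) <= 0))  # rank 1 is the most accurate
  expect_error(screen_and_rank_subsets(subs, ds, sp, theta_ac = 1.01),
               "theta_ac")
  expect_error(screen_and_rank_subsets(subs, ds, sp, theta_ac = -0.1),
               "theta_ac")
  expect_error(screen_and_rank_subsets(list(), ds, sp, 0.5), "no candidate")
})

test_that("an unreachable threshold fails loudly with advice", {
  out <- make_separable(n_per_class = c(6, 6), n_genes = 10,
                        n_informative = 0, effect = 0)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.7, seed = 1)
  pool <- build_first_level_pool(ds, sp, 10)
  subs <- generate_candidate_subsets(pool, 10, c(2L, 3L), seed = 2)
  expect_error(
    screen_and_rank_subsets(subs, ds, sp, theta_ac = 0.999, seed = 3),
    "lower theta_ac")
})

test_that("survivors are enriched for planted genes on separable data", {
  out <- make_separable(n_per_class = c(10, 10), n_genes = 60,
                        n_informative = 6, effect = 3, seed = 77)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.7, seed = 7)
  pool <- build_first_level_pool(ds, sp, 60)
  subs <- generate_candidate_subsets(pool, 120, c(2L, 6L), seed = 8)
  has_planted <- vapply(subs, function(s) any(s$gene_indices %in% out$truth),
                        logical(1))
  ranked <- screen_and_rank_subsets(subs, ds, sp, theta_ac = 0.85, seed = 9)
  survivors <- vapply(ranked, function(s) any(s$gene_indices %in% out$truth),
                      logical(1))
  expect_gt(mean(survivors), mean(has_planted))
})

test_that("gene scoring follows the reversed-rank rule", {
  pool <- make_pool(1:6)
  # subsets ranked 1..4; gene 1 sits in ranks {1,2}, gene 2 in ranks {3,4}
  ranked <- make_ranked(list(c(1L, 3L), c(1L, 4L), c(2L, 5L), c(2L, 6L)))
  scores <- score_genes(ranked, pool,
                        weight_fn = function(r, l) l - r + 1)
  raw <- c(4 + 3, 2 + 1, 4, 3, 2, 1)
  expect_equal(scores, (raw - 1) / (7 - 1))
  expect_equal(order(-scores)[1], 1L)
})

test_that("single surviving subset scores its members 1 and the rest 0", {
  pool <- make_pool(1:3)
  ranked <- make_ranked(list(c(1L, 2L)))
  expect_equal(score_genes(ranked, pool), c(1, 1, 0))
})

test_that("degenerate normalization maps equal raw scores to 1", {
  pool <- make_pool(1:4)
  ranked <- make_ranked(list(c(1L, 2L), c(1L, 2L)))
  expect_equal(score_genes(ranked, pool), c(1, 1, 0, 0))
  expect_error(score_genes(list(), pool), "empty")
})

test_that("joining one more surviving subset never lowers a raw score", {
  pool <- make_pool(1:8)
  base_members <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  raw_of <- function(members, gene) {
    ranked <- make_ranked(members)
    l <- length(ranked)
    sum(vapply(ranked, function(s)
      if (gene %in% s$gene_indices) l - s$rank + 1 else 0, numeric(1)))
  }
  for (gene in c(1L, 3L, 7L)) {
    before <- raw_of(base_members, gene)
    extended <- c(base_members, list(c(gene, 8L)))
    expect_gte(raw_of(extended, gene), before)
  }
})

test_that("third-level pool selects top scores with IIC tie-breaks", {
  pool <- make_pool(1:6, iic = c(5, 4, 3, 2, 1, 6))
  scores <- c(0.9, 0.5, 0.5, 0.2, 0, 0.9)
  p3 <- build_third_level_pool(scores, pool, 4)
  expect_s3_class(p3, "gene_pool")
  expect_equal(p3$level, 3L)
  # 0.9 tie: gene 6 has higher IIC than gene 1; 0.5 tie: gene 2 beats 3
  expect_equal(p3$gene_indices, c(6L, 1L, 2L, 3L))
  # zero-score genes never enter; shortage warns and truncates
  expect_warning(p_all <- build_third_level_pool(scores, pool, 6),
                 "positive scores")
  expect_setequal(p_all$gene_indices, c(1L, 2L, 3L, 4L, 6L))
  expect_error(build_third_level_pool(scores, pool, 0), "pool_size")
})

test_that("pool levels nest: level 3 within survivors within level 1", {
  out <- make_separable(n_per_class = c(10, 10), n_genes = 50,
                        n_informative = 5, effect = 3)
  ds <- out$dataset
  sp <- split_dataset(ds, 0.7, seed = 12)
  pool1 <- build_first_level_pool(ds, sp, 30)
  subs <- generate_candidate_subsets(pool1, 60, c(2L, 6L), seed = 13)
  ranked <- screen_and_rank_subsets(subs, ds, sp, 0.5, seed = 14)
  level2_genes <- unique(unlist(lapply(ranked, `[[`, "gene_indices")))
  scores <- score_genes(ranked, pool1)
  pool3 <- suppressWarnings(build_third_level_pool(scores, pool1, 10))
  expect_true(all(pool3$gene_indices %in% level2_genes))
  expect_true(all(level2_genes %in% pool1$gene_indices))
})
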