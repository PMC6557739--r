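# Extreme learning machine: a single-hidden-layer feedforward network whose
# hidden layer is drawn at random once and never adjusted; only the output
# weights are solved, in closed form, as the minimum-norm least-squares
# solution of H %*% wo = T via the Moore-Penrose pseudoinverse.

elm_activations <- list(
  sigmoid = function(z) 1 / (1 + exp(-z)),
  tanh    = function(z) tanh(z),
  relu    = function(z) pmax(z, 0)
)

#' Moore-Penrose pseudoinverse via singular value decomposition
#'
#' Rank-revealing pseudoinverse used to solve for ELM output weights.
#' Singular values below `tol * max(singular value)` are truncated to keep
#' the solution stable on ill-conditioned hidden-layer matrices.
#'
#' @param a Numeric matrix.
#' @param tol Relative truncation threshold.
#' @return The pseudoinverse of `a`.
#' @keywords internal
pinv <- function(a, tol = 1e-10) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(a), nrow(a)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Train an extreme learning machine classifier
#'
#' Input weights and hidden biases are drawn uniformly from `[-1, 1]` and
#' frozen; output weights are the minimum-norm least-squares solution
#' `wo = pinv(H) %*% T`, where `H` is the hidden-layer activation matrix and
#' `T` the one-hot (0/1) target matrix. With `n_hidden` equal to the number
#' of distinct training samples and a full-rank `H`, the network interpolates
#' the training labels exactly.
#'
#' @param x Numeric matrix, samples by features.
#' @param labels Integer class labels in `1..n_classes`.
#' @param n_hidden Number of hidden neurons; default
#'   `min(ceiling(nrow(x) / 2), 20)`, which keeps the network below the
#'   interpolation regime (see the methods vignette).
#' @param activation Activation name: `"sigmoid"` (default), `"tanh"` or
#'   `"relu"`.
#' @param seed Integer seed for the random hidden layer; training is
#'   deterministic (bit-stable) given the seed.
#' @param n_classes Number of classes; defaults to `max(labels)`.
#' @return An object of class `elm_model` with elements `wh` (features x
#'   hidden input weights), `b` (hidden biases), `wo` (hidden x classes
#'   output weights), `activation`, `n_hidden`, `n_features`, `n_classes`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' y <- rep(1:2, each = 5)
#' m <- train_elm(x, y, n_hidden = 10, seed = 1)
#' all(predict(m, x) == y)
#' @export
train_elm <- function(x, labels, n_hidden = NULL, activation = "sigmoid",
                      seed = NULL, n_classes = max(labels)) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  stopifnot(nrow(x) >= 1L, ncol(x) >= 1L, length(labels) == nrow(x),
            all(labels >= 1L), n_classes >= 1L)
  if (is.null(n_hidden)) n_hidden <- default_n_hidden(nrow(x))
  if (n_hidden < 1L) stop_scipso("elm", "n_hidden must be >= 1")
  act <- elm_activations[[activation]]
  if (is.null(act)) {
    stop_scipso("elm", "unknown activation '", activation, "'; available: ",
                paste(names(elm_activations), collapse = ", "))
  }
  draw <- function() {
    list(wh = matrix(stats::runif(ncol(x) * n_hidden, -1, 1), ncol(x), n_hidden),
         b = stats::runif(n_hidden, -1, 1))
  }
  rnd <- if (is.null(seed)) draw() else with_seed(seed, draw())
  h <- act(x %*% rnd$wh + matrix(rnd$b, nrow(x), n_hidden, byrow = TRUE))
  targets <- matrix(0, nrow(x), n_classes)
  targets[cbind(seq_len(nrow(x)), labels)] <- 1
  wo <- pinv(h) %*% targets
  structure(
    list(wh = rnd$wh, b = rnd$b, wo = wo, activation = activation,
         n_hidden = n_hidden, n_features = ncol(x), n_classes = n_classes),
    class = "elm_model"
  )
}

#' Predict class labels with a trained ELM
#'
#' Computes the output-neuron responses and decodes each sample to the class
#' with the maximal response. Ties go to the lowest class index.
#'
#' @param object An `elm_model`.
#' @param newdata Numeric matrix with the training feature count.
#' @param ... Unused.
#' @return Integer labels in `1..n_classes`.
#' @export
predict.elm_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop_scipso("elm", "feature count mismatch: model has ", object$n_features,
                ", data has ", ncol(newdata))
  }
  act <- elm_activations[[object$activation]]
  h <- act(newdata %*% object$wh +
             matrix(object$b, nrow(newdata), object$n_hidden, byrow = TRUE))
  out <- h %*% object$wo
  # which.max returns the first maximum: ties break to the lowest class
  as.integer(apply(out, 1L, which.max))
}

#' Serialize / deserialize an ELM model as JSON
#'
#' @param model An `elm_model`.
#' @param path Output path.
#' @return `path` (write) or an `elm_model` (read).
#' @export
write_elm_model <- function(model, path) {
  stopifnot(inherits(model, "elm_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$wh <- matrix(m$wh, m$n_features, m$n_hidden)
  m$wo <- matrix(m$wo, m$n_hidden, m$n_classes)
  structure(m, class = "elm_model")
}

# Minimum-norm least-squares solve pinv(a) %*% b without forming the
# pseudoinverse explicitly (same truncation rule as pinv()).
pinv_solve <- function(a, b, tol = 1e-10) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(a), ncol(b)))
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * (t(s$u[, keep, drop = FALSE]) %*% b))
}

# Shared cross-validation context for screening and swarm fitness: fold
# assignment, one-hot targets, and one frozen random hidden layer per fold
# (drawn for the maximum feature count; a subset of d features uses the
# first d rows of the input-weight matrix). Freezing the layers per run
# keeps every subset's fitness stable and comparable within a run.
cv_context <- function(x, labels, k, seed, n_hidden, activation, n_classes,
                       d_max) {
  folds <- stratified_folds(labels, k, seed)
  targets <- matrix(0, length(labels), n_classes)
  targets[cbind(seq_along(labels), labels)] <- 1
  hidden_seeds <- derive_seeds(seed, k)
  hidden <- lapply(seq_len(k), function(f) {
    n_tr <- sum(folds != f)
    nh <- if (is.null(n_hidden)) default_n_hidden(n_tr) else n_hidden
    with_seed(hidden_seeds[f], list(
      wh = matrix(stats::runif(d_max * nh, -1, 1), d_max, nh),
      b = stats::runif(nh, -1, 1)
    ))
  })
  list(x = x, labels = labels, folds = folds, k = k, targets = targets,
       hidden = hidden, act = elm_activations[[activation]],
       n_classes = n_classes)
}

# Mean held-out accuracy over the context's folds for a gene subset
# (columns of ctx$x). The lean inner loop behind screening and the swarm
# fitness: hidden layer -> minimum-norm output weights -> argmax decode.
cv_accuracy_ctx <- function(ctx, genes) {
  xg <- ctx$x[, genes, drop = FALSE]
  d <- length(genes)
  correct <- 0L
  n_eval <- 0L
  for (f in seq_len(ctx$k)) {
    val <- ctx$folds == f
    if (!any(val)) next
    hid <- ctx$hidden[[f]]
    wh <- hid$wh[seq_len(d), , drop = FALSE]
    pre <- xg %*% wh
    pre <- sweep(pre, 2L, hid$b, "+")
    h <- ctx$act(pre)
    wo <- pinv_solve(h[!val, , drop = FALSE],
                     ctx$targets[!val, , drop = FALSE])
    scores <- h[val, , drop = FALSE] %*% wo
    pred <- max.col(scores, ties.method = "first")
    correct <- correct + sum(pred == ctx$labels[val])
    n_eval <- n_eval + sum(val)
  }
  correct / n_eval
}

# Stratified fold assignment: per class, shuffle and deal round-robin so
# every sample lands in exactly one validation fold and class proportions
# are preserved as closely as the counts allow.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2L || k > n) stop_scipso("elm", "k must be in [2, n_samples]")
  folds <- integer(n)
  start <- 0L
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      folds[idx] <- (start + seq_along(idx) - 1L) %% k + 1L
      start <- start + length(idx)
    }
  })
  folds
}

#' Stratified k-fold cross-validation accuracy of an ELM
#'
#' The subset-fitness measure used throughout the pipeline: mean held-out
#' classification accuracy of an ELM over `k` stratified folds. Folds are
#' deterministic given the seed; the ELM hidden layer of each fold is
#' re-seeded from the same stream.
#'
#' @inheritParams train_elm
#' @param k Number of folds (default 5); `k = nrow(x)` gives leave-one-out.
#' @param seed Integer seed controlling fold assignment and hidden layers.
#' @return An object of class `cv_result`: `fold_accuracies` (length `k`),
#'   `mean_accuracy`, `std`, and a `degraded` flag set when some class has
#'   fewer than `k` samples so that folds can miss a class.
#' @export
kfold_cv_accuracy <- function(x, labels, k = 5L, n_hidden = NULL,
                              activation = "sigmoid", seed = 1L,
                              n_classes = max(labels)) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  folds <- stratified_folds(labels, k, seed)
  degraded <- any(tabulate(labels, n_classes) < k)
  elm_seeds <- derive_seeds(seed, k)
  acc <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    if (!any(!tr)) return(NA_real_)
    m <- train_elm(x[tr, , drop = FALSE], labels[tr], n_hidden = n_hidden,
                   activation = activation, seed = elm_seeds[f],
                   n_classes = n_classes)
    mean(predict(m, x[!tr, , drop = FALSE]) == labels[!tr])
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  structure(list(fold_accuracies = acc, mean_accuracy = mean(acc),
                 std = stats::sd(acc), k = k, degraded = degraded),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.4f (sd %.4f)%s\n", x$k,
              x$mean_accuracy, x$std,
              if (isTRUE(x$degraded)) " [some class smaller than k]" else ""))
  invisible(x)
}
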