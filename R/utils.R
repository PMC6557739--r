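# Internal helpers shared across modules.

#' Derive a vector of child seeds from a master seed
#'
#' Fans a single master seed out into `n` reproducible child seeds so that
#' independent stages (or repeats) of a run can each be re-seeded in
#' isolation. The fan-out itself is deterministic given the master seed.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds required.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a locally-set seed, restoring the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default ELM hidden width: half the training-sample count, capped at 20.
# Keeping the width well below n avoids the interpolation regime, where the
# network fits its training fold exactly and held-out predictions become
# high-variance; capping keeps cross-validation cheap on larger splits.
default_n_hidden <- function(n_train) {
  max(1L, min(as.integer(ceiling(n_train / 2)), 20L))
}

stop_scipso <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
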