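#' Boosted-machine hyperparameters
#'
#' Fixed settings shared by every machine the FIR scan fits (the reduced
#' machine and the four stratum machines). Defaults are the values selected by
#' grid search on the full simulated data: learning rate 0.05, 300 trees,
#' early stopping after 10 rounds without validation improvement, maximum tree
#' depth 6, and 10-fold cross-validation.
#'
#' @param learning_rate shrinkage applied to each tree's contribution.
#' @param n_trees maximum number of boosting rounds.
#' @param early_stopping_rounds stop when the held-out RMSE has not improved
#'   for this many consecutive rounds; predictions are taken at the best round.
#' @param max_depth maximum depth of each regression tree.
#' @param cv_folds number of cross-validation folds used to pool the RMSE.
#' @param lambda L2 regularization on leaf weights (library default 1).
#' @return an object of class `fir_hyperparams`.
#' @export
#' @examples
#' fir_hyperparams()
#' fir_hyperparams_smoke()  # cheaper profile for CI pipelines
fir_hyperparams <- function(learning_rate = 0.05, n_trees = 300L,
                            early_stopping_rounds = 10L, max_depth = 6L,
                            cv_folds = 10L, lambda = 1) {
  stopifnot(learning_rate > 0, n_trees >= 1, early_stopping_rounds >= 1,
            max_depth >= 1, cv_folds >= 2, lambda >= 0)
  structure(list(learning_rate = learning_rate,
                 n_trees = as.integer(n_trees),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 max_depth = as.integer(max_depth),
                 cv_folds = as.integer(cv_folds),
                 lambda = lambda),
            class = "fir_hyperparams")
}

#' @rdname fir_hyperparams
#' @export
fir_hyperparams_smoke <- function() {
  fir_hyperparams(n_trees = 100L, cv_folds = 5L)
}

#' @export
print.fir_hyperparams <- function(x, ...) {
  cat("Boosted-machine hyperparameters:\n")
  cat(sprintf("  learning_rate=%.3g  n_trees=%d  early_stopping=%d  max_depth=%d  cv_folds=%d  lambda=%.3g\n",
              x$learning_rate, x$n_trees, x$early_stopping_rounds,
              x$max_depth, x$cv_folds, x$lambda))
  invisible(x)
}
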