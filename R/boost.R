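#' Cross-validated RMSE of a boosted machine
#'
#' Fits gradient-boosted regression trees predicting Y from the non-excluded
#' features and returns the root-mean-squared error of out-of-sample
#' predictions. In the default `"cv"` mode the rows are partitioned into
#' `cv_folds` folds; each fold is held out in turn, doubles as the
#' early-stopping evaluation set for the machine trained on the remaining
#' folds, and the RMSE is pooled over all held-out predictions (taken at each
#' machine's best boosting round). The alternative `"split"` mode uses a
#' single 80/20 train/test split, with the 20% test set serving both as the
#' early-stopping set and the RMSE set.
#'
#' Deterministic given `seed`: the seed fixes the fold (or split) assignment
#' and the tree fitting itself contains no randomness.
#'
#' @param data a [fir_dataset()].
#' @param excluded_features feature names dropped before fitting (e.g. the
#'   candidate interaction pair).
#' @param hp a [fir_hyperparams()].
#' @param seed integer seed.
#' @param mode `"cv"` (pooled k-fold, default) or `"split"` (80/20).
#' @param cv_folds number of folds; defaults to `hp$cv_folds`. Stratum
#'   machines on small row sets pass a reduced value.
#' @return a single numeric RMSE.
#' @export
fit_rmse <- function(data, excluded_features = character(), hp = fir_hyperparams(),
                     seed = 1L, mode = c("cv", "split"), cv_folds = hp$cv_folds) {
  stopifnot(inherits(data, "fir_dataset"), inherits(hp, "fir_hyperparams"))
  mode <- match.arg(mode)
  excluded_features <- as.character(excluded_features)
  unknown <- setdiff(excluded_features, data$feature_names)
  if (length(unknown))
    stop("excluded feature(s) not in dataset: ", paste(unknown, collapse = ", "))
  keep <- setdiff(data$feature_names, excluded_features)
  if (!length(keep)) stop("all features excluded; nothing to fit")
  X <- data$x[, keep, drop = FALSE]
  y <- data$y
  n <- length(y)

  if (mode == "split") {
    n_test <- max(1L, round(0.2 * n))
    test <- with_seed(derive_seed(seed, "split80"), sample.int(n, n_test))
    fit <- .gbrt_fit_cpp(X[-test, , drop = FALSE], y[-test],
                         X[test, , drop = FALSE], y[test],
                         hp$n_trees, hp$learning_rate, hp$max_depth,
                         hp$early_stopping_rounds, hp$lambda, 1e-12)
    return(fit$val_rmse)
  }

  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 2L) stop("cv_folds must be at least 2")
  if (n < cv_folds)
    stop("fewer rows (", n, ") than cross-validation folds (", cv_folds, ")")
  fold <- with_seed(derive_seed(seed, "folds", cv_folds),
                    sample(rep(seq_len(cv_folds), length.out = n)))
  pooled <- numeric(n)
  for (k in seq_len(cv_folds)) {
    held <- fold == k
    fit <- .gbrt_fit_cpp(X[!held, , drop = FALSE], y[!held],
                         X[held, , drop = FALSE], y[held],
                         hp$n_trees, hp$learning_rate, hp$max_depth,
                         hp$early_stopping_rounds, hp$lambda, 1e-12)
    pooled[held] <- fit$val_pred
  }
  sqrt(mean((y - pooled)^2))
}
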