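# Shared fixtures. Everything is generated in code; heavier objects are built
# once per test run and reused read-only.

# cheap hyperparameters for unit tests where the boosting settings themselves
# are not under test
tiny_hp <- function(n_trees = 40L, cv_folds = 3L, max_depth = 3L) {
  fir_hyperparams(n_trees = n_trees, cv_folds = cv_folds, max_depth = max_depth)
}

base_cormat <- function() build_correlation_matrix(correlation_spec())

# dataset of independent standard-normal features plus configurable outcome
noise_dataset <- function(n = 200L, K = 4L, seed = 1L, y = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("X", 1:K)))
  if (is.null(y)) y <- rnorm(n)
  fir_dataset(y, x)
}

# fabricate a fir_scan around a given FIR vector, for significance-layer tests
# that do not need real machine fits
fabricated_scan <- function(firs, feature1 = NULL, feature2 = NULL) {
  n <- length(firs)
  if (is.null(feature1)) {
    pairs <- utils::combn(paste0("X", seq_len(ceiling((1 + sqrt(1 + 8 * n)) / 2))),
                          2L)
    feature1 <- pairs[1L, seq_len(n)]
    feature2 <- pairs[2L, seq_len(n)]
  }
  tab <- data.frame(feature1 = feature1, feature2 = feature2,
                    rmse_reduced = 1, rmse_hi_hi = firs, rmse_hi_lo = firs,
                    rmse_lo_hi = firs, rmse_lo_lo = firs, fir = firs,
                    stringsAsFactors = FALSE)
  structure(list(results = list(), table = tab, n_pairs = n,
                 failed = data.frame(feature1 = character(),
                                     feature2 = character(),
                                     reason = character()),
                 hyperparams = fir_hyperparams(), seed = 1L),
            class = "fir_scan")
}

# orthant probability P(Z1 > 0, Z2 > 0) for a standard bivariate normal:
# 1/4 + asin(rho) / (2*pi)
orthant_prob <- function(rho) 0.25 + asin(rho) / (2 * pi)
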