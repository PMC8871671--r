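#' Stratify a dataset into four subgroups by a feature pair's medians
#'
#' Each row is assigned to one of four strata by comparing the two pair
#' features with their full-dataset medians: `hi_hi` (both >= median), `hi_lo`
#' (first >= , second <), `lo_hi` and `lo_lo`. Ties at the median go to the
#' high stratum. The four strata always partition the rows exactly; within a
#' stratum the two-way interaction of the pair cannot vary, which is what
#' makes the stratum machines interaction-free.
#'
#' @param data a [fir_dataset()].
#' @param pair two feature names.
#' @param min_stratum_size smallest admissible stratum (default 40); a smaller
#'   stratum raises an error naming it.
#' @return an object of class `fir_strata` with the pair, its two median
#'   thresholds and the four row-index sets.
#' @export
median_stratify <- function(data, pair, min_stratum_size = 40L) {
  stopifnot(inherits(data, "fir_dataset"))
  pair <- check_pair(data, pair)
  x1 <- data$x[, pair[1L]]
  x2 <- data$x[, pair[2L]]
  if (length(unique(x1)) == 1L || length(unique(x2)) == 1L)
    stop("pair feature is constant; cannot stratify at the median")
  m1 <- median(x1)
  m2 <- median(x2)
  hi1 <- x1 >= m1
  hi2 <- x2 >= m2
  strata <- list(hi_hi = which(hi1 & hi2),
                 hi_lo = which(hi1 & !hi2),
                 lo_hi = which(!hi1 & hi2),
                 lo_lo = which(!hi1 & !hi2))
  sizes <- lengths(strata)
  if (any(sizes < min_stratum_size)) {
    bad <- names(strata)[which.min(sizes)]
    stop("stratum '", bad, "' of pair (", pair[1L], ", ", pair[2L],
         ") has ", min(sizes), " rows; need at least ", min_stratum_size)
  }
  structure(list(pair = pair, thresholds = c(m1, m2), strata = strata),
            class = "fir_strata")
}

# stratum machines cannot sustain full k-fold CV on small row sets: reduce
# folds to one per 20 rows, capped at the configured folds, floored at 2
stratum_cv_folds <- function(stratum_n, cv_folds) {
  max(2L, min(as.integer(cv_folds), stratum_n %/% 20L))
}

#' Feature interaction ratio of one candidate pair
#'
#' Computes the FIR statistic: the reduced machine is fitted to all rows with
#' the pair's two features removed (denominator RMSE); four machines are
#' fitted within the pair's median strata, again without the pair
#' (numerator = mean of the four stratum RMSEs); the FIR is their ratio.
#' Stratification removes the pair's two-way interaction but not its main
#' effects, and the reduced machine removes both, so the ratio isolates the
#' interaction: the smaller the FIR, the stronger the interaction.
#'
#' @param data a [fir_dataset()].
#' @param pair two feature names.
#' @param hp a [fir_hyperparams()].
#' @param seed master seed; per-machine seeds are derived from it.
#' @param min_stratum_size passed to [median_stratify()].
#' @return an object of class `fir_result` with `pair`, `rmse_reduced`,
#'   `rmse_strata` (named length-4), `mean_rmse_strata` and `fir`.
#' @export
compute_fir <- function(data, pair, hp = fir_hyperparams(), seed = 1L,
                        min_stratum_size = 40L) {
  stopifnot(inherits(data, "fir_dataset"), inherits(hp, "fir_hyperparams"))
  pair <- check_pair(data, pair)
  split <- median_stratify(data, pair, min_stratum_size)
  rmse_reduced <- fit_rmse(data, excluded_features = pair, hp = hp,
                           seed = derive_seed(seed, pair[1L], pair[2L],
                                              "reduced"))
  rmse_strata <- vapply(names(split$strata), function(label) {
    rows <- split$strata[[label]]
    fit_rmse(subset_dataset(data, rows), excluded_features = pair, hp = hp,
             seed = derive_seed(seed, pair[1L], pair[2L], label),
             cv_folds = stratum_cv_folds(length(rows), hp$cv_folds))
  }, numeric(1))
  mean_rmse_strata <- mean(rmse_strata)
  structure(list(pair = pair, rmse_reduced = rmse_reduced,
                 rmse_strata = rmse_strata,
                 mean_rmse_strata = mean_rmse_strata,
                 fir = mean_rmse_strata / rmse_reduced),
            class = "fir_result")
}

#' @export
print.fir_result <- function(x, ...) {
  cat(sprintf("FIR(%s, %s) = %.4f  [mean stratum RMSE %.4f / reduced RMSE %.4f]\n",
              x$pair[1L], x$pair[2L], x$fir, x$mean_rmse_strata,
              x$rmse_reduced))
  invisible(x)
}

#' Scan all feature pairs of a dataset for interactions
#'
#' Computes the FIR for every unordered pair of features (C(K,2) = K(K-1)/2
#' pairs, in lexicographic column order), building the empirical FIR
#' distribution that [declare_significance()] thresholds. A pair that fails
#' stratification (a stratum below `min_stratum_size`) is recorded in the
#' `failed` table with its reason, not silently dropped.
#'
#' @param data a [fir_dataset()].
#' @param hp a [fir_hyperparams()].
#' @param seed master seed.
#' @param pairs optional subset of pairs to scan, as a list of length-2
#'   character vectors; defaults to all pairs. Sub-sampling the scan is a
#'   performance device for simulation pipelines; the FIR null distribution is
#'   then built from the scanned subset only.
#' @param min_stratum_size passed to [median_stratify()].
#' @return an object of class `fir_scan`: `results` (list of `fir_result`),
#'   `table` (one row per pair), `n_pairs`, `failed`, `hyperparams`, `seed`.
#' @export
#' @examples
#' \donttest{
#' m <- build_correlation_matrix(correlation_spec())
#' d <- simulate_dataset(m, n = 500, seed = 1)
#' scan <- scan_all_pairs(d, fir_hyperparams_smoke(), seed = 1)
#' declare_significance(scan, target_pair = c("X1", "X2"))
#' }
scan_all_pairs <- function(data, hp = fir_hyperparams(), seed = 1L,
                           pairs = NULL, min_stratum_size = 40L) {
  stopifnot(inherits(data, "fir_dataset"))
  K <- length(data$feature_names)
  if (K < 3L) stop("need at least 3 features to build a FIR distribution")
  if (is.null(pairs)) {
    pairs <- utils::combn(data$feature_names, 2L, simplify = FALSE)
  } else {
    pairs <- lapply(pairs, function(p) check_pair(data, p))
  }
  results <- vector("list", length(pairs))
  failed <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    r <- tryCatch(compute_fir(data, p, hp = hp, seed = seed,
                              min_stratum_size = min_stratum_size),
                  error = function(e)
                    structure(list(pair = p, reason = conditionMessage(e)),
                              class = "fir_failure"))
    if (inherits(r, "fir_failure")) failed[[length(failed) + 1L]] <- r
    else results[[i]] <- r
  }
  results <- Filter(Negate(is.null), results)
  tab <- if (length(results)) {
    do.call(rbind, lapply(results, function(r) {
      data.frame(feature1 = r$pair[1L], feature2 = r$pair[2L],
                 rmse_reduced = r$rmse_reduced,
                 rmse_hi_hi = r$rmse_strata[["hi_hi"]],
                 rmse_hi_lo = r$rmse_strata[["hi_lo"]],
                 rmse_lo_hi = r$rmse_strata[["lo_hi"]],
                 rmse_lo_lo = r$rmse_strata[["lo_lo"]],
                 fir = r$fir, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(feature1 = character(), feature2 = character(),
               rmse_reduced = numeric(), rmse_hi_hi = numeric(),
               rmse_hi_lo = numeric(), rmse_lo_hi = numeric(),
               rmse_lo_lo = numeric(), fir = numeric(),
               stringsAsFactors = FALSE)
  }
  failed_tab <- if (length(failed)) {
    do.call(rbind, lapply(failed, function(f)
      data.frame(feature1 = f$pair[1L], feature2 = f$pair[2L],
                 reason = f$reason, stringsAsFactors = FALSE)))
  } else {
    data.frame(feature1 = character(), feature2 = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  structure(list(results = results, table = tab,
                 n_pairs = length(pairs), failed = failed_tab,
                 hyperparams = hp, seed = as.integer(seed)),
            class = "fir_scan")
}

#' @export
print.fir_scan <- function(x, ...) {
  cat(sprintf("fir_scan: %d pair(s) scanned (%d failed), seed %d\n",
              x$n_pairs, nrow(x$failed), x$seed))
  if (nrow(x$table)) {
    ord <- order(x$table$fir)
    cat("lowest FIRs:\n")
    print(utils::head(x$table[ord, c("feature1", "feature2", "fir")], 5),
          row.names = FALSE)
  }
  invisible(x)
}

# evenly spaced deterministic subset of the pair list, always containing the
# target pair: used to sub-sample the null scan in simulation pipelines
subsample_pairs <- function(feature_names, target_pair, n_pairs) {
  all_pairs <- utils::combn(feature_names, 2L, simplify = FALSE)
  is_target <- vapply(all_pairs, function(p) setequal(p, target_pair),
                      logical(1))
  others <- all_pairs[!is_target]
  n_other <- min(length(others), max(3L, n_pairs - 1L))
  idx <- unique(round(seq(1L, length(others), length.out = n_other)))
  c(all_pairs[is_target], others[idx])
}
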