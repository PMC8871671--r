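#' Wald binomial confidence interval for a rejection proportion
#'
#' Normal-approximation interval p +/- z*sqrt(p(1-p)/reps), clipped to
#' `[0, 1]`. This is the convention behind the printed intervals of the power
#' tables (e.g. 0.14 over 100 repetitions gives (0.07, 0.21)); a Wilson
#' interval is available as an option.
#'
#' @param p_hat observed proportion.
#' @param reps number of repetitions.
#' @param level confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return numeric `c(low, high)`.
#' @export
#' @examples
#' round(wald_ci(0.14, 100), 2)   # 0.07 0.21
#' round(wald_ci(0.04, 100), 3)   # 0.002 0.078
wald_ci <- function(p_hat, reps, level = 0.95, method = c("wald", "wilson")) {
  stopifnot(p_hat >= 0, p_hat <= 1, reps >= 1, level > 0, level < 1)
  method <- match.arg(method)
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p_hat * (1 - p_hat) / reps)
    ci <- c(p_hat - half, p_hat + half)
  } else {
    den <- 1 + z^2 / reps
    centre <- (p_hat + z^2 / (2 * reps)) / den
    half <- z * sqrt(p_hat * (1 - p_hat) / reps + z^2 / (4 * reps^2)) / den
    ci <- c(centre - half, centre + half)
  }
  pmin(pmax(ci, 0), 1)
}

#' Configure a type-I error / power experiment
#'
#' Bundles everything one simulation cell needs: the correlation structure,
#' sample size, interaction effect (level `"none"` estimates the type-I
#' error), repetition count, methods to run, and the boosted-machine
#' hyperparameters. Non-positive-definite designs are repaired automatically
#' at run time.
#'
#' @param spec a [correlation_spec()] or [scenario_spec()].
#' @param n sample size per repetition.
#' @param effect an [interaction_effect()].
#' @param reps number of repetitions (study default 100).
#' @param master_seed integer; every repetition derives its seeds from it.
#' @param methods subset of `c("xgb_fi", "regression")`.
#' @param hp a [fir_hyperparams()].
#' @param pair the target pair under test.
#' @param scan_pairs `NULL` to scan all pairs, or an integer m to sub-sample
#'   the scan to the target pair plus about m-1 evenly spaced other pairs (a
#'   performance device for simulation pipelines), or an explicit list of
#'   pairs.
#' @param min_stratum_size passed through to the scan.
#' @param label optional scenario label carried into result tables.
#' @return an object of class `fir_config`.
#' @export
experiment_config <- function(spec = correlation_spec(), n = 1000L,
                              effect = interaction_effect("none"),
                              reps = 100L, master_seed = 1L,
                              methods = c("xgb_fi", "regression"),
                              hp = fir_hyperparams(), pair = c("X1", "X2"),
                              scan_pairs = NULL, min_stratum_size = 40L,
                              label = NULL) {
  stopifnot(inherits(spec, "fir_corspec"), inherits(effect, "fir_effect"),
            inherits(hp, "fir_hyperparams"))
  methods <- match.arg(methods, c("xgb_fi", "regression"), several.ok = TRUE)
  if (reps < 1L) stop("reps must be at least 1")
  structure(list(spec = spec, n = as.integer(n), effect = effect,
                 reps = as.integer(reps),
                 master_seed = as.integer(master_seed), methods = methods,
                 hp = hp, pair = as.character(pair), scan_pairs = scan_pairs,
                 min_stratum_size = as.integer(min_stratum_size),
                 label = label),
            class = "fir_config")
}

#' Estimate type-I error or power over simulated repetitions
#'
#' For each repetition: simulate a dataset from the (repaired if necessary)
#' correlation matrix, inject the interaction effect unless the level is
#' `"none"`, run each configured method on the target pair, and record
#' whether it rejected. Rejections are aggregated into one `PowerEstimate`
#' row per method with a 95% Wald binomial interval. With `effect = "none"`
#' the estimate is the type-I error. Fully reproducible from `master_seed`;
#' the simulated X matrix of a repetition is shared between the null and
#' injected arms because injection only perturbs Y.
#'
#' Failed repetitions are recorded and excluded with a warning when fewer
#' than 5% fail; more than that is a hard error.
#'
#' @param config an [experiment_config()].
#' @return an object of class `fir_power`: `estimates` (data frame, one row
#'   per method with rejections, reps, power, ci_low, ci_high), `rejections`
#'   (per-repetition logical matrix), `failures`, `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "fir_config"))
  mat <- build_correlation_matrix(config$spec)
  if (mat$min_eigenvalue < 1e-8) mat <- repair_positive_definite(mat)
  pairs <- config$scan_pairs
  if (is.numeric(pairs) && length(pairs) == 1L) {
    K <- config$spec$n_interactive + config$spec$n_marginal + config$spec$n_noise
    pairs <- subsample_pairs(paste0("X", seq_len(K)), config$pair,
                             as.integer(pairs))
  }
  rej <- matrix(NA, nrow = config$reps, ncol = length(config$methods),
                dimnames = list(NULL, config$methods))
  failures <- list()
  for (r in seq_len(config$reps)) {
    base_seed <- derive_seed(config$master_seed, "rep", r)
    d <- tryCatch({
      d0 <- simulate_dataset(mat, config$n, seed = base_seed)
      if (config$effect$level == "none") d0
      else inject_interaction(d0, config$pair, config$effect,
                              seed = derive_seed(config$master_seed,
                                                 "inject", r))
    }, error = function(e) e)
    if (inherits(d, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, method = "simulate", reason = conditionMessage(d))
      next
    }
    for (m in config$methods) {
      res <- tryCatch({
        if (m == "xgb_fi") {
          scan <- scan_all_pairs(d, hp = config$hp,
                                 seed = derive_seed(config$master_seed,
                                                    "scan", r),
                                 pairs = pairs,
                                 min_stratum_size = config$min_stratum_size)
          sig <- declare_significance(scan, target_pair = config$pair)
          isTRUE(sig$target$significant)
        } else {
          regression_interaction_test(d, config$pair)$significant
        }
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(rep = r, method = m, reason = conditionMessage(res))
      } else {
        rej[r, m] <- res
      }
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures)
              else data.frame(rep = integer(), method = character(),
                              reason = character())
  estimates <- do.call(rbind, lapply(config$methods, function(m) {
    ok <- !is.na(rej[, m])
    n_ok <- sum(ok)
    if (n_ok < config$reps * 0.95)
      stop("more than 5% of repetitions failed for method '", m, "' (",
           config$reps - n_ok, " of ", config$reps, ")")
    k <- sum(rej[ok, m])
    p <- k / n_ok
    ci <- wald_ci(p, n_ok)
    data.frame(method = m, rejections = k, reps = n_ok, power = p,
               ci_low = ci[1L], ci_high = ci[2L], stringsAsFactors = FALSE)
  }))
  if (nrow(failures))
    warning(nrow(failures), " repetition/method cell(s) failed and were excluded")
  structure(list(estimates = estimates, rejections = rej,
                 failures = failures, config = config),
            class = "fir_power")
}

#' @export
print.fir_power <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Power experiment: n=%d, effect=%s, %d reps, seed %d\n",
              cfg$n, cfg$effect$level, cfg$reps, cfg$master_seed))
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-12s %.2f (%.2f, %.2f)  [%d/%d rejections]\n",
                est$method[i], est$power[i], est$ci_low[i], est$ci_high[i],
                est$rejections[i], est$reps[i]))
  invisible(x)
}

#' Run a grid of experiments and tabulate the power estimates
#'
#' One [run_experiment()] per config; a cell failure is recorded in the table
#' and the grid continues. The result mirrors the layout of the power
#' comparison tables: one row per (scenario label, sample size, effect level,
#' method).
#'
#' @param configs list of [experiment_config()] objects.
#' @return a data frame with columns label, n, effect, method, rejections,
#'   reps, power, ci_low, ci_high, error.
#' @export
run_scenario_grid <- function(configs) {
  empty <- data.frame(label = character(), n = integer(), effect = character(),
                      method = character(), rejections = integer(),
                      reps = integer(), power = numeric(), ci_low = numeric(),
                      ci_high = numeric(), error = character(),
                      stringsAsFactors = FALSE)
  if (!length(configs)) return(empty)
  rows <- lapply(configs, function(cfg) {
    stopifnot(inherits(cfg, "fir_config"))
    lab <- if (is.null(cfg$label)) "" else cfg$label
    res <- tryCatch(run_experiment(cfg), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(label = lab, n = cfg$n, effect = cfg$effect$level,
                 method = paste(cfg$methods, collapse = "+"),
                 rejections = NA_integer_, reps = NA_integer_,
                 power = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(label = lab, n = cfg$n, effect = cfg$effect$level,
                       stringsAsFactors = FALSE),
            res$estimates, error = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
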