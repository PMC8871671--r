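#' Multiple-regression baseline test for a product interaction
#'
#' The conventional comparator: ordinary least squares of Y on the predictors
#' plus the product of the candidate pair, with a two-sided t-test on the
#' product term's slope. By default all K predictors enter as main effects
#' alongside the single product term; `covariates = "pair_only"` fits the
#' three-term textbook model Y ~ X1 + X2 + X1*X2 instead.
#'
#' @param data a [fir_dataset()].
#' @param pair two feature names whose product is tested.
#' @param alpha significance level (default 0.05).
#' @param covariates `"all"` (default) or `"pair_only"`.
#' @return an object of class `fir_regtest` with `betas` (all coefficients),
#'   `beta_int` (the product slope), `p_value`, `significant` and `alpha`.
#' @export
regression_interaction_test <- function(data, pair = c("X1", "X2"),
                                        alpha = 0.05,
                                        covariates = c("all", "pair_only")) {
  stopifnot(inherits(data, "fir_dataset"), alpha > 0, alpha < 1)
  pair <- check_pair(data, pair)
  covariates <- match.arg(covariates)
  main <- if (covariates == "all") data$feature_names else pair
  df <- as.data.frame(data$x[, main, drop = FALSE])
  df$.y <- data$y
  df$.int <- data$x[, pair[1L]] * data$x[, pair[2L]]
  fml <- stats::as.formula(paste(".y ~", paste(c(main, ".int"), collapse = " + ")))
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit)))
    stop("design matrix is rank deficient (collinear predictors); ",
         "cannot test the interaction slope")
  sm <- summary(fit)$coefficients
  betas <- coef(fit)
  names(betas)[names(betas) == ".int"] <-
    paste(pair, collapse = ":")
  p <- sm[".int", "Pr(>|t|)"]
  structure(list(betas = betas,
                 beta_int = unname(sm[".int", "Estimate"]),
                 p_value = unname(p),
                 significant = unname(p < alpha),
                 alpha = alpha, covariates = covariates, pair = pair),
            class = "fir_regtest")
}

#' @export
print.fir_regtest <- function(x, ...) {
  cat(sprintf("OLS interaction test (%s x %s, %s covariates): beta_int=%.4f, p=%.4g -> %ssignificant at alpha=%.2g\n",
              x$pair[1L], x$pair[2L], x$covariates, x$beta_int, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
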