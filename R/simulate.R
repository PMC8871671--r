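#' Draw a dataset from a specified correlation structure
#'
#' Samples n rows of (Y, X1..XK) from a zero-mean, unit-variance multivariate
#' normal with the given correlation matrix. Because the noise block of the
#' matrix is the identity and uncorrelated with everything, the joint draw is
#' equivalent to generating the correlated variables first and appending
#' independent standard-normal noise features. Deterministic given `seed`.
#'
#' @param matrix a positive-definite `fir_cormat` (repair non-PD designs with
#'   [repair_positive_definite()] first).
#' @param n sample size, at least 40.
#' @param seed integer seed.
#' @return a [fir_dataset()] with `Y` as outcome and features `X1..XK`.
#' @export
#' @examples
#' m <- build_correlation_matrix(correlation_spec())
#' d <- simulate_dataset(m, n = 500, seed = 1)
#' cor(d$x[, "X1"], d$x[, "X2"])  # close to 0.8
simulate_dataset <- function(matrix, n, seed) {
  stopifnot(inherits(matrix, "fir_cormat"))
  if (matrix$min_eigenvalue <= 0)
    stop("correlation matrix is not positive definite (min eigenvalue ",
         format(matrix$min_eigenvalue),
         "); apply repair_positive_definite() first")
  if (n < 40L) stop("n must be at least 40, got ", n)
  p <- length(matrix$labels)
  draws <- with_seed(seed, {
    z <- matrix(rnorm(n * p), nrow = n, ncol = p)
    z %*% chol(matrix$values)
  })
  colnames(draws) <- matrix$labels
  fir_dataset(y = draws[, 1L], x = draws[, -1L, drop = FALSE],
              feature_names = matrix$labels[-1L])
}

#' Interaction effect settings
#'
#' The subgroup effect added to Y where both interactive features exceed their
#' medians. The named levels are draws from a normal distribution with unit
#' variance and mean 0.5 (`mild`), 1 (`moderate`) or 2 (`considerable`);
#' `none` injects nothing.
#'
#' @param level one of `"none"`, `"mild"`, `"moderate"`, `"considerable"`.
#' @param mean optional custom effect mean (overrides the level's value).
#' @param sd effect standard deviation (1 for all named levels).
#' @return an object of class `fir_effect`.
#' @export
interaction_effect <- function(level = c("none", "mild", "moderate",
                                         "considerable"),
                               mean = NULL, sd = 1) {
  level <- match.arg(level)
  if (is.null(mean))
    mean <- switch(level, none = 0, mild = 0.5, moderate = 1, considerable = 2)
  if (level != "none" && sd <= 0) stop("effect sd must be positive")
  structure(list(level = level, mean = mean, sd = sd), class = "fir_effect")
}

#' Inject a subgroup interaction effect into the outcome
#'
#' Adds an independent normal(mean, sd^2) draw to Y for every row where BOTH
#' pair features strictly exceed their within-dataset empirical medians
#' (computed before injection). All other rows, and the entire feature matrix,
#' are untouched, so the null dataset and its injected version share identical
#' X. The injection noise stream is seeded independently of the base draw.
#'
#' @param data a [fir_dataset()].
#' @param pair the two interacting feature names, default `c("X1", "X2")`.
#' @param effect an [interaction_effect()]; level `"none"` returns the input
#'   unchanged.
#' @param seed integer seed for the injection draws.
#' @return the modified `fir_dataset`, with attribute `"injected_rows"` giving
#'   the affected row indices.
#' @export
inject_interaction <- function(data, pair = c("X1", "X2"), effect, seed) {
  stopifnot(inherits(data, "fir_dataset"), inherits(effect, "fir_effect"))
  pair <- check_pair(data, pair)
  if (effect$level == "none") return(data)
  x1 <- data$x[, pair[1L]]
  x2 <- data$x[, pair[2L]]
  if (length(unique(x1)) == 1L || length(unique(x2)) == 1L)
    stop("pair feature is constant; median is undefined as a splitter")
  rows <- which(x1 > median(x1) & x2 > median(x2))
  shift <- with_seed(derive_seed(seed, "inject", pair[1L], pair[2L]),
                     rnorm(length(rows), mean = effect$mean, sd = effect$sd))
  y <- data$y
  y[rows] <- y[rows] + shift
  out <- new_fir_dataset(y, data$x, data$feature_names)
  attr(out, "injected_rows") <- rows
  out
}
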