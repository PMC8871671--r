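#' Construct a dataset of one continuous outcome and K continuous predictors
#'
#' The universal unit of analysis: an outcome vector `y` and an n x K numeric
#' predictor matrix with column names. At least 3 predictors and 40 rows are
#' required (enough to stratify into four subgroups and cross-validate), and
#' missing values are rejected.
#'
#' @param y numeric outcome vector.
#' @param x numeric matrix (or data frame) of predictors, one column per
#'   feature.
#' @param feature_names optional feature labels; defaults to `colnames(x)` or
#'   `X1..XK`.
#' @return an object of class `fir_dataset` with elements `y`, `x`,
#'   `feature_names` and `n`.
#' @export
fir_dataset <- function(y, x, feature_names = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- paste0("X", seq_len(ncol(x)))
  }
  if (length(feature_names) != ncol(x))
    stop("feature_names length (", length(feature_names),
         ") does not match number of predictor columns (", ncol(x), ")")
  if (length(y) != nrow(x))
    stop("outcome length (", length(y), ") does not match rows (", nrow(x), ")")
  if (anyNA(y) || anyNA(x)) stop("dataset contains missing values")
  if (nrow(x) < 40L)
    stop("need at least 40 rows for stratification and cross-validation, got ",
         nrow(x))
  if (ncol(x) < 3L) stop("need at least 3 predictors, got ", ncol(x))
  colnames(x) <- feature_names
  new_fir_dataset(y, x, feature_names)
}

# internal constructor without size validation, used for stratum subsets
new_fir_dataset <- function(y, x, feature_names) {
  structure(list(y = y, x = x, feature_names = feature_names,
                 n = length(y)),
            class = "fir_dataset")
}

subset_dataset <- function(data, rows) {
  new_fir_dataset(data$y[rows], data$x[rows, , drop = FALSE],
                  data$feature_names)
}

check_pair <- function(data, pair) {
  pair <- as.character(pair)
  if (length(pair) != 2L || anyDuplicated(pair))
    stop("'pair' must be two distinct feature names")
  missing <- setdiff(pair, data$feature_names)
  if (length(missing))
    stop("pair feature(s) not in dataset: ", paste(missing, collapse = ", "))
  pair
}

#' @export
print.fir_dataset <- function(x, ...) {
  cat(sprintf("fir_dataset: n=%d rows, K=%d features (%s%s)\n",
              x$n, length(x$feature_names),
              paste(utils::head(x$feature_names, 4), collapse = ", "),
              if (length(x$feature_names) > 4) ", ..." else ""))
  invisible(x)
}
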