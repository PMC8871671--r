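#' Read a dataset from a headered CSV file
#'
#' Expects comma-separated UTF-8 with a mandatory header and "." decimals;
#' the outcome column (default `Y`) is extracted and the remaining columns
#' become features in file order. Rows containing any missing value are
#' rejected, with the count reported.
#'
#' @param path CSV file path.
#' @param outcome_column name of the outcome column.
#' @return a [fir_dataset()].
#' @export
read_dataset <- function(path, outcome_column = "Y") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (!outcome_column %in% names(df))
    stop("outcome column '", outcome_column, "' not found; available columns: ",
         paste(names(df), collapse = ", "))
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric column(s) in ", path, ": ",
         paste(non_num, collapse = ", "))
  complete <- stats::complete.cases(df)
  if (!all(complete)) {
    warning(sum(!complete), " row(s) with missing values rejected")
    df <- df[complete, , drop = FALSE]
  }
  y <- df[[outcome_column]]
  x <- as.matrix(df[setdiff(names(df), outcome_column)])
  fir_dataset(y, x)
}

#' Write a dataset to CSV with Y first
#'
#' @param data a [fir_dataset()].
#' @param path output CSV path.
#' @param outcome_column name to give the outcome column.
#' @return the path, invisibly.
#' @export
write_dataset <- function(data, path, outcome_column = "Y") {
  stopifnot(inherits(data, "fir_dataset"))
  df <- data.frame(data$y, data$x, check.names = FALSE)
  names(df)[1L] <- outcome_column
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a scan, significance report or power table
#'
#' CSV output carries the tabular core (floats at 6 significant digits);
#' JSON output carries the full structure at full precision, including scan
#' provenance (hyperparameters and master seed).
#'
#' @param x a `fir_scan`, `fir_significance`, `fir_power` or data frame.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- if (inherits(x, "fir_scan")) x$table
         else if (inherits(x, "fir_significance")) x$table
         else if (inherits(x, "fir_power")) x$estimates
         else if (is.data.frame(x)) x
         else stop("cannot serialize object of class ",
                   paste(class(x), collapse = "/"))
  if (format == "csv") {
    out <- tab
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], signif, digits = 6)
    write.csv(out, path, row.names = FALSE)
  } else {
    payload <- if (inherits(x, "fir_scan")) {
      list(table = tab, n_pairs = x$n_pairs, failed = x$failed,
           hyperparams = unclass(x$hyperparams), seed = x$seed)
    } else if (inherits(x, "fir_significance")) {
      list(q1 = x$q1, iqr = x$iqr, threshold = x$threshold,
           quantile_type = x$quantile_type, n_pairs = x$n_pairs,
           table = tab, significant_pairs = x$significant_pairs,
           target = x$target)
    } else if (inherits(x, "fir_power")) {
      list(estimates = tab, failures = x$failures)
    } else {
      list(table = tab)
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Build a run manifest for reproducibility
#'
#' Records the master seed, package and R versions, a timestamp and the md5
#' checksums of the produced output files: together with the configuration
#' this is sufficient to re-run bit-identically under identical library
#' versions.
#'
#' @param master_seed the run's master seed.
#' @param outputs character vector of output file paths.
#' @param config optional configuration object to snapshot.
#' @return a list of class `fir_manifest`.
#' @export
run_manifest <- function(master_seed, outputs = character(), config = NULL) {
  structure(list(
    master_seed = as.integer(master_seed),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("firtest")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = if (length(outputs))
      data.frame(path = outputs, md5 = unname(tools::md5sum(outputs)),
                 stringsAsFactors = FALSE)
    else data.frame(path = character(), md5 = character()),
    config = if (is.null(config)) NULL else unclass(config)
  ), class = "fir_manifest")
}
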