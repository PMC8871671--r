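#' Tukey-fence outlier threshold on a FIR distribution
#'
#' The significance threshold is the boxplot lower fence Q1 - 1.5*IQR of the
#' empirical FIR distribution over all scanned pairs. Quartiles use the
#' linear-interpolation convention (`type = 7`, the mainstream default);
#' because Q1 and IQR are convention-sensitive the convention is recorded in
#' the result.
#'
#' @param firs numeric vector of FIR values (at least 4 finite values).
#' @return a list with `q1`, `iqr`, `threshold` and `quantile_type`.
#' @export
#' @examples
#' tukey_threshold(1:8)  # q1 = 2.75, iqr = 3.5, threshold = -2.5
tukey_threshold <- function(firs) {
  firs <- firs[is.finite(firs)]
  if (length(firs) < 4L)
    stop("need at least 4 finite FIR values to form a null distribution, got ",
         length(firs))
  q <- quantile(firs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  list(q1 = q[1L], iqr = iqr, threshold = q[1L] - 1.5 * iqr,
       quantile_type = 7L)
}

#' Declare significant feature interactions from a scan
#'
#' Thresholds the empirical FIR distribution of a [scan_all_pairs()] result at
#' the Tukey lower fence. A pair is significant iff its FIR is strictly below
#' Q1 - 1.5*IQR; the null distribution always includes the tested pair's own
#' FIR. Each pair's percentile rank among all FIRs (fraction of FIRs <= its
#' own) is reported as a descriptive empirical p-value; the binary fence
#' decision is the headline output because percentile cutoffs do not hold the
#' nominal level.
#'
#' @param scan a `fir_scan`.
#' @param target_pair optional pair of interest; if given, the report carries
#'   a `target` element with that pair's decision (error if the pair was not
#'   scanned).
#' @return an object of class `fir_significance` with `q1`, `iqr`,
#'   `threshold`, per-pair `table` (fir, empirical_p, significant) and
#'   `significant_pairs`.
#' @export
declare_significance <- function(scan, target_pair = NULL) {
  stopifnot(inherits(scan, "fir_scan"))
  tab <- scan$table
  if (nrow(tab) < 4L)
    stop("scan has only ", nrow(tab),
         " completed pair(s); need at least 4 for the FIR null distribution")
  fence <- tukey_threshold(tab$fir)
  n <- nrow(tab)
  tab$empirical_p <- vapply(tab$fir, function(f) mean(tab$fir <= f), numeric(1))
  tab$significant <- tab$fir < fence$threshold
  out_tab <- tab[order(tab$fir),
                 c("feature1", "feature2", "fir", "empirical_p", "significant")]
  rownames(out_tab) <- NULL
  sig <- out_tab[out_tab$significant, c("feature1", "feature2")]
  report <- structure(
    list(q1 = fence$q1, iqr = fence$iqr, threshold = fence$threshold,
         quantile_type = fence$quantile_type, n_pairs = n,
         table = out_tab,
         significant_pairs = if (nrow(sig))
           paste(sig$feature1, sig$feature2, sep = ":") else character()),
    class = "fir_significance")
  if (!is.null(target_pair)) {
    target_pair <- as.character(target_pair)
    hit <- (out_tab$feature1 == target_pair[1L] & out_tab$feature2 == target_pair[2L]) |
           (out_tab$feature1 == target_pair[2L] & out_tab$feature2 == target_pair[1L])
    if (!any(hit))
      stop("target pair (", paste(target_pair, collapse = ", "),
           ") was not scanned")
    report$target <- out_tab[which(hit)[1L], ]
  }
  report
}

#' @export
print.fir_significance <- function(x, ...) {
  cat(sprintf("FIR significance report: %d pairs, Q1=%.4f IQR=%.4f threshold=%.4f\n",
              x$n_pairs, x$q1, x$iqr, x$threshold))
  if (length(x$significant_pairs))
    cat("significant interactions:", paste(x$significant_pairs, collapse = ", "), "\n")
  else cat("no significant interactions\n")
  if (!is.null(x$target))
    cat(sprintf("target pair (%s, %s): FIR=%.4f, empirical p=%.3f, %ssignificant\n",
                x$target$feature1, x$target$feature2, x$target$fir,
                x$target$empirical_p,
                if (x$target$significant) "" else "not "))
  invisible(x)
}
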