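## Read-accuracy metric and evaluation reports.

#' Per-read base-calling accuracy
#'
#' One minus the ratio of the alignment edit distance to the base-call
#' length: `1 - editDistance(call, reference) / nchar(call)`, floored at 0.
#' The edit distance is the Levenshtein distance with unit costs; note the
#' denominator is the *call* length, not the reference length.
#'
#' @param call decoded base string (must be nonempty; empty calls are
#'   treated as unmapped and return `NA`).
#' @param reference true base string.
#' @return accuracy in `[0, 1]`, or `NA` for an empty call.
#' @export
read_accuracy <- function(call, reference) {
  if (nchar(call) == 0L) return(NA_real_)
  d <- utils::adist(call, reference)[1L, 1L]
  max(0, 1 - d / nchar(call))
}

#' Accuracy report for a set of reads
#'
#' Computes [read_accuracy()] per read, the median over reads with a
#' nonempty call, and the mapped fraction — here the fraction of reads whose
#' call is nonempty (no external aligner is involved).
#'
#' @param calls character vector of decoded sequences.
#' @param references character vector of true sequences (same length).
#' @return an object of class `accuracy_report`: list with `per_read`,
#'   `median` and `mapped_fraction`.
#' @export
accuracy_report <- function(calls, references) {
  stopifnot(length(calls) == length(references))
  acc <- mapply(read_accuracy, calls, references, USE.NAMES = FALSE)
  structure(list(per_read = acc,
                 median = stats::median(acc, na.rm = TRUE),
                 mapped_fraction = mean(!is.na(acc))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "<accuracy_report> %d reads | mapped %.1f%% | median read accuracy %.3f\n",
    length(x$per_read), 100 * x$mapped_fraction, x$median))
  invisible(x)
}
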