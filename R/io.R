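## Signal and sequence I/O.
##
## The signal interchange format is a plain TSV: optional '#'-prefixed
## header lines (tool version, config hash, seed), then one line per read:
## read_id TAB comma-separated samples.  Doubles are printed with 17
## significant digits so a write/read round trip is bit-exact.

#' Read raw signals from the TSV signal format
#'
#' @param path input file.
#' @return a named list of numeric signal vectors, in file order.
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) stop(sprintf("signal file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0L) stop(sprintf("empty signal file: %s", path))
  out <- list()
  for (ln in body) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("%s:%d: expected 'id<TAB>samples', got %d fields",
                   path, ln, length(parts)))
    vals <- suppressWarnings(
      as.numeric(strsplit(parts[2L], ",", fixed = TRUE)[[1]]))
    if (anyNA(vals))
      stop(sprintf("%s:%d: non-numeric sample value", path, ln))
    out[[parts[1L]]] <- vals
  }
  out
}

#' Write raw signals in the TSV signal format
#'
#' @param signals named list of numeric vectors.
#' @param path output file.
#' @param seed seed recorded in the provenance header.
#' @param config_hash configuration fingerprint for the header.
#' @export
write_signals <- function(signals, path, seed = NA_integer_,
                          config_hash = "none") {
  lines <- vapply(names(signals), function(id)
    paste0(id, "\t", paste(sprintf("%.17g", signals[[id]]), collapse = ",")),
    character(1))
  writeLines(c(artifact_header("raw signals", seed, config_hash), lines),
             path)
  invisible(path)
}

#' Write base calls as FASTA or FASTQ
#'
#' FASTQ qualities are a constant placeholder (`'I'`, Phred 40) because the
#' model emits no per-base quality.  Optional per-read accuracies are
#' appended to the record descriptions.  Provenance (version, seed) is
#' written to a sidecar `<path>.json`, keeping the sequence files
#' standards-compliant.
#'
#' @param ids,seqs character vectors of read ids and sequences.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @param accuracies optional numeric vector of per-read accuracies.
#' @param seed seed recorded in the sidecar.
#' @export
write_calls <- function(ids, seqs, path, format = c("fasta", "fastq"),
                        accuracies = NULL, seed = NA_integer_) {
  format <- match.arg(format)
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0L) {
    file.create(path)
  } else {
    labels <- if (is.null(accuracies)) ids
              else sprintf("%s accuracy=%.4f", ids, accuracies)
    xs <- Biostrings::DNAStringSet(seqs)
    names(xs) <- labels
    if (format == "fasta") {
      Biostrings::writeXStringSet(xs, path)
    } else {
      q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
        paste(rep("I", n), collapse = ""), character(1)))
      xq <- Biostrings::QualityScaledDNAStringSet(
        xs, Biostrings::PhredQuality(q))
      Biostrings::writeQualityScaledXStringSet(xq, path)
    }
  }
  writeLines(jsonlite::toJSON(list(tool = "nanocallr",
                                   version = package_version_string(),
                                   seed = seed, n_reads = length(ids),
                                   format = format),
                              auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}
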