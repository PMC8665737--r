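## CTC loss and decoding over {A, C, G, T, blank}.

encode_bases <- function(seq) {
  if (nchar(seq) == 0L) return(integer(0))
  idx <- match(strsplit(seq, "")[[1]], BASES)
  if (anyNA(idx))
    stop("label sequence contains characters outside {A, C, G, T}")
  idx
}

decode_bases <- function(idx) paste(BASES[idx], collapse = "")

#' CTC loss with exact gradient
#'
#' Negative log-probability of a label sequence under the connectionist
#' temporal classification model: the sum over all blank-augmented
#' alignments of the product of per-frame scores, computed by the standard
#' forward recursion in log space (underflow-safe for very long inputs).
#' The gradient is taken with respect to the log-score matrix and is exact
#' (forward-backward occupancy), so it can be checked by finite differences.
#'
#' A label that cannot fit in the available frames (fewer frames than bases
#' plus required repeat-separating blanks) yields `+Inf` loss and a zero
#' gradient, not an error.
#'
#' @param log_posteriors `(T', 5)` matrix of per-frame log-scores in channel
#'   order A, C, G, T, blank.
#' @param label character string over `{A, C, G, T}` (may be empty).
#' @return a list with `neg_log_prob` (scalar, `>= 0` for normalized rows)
#'   and `gradient` (same shape as the input).
#' @export
ctc_loss <- function(log_posteriors, label) {
  lp <- as.matrix(log_posteriors)
  if (ncol(lp) != 5L) stop("ctc_loss: log_posteriors must have 5 columns")
  res <- ctc_forward_backward(lp, as.integer(encode_bases(label)))
  list(neg_log_prob = res$nll, gradient = res$grad)
}

#' Brute-force CTC path enumeration (test oracle)
#'
#' Exact total probability of a label by enumerating all `5^T'` frame-level
#' paths, collapsing each (merge repeats, drop blanks) and summing the
#' probabilities of paths that collapse to the label.  Exponential in `T'`;
#' restricted to `T' <= 8`.
#'
#' @param posteriors `(T', 5)` matrix of per-frame probabilities.
#' @param label character string over `{A, C, G, T}`.
#' @return the alignment probability (a plain probability, not a log).
#' @export
brute_force_ctc <- function(posteriors, label) {
  p <- as.matrix(posteriors)
  T_ <- nrow(p)
  if (T_ > 8L) stop("brute_force_ctc: T' too large for enumeration (max 8)")
  paths <- as.matrix(expand.grid(rep(list(1:5), T_)))
  collapse <- function(path) {
    r <- path[c(TRUE, diff(path) != 0L)]
    decode_bases(r[r != 5L])
  }
  keys <- apply(paths, 1L, collapse)
  probs <- apply(paths, 1L, function(path)
    prod(p[cbind(seq_len(T_), path)]))
  sum(probs[keys == label])
}

#' Deterministic tie-break for equal frame maxima
#'
#' When several channels share the maximal probability in a frame, the
#' lowest channel index wins (order A, C, G, T, blank).  This is the rule
#' used by [best_path_decode()] and is stable across runs.
#'
#' @param frame_probs numeric vector of length 5.
#' @return the winning channel index (1-based).
#' @export
tie_break <- function(frame_probs) which.max(frame_probs)

#' Greedy best-path CTC decoding
#'
#' Per-frame argmax (ties broken toward the lowest channel index), collapse
#' of consecutive repeats, removal of blanks.
#'
#' @param posteriors `(T', 5)` posterior matrix.
#' @return the decoded base string.
#' @export
best_path_decode <- function(posteriors) {
  p <- as.matrix(posteriors)
  if (ncol(p) != 5L) stop("best_path_decode: posteriors must have 5 columns")
  path <- max.col(p, ties.method = "first")
  r <- path[c(TRUE, diff(path) != 0L)]
  decode_bases(r[r != 5L])
}

#' Prefix beam-search CTC decoding
#'
#' Standard prefix beam search over collapsed prefixes, tracking blank- and
#' non-blank-ending probabilities in log space.  `width = 1` reduces to
#' greedy decoding in practice; moderate widths can recover sequences the
#' per-frame argmax misses.
#'
#' @param posteriors `(T', 5)` posterior matrix.
#' @param width beam width (number of prefixes kept per frame).
#' @return the highest-probability base string.
#' @export
beam_search_decode <- function(posteriors, width = 4L) {
  p <- log(pmax(as.matrix(posteriors), 1e-300))
  T_ <- nrow(p)
  if (width <= 1L) return(best_path_decode(exp(p)))
  la <- function(a, b) {
    if (a == -Inf) return(b); if (b == -Inf) return(a)
    m <- max(a, b); m + log1p(exp(-abs(a - b)))
  }
  ## beams: named list ".prefix" -> c(p_blank, p_nonblank) in log space
  ## (keys carry a leading "." sentinel so the empty prefix is addressable)
  beams <- list(); beams[["."]] <- c(0, -Inf)
  for (t in seq_len(T_)) {
    nb <- list()
    bump <- function(key, kind, val) {
      cur <- nb[[key]]
      if (is.null(cur)) cur <- c(-Inf, -Inf)
      cur[kind] <- la(cur[kind], val)
      nb[[key]] <<- cur
    }
    for (pre in names(beams)) {
      pb <- beams[[pre]][1L]; pn <- beams[[pre]][2L]
      tot <- la(pb, pn)
      bump(pre, 1L, tot + p[t, 5L])                     # extend with blank
      last <- substr(pre, nchar(pre), nchar(pre))       # "." if empty prefix
      for (ci in 1:4) {
        ch <- BASES[ci]
        if (ch == last) {
          bump(pre, 2L, pn + p[t, ci])                  # repeat, merged
          bump(paste0(pre, ch), 2L, pb + p[t, ci])      # after a blank
        } else {
          bump(paste0(pre, ch), 2L, tot + p[t, ci])
        }
      }
    }
    sc <- vapply(nb, function(v) la(v[1L], v[2L]), numeric(1))
    keep <- names(sort(sc, decreasing = TRUE))[seq_len(min(width, length(sc)))]
    beams <- nb[keep]
  }
  sc <- vapply(beams, function(v) la(v[1L], v[2L]), numeric(1))
  sub(".", "", names(which.max(sc)), fixed = TRUE)
}
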