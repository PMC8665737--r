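## Synthetic nanopore squiggle simulator.
##
## Emulates the physics a base caller must invert: current is sampled at
## ~4000 Hz while DNA translocates at ~450 bases/s, so each base dwells in
## the pore for ~8.9 samples with large variance; the measured level depends
## on a short DNA context (5-12 bases) around the pore head; Gaussian noise
## is added per sample.  Ground-truth sequences, dwell times and per-sample
## event boundaries are returned so segmentation and base identity can be
## supervised and probed.

#' Pore model
#'
#' Additive per-position context model: the level of the event for base `b`
#' is the sum of contributions `table[pos, base]` over the `context_length`
#' bases in the window centred (position `ceiling(context_length / 2)`) on
#' `b`, plus a small seeded pairwise-interaction term between adjacent
#' context positions (so that distinct contexts can collide on very similar
#' levels, as in real pores).  An additive table is used instead of a
#' `4^c` lookup: it stays context-dependent while remaining desk-scale.
#'
#' The central-position contributions are fixed, equally spaced, at
#' `A = 1.2, G = 0.4, C = -0.4, T = -1.2` (in normalized signal units):
#' every pair of bases differs by at least 0.8 at the centre, the purine
#' mean and pyrimidine mean differ by 1.6 — well over one `noise_sd` — and
#' each base is individually identifiable from a correctly segmented event,
#' as in real pore tables.  Flank and interaction contributions are drawn
#' from bounded uniforms (`U(-0.12, 0.12)` and `U(-0.02, 0.02)`) whose
#' worst-case sum (0.7) stays below the minimal central gap (0.8), so
#' noiseless event means are strictly separable by construction.
#'
#' @param context_length context size in bases, between 5 and 12.
#' @param noise_sd per-sample Gaussian noise standard deviation, in
#'   normalized signal units.  The default 0.25 is a stand-in (no
#'   quantitative noise magnitude is published for the pore) and is recorded
#'   in every simulator output.
#' @param sample_rate signal samples per second.
#' @param translocation_speed DNA speed through the pore, bases per second.
#' @param dwell_dispersion size parameter of the shifted negative-binomial
#'   dwell distribution (smaller = more variable dwell).
#' @param seed seed for the random flank/interaction tables.
#' @return an object of class `pore_model`.
#' @export
pore_model <- function(context_length = 6L, noise_sd = 0.25,
                       sample_rate = 4000, translocation_speed = 450,
                       dwell_dispersion = 3.3, seed = 101L) {
  context_length <- as.integer(context_length)
  if (context_length < 5L || context_length > 12L)
    stop("pore_model: context_length must be in [5, 12]")
  if (noise_sd <= 0) stop("pore_model: noise_sd must be positive")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  tab <- matrix(stats::runif(context_length * 4L, -0.12, 0.12),
                context_length, 4L, dimnames = list(NULL, BASES))
  centre <- as.integer(ceiling(context_length / 2))
  tab[centre, ] <- c(A = 1.2, C = -0.4, G = 0.4, T = -1.2)
  inter <- array(stats::runif((context_length - 1L) * 16L, -0.02, 0.02),
                 dim = c(context_length - 1L, 4L, 4L))
  structure(list(context_length = context_length, centre = centre,
                 table = tab, interactions = inter,
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 translocation_speed = translocation_speed,
                 mean_dwell = sample_rate / translocation_speed,
                 dwell_dispersion = dwell_dispersion, seed = as.integer(seed)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf(
    "<pore_model> context %d bases (centre %d), noise_sd %.3g (stand-in), %g Hz / %g bases/s (mean dwell %.2f)\n",
    x$context_length, x$centre, x$noise_sd, x$sample_rate,
    x$translocation_speed, x$mean_dwell))
  invisible(x)
}

#' Uniform random DNA sequence
#'
#' @param length sequence length in bases.
#' @param seed integer seed; same seed gives the same sequence.
#' @return a base string over `{A, C, G, T}`.
#' @export
random_sequence <- function(length, seed = NULL) {
  if (length == 0L) return("")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(as.integer(seed))
  }
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

## Event level for every base of an encoded sequence (integer vector 1..4).
event_levels <- function(idx, pore) {
  L <- length(idx)
  cl <- pore$context_length
  centre <- pore$centre
  lev <- numeric(L)
  for (pos in seq_len(cl)) {
    off <- pos - centre
    src <- seq_len(L) + off
    ok <- src >= 1L & src <= L
    lev[ok] <- lev[ok] + pore$table[pos, idx[src[ok]]]
  }
  ## adjacent-position interactions
  for (pos in seq_len(cl - 1L)) {
    off1 <- pos - centre; off2 <- pos + 1L - centre
    s1 <- seq_len(L) + off1; s2 <- seq_len(L) + off2
    ok <- s1 >= 1L & s2 <= L
    lev[ok] <- lev[ok] +
      pore$interactions[cbind(pos, idx[s1[ok]], idx[s2[ok]])]
  }
  lev
}

#' Simulate a squiggle read
#'
#' Per-base dwell times are drawn from a shifted negative binomial with mean
#' `sample_rate / translocation_speed` (~8.9 samples) and coefficient of
#' variation around 0.58 ("large variance"), minimum 1 sample.  The event
#' level is the context-table sum for the base's window; i.i.d. Gaussian
#' noise of sd `noise_sd` is added to every sample.  The first sample of
#' each base's event is marked in `boundaries`.
#'
#' @param seq base string; must be at least `context_length` long.
#' @param pore a [pore_model()].
#' @param seed integer seed; the same `(seq, seed)` reproduces the read.
#' @param id read identifier.
#' @return an object of class `squiggle_read`: list with `id`, `signal`,
#'   `sequence`, `dwell`, `boundaries`, `levels` and `params`.
#' @export
simulate_squiggle <- function(seq, pore = pore_model(), seed = 1L,
                              id = "read") {
  idx <- encode_bases(seq)
  if (length(idx) < pore$context_length)
    stop("simulate_squiggle: sequence shorter than the pore context")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  L <- length(idx)
  mu <- pore$mean_dwell - 1
  dwell <- 1L + stats::rnbinom(L, size = pore$dwell_dispersion, mu = mu)
  levels <- event_levels(idx, pore)
  signal <- rep(levels, dwell) + stats::rnorm(sum(dwell), 0, pore$noise_sd)
  boundaries <- integer(sum(dwell))
  boundaries[cumsum(c(1L, dwell[-L]))] <- 1L
  structure(list(id = id, signal = signal, sequence = seq,
                 dwell = as.integer(dwell), boundaries = boundaries,
                 levels = levels,
                 params = list(noise_sd = pore$noise_sd,
                               context_length = pore$context_length,
                               sample_rate = pore$sample_rate,
                               translocation_speed = pore$translocation_speed,
                               seed = as.integer(seed))),
            class = "squiggle_read")
}

#' @export
print.squiggle_read <- function(x, ...) {
  cat(sprintf(
    "<squiggle_read> %s: %d bases, %d samples (mean dwell %.2f), noise_sd %.3g\n",
    x$id, nchar(x$sequence), length(x$signal),
    length(x$signal) / nchar(x$sequence), x$params$noise_sd))
  invisible(x)
}

#' Simulate a dataset of squiggle reads
#'
#' Read lengths are drawn uniformly from `length_range`.  Fully reproducible
#' from `(pore, seed)`: each read gets its own derived seed.
#'
#' @param n_reads number of reads.
#' @param length_range integer pair, bases per read (default desk-scale
#'   200-1000).
#' @param pore a [pore_model()].
#' @param seed integer master seed.
#' @return a list of [simulate_squiggle()] reads.
#' @export
simulate_dataset <- function(n_reads, length_range = c(200L, 1000L),
                             pore = pore_model(), seed = 1L) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  lens <- sample(seq(length_range[1L], length_range[2L]), n_reads,
                 replace = TRUE)
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_reads)
  lapply(seq_len(n_reads), function(i) {
    simulate_squiggle(random_sequence(lens[i], seeds[i]), pore,
                      seed = seeds[i] + 1L,
                      id = sprintf("synthetic_read_%04d", i))
  })
}

#' Robust signal normalization
#'
#' Centres and scales by median and MAD: `(x - median) / (1.4826 * MAD)`.
#' Affine-invariant: `normalize_signal(a * x + b)` equals
#' `sign(a) * normalize_signal(x)`.  Applied identically at training and
#' inference time.
#'
#' @param signal numeric vector with at least 10 samples.
#' @return the normalized signal.
#' @export
normalize_signal <- function(signal) {
  if (length(signal) < 10L)
    stop("normalize_signal: need at least 10 samples")
  s <- stats::mad(signal)   # 1.4826 * median absolute deviation
  if (s == 0)
    stop("normalize_signal: MAD is zero (degenerate constant signal)")
  (signal - stats::median(signal)) / s
}

#' Per-event mean signal levels
#'
#' Mean of the samples within each base's event, using the read's
#' ground-truth boundaries.
#'
#' @param read a [simulate_squiggle()] read (or any list with `signal` and
#'   `dwell`).
#' @return numeric vector, one mean per base.
#' @export
event_means <- function(read) {
  ev <- rep(seq_along(read$dwell), read$dwell)
  as.numeric(tapply(read$signal, ev, mean))
}

## ---- dataset export / import --------------------------------------------

#' Export / import a squiggle dataset
#'
#' Writes three files under `dir`: `signals.tsv` (one line per read:
#' `read_id TAB comma-separated samples`, doubles printed with 17
#' significant digits for bit-exact reimport), `references.fasta` (true
#' sequences) and `meta.json` (per-read dwell run-lengths, generation
#' parameters — including the stand-in `noise_sd` — and the provenance
#' header fields).
#'
#' @param reads list of [simulate_squiggle()] reads.
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the provenance header.
#' @return `read_squiggle_dataset` returns the list of reads.
#' @export
write_squiggle_dataset <- function(reads, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, "signals.tsv")
  lines <- vapply(reads, function(r)
    paste0(r$id, "\t", paste(sprintf("%.17g", r$signal), collapse = ",")),
    character(1))
  writeLines(c(artifact_header("squiggle signals", seed), lines), sig_path)
  refs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1),
                                          "sequence"))
  names(refs) <- vapply(reads, `[[`, character(1), "id")
  Biostrings::writeXStringSet(refs, file.path(dir, "references.fasta"))
  meta <- list(tool = "nanocallr", version = package_version_string(),
               seed = seed,
               params = reads[[1L]]$params,
               reads = lapply(reads, function(r)
                 list(id = r$id, dwell = r$dwell)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_squiggle_dataset
#' @export
read_squiggle_dataset <- function(dir) {
  sigs <- read_signals(file.path(dir, "signals.tsv"))
  refs <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"),
                             simplifyVector = FALSE)
  lapply(seq_along(sigs), function(i) {
    id <- names(sigs)[i]
    dwell <- as.integer(unlist(meta$reads[[i]]$dwell))
    L <- length(dwell)
    boundaries <- integer(sum(dwell))
    boundaries[cumsum(c(1L, dwell[-L]))] <- 1L
    structure(list(id = id, signal = sigs[[i]],
                   sequence = as.character(refs[[id]]),
                   dwell = dwell, boundaries = boundaries,
                   levels = NULL,
                   params = lapply(meta$params, unlist)),
              class = "squiggle_read")
  })
}

package_version_string <- function() {
  as.character(utils::packageVersion("nanocallr"))
}

artifact_header <- function(what, seed = NA_integer_, config_hash = "none") {
  c(sprintf("# nanocallr %s | %s", package_version_string(), what),
    sprintf("# seed: %s | config: %s", as.character(seed), config_hash))
}
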