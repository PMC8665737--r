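## Desk-scale CTC training loop and the three companion experiments
## (identity-initialization ablation, event-boundary input, purine probe).

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param steps number of optimizer steps.
#' @param batch_size reads per step.
#' @param seed master seed (initialization and batch sampling).
#' @param init `"identity"` or `"glorot"` initialization mode.
#' @param epsilon identity-initialization noise half-width.
#' @param boundary_channel append the ground-truth event-boundary series as
#'   a second input channel (diagnostic only — a real base caller cannot be
#'   given ground-truth boundaries, so models trained this way must not be
#'   used for base calling).
#' @param eval_every evaluate held-out accuracy every this many steps
#'   (0 = only at the end).
#' @param eval_reads cap on held-out reads used per evaluation.
#' @param chunk_samples training chunk length in samples: reads are cut at
#'   event boundaries into chunks of roughly this many samples (with the
#'   matching label slice), which keeps CTC cost per step low.  0 trains on
#'   whole reads.
#' @param lr_schedule `"cosine"` (half-cosine decay from `lr` to 0 over the
#'   budget, the default) or `"constant"`.
#' @param eval_decoder decoder for the final held-out evaluation:
#'   `"beam"` (prefix beam search, the default — recovers short events the
#'   per-frame argmax drops) or `"greedy"`.  Periodic evaluations during
#'   training always use the cheap greedy decoder.
#' @param eval_beam_width beam width for the final evaluation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 4e-3, steps = 120L, batch_size = 8L,
                         seed = 1L, init = c("identity", "glorot"),
                         epsilon = 0.02, boundary_channel = FALSE,
                         eval_every = 0L, eval_reads = 40L,
                         chunk_samples = 1200L,
                         lr_schedule = c("cosine", "constant"),
                         eval_decoder = c("beam", "greedy"),
                         eval_beam_width = 8L) {
  init <- match.arg(init)
  lr_schedule <- match.arg(lr_schedule)
  eval_decoder <- match.arg(eval_decoder)
  stopifnot(steps >= 1L, batch_size >= 1L)
  structure(list(optimizer = "adam", lr = lr, steps = as.integer(steps),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init = init, epsilon = epsilon,
                 boundary_channel = isTRUE(boundary_channel),
                 eval_every = as.integer(eval_every),
                 eval_reads = as.integer(eval_reads),
                 chunk_samples = as.integer(chunk_samples),
                 lr_schedule = lr_schedule,
                 eval_decoder = eval_decoder,
                 eval_beam_width = as.integer(eval_beam_width)),
            class = "train_config")
}

## Cut a read into training chunks at event boundaries: each chunk carries
## its input slice and exact label sub-sequence.  Chunks shorter than half
## the target are merged into the previous chunk.
chunk_read <- function(read, target, boundary_channel = FALSE) {
  x <- model_input(read, boundary_channel)
  if (target <= 0L || nrow(x) <= 1.5 * target) {
    return(list(list(x = x, label = encode_bases(read$sequence))))
  }
  idx <- encode_bases(read$sequence)
  ends <- cumsum(read$dwell)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunks <- list()
  ev_from <- 1L
  repeat {
    remaining <- length(ends) - ev_from + 1L
    if (remaining <= 0L) break
    cut <- which(ends - starts[ev_from] + 1L >= target)
    cut <- cut[cut >= ev_from]
    ev_to <- if (length(cut)) cut[1L] else length(ends)
    ## avoid a stub tail: absorb it into this chunk
    tail_samples <- if (ev_to < length(ends))
      ends[length(ends)] - ends[ev_to] else 0L
    if (tail_samples > 0L && tail_samples < target %/% 2L)
      ev_to <- length(ends)
    rows <- starts[ev_from]:ends[ev_to]
    chunks[[length(chunks) + 1L]] <-
      list(x = x[rows, , drop = FALSE], label = idx[ev_from:ev_to])
    ev_from <- ev_to + 1L
  }
  chunks
}

## deterministic 80/20 split by read-id hash
split_by_id <- function(reads) {
  h <- vapply(reads, function(r)
    sum(utf8ToInt(r$id) * seq_len(nchar(r$id))) %% 5L, numeric(1))
  list(train = reads[h != 0], heldout = reads[h == 0])
}

model_input <- function(read, boundary_channel = FALSE) {
  x <- normalize_signal(read$signal)
  if (boundary_channel) cbind(x, read$boundaries) else matrix(x, ncol = 1L)
}

## Adam step over the parameter tree; opt carries m/v trees keyed by path.
adam_update <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  net <- map_params(net, grads, function(w, g, key) {
    if (is.null(g)) return(w)
    m <- opt$m[[key]]; v <- opt$v[[key]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    opt$m[[key]] <<- m
    opt$v[[key]] <<- v
    w - lr * (m / corr1) / (sqrt(v / corr2) + eps)
  })
  list(net = net, opt = opt)
}

scale_grads <- function(b, w) {
  lapply(b, function(x) {
    if (is.null(x)) NULL
    else if (is.list(x)) scale_grads(x, w)
    else w * x
  })
}

accumulate_grads <- function(a, b, w = 1) {
  if (is.null(a)) return(scale_grads(b, w))
  stopifnot(length(a) == length(b))
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    a[[i]] <- if (is.list(b[[i]])) accumulate_grads(a[[i]], b[[i]], w)
              else a[[i]] + w * b[[i]]
  }
  a
}

## Held-out evaluation uses read-adaptive ("instance") batch-norm
## statistics, matching the per-read normalization philosophy of the
## pipeline; see the methods vignette.
eval_model <- function(model, reads, boundary_channel = FALSE,
                       max_reads = Inf, decoder = "greedy", width = 8L) {
  if (length(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  calls <- vapply(reads, function(r) {
    p <- forward_signal(model, model_input(r, boundary_channel),
                        mode = "instance")
    if (decoder == "beam") beam_search_decode(p, width)
    else best_path_decode(p)
  }, character(1))
  refs <- vapply(reads, `[[`, character(1), "sequence")
  accuracy_report(calls, refs)
}

#' Train a base caller on squiggle reads
#'
#' Minimizes the frame-normalized CTC loss with Adam over mini-batches of
#' whole reads.  Signals are median/MAD-normalized; reads are split 80/20
#' into training and held-out sets by a deterministic id hash.  Gradients
#' for every operator are hand-derived and finite-difference verified (see
#' the package tests).  Training aborts with diagnostics if the loss turns
#' non-finite.
#'
#' @param reads list of [simulate_squiggle()] reads (or reads reimported
#'   with [read_squiggle_dataset()]).
#' @param model_cfg a [model_config()]; its `in_channels` is overridden to
#'   match `cfg$boundary_channel`.
#' @param cfg a [train_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `basecaller`: the fitted model plus loss and
#'   accuracy curves, the configs and the held-out evaluation.
#' @export
train_basecaller <- function(reads, model_cfg = model_config("small"),
                             cfg = train_config(), quiet = TRUE) {
  model_cfg$in_channels <- if (cfg$boundary_channel) 2L else 1L
  model_cfg$blocks[[1L]]$cin <- model_cfg$in_channels
  init <- if (cfg$init == "identity") identity_init_spec(cfg$epsilon)
          else identity_init_spec(cfg$epsilon, depthwise = FALSE,
                                  fat_pointwise = FALSE)
  model <- build_model(model_cfg, init, seed = cfg$seed)
  sp <- split_by_id(reads)
  if (length(sp$train) == 0L) stop("train_basecaller: no training reads")
  chunks <- unlist(lapply(sp$train, chunk_read, target = cfg$chunk_samples,
                          boundary_channel = cfg$boundary_channel),
                   recursive = FALSE)
  inputs <- lapply(chunks, `[[`, "x")
  labels <- lapply(chunks, `[[`, "label")

  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(cfg$seed + 7L)
  opt <- list(t = 0L, m = list(), v = list())
  loss_curve <- numeric(cfg$steps)
  acc_curve <- data.frame(step = integer(0), median_accuracy = numeric(0))
  n <- length(inputs)
  for (step in seq_len(cfg$steps)) {
    idx <- sample.int(n, min(cfg$batch_size, n))
    grads <- NULL
    total <- 0
    for (i in idx) {
      fw <- layer_forward(model$net, inputs[[i]], training = TRUE)
      model$net <- fw$layer
      res <- ctc_forward_backward(fw$y, labels[[i]])
      Tp <- nrow(fw$y)
      if (!is.finite(res$nll)) next       # label does not fit; skip read
      total <- total + res$nll / Tp
      bw <- layer_backward(model$net, fw$cache, res$grad / Tp)
      grads <- accumulate_grads(grads, bw$grads, 1 / length(idx))
    }
    if (is.null(grads) || !is.finite(total))
      stop(sprintf(
        "train_basecaller: non-finite loss at step %d (lr %.3g); aborting",
        step, cfg$lr))
    lr_t <- if (identical(cfg$lr_schedule, "cosine"))
      cfg$lr * 0.5 * (1 + cos(pi * (step - 1) / cfg$steps)) else cfg$lr
    up <- adam_update(model$net, grads, opt, lr_t)
    model$net <- up$net
    opt <- up$opt
    loss_curve[step] <- total / length(idx)
    if (cfg$eval_every > 0L && step %% cfg$eval_every == 0L &&
        length(sp$heldout) > 0L) {
      model$net <- calibrate_bn(model$net, inputs[sample.int(n, min(8L, n))])
      rep_ <- eval_model(model, sp$heldout, cfg$boundary_channel,
                         cfg$eval_reads)
      acc_curve <- rbind(acc_curve,
                         data.frame(step = step,
                                    median_accuracy = rep_$median))
      if (!quiet)
        message(sprintf("step %d: loss %.4f, held-out median accuracy %.3f",
                        step, loss_curve[step], rep_$median))
    } else if (!quiet && step %% 10L == 0L) {
      message(sprintf("step %d: loss %.4f", step, loss_curve[step]))
    }
  }
  ## refresh batch-norm running statistics with frozen weights so that
  ## inference (which uses them) matches the training-time distribution
  calib_idx <- sample.int(n, min(40L, n))
  model$net <- calibrate_bn(model$net, inputs[calib_idx])
  ## final held-out evaluation decodes with the prefix beam search: the
  ## frame-synchronous argmax drops short events whose probability mass is
  ## spread over neighbouring frames (see the methods vignette)
  heldout <- if (length(sp$heldout) > 0L)
    eval_model(model, sp$heldout, cfg$boundary_channel,
               decoder = cfg$eval_decoder, width = cfg$eval_beam_width)
    else NULL
  structure(list(model = model, loss_curve = loss_curve,
                 accuracy_curve = acc_curve, heldout = heldout,
                 n_train = length(sp$train), n_heldout = length(sp$heldout),
                 train_config = cfg, model_config = model_cfg),
            class = "basecaller")
}

## ---- basecaller S3 methods ----------------------------------------------

#' @export
print.basecaller <- function(x, ...) {
  cat(sprintf("<basecaller> trained %d steps on %d reads (%s init%s)\n",
              x$train_config$steps, x$n_train, x$train_config$init,
              if (x$train_config$boundary_channel)
                ", diagnostic boundary channel" else ""))
  print(x$model)
  if (!is.null(x$heldout))
    cat(sprintf("  held-out (%d reads): median accuracy %.3f, mapped %.1f%%\n",
                x$n_heldout, x$heldout$median,
                100 * x$heldout$mapped_fraction))
  invisible(x)
}

#' @export
summary.basecaller <- function(object, ...) {
  w <- min(50L, length(object$loss_curve))
  ma <- stats::filter(object$loss_curve, rep(1 / w, w), sides = 1)
  out <- list(final_loss = utils::tail(object$loss_curve, 1L),
              smoothed_final_loss = utils::tail(ma[!is.na(ma)], 1L),
              initial_loss = object$loss_curve[1L],
              heldout = object$heldout,
              accuracy_curve = object$accuracy_curve,
              n_params = object$model$n_params)
  class(out) <- "summary.basecaller"
  out
}

#' @export
print.summary.basecaller <- function(x, ...) {
  cat(sprintf("CTC loss per frame: %.4f (first step) -> %.4f (last step, MA %.4f)\n",
              x$initial_loss, x$final_loss, x$smoothed_final_loss))
  cat(sprintf("parameters: %s\n", format(x$n_params, big.mark = ",")))
  if (!is.null(x$heldout)) print(x$heldout)
  invisible(x)
}

#' Predict from a trained base caller
#'
#' @param object a `basecaller`.
#' @param signals list of raw (unnormalized) signal vectors, or a list of
#'   `squiggle_read`s.
#' @param type `"sequence"` for decoded calls, `"posterior"` for the
#'   per-frame probability matrices.
#' @param decoder `"beam"` (default; recovers short events the per-frame
#'   argmax drops) or `"greedy"`.
#' @param width beam width when `decoder = "beam"`.
#' @param ... unused.
#' @return character vector of calls, or list of posterior matrices.
#' @export
predict.basecaller <- function(object, signals,
                               type = c("sequence", "posterior"),
                               decoder = c("beam", "greedy"), width = 8L,
                               ...) {
  type <- match.arg(type)
  decoder <- match.arg(decoder)
  if (inherits(signals, "squiggle_read")) signals <- list(signals)
  if (is.numeric(signals)) signals <- list(signals)
  bc <- object$train_config$boundary_channel
  if (bc)
    warning("model was trained with the diagnostic boundary channel; ",
            "predictions require ground-truth boundaries and are not usable ",
            "for base calling")
  posts <- lapply(signals, function(s) {
    x <- if (inherits(s, "squiggle_read")) model_input(s, bc)
         else matrix(normalize_signal(s), ncol = 1L)
    forward_signal(object$model, x, mode = "instance")
  })
  if (type == "posterior") return(posts)
  vapply(posts, function(p)
    if (decoder == "greedy") best_path_decode(p)
    else beam_search_decode(p, width), character(1))
}

#' @export
coef.basecaller <- function(object, ...) collect_params(object$model$net)

#' @export
plot.basecaller <- function(x, ...) {
  has_acc <- nrow(x$accuracy_curve) > 0L
  if (has_acc) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  graphics::plot(x$loss_curve, type = "l", xlab = "step",
                 ylab = "CTC loss per frame", main = "Training loss", ...)
  if (has_acc)
    graphics::plot(x$accuracy_curve$step, x$accuracy_curve$median_accuracy,
                   type = "b", xlab = "step",
                   ylab = "held-out median read accuracy",
                   main = "Held-out accuracy")
  invisible(x)
}

## ---- experiments ---------------------------------------------------------

#' Identity-initialization ablation
#'
#' Trains the same architecture under identity and Glorot initialization,
#' `n_seeds` seeds each with otherwise identical configurations, and reports
#' per-seed held-out median accuracies at the fixed budget, arm medians and
#' a win/loss tally.
#'
#' @param reads list of squiggle reads.
#' @param model_cfg a [model_config()].
#' @param cfg base [train_config()] (its `init` field is overridden per arm).
#' @param n_seeds seeds per arm (>= 3 recommended).
#' @return an object of class `ablation_report`.
#' @export
ablation_identity_init <- function(reads, model_cfg = model_config("small"),
                                   cfg = train_config(), n_seeds = 3L) {
  run_arm <- function(init) {
    vapply(seq_len(n_seeds), function(s) {
      c2 <- cfg; c2$init <- init; c2$seed <- cfg$seed + s
      fit <- train_basecaller(reads, model_cfg, c2)
      fit$heldout$median
    }, numeric(1))
  }
  identity <- run_arm("identity")
  glorot <- run_arm("glorot")
  structure(list(identity = identity, glorot = glorot,
                 median_identity = stats::median(identity),
                 median_glorot = stats::median(glorot),
                 wins_identity = sum(identity > glorot),
                 n_seeds = n_seeds, config = cfg),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf(
    "<ablation_report> identity init: median %.3f | glorot: median %.3f | identity wins %d/%d\n",
    x$median_identity, x$median_glorot, x$wins_identity, x$n_seeds))
  invisible(x)
}

#' Event-boundary input experiment
#'
#' Compares training speed with and without a second input channel carrying
#' the ground-truth event-boundary indicator: for each seed, the number of
#' steps needed to first reach `threshold` held-out median accuracy
#' (evaluated every `cfg$eval_every` steps; `Inf` if never reached within
#' the budget).  The report is diagnostic-only: a base caller cannot receive
#' ground-truth event boundaries as an input, so the boundary arm must not
#' be used for base calling.
#'
#' @param reads list of squiggle reads.
#' @param model_cfg a [model_config()].
#' @param cfg a [train_config()] with `eval_every > 0`.
#' @param n_seeds seeds per arm.
#' @param threshold held-out median accuracy to reach.  The default (0.75)
#'   sits in the segmentation-limited regime: in the first optimization
#'   phase both arms learn per-event level decoding at a similar rate, and
#'   the boundary channel pays off once segmentation ambiguity becomes the
#'   bottleneck.
#' @return an object of class `boundary_report`.
#' @export
experiment_boundary_input <- function(reads,
                                      model_cfg = model_config("small"),
                                      cfg = train_config(eval_every = 25L),
                                      n_seeds = 3L, threshold = 0.75) {
  if (cfg$eval_every <= 0L)
    stop("experiment_boundary_input: cfg$eval_every must be positive")
  steps_to <- function(fit) {
    ac <- fit$accuracy_curve
    hit <- ac$step[ac$median_accuracy >= threshold]
    if (length(hit)) min(hit) else Inf
  }
  run_arm <- function(boundary) {
    vapply(seq_len(n_seeds), function(s) {
      c2 <- cfg; c2$boundary_channel <- boundary; c2$seed <- cfg$seed + s
      steps_to(train_basecaller(reads, model_cfg, c2))
    }, numeric(1))
  }
  baseline <- run_arm(FALSE)
  boundary <- run_arm(TRUE)
  structure(list(baseline_steps = baseline, boundary_steps = boundary,
                 median_baseline = stats::median(baseline),
                 median_boundary = stats::median(boundary),
                 threshold = threshold, n_seeds = n_seeds,
                 note = "diagnostic-only: not usable for base calling"),
            class = "boundary_report")
}

#' @export
print.boundary_report <- function(x, ...) {
  cat(sprintf(
    "<boundary_report> steps to %.2f accuracy: baseline median %s, boundary median %s (%s)\n",
    x$threshold, format(x$median_baseline), format(x$median_boundary),
    x$note))
  invisible(x)
}

#' Purine/pyrimidine probe on segmented events
#'
#' Fits a logistic regression (single feature: the event mean level from
#' ground-truth segmentation) to classify purines {A, G} against pyrimidines
#' {C, T}, training on a random half of the events and reporting accuracy on
#' the other half.  With the default pore model the classes are separable
#' well above chance; shuffling the labels collapses accuracy to ~0.5.
#'
#' @param reads list of squiggle reads.
#' @param seed seed for the train/test split (and the optional shuffle).
#' @param shuffle_labels permute labels first (null control).
#' @return list with `accuracy`, `n_events` and the fitted glm coefficients.
#' @export
experiment_purine_probe <- function(reads, seed = 1L,
                                    shuffle_labels = FALSE) {
  means <- unlist(lapply(reads, event_means))
  bases <- unlist(lapply(reads, function(r) encode_bases(r$sequence)))
  purine <- as.integer(bases %in% c(1L, 3L))   # A, G
  if (length(unique(purine)) < 2L)
    stop("experiment_purine_probe: degenerate single-class data")
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(as.integer(seed))
  if (shuffle_labels) purine <- sample(purine)
  n <- length(means)
  idx <- sample.int(n, n %/% 2L)
  df <- data.frame(y = purine, x = means)
  ## quasi-complete separation is expected by construction at low noise;
  ## the fitted classifier is still well-defined, so the glm warning is noise
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), data = df[idx, ]))
  pred <- as.integer(stats::predict(fit, df[-idx, ], type = "response") > 0.5)
  list(accuracy = mean(pred == df$y[-idx]),
       n_events = n, coefficients = stats::coef(fit))
}
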