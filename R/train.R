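#' Training configuration
#'
#' Defaults mirror the published protocol: binary cross-entropy minimized by
#' Adam at an initial learning rate of 1e-4, batch size 200, gradients
#' clipped to norm 1 and value 0.5, the learning rate multiplied by 0.8 when
#' the validation AUPRC plateaus, a fresh random 10\% subsample of the
#' negative (correctly assembled) class each epoch, and AUPRC-based model
#' selection every second epoch.
#'
#' @param epochs number of training epochs.
#' @param batch_size samples per optimizer step.
#' @param lr initial Adam learning rate.
#' @param lr_decay multiplicative decay applied on validation plateau.
#' @param plateau_patience evaluations without improvement before decay.
#' @param grad_clip_norm per-tensor gradient norm ceiling.
#' @param grad_clip_value element-wise gradient magnitude ceiling.
#' @param neg_subsample_frac fraction of negatives drawn each epoch.
#' @param validation_frac fraction of contigs held out for validation.
#' @param eval_every epochs between validation evaluations.
#' @param window_len training window length (bp); must equal the model's
#'   `max_input_length`.
#' @param seed integer RNG seed.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 200L, lr = 1e-4,
                         lr_decay = 0.8, plateau_patience = 2L,
                         grad_clip_norm = 1, grad_clip_value = 0.5,
                         neg_subsample_frac = 0.10, validation_frac = 0.10,
                         eval_every = 2L, window_len = 20000L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1,
            neg_subsample_frac > 0, neg_subsample_frac <= 1,
            validation_frac >= 0, validation_frac < 1,
            eval_every >= 1, window_len > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay = lr_decay,
                 plateau_patience = as.integer(plateau_patience),
                 grad_clip_norm = grad_clip_norm,
                 grad_clip_value = grad_clip_value,
                 neg_subsample_frac = neg_subsample_frac,
                 validation_frac = validation_frac,
                 eval_every = as.integer(eval_every),
                 window_len = as.integer(window_len),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Compose one training epoch under negative subsampling
#'
#' Keeps every positive (misassembled) contig and an independent uniform
#' subsample (without replacement) of `round(neg_frac * N)` negatives, then
#' shuffles. The realized positive fraction is therefore exactly
#' `P / (P + round(neg_frac * N))`.
#'
#' @param labels 0/1 vector.
#' @param neg_frac fraction of negatives to keep.
#' @param epoch_seed integer RNG seed for this epoch.
#' @return Integer index vector into `labels`.
#' @export
make_epoch_sample <- function(labels, neg_frac, epoch_seed) {
  stopifnot(all(labels %in% c(0, 1)))
  withr_seed(epoch_seed)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0) warning("no positive contigs in training data")
  k <- round(neg_frac * length(neg))
  idx <- c(pos, sample(neg, k))
  sample(idx)
}

#' Select a training window on a contig
#'
#' Contigs shorter than `window_len` are used whole (and zero-padded
#' downstream). For longer misassembled contigs a breakpoint is chosen
#' uniformly, then a window containing it is chosen uniformly among all
#' windows that lie fully inside the contig; for longer correctly assembled
#' contigs the window start is uniform.
#'
#' @param contig_len contig length (bp).
#' @param label 0/1 truth label.
#' @param breakpoints integer breakpoint positions (bases before each
#'   junction); required non-empty when `label == 1`.
#' @param window_len window length (bp).
#' @param seed integer RNG seed.
#' @return `c(start, end)`, 1-based closed.
#' @export
select_window <- function(contig_len, label, breakpoints = integer(0),
                          window_len = 20000L, seed = NULL) {
  stopifnot(window_len > 0)
  if (label == 1 && length(breakpoints) == 0)
    stop("misassembled contig without breakpoints")
  if (contig_len <= window_len) return(c(1L, as.integer(contig_len)))
  withr_seed(seed)
  max_start <- contig_len - window_len + 1L
  if (label == 1) {
    bp <- if (length(breakpoints) == 1L) breakpoints else
      sample(breakpoints, 1L)
    # windows [s, s + window_len - 1] containing the junction (bp, bp + 1)
    lo <- max(1L, bp + 1L - window_len + 1L)
    hi <- min(max_start, bp)
    if (hi < lo) { lo <- max(1L, min(bp, max_start)); hi <- lo }
    s <- if (hi == lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
  } else {
    s <- sample.int(max_start, 1L)
  }
  c(as.integer(s), as.integer(s + window_len - 1L))
}

# ---- optimizer -----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

clip_grads <- function(grads, clip_norm, clip_value) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    nrm <- sqrt(sum(g * g))
    if (is.finite(nrm) && nrm > clip_norm) g <- g * (clip_norm / nrm)
    g[g > clip_value] <- clip_value
    g[g < -clip_value] <- -clip_value
    grads[[nm]] <- g
  }
  grads
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    mhat <- opt$m[[nm]] / bc1
    vhat <- opt$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

# ---- batching ------------------------------------------------------------

# assemble [C, L*B] batch from normalized feature matrices (selected
# channels, positions x channels), zero-padded to a common length that is
# at least the network's minimum input length
make_batch <- function(mats, selected, min_len) {
  lens <- vapply(mats, function(m) nrow(m$values), 0L)
  len <- pmax(lens, min_len)
  L <- max(len)
  B <- length(mats)
  C <- length(selected)
  X <- matrix(0, nrow = C, ncol = L * B)
  for (b in seq_len(B)) {
    v <- mats[[b]]$values[, selected, drop = FALSE]
    X[, (b - 1L) * L + seq_len(nrow(v))] <- t(v)
  }
  list(X = X, len = as.integer(len), L = L, B = B)
}

#' Train the model
#'
#' Implements the full protocol: per-epoch negative subsampling,
#' breakpoint-aware window selection, BCE + Adam with gradient clipping,
#' learning-rate decay on validation plateau, and checkpointing of the
#' model whenever the validation AUPRC (computed every `eval_every` epochs)
#' improves. Validation windows are fixed once so the metric is comparable
#' across epochs.
#'
#' @param model a `contiguard_model` (see [build_model()]).
#' @param store a `feature_store` of *normalized* matrices with labels.
#' @param config a [train_config()].
#' @param quiet suppress per-epoch progress messages.
#' @return List: `model` (best checkpoint by validation AUPRC), `history`
#'   (data.frame of epoch, loss, val_auprc, lr), `best_auprc`,
#'   `final_model`.
#' @export
train_model <- function(model, store, config = train_config(),
                        quiet = TRUE) {
  stopifnot(inherits(store, "feature_store"), !is.null(store$labels))
  cfg <- model$cfg
  selected <- store$catalog$selected
  stopifnot(length(selected) == cfg$in_channels)
  min_len <- min_input_length(cfg)

  ids <- names(store$matrices)
  labels <- store$labels[ids]
  n <- length(ids)
  withr_seed(config$seed)
  n_val <- max(1L, round(config$validation_frac * n))
  if (config$validation_frac == 0) n_val <- 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  if (n_val == 0) stop("empty validation set; increase validation_frac")
  train_idx <- setdiff(seq_len(n), val_idx)

  # fixed validation windows
  val_mats <- lapply(val_idx, function(i) {
    m <- store$matrices[[i]]
    w <- select_window(nrow(m$values), labels[i],
                       store$breakpoints[[ids[i]]], config$window_len,
                       seed = config$seed + i)
    slice_matrix(m, w)
  })
  val_labels <- labels[val_idx]

  opt <- adam_init(model$params)
  lr <- config$lr
  best <- list(auprc = -Inf, model = NULL)
  since_improve <- 0L
  history <- list()

  for (epoch in seq_len(config$epochs)) {
    ep_seed <- config$seed * 1000L + epoch
    tr_labels <- labels[train_idx]
    samp <- make_epoch_sample(tr_labels, config$neg_subsample_frac,
                              ep_seed)
    epoch_ids <- train_idx[samp]
    losses <- c()
    withr_seed(ep_seed + 500000L)
    # bucket same-sized contigs together so batch padding stays small;
    # batch order is then re-shuffled
    sizes <- vapply(store$matrices[epoch_ids], function(m)
      min(nrow(m$values), config$window_len), 0L)
    epoch_ids <- epoch_ids[order(sizes)]
    nb <- ceiling(length(epoch_ids) / config$batch_size)
    batch_order <- sample.int(nb)
    for (bi in batch_order) {
      sel <- epoch_ids[((bi - 1L) * config$batch_size + 1L):
                         min(bi * config$batch_size, length(epoch_ids))]
      mats <- lapply(sel, function(i) {
        m <- store$matrices[[i]]
        w <- select_window(nrow(m$values), labels[i],
                           store$breakpoints[[ids[i]]], config$window_len)
        slice_matrix(m, w)
      })
      bt <- make_batch(mats, selected, min_len)
      fwd <- model_forward(model, bt$X, bt$len, training = TRUE,
                           keep_cache = TRUE)
      bwd <- model_backward(model, fwd, labels[sel])
      grads <- clip_grads(bwd$grads, config$grad_clip_norm,
                          config$grad_clip_value)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params
      opt <- st$opt
      model$state[names(fwd$state_out)] <- fwd$state_out
      losses <- c(losses, bwd$loss)
    }

    val_auprc <- NA_real_
    if (epoch %% config$eval_every == 0L || epoch == config$epochs) {
      val_scores <- predict_matrices(model, val_mats, selected, min_len,
                                     batch_size = config$batch_size)
      val_auprc <- auprc(val_scores, val_labels)
      if (val_auprc > best$auprc) {
        best <- list(auprc = val_auprc, model = model)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
        if (since_improve >= config$plateau_patience) {
          lr <- lr * config$lr_decay
          since_improve <- 0L
        }
      }
    }
    history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                                   val_auprc = val_auprc, lr = lr)
    if (!quiet)
      message(sprintf("epoch %d  loss %.4f  val AUPRC %s  lr %.2g",
                      epoch, mean(losses),
                      ifelse(is.na(val_auprc), "-",
                             sprintf("%.3f", val_auprc)), lr))
  }
  if (is.null(best$model)) best <- list(auprc = NA_real_, model = model)
  list(model = best$model, history = do.call(rbind, history),
       best_auprc = best$auprc, final_model = model)
}

slice_matrix <- function(m, w) {
  rows <- w[1]:min(w[2], nrow(m$values))
  m$values <- m$values[rows, , drop = FALSE]
  m$coverage <- m$coverage[rows]
  m$mask <- m$mask[rows]
  m
}

# score a list of (already windowed) matrices in mini-batches
predict_matrices <- function(model, mats, selected, min_len,
                             batch_size = 200L) {
  scores <- numeric(length(mats))
  nb <- ceiling(length(mats) / batch_size)
  for (bi in seq_len(nb)) {
    sel <- ((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(mats))
    bt <- make_batch(mats[sel], selected, min_len)
    fwd <- model_forward(model, bt$X, bt$len, training = FALSE)
    scores[sel] <- fwd$scores
  }
  scores
}

#' Save / load a model checkpoint
#'
#' A checkpoint is self-contained: weights, moving statistics, model
#' configuration, feature catalog and standardization statistics.
#'
#' @param model a `contiguard_model`.
#' @param path file path.
#' @param catalog,stats the catalog / stats the model was trained with.
#' @return `load_checkpoint` returns a list `model`, `catalog`, `stats`.
#' @export
save_checkpoint <- function(model, path, catalog = NULL, stats = NULL) {
  saveRDS(list(format_version = 1L, model = model, catalog = catalog,
               stats = stats), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(!is.null(ck$format_version), inherits(ck$model,
                                                  "contiguard_model"))
  ck
}
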