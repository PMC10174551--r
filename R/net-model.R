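#' Configuration of the residual misassembly-detection network
#'
#' The network maps a batch of per-position feature windows (batch x length
#' x channels) to one misassembly probability per contig. It consists of an
#' input batch-normalization over the feature channels, an initial
#' batch-normalized convolution, four residual groups of 2/5/5/2 residual
#' blocks whose filter counts double group to group (16 to 128) while the
#' first convolution of groups 2-4 halves the length (stride 2), masked
#' global average pooling over valid positions, a 50-neuron dense layer
#' (ReLU), and a one-neuron sigmoid output. Convolutions are unpadded, so a
#' stride-1 residual block crops the last `2*(K-1)` positions of its input
#' before the element-wise skip addition; a downsampling block passes its
#' input through a kernel-1, stride-2 convolution instead.
#'
#' With the defaults (`in_channels = 14`, `initial_kernel = 10`,
#' `kernel_size = 5`) the model has 562,573 parameters of which 559,441 are
#' trainable (the difference being the moving means and variances of the
#' batch-normalization layers).
#'
#' @param in_channels number of input feature channels.
#' @param initial_filters filters of the initial convolution.
#' @param initial_kernel kernel size of the initial convolution.
#' @param group_blocks residual blocks per group.
#' @param group_filters filters per group (must double group to group).
#' @param kernel_size kernel size of the block convolutions.
#' @param dense_units hidden units of the penultimate dense layer.
#' @param max_input_length longest window the model is meant to score (bp).
#' @param bn_momentum,bn_eps batch-normalization moving-average momentum and
#'   variance epsilon.
#' @return A `model_config`.
#' @export
model_config <- function(in_channels = 14L, initial_filters = 16L,
                         initial_kernel = 10L,
                         group_blocks = c(2L, 5L, 5L, 2L),
                         group_filters = c(16L, 32L, 64L, 128L),
                         kernel_size = 5L, dense_units = 50L,
                         max_input_length = 20000L,
                         bn_momentum = 0.9, bn_eps = 1e-3) {
  stopifnot(length(group_blocks) == length(group_filters),
            length(group_blocks) == 4L,
            all(group_blocks >= 1L), in_channels >= 1L,
            initial_filters == group_filters[1])
  if (!all(group_filters[-1] == 2L * group_filters[-length(group_filters)]))
    stop("group filters must double between consecutive groups")
  structure(list(in_channels = as.integer(in_channels),
                 initial_filters = as.integer(initial_filters),
                 initial_kernel = as.integer(initial_kernel),
                 group_blocks = as.integer(group_blocks),
                 group_filters = as.integer(group_filters),
                 kernel_size = as.integer(kernel_size),
                 dense_units = as.integer(dense_units),
                 max_input_length = as.integer(max_input_length),
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "model_config")
}

# architecture walk: list of layer descriptors in forward order
model_arch <- function(cfg) {
  arch <- list(list(type = "input_bn", id = "in_bn", C = cfg$in_channels))
  arch[[length(arch) + 1L]] <-
    list(type = "conv_bn_relu", id = "conv0", K = cfg$initial_kernel,
         S = 1L, Cin = cfg$in_channels, Cout = cfg$initial_filters)
  Cin <- cfg$initial_filters
  for (g in seq_along(cfg$group_blocks)) {
    Fg <- cfg$group_filters[g]
    for (b in seq_len(cfg$group_blocks[g])) {
      S <- if (b == 1L && g > 1L) 2L else 1L
      arch[[length(arch) + 1L]] <-
        list(type = "block", id = sprintf("g%db%d", g, b),
             K = cfg$kernel_size, S = S, Cin = Cin, F = Fg,
             has_skip = (S == 2L))
      Cin <- Fg
    }
  }
  arch[[length(arch) + 1L]] <- list(type = "pool", C = Cin)
  arch[[length(arch) + 1L]] <-
    list(type = "dense", id = "d1", In = Cin, Out = cfg$dense_units,
         act = "relu")
  arch[[length(arch) + 1L]] <-
    list(type = "dense", id = "d2", In = cfg$dense_units, Out = 1L,
         act = "sigmoid")
  arch
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow = nrow)
}

#' Build (initialize) a model
#'
#' Convolution weights use He initialization, batch-norm scale/shift start
#' at 1/0, and moving statistics at 0/1. Deterministic for a fixed seed.
#'
#' @param cfg a [model_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return A `contiguard_model`: list with `cfg`, `params` (trainable
#'   tensors), `state` (batch-norm moving statistics) and `arch`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  withr_seed(seed)
  arch <- model_arch(cfg)
  params <- list()
  state <- list()
  add_bn <- function(id, C) {
    params[[paste0(id, ".gamma")]] <<- rep(1, C)
    params[[paste0(id, ".beta")]] <<- rep(0, C)
    state[[paste0(id, ".mmean")]] <<- rep(0, C)
    state[[paste0(id, ".mvar")]] <<- rep(1, C)
  }
  add_conv <- function(id, K, Cin, Cout) {
    params[[paste0(id, ".W")]] <<- he_init(Cout, K * Cin, K * Cin)
    params[[paste0(id, ".b")]] <<- rep(0, Cout)
  }
  for (ly in arch) {
    if (ly$type == "input_bn") {
      add_bn(ly$id, ly$C)
    } else if (ly$type == "conv_bn_relu") {
      add_conv(ly$id, ly$K, ly$Cin, ly$Cout)
      add_bn(paste0(ly$id, ".bn"), ly$Cout)
    } else if (ly$type == "block") {
      add_conv(paste0(ly$id, ".c1"), ly$K, ly$Cin, ly$F)
      add_bn(paste0(ly$id, ".bn1"), ly$F)
      add_conv(paste0(ly$id, ".c2"), ly$K, ly$F, ly$F)
      add_bn(paste0(ly$id, ".bn2"), ly$F)
      if (ly$has_skip) add_conv(paste0(ly$id, ".sk"), 1L, ly$Cin, ly$F)
    } else if (ly$type == "dense") {
      params[[paste0(ly$id, ".W")]] <- he_init(ly$Out, ly$In, ly$In)
      params[[paste0(ly$id, ".b")]] <- rep(0, ly$Out)
    }
  }
  structure(list(cfg = cfg, params = params, state = state, arch = arch),
            class = "contiguard_model")
}

#' Count model parameters
#'
#' @param model a `contiguard_model`.
#' @return Named list `total` and `trainable`; the non-trainable remainder
#'   is the batch-normalization moving statistics.
#' @export
count_parameters <- function(model) {
  trainable <- sum(vapply(model$params, length, 0))
  non_trainable <- sum(vapply(model$state, length, 0))
  list(total = trainable + non_trainable, trainable = trainable)
}

#' Minimum input length the network accepts
#'
#' The smallest padded window length for which every convolution still has
#' at least one output position. Shorter contigs are zero-padded up to this
#' length before scoring.
#'
#' @param cfg a [model_config()].
#' @return Integer length in bp.
#' @export
min_input_length <- function(cfg = model_config()) {
  ok <- function(L) {
    len <- L
    len <- conv_len(len, cfg$initial_kernel, 1L)
    if (len < 1L) return(FALSE)
    for (g in seq_along(cfg$group_blocks)) {
      for (b in seq_len(cfg$group_blocks[g])) {
        S <- if (b == 1L && g > 1L) 2L else 1L
        l1 <- conv_len(len, cfg$kernel_size, S)
        len <- conv_len(l1, cfg$kernel_size, 1L)
        if (len < 1L) return(FALSE)
      }
    }
    TRUE
  }
  lo <- 1L; hi <- 4L
  while (!ok(hi)) hi <- hi * 2L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid + 1L
  }
  lo
}

# ---- forward -------------------------------------------------------------

block_forward <- function(X, L, B, len, ly, params, state, cfg, training,
                          state_out) {
  pid <- function(s) paste0(ly$id, ".", s)
  K <- ly$K; S <- ly$S
  cv1 <- conv_forward(X, params[[pid("c1.W")]], params[[pid("c1.b")]],
                      K, S, L, B)
  L1 <- cv1$L_out; len1 <- conv_len(len, K, S)
  cm1 <- col_mask(L1, len1)
  bn1 <- bn_run(cv1$Y, pid("bn1"), params, state, cm1, training, cfg,
                state_out)
  A1 <- relu_forward(bn1$Y)
  cv2 <- conv_forward(A1, params[[pid("c2.W")]], params[[pid("c2.b")]],
                      K, 1L, L1, B)
  L2 <- cv2$L_out; len2 <- conv_len(len1, K, 1L)
  cm2 <- col_mask(L2, len2)
  bn2 <- bn_run(cv2$Y, pid("bn2"), params, state, cm2, training, cfg,
                state_out)
  body <- bn2$Y
  if (ly$has_skip) {
    sk <- conv_forward(X, params[[pid("sk.W")]], params[[pid("sk.b")]],
                       1L, S, L, B)
    skipY <- crop_cols(sk$Y, sk$L_out, L2, B)
    Ls <- sk$L_out
  } else {
    skipY <- crop_cols(X, L, L2, B)
    sk <- NULL; Ls <- L
  }
  Y <- cpp_add_relu_masked(body, skipY, cm2)
  list(Y = Y, L_out = L2, len_out = len2,
       cache = list(cv1 = cv1, bn1 = bn1, A1 = A1, cv2 = cv2, bn2 = bn2,
                    sk = sk, Ls = Ls, cm1 = cm1, cm2 = cm2, L1 = L1,
                    len1 = len1, Y = Y, X = X))
}

# run a BN layer by id, recording updated moving stats in state_out (env)
bn_run <- function(X, id, params, state, cm, training, cfg, state_out) {
  res <- bn_forward(X, params[[paste0(id, ".gamma")]],
                    params[[paste0(id, ".beta")]],
                    state[[paste0(id, ".mmean")]],
                    state[[paste0(id, ".mvar")]],
                    cm, training, eps = cfg$bn_eps,
                    momentum = cfg$bn_momentum)
  if (training && !is.null(state_out)) {
    state_out[[paste0(id, ".mmean")]] <- res$mmean
    state_out[[paste0(id, ".mvar")]] <- res$mvar
  }
  res
}

#' Forward pass
#'
#' @param model a `contiguard_model`.
#' @param X batch matrix `[channels, L * B]` (samples concatenated
#'   column-wise, zero-padded to the common length `L`).
#' @param len integer vector of valid lengths per sample.
#' @param training logical; use batch statistics (TRUE) or moving
#'   statistics (FALSE) in batch normalization.
#' @param keep_cache retain intermediate activations for [model_backward()].
#' @return List with `scores` (numeric vector of probabilities), `z`
#'   (pre-sigmoid), and when requested `cache` and `state_out` (updated
#'   moving statistics).
#' @export
model_forward <- function(model, X, len, training = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$cfg
  B <- length(len)
  stopifnot(ncol(X) %% B == 0L)
  L <- ncol(X) / B
  stopifnot(nrow(X) == cfg$in_channels)
  state_out <- if (training) new.env(parent = emptyenv()) else NULL
  caches <- list()
  lens <- list()

  cm <- col_mask(L, len)
  X <- zero_invalid(X, cm)
  bn_in <- bn_run(X, "in_bn", model$params, model$state, cm, training, cfg,
                  state_out)
  caches$in_bn <- list(bn = bn_in, cm = cm, X = X, L = L)
  H <- bn_in$Y

  cv0 <- conv_forward(H, model$params[["conv0.W"]],
                      model$params[["conv0.b"]], cfg$initial_kernel, 1L,
                      L, B)
  L0 <- cv0$L_out; len0 <- conv_len(len, cfg$initial_kernel, 1L)
  cm0 <- col_mask(L0, len0)
  bn0 <- bn_run(cv0$Y, "conv0.bn", model$params, model$state, cm0,
                training, cfg, state_out)
  A0 <- relu_forward(bn0$Y)
  caches$conv0 <- list(cv = cv0, bn = bn0, A = A0, cm = cm0, L_in = L)
  H <- A0; Lc <- L0; lenc <- len0

  blocks <- Filter(function(a) a$type == "block", model$arch)
  for (ly in blocks) {
    bf <- block_forward(H, Lc, B, lenc, ly, model$params, model$state,
                        cfg, training, state_out)
    caches[[ly$id]] <- c(bf$cache, list(L_in = Lc, len_in = lenc, ly = ly))
    H <- bf$Y; Lc <- bf$L_out; lenc <- bf$len_out
  }

  P <- pool_forward(H, Lc, B, lenc)
  caches$pool <- list(L = Lc, len = lenc, C = nrow(H))

  W1 <- model$params[["d1.W"]]; b1 <- model$params[["d1.b"]]
  Z1 <- W1 %*% P + b1
  A1 <- relu_forward(Z1)
  W2 <- model$params[["d2.W"]]; b2 <- model$params[["d2.b"]]
  z <- as.vector(W2 %*% A1 + b2)
  scores <- sigmoid(z)
  caches$dense <- list(P = P, Z1 = Z1, A1 = A1)

  out <- list(scores = scores, z = z)
  if (keep_cache) {
    out$cache <- caches
    out$B <- B
  }
  if (training) out$state_out <- as.list(state_out)
  out
}

# ---- backward ------------------------------------------------------------

block_backward <- function(dY, cache, params, B, grads) {
  ly <- cache$ly
  pid <- function(s) paste0(ly$id, ".", s)
  dY <- relu_backward(dY, cache$Y)
  d_body <- dY
  d_skip <- dY
  # body: bn2 <- conv2 <- relu1 <- bn1 <- conv1
  bb2 <- bn_backward(d_body, cache$bn2, params[[pid("bn2.gamma")]],
                     cache$cm2)
  grads[[pid("bn2.gamma")]] <- bb2$dgamma
  grads[[pid("bn2.beta")]] <- bb2$dbeta
  cb2 <- conv_backward(bb2$dX, cache$cv2, cache$L1, B)
  grads[[pid("c2.W")]] <- grads[[pid("c2.W")]] + cb2$dW
  grads[[pid("c2.b")]] <- grads[[pid("c2.b")]] + cb2$db
  dA1 <- relu_backward(cb2$dX, cache$A1)
  bb1 <- bn_backward(dA1, cache$bn1, params[[pid("bn1.gamma")]],
                     cache$cm1)
  grads[[pid("bn1.gamma")]] <- bb1$dgamma
  grads[[pid("bn1.beta")]] <- bb1$dbeta
  cb1 <- conv_backward(bb1$dX, cache$cv1, cache$L_in, B)
  grads[[pid("c1.W")]] <- grads[[pid("c1.W")]] + cb1$dW
  grads[[pid("c1.b")]] <- grads[[pid("c1.b")]] + cb1$db
  dX <- cb1$dX
  # skip path
  dS <- uncrop_cols(d_skip, cache$Ls, ncol(d_skip) / B, B, nrow(d_skip))
  if (ly$has_skip) {
    cbs <- conv_backward(dS, cache$sk, cache$L_in, B)
    grads[[pid("sk.W")]] <- grads[[pid("sk.W")]] + cbs$dW
    grads[[pid("sk.b")]] <- grads[[pid("sk.b")]] + cbs$db
    dX <- dX + cbs$dX
  } else {
    dX <- dX + dS
  }
  list(dX = dX, grads = grads)
}

#' Backward pass (binary cross-entropy loss)
#'
#' @param model a `contiguard_model`.
#' @param fwd output of [model_forward()] with `keep_cache = TRUE` and
#'   `training = TRUE`.
#' @param labels 0/1 vector, one per sample.
#' @return List with `grads` (named like `model$params`) and `loss` (mean
#'   BCE over the batch).
#' @export
model_backward <- function(model, fwd, labels) {
  caches <- fwd$cache
  B <- fwd$B
  p <- fwd$scores
  eps <- 1e-12
  loss <- -mean(labels * log(p + eps) + (1 - labels) * log(1 - p + eps))
  grads <- lapply(model$params, function(x) x * 0)
  cfg <- model$cfg

  dz <- (p - labels) / B                       # d loss / d pre-sigmoid
  dc <- caches$dense
  grads[["d2.W"]] <- matrix(dz, nrow = 1) %*% t(dc$A1)
  grads[["d2.b"]] <- sum(dz)
  dA1 <- t(model$params[["d2.W"]]) %*% matrix(dz, nrow = 1)
  dZ1 <- relu_backward(dA1, dc$A1)
  grads[["d1.W"]] <- dZ1 %*% t(dc$P)
  grads[["d1.b"]] <- rowSums(dZ1)
  dP <- t(model$params[["d1.W"]]) %*% dZ1

  pc <- caches$pool
  dH <- pool_backward(dP, pc$L, B, pc$len, pc$C)

  blocks <- rev(Filter(function(a) a$type == "block", model$arch))
  for (ly in blocks) {
    bb <- block_backward(dH, caches[[ly$id]], model$params, B, grads)
    dH <- bb$dX
    grads <- bb$grads
  }

  c0 <- caches$conv0
  dA0 <- relu_backward(dH, c0$A)
  bb0 <- bn_backward(dA0, c0$bn, model$params[["conv0.bn.gamma"]], c0$cm)
  grads[["conv0.bn.gamma"]] <- bb0$dgamma
  grads[["conv0.bn.beta"]] <- bb0$dbeta
  cb0 <- conv_backward(bb0$dX, c0$cv, c0$L_in, B)
  grads[["conv0.W"]] <- grads[["conv0.W"]] + cb0$dW
  grads[["conv0.b"]] <- grads[["conv0.b"]] + cb0$db

  ib <- caches$in_bn
  bbi <- bn_backward(cb0$dX, ib$bn, model$params[["in_bn.gamma"]], ib$cm)
  grads[["in_bn.gamma"]] <- bbi$dgamma
  grads[["in_bn.beta"]] <- bbi$dbeta

  list(grads = grads, loss = loss)
}
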