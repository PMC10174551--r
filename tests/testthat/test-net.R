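test_that("the default architecture reproduces the published totals", {
  m <- build_model(model_config(), seed = 1)
  pc <- count_parameters(m)
  expect_identical(pc$total, 562573)
  expect_identical(pc$trainable, 559441)
})

test_that("parameter counts are a pure function of the configuration", {
  a <- count_parameters(build_model(model_config(), seed = 1))
  b <- count_parameters(build_model(model_config(), seed = 999))
  expect_identical(a, b)
  tiny <- count_parameters(build_model(tiny_config(), seed = 1))
  expect_lt(tiny$total, 10000)
  expect_identical(count_parameters(build_model(tiny_config(), seed = 2)),
                   tiny)
})

test_that("configuration invariants are enforced", {
  expect_error(model_config(group_filters = c(16, 32, 64, 100)),
               "double")
  expect_error(model_config(group_blocks = c(2, 5, 5)), class = "error")
})

test_that("unpadded convolution lengths follow the cropping rule", {
  K <- 5L
  for (L in c(100L, 333L)) {
    # stride-1 block shortens by 2*(K-1)
    expect_equal(conv_len(conv_len(L, K, 1L), K, 1L), L - 2L * (K - 1L))
  }
  # stride-2 block: skip path (K = 1, S = 2) is at least as long as the
  # body, so cropping the skip to the body length is always possible
  for (L in 100:120) {
    body <- conv_len(conv_len(L, K, 2L), K, 1L)
    skip <- conv_len(L, 1L, 2L)
    expect_gte(skip, body)
  }
})

test_that("masked global pooling averages only valid positions", {
  # hand case: channel values 1, 2, 3 with two padded tails -> mean 2
  X <- matrix(c(1, 2, 3, 99, 99), nrow = 1)
  expect_equal(as.vector(pool_forward(X, 5L, 1L, 3L)), 2)
  # constant input pools to the constant under any padding
  C <- 4L
  X2 <- cbind(matrix(7, C, 6), matrix(0, C, 4))
  expect_equal(as.vector(pool_forward(X2, 10L, 1L, 6L)), rep(7, C))
})

test_that("scores are probabilities and deterministic at inference", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 3)
  set.seed(11)
  L <- 120L; B <- 3L
  len <- c(120L, 90L, 60L)
  X <- matrix(rnorm(cfg$in_channels * L * B), nrow = cfg$in_channels)
  f1 <- model_forward(m, X, len)
  f2 <- model_forward(m, X, len)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(f1$scores > 0 & f1$scores < 1))
  expect_length(f1$scores, B)
  # identical rows duplicated in a batch give identical scores
  X2 <- cbind(X[, 1:L], X[, 1:L])
  f3 <- model_forward(m, X2, c(120L, 120L))
  expect_equal(f3$scores[1], f3$scores[2], tolerance = 1e-12)
})

test_that("padding a contig to different batch lengths keeps its score", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 5)
  set.seed(13)
  L0 <- 100L
  V <- matrix(rnorm(cfg$in_channels * L0), nrow = cfg$in_channels)
  score_at <- function(Lpad) {
    X <- cbind(V, matrix(0, cfg$in_channels, Lpad - L0))
    model_forward(m, X, L0)$scores
  }
  s <- vapply(c(100L, 130L, 200L, 357L), score_at, 0)
  expect_true(all(abs(s - s[1]) < 1e-6))
})

test_that("variable-length batches work across the full model", {
  m <- warm_model(build_model(model_config(), seed = 2))
  min_len <- min_input_length(model_config())
  expect_equal(min_len, 366L)
  set.seed(17)
  lens <- c(400L, 500L, 371L)
  L <- max(lens); B <- 3L
  X <- matrix(0, 14, L * B)
  for (b in seq_len(B)) {
    X[, (b - 1L) * L + seq_len(lens[b])] <-
      rnorm(14 * lens[b])
  }
  f <- model_forward(m, X, lens)
  expect_length(f$scores, 3L)
  expect_true(all(f$scores > 0 & f$scores < 1))
  expect_error(model_forward(m, X[1:13, , drop = FALSE], lens))
})

test_that("analytic gradients match numeric differentiation", {
  cfg <- tiny_config()
  m <- build_model(cfg, seed = 7)
  set.seed(42)
  L <- 80L; B <- 2L
  len <- c(80L, 64L)
  X <- matrix(rnorm(cfg$in_channels * L * B), nrow = cfg$in_channels)
  y <- c(1, 0)
  fwd <- model_forward(m, X, len, training = TRUE, keep_cache = TRUE)
  bwd <- model_backward(m, fwd, y)
  lossfn <- function(mm) {
    p <- model_forward(mm, X, len, training = TRUE)$scores
    -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12))
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    g <- bwd$grads[[nm]]
    expect_true(all(is.finite(g)), info = nm)
    idx <- sample(length(g), min(2, length(g)))
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
      mn <- m; mn$params[[nm]][i] <- mn$params[[nm]][i] - eps
      num <- (lossfn(mp) - lossfn(mn)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])),
                1e-3)
    }
  }
})

test_that("checkpoints restore weights, catalog and statistics exactly", {
  m <- build_model(tiny_config(), seed = 9)
  cat23 <- feature_catalog()
  stats <- structure(list(mean = c(x = 1), sd = c(x = 2), channels = "x"),
                     class = "feature_stats")
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path, catalog = cat23, stats = stats)
  ck <- load_checkpoint(path)
  expect_identical(ck$model$params, m$params)
  expect_identical(ck$model$state, m$state)
  expect_identical(ck$catalog$selected, cat23$selected)
  expect_identical(ck$stats$mean, stats$mean)
})
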