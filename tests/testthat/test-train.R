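test_that("epoch composition keeps all positives and a negative fraction", {
  labels <- c(rep(1, 100), rep(0, 1000))
  idx <- make_epoch_sample(labels, 0.1, epoch_seed = 1)
  expect_length(idx, 200L)
  expect_equal(sum(labels[idx] == 1), 100L)
  expect_equal(sum(labels[idx] == 0), 100L)
  # realized positive fraction follows P / (P + round(f N)) exactly
  for (f in c(0.05, 0.25, 0.6)) {
    i2 <- make_epoch_sample(labels, f, epoch_seed = 2)
    expect_equal(mean(labels[i2]), 100 / (100 + round(f * 1000)))
  }
  # fresh negatives each epoch, positives always identical
  a <- make_epoch_sample(labels, 0.1, epoch_seed = 10)
  b <- make_epoch_sample(labels, 0.1, epoch_seed = 11)
  expect_setequal(intersect(a, which(labels == 1)),
                  intersect(b, which(labels == 1)))
  expect_false(setequal(setdiff(a, which(labels == 1)),
                        setdiff(b, which(labels == 1))))
  expect_length(make_epoch_sample(labels, 1, epoch_seed = 3), 1100L)
  expect_identical(sort(make_epoch_sample(labels, 0.1, 42)),
                   sort(make_epoch_sample(labels, 0.1, 42)))
})

test_that("window selection pads short contigs and tracks breakpoints", {
  expect_equal(select_window(8000, 0, window_len = 20000), c(1L, 8000L))
  expect_equal(select_window(8000, 1, breakpoints = 5000L,
                             window_len = 20000), c(1L, 8000L))
  # every window on a long misassembled contig contains the junction
  for (s in 1:200) {
    w <- select_window(60000, 1, breakpoints = 30000L,
                       window_len = 20000, seed = s)
    expect_equal(w[2] - w[1] + 1L, 20000L)
    expect_true(w[1] >= 1 && w[2] <= 60000)
    expect_true(w[1] <= 30000 && w[2] >= 30001)
  }
  expect_error(select_window(60000, 1, breakpoints = integer(0)),
               "breakpoints")
})

test_that("clean-contig window starts are uniform over feasible starts", {
  starts <- vapply(1:10000, function(s)
    select_window(60000, 0, window_len = 20000, seed = s)[1], 0L)
  expect_true(all(starts >= 1 & starts <= 40001))
  # mean of Uniform(1, 40001) is 20001, sd/sqrt(n) ~ 115
  expect_lt(abs(mean(starts) - 20001), 600)
})

test_that("gradient clipping bounds norms and values", {
  g <- list(a = matrix(c(3, 4), 1), b = c(-10, 0.2))
  cl <- clip_grads(g, clip_norm = 1, clip_value = 0.5)
  expect_lte(sqrt(sum(cl$a^2)), 1 + 1e-12)
  expect_true(all(abs(cl$b) <= 0.5))
  # small gradients pass through untouched
  g2 <- list(a = matrix(c(0.1, 0.2), 1))
  expect_identical(clip_grads(g2, 1, 0.5)$a, g2$a)
})

# synthetic feature store with a planted signature: positives carry a
# coverage-drop-like dip in channel 1 at the contig center
toy_store <- function(n = 40L, len = 60L, seed = 1L, noise = 0.3) {
  set.seed(seed)
  selected <- c("f1", "f2", "f3")
  labels <- rep(c(0L, 1L), length.out = n)
  mats <- lapply(seq_len(n), function(i) {
    v <- matrix(rnorm(len * 3, sd = noise), nrow = len,
                dimnames = list(NULL, selected))
    if (labels[i] == 1) {
      at <- (len %/% 2 - 5):(len %/% 2 + 5)
      v[at, 1] <- v[at, 1] - 2
      v[at, 2] <- v[at, 2] + 2
    }
    structure(list(contig_id = paste0("t", i), values = v,
                   coverage = rep(5L, len), mask = rep(TRUE, len),
                   normalized = TRUE),
              class = "feature_matrix")
  })
  names(mats) <- paste0("t", seq_len(n))
  names(labels) <- names(mats)
  cat3 <- feature_catalog()
  cat3$selected <- selected
  bps <- lapply(labels, function(l) if (l == 1) len %/% 2L else integer(0))
  feature_store(mats, labels = labels, catalog = cat3, breakpoints = bps)
}

test_that("the model memorizes a small separable dataset", {
  store <- toy_store(n = 40, seed = 2)
  cfg <- tiny_config(3L)
  model <- build_model(cfg, seed = 3)
  # a learning rate matched to the reduced network; this is a capacity
  # check (overfit a separable set), not a protocol run
  tc <- train_config(epochs = 150, batch_size = 20, lr = 1e-3,
                     neg_subsample_frac = 1, validation_frac = 0.2,
                     eval_every = 50, window_len = cfg$max_input_length,
                     seed = 5)
  fit <- train_model(model, store, tc)
  hist <- fit$history
  # loss trends down early and reaches memorization late
  expect_lt(hist$loss[5], hist$loss[1])
  expect_lt(tail(hist$loss, 1), 0.05)
  # model selection returns the running-best validation AUPRC
  expect_equal(fit$best_auprc, max(hist$val_auprc, na.rm = TRUE))
  evals <- sum(!is.na(hist$val_auprc))
  expect_lte(evals, floor(tc$epochs / tc$eval_every) + 1L)
})

test_that("training is reproducible for a fixed seed", {
  store <- toy_store(n = 20, seed = 7)
  cfg <- tiny_config(3L)
  tc <- train_config(epochs = 2, batch_size = 10, neg_subsample_frac = 1,
                     validation_frac = 0.2, eval_every = 2,
                     window_len = cfg$max_input_length, seed = 9)
  f1 <- train_model(build_model(cfg, seed = 4), store, tc)
  f2 <- train_model(build_model(cfg, seed = 4), store, tc)
  expect_identical(f1$final_model$params, f2$final_model$params)
  expect_identical(f1$history, f2$history)
})
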