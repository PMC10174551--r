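test_that("contig chunking follows the stride rule and covers everything", {
  expect_equal(chunk_contig(20000), cbind(start = 1L, end = 20000L))
  expect_equal(chunk_contig(500), cbind(start = 1L, end = 500L))
  ch <- chunk_contig(39500, 20000, 500)
  expect_equal(ch, cbind(start = c(1L, 19501L), end = c(20000L, 39500L)))
  set.seed(3)
  for (L in sample(1:100000, 1000)) {
    ch <- chunk_contig(L, 20000, 500)
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(ch))) covered[ch[i, 1]:ch[i, 2]] <- TRUE
    expect_true(all(covered))
    expect_true(all(ch[, 2] - ch[, 1] + 1L <= 20000L))
    if (L > 20000) expect_true(all(ch[, 2] - ch[, 1] + 1L == 20000L))
  }
})

test_that("contig scores aggregate chunk scores by maximum", {
  cfg <- tiny_config(3L)
  model <- build_model(cfg, seed = 21)
  set.seed(22)
  len <- 1300L
  selected <- c("f1", "f2", "f3")
  v <- matrix(rnorm(len * 3), nrow = len,
              dimnames = list(NULL, selected))
  fm <- structure(list(contig_id = "long", values = v,
                       coverage = rep(3L, len), mask = rep(TRUE, len)),
                  class = "feature_matrix")
  cat3 <- feature_catalog(); cat3$selected <- selected
  store <- feature_store(list(long = fm), catalog = cat3)
  icfg <- inference_config(window_len = 500L, chunk_overlap = 100L)
  pr <- predict_contigs(model, store, config = icfg)
  expect_equal(pr$score, max(pr$chunk_scores[[1]]))
  expect_gt(pr$n_chunks, 1L)
  # direct single-window forward agrees with a single-chunk prediction
  short <- structure(list(contig_id = "s", values = v[1:400, ],
                          coverage = rep(3L, 400), mask = rep(TRUE, 400)),
                     class = "feature_matrix")
  store2 <- feature_store(list(s = short), catalog = cat3)
  pr2 <- predict_contigs(model, store2, config = icfg)
  bt <- contiguard:::make_batch(list(short), selected,
                                min_input_length(cfg))
  direct <- model_forward(model, bt$X, bt$len)$scores
  expect_equal(pr2$score, direct, tolerance = 1e-12)
  expect_error(predict_contigs(model, store2, contig_ids = "missing"),
               "not in store")
  # a finer stride scores a superset of windows: max can only grow
  icfg2 <- inference_config(window_len = 500L, chunk_overlap = 400L)
  pr3 <- predict_contigs(model, store, config = icfg2)
  sub <- vapply(pr$chunk_scores[[1]],
                function(s) any(abs(pr3$chunk_scores[[1]] - s) < 1e-9),
                TRUE)
  expect_true(all(sub))
  expect_gte(pr3$score + 1e-9, pr$score)
})

test_that("AUPRC and AUROC match brute-force threshold enumeration", {
  # 4-point hand case
  sc <- c(0.9, 0.8, 0.3, 0.1); lab <- c(1, 0, 1, 0)
  expect_equal(auprc(sc, lab), brute_force_auprc(sc, lab))
  expect_equal(auprc(sc, lab), 1 / 2 * 1 + 0 + 1 / 2 * (2 / 3) + 0)
  # perfect separation
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # random draws with ties, cross-checked against the oracle and pROC
  for (s in 1:40) {
    set.seed(s)
    n <- sample(4:12, 1)
    lab <- sample(0:1, n, replace = TRUE)
    if (all(lab == 0)) lab[1] <- 1
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(auprc(sc, lab), brute_force_auprc(sc, lab),
                 tolerance = 1e-12)
    if (length(unique(lab)) == 2) {
      proc_auc <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                                 direction = "<")))
      expect_equal(auroc(sc, lab), proc_auc, tolerance = 1e-9)
    }
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_true(is.na(evaluate_scores(c(0.1, 0.2), c(1, 1))$auroc))
})

test_that("uninformative scores give an AUPRC equal to the prevalence", {
  set.seed(7)
  n <- 100000
  lab <- rbinom(n, 1, 0.1)
  sc <- runif(n)
  expect_lt(abs(auprc(sc, lab) - 0.1), 0.01)
})

test_that("N50 and assembly reports match their definitions", {
  expect_equal(n50(c(2, 3, 4, 5, 6)), 5)
  expect_equal(n50(c(2, 3, 4, 5, 6)), brute_force_n50(c(2, 3, 4, 5, 6)))
  set.seed(9)
  for (i in 1:20) {
    lens <- sample(1:5000, sample(2:50, 1))
    v <- n50(lens)
    expect_equal(v, brute_force_n50(lens))
    expect_true(v %in% lens)
    expect_gte(sum(lens[lens >= v]), sum(lens) / 2)
  }
  rep1 <- assembly_report(c(100, 300), labels = c(1, 0))
  expect_equal(rep1$misassemblies_length, 0.25)
  expect_equal(rep1$misassembly_rate, 0.5)
  expect_equal(rep1$total_bases, 400)
})

test_that("score filtering discards flagged contigs and reports both sets", {
  lens <- c(2, 3, 4, 5, 6) * 100
  scores <- c(0.95, 0.1, 0.85, 0.2, 0.3)
  labs <- c(1, 0, 1, 0, 0)
  res <- filter_assembly(lens, scores, 0.8, labels = labs)
  expect_equal(sum(res$kept), 3L)
  expect_equal(res$after$misassembly_rate, 0)
  expect_lt(res$after$misassembly_rate, res$before$misassembly_rate)
  # all scores under threshold: identity
  res2 <- filter_assembly(lens, rep(0.5, 5), 0.8, labels = labs)
  expect_true(all(res2$kept))
  expect_equal(res2$after$n50, res2$before$n50)
  # threshold 1 can never discard (scores are probabilities)
  expect_true(all(filter_assembly(lens, scores, 1 - 1e-9)$kept))
})

test_that("misassembly-rate estimates count strict threshold exceedances", {
  expect_equal(estimate_misassembly_rate(c(0.9, 0.95, 0.1, 0.2), 0.8), 0.5)
  expect_equal(estimate_misassembly_rate(rep(0, 5), 0.8), 0)
  expect_equal(estimate_misassembly_rate(c(0.4, 0.5), 0), 1)
  expect_error(estimate_misassembly_rate(numeric(0)), "no scores")
})

test_that("assembly ranking is monotone-invariant and correlates", {
  truth <- c(a = 0.01, b = 0.05, c = 0.10, d = 0.30)
  r1 <- rank_assemblies(truth * 1.5, true_rates = truth)
  expect_equal(r1$spearman, 1)
  expect_equal(r1$ranking, c("a", "b", "c", "d"))
  r2 <- rank_assemblies(rev(unname(truth)), true_rates = unname(truth))
  expect_equal(r2$spearman, -1)
  expect_error(rank_assemblies(c(0.1, 0.2), true_rates = c(0.1, 0.2, 0.3)),
               "length")
  expect_error(rank_assemblies(0.5), class = "error")
})

test_that("the insert-size guard excludes out-of-range datasets loudly", {
  pass_prof <- list(q05 = 150, q50 = 250, q95 = 400)
  expect_equal(insert_size_guard(pass_prof), "pass")
  expect_warning(dec <- insert_size_guard(list(q05 = 150, q50 = 300,
                                               q95 = 600)),
                 "less accurate")
  expect_equal(dec, "exclude")
  expect_equal(insert_size_guard(list(q05 = 117, q50 = 300, q95 = 493)),
               "pass")
  expect_warning(insert_size_guard(list(q05 = 100, q50 = 300, q95 = 400)))
})
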