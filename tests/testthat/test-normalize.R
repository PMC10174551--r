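make_norm_fixture <- function(seeds = c(301, 302, 303)) {
  mats <- lapply(seeds, function(s) {
    inst <- random_pileup_instance(s)
    compute_pileup(inst$contig, inst$al)
  })
  names(mats) <- paste0("c", seq_along(mats))
  mats
}

test_that("fit-then-apply standardization is centered and unit scaled", {
  mats <- make_norm_fixture()
  cat23 <- feature_catalog()
  stats <- suppressWarnings(fit_normalization(mats, cat23))
  norm <- lapply(mats, apply_normalization, stats = stats, catalog = cat23)
  # recompute moments over covered positions of the standardized channels
  chans <- setdiff(numeric_channels(cat23),
                   names(which(stats$sd == 1 & stats$mean == 0)))
  for (cn in chans) {
    xs <- unlist(lapply(seq_along(norm), function(i)
      norm[[i]]$values[mats[[i]]$mask, cn]))
    raw <- unlist(lapply(mats, function(m) m$values[m$mask, cn]))
    xs <- xs[!is.na(raw)]
    if (stats$sd[cn] == 1 && all(raw == raw[1], na.rm = TRUE)) next
    expect_lt(abs(mean(xs)), 1e-6)
    expect_lt(abs(sd(xs) - 1), 1e-6)
  }
})

test_that("count channels are coverage fractions in [0, 1]", {
  mats <- make_norm_fixture(c(311, 312))
  cat23 <- feature_catalog()
  stats <- suppressWarnings(fit_normalization(mats, cat23))
  for (m in mats) {
    nm <- apply_normalization(m, stats, cat23)
    cc <- nm$values[, count_channels(cat23)]
    expect_true(all(cc >= 0 & cc <= 1))
    # spot check the definition: proper fraction at a covered position
    p <- which(m$mask)[1]
    expect_equal(nm$values[p, "num_proper"],
                 m$values[p, "num_proper"] / m$values[p, "coverage"])
  }
})

test_that("zero-coverage rows become all-zero after preprocessing", {
  mats <- make_norm_fixture(c(321))
  cat23 <- feature_catalog()
  stats <- suppressWarnings(fit_normalization(mats, cat23))
  m <- mats[[1]]
  if (!any(!m$mask)) {
    # force an uncovered stretch
    m$values <- rbind(m$values, m$values)
    m$coverage <- c(m$coverage, rep(0L, nrow(mats[[1]]$values)))
    m$values[seq(nrow(m$values) / 2 + 1, nrow(m$values)), "coverage"] <- 0
    m$mask <- m$coverage > 0
  }
  nm <- apply_normalization(m, stats, cat23)
  expect_true(all(nm$values[!m$mask, ] == 0))
})

test_that("constant channels standardize to zero with a warning", {
  mats <- make_norm_fixture(c(331, 332))
  # force a constant mapping quality so its statistics are degenerate
  mats <- lapply(mats, function(m) {
    m$values[m$mask, c("min_mapq", "mean_mapq")] <- 42
    m$values[m$mask, "stdev_mapq"] <- 0
    m
  })
  expect_warning(stats <- fit_normalization(mats, feature_catalog()),
                 "zero-variance")
  expect_equal(unname(stats$sd["mean_mapq"]), 1)
  nm <- apply_normalization(mats[[1]], stats, feature_catalog())
  expect_true(all(nm$values[mats[[1]]$mask, "mean_mapq"] == 0))
})

test_that("statistics serialize and reload to a bitwise-equal transform", {
  mats <- make_norm_fixture(c(341, 342))
  cat23 <- feature_catalog()
  stats <- suppressWarnings(fit_normalization(mats, cat23))
  path <- tempfile(fileext = ".rds")
  write_feature_stats(stats, path)
  stats2 <- read_feature_stats(path)
  expect_identical(stats2$mean, stats$mean)
  expect_identical(stats2$sd, stats$sd)
  a <- apply_normalization(mats[[1]], stats, cat23)
  b <- apply_normalization(mats[[1]], stats2, cat23)
  expect_identical(a$values, b$values)
})

test_that("duplicating every read leaves coverage-normalized counts fixed", {
  inst <- random_pileup_instance(351)
  al2 <- data.table::copy(inst$al)
  al2$qname <- paste0(al2$qname, "_dup")
  doubled <- data.table::rbindlist(list(inst$al, al2))
  m1 <- compute_pileup(inst$contig, inst$al)
  m2 <- compute_pileup(inst$contig, doubled)
  cat23 <- feature_catalog()
  stats <- suppressWarnings(fit_normalization(list(m1), cat23))
  n1 <- apply_normalization(m1, stats, cat23)
  n2 <- apply_normalization(m2, stats, cat23)
  cc <- count_channels(cat23)
  expect_equal(n1$values[, cc], n2$values[, cc], tolerance = 1e-12)
})

test_that("feature store round-trips and slices by contig and window", {
  mats <- make_norm_fixture(c(361, 362))
  labels <- c(c1 = 0L, c2 = 1L)
  store <- feature_store(mats, labels = labels,
                         breakpoints = list(c1 = integer(0), c2 = 50L))
  path <- tempfile(fileext = ".rds")
  feature_store_write(store, path)
  back <- feature_store_read(path)
  expect_identical(back$matrices$c1$values, mats$c1$values)
  expect_identical(back$labels, labels)
  win <- feature_store_read(path, contig_ids = "c2", window = c(100, 199))
  expect_equal(nrow(win$matrices$c2$values), 100L)
  expect_identical(win$matrices$c2$values,
                   mats$c2$values[100:199, ])
  expect_error(feature_store_read(path, contig_ids = "nope"),
               "not in store")
  sl <- store_window(store, "c1", c(10, 29))
  expect_identical(sl$values, mats$c1$values[10:29, ])
})
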