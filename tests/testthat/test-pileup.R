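test_that("pileup matches the brute-force per-read oracle", {
  for (s in 1:25) {
    inst <- random_pileup_instance(1000 + s)
    fm <- compute_pileup(inst$contig, inst$al)
    bf <- brute_force_pileup(inst$contig, inst$al)
    v <- fm$values
    expect_equal(unname(v[, "coverage"]), as.numeric(bf$coverage))
    for (b in c("A", "C", "G", "T"))
      expect_equal(unname(v[, paste0("num_query_", b)]),
                   as.numeric(bf$bases[, b]))
    expect_equal(unname(v[, "num_SNPs"]), as.numeric(bf$num_SNPs))
    expect_equal(unname(v[, "num_proper"]), as.numeric(bf$num_proper))
    expect_equal(unname(v[, "num_orphan"]), as.numeric(bf$num_orphan))
    expect_equal(unname(v[, "num_proper_SNP"]),
                 as.numeric(bf$num_proper_SNP))
    expect_equal(unname(v[, "num_discordant"]),
                 as.numeric(bf$num_discordant))
    expect_equal(unname(v[, "num_pairs"]), as.numeric(bf$num_pairs))
    covered <- bf$coverage > 0
    expect_equal(unname(v[covered, "mean_mapq"]),
                 vapply(bf$mapq[covered], mean, 0))
    expect_equal(unname(v[covered, "min_al_score"]),
                 vapply(bf$al_score[covered], min, 0))
    expect_equal(unname(v[covered, "stdev_mapq"]),
                 vapply(bf$mapq[covered], sd_or_zero, 0))
    expect_equal(unname(v[covered, "stdev_al_score"]),
                 vapply(bf$al_score[covered], sd_or_zero, 0))
    ins_cov <- lengths(bf$insert) > 0
    expect_equal(unname(v[ins_cov, "mean_insert_size"]),
                 vapply(bf$insert[ins_cov], mean, 0))
  }
})

test_that("two overlapping reads produce the textbook coverage profile", {
  contig <- strrep("A", 15)
  al <- data.table::data.table(
    qname = c("r1", "r2"), mate = 1L, contig_id = "c",
    pos = c(1L, 6L), strand = "+", seq = strrep("A", 10), qlen = 10L,
    mate_pos = 1L, nm_pos = list(integer(0), integer(0)),
    n_mismatch = 0L, mapq = 42L, al_score = 0,
    isize = NA_integer_, is_proper = FALSE, is_orphan = TRUE,
    is_discordant = FALSE)
  cov <- compute_pileup(contig, al)$values[, "coverage"]
  expect_equal(unname(cov), c(rep(1, 5), rep(2, 5), rep(1, 5)))
})

test_that("count channels are bounded by coverage and partition it", {
  inst <- random_pileup_instance(77)
  v <- compute_pileup(inst$contig, inst$al)$values
  cov <- v[, "coverage"]
  base_sum <- rowSums(v[, paste0("num_query_", c("A", "C", "G", "T"))])
  expect_equal(unname(base_sum), unname(cov))
  expect_true(all(v[, "num_proper_SNP"] <= v[, "num_SNPs"]))
  expect_true(all(v[, "num_SNPs"] <= cov))
  expect_equal(unname(v[, "num_orphan"] + v[, "num_pairs"]), unname(cov))
})

test_that("uncovered positions have zero counts and masked statistics", {
  contig <- strrep("ACGT", 25)
  al <- compute_pileup(contig,
                       random_pileup_instance(5)$al[0, ])
  expect_true(all(al$values[, "coverage"] == 0))
  expect_true(all(!al$mask))
  expect_true(all(is.na(al$values[, "mean_mapq"])))
  expect_true(all(al$values[, "num_SNPs"] == 0))
})

test_that("coverage subsampling caps the mean and drops mates together", {
  inst <- random_pileup_instance(123)
  al <- inst$al
  L <- nchar(inst$contig)
  # inflate to ~40x coverage by replicating reads under fresh pair names
  mean_cov <- function(a) sum(a$qlen) / L
  reps <- ceiling(40 / mean_cov(al))
  big <- data.table::rbindlist(lapply(seq_len(reps), function(k) {
    x <- data.table::copy(al)
    x$qname <- paste0(x$qname, "_", k)
    x
  }))
  data.table::setattr(big, "contig_len", L)
  expect_gt(mean_cov(big), 20)
  sub <- subsample_to_coverage(big, L, max_mean_cov = 20, seed = 3)
  expect_lte(mean_cov(sub), 20)
  expect_gt(mean_cov(sub), 18)
  expect_true(all(table(sub$qname) == table(big$qname)[names(table(sub$qname))]))
  sub2 <- subsample_to_coverage(big, L, max_mean_cov = 20, seed = 3)
  expect_identical(sub$qname, sub2$qname)
  # low-coverage input passes through unchanged
  expect_identical(subsample_to_coverage(al, L, 1e6, seed = 1), al)
  # subsampling never increases per-position coverage
  cov_big <- compute_pileup(inst$contig, big)$values[, "coverage"]
  cov_sub <- compute_pileup(inst$contig, sub)$values[, "coverage"]
  expect_true(all(cov_sub <= cov_big))
})

test_that("the insert-size profile summarizes proper pairs and gates", {
  mkal <- function(ins) {
    n <- length(ins)
    data.table::data.table(
      qname = paste0("p", seq_len(n)), mate = 1L, contig_id = "c",
      pos = 1L, strand = "+", seq = "ACGT", qlen = 4L, mate_pos = 1L,
      nm_pos = list(integer(0)), n_mismatch = 0L, mapq = 42L,
      al_score = 0, isize = as.integer(ins), is_proper = TRUE,
      is_orphan = FALSE, is_discordant = FALSE)
  }
  set.seed(1)
  pr <- insert_size_profile(mkal(round(rnorm(2000, 270, 50))))
  expect_true(pr$pass)
  expect_gt(pr$q05, 117); expect_lt(pr$q95, 493)
  expect_false(insert_size_profile(mkal(rep(600, 10)))$pass)
  expect_true(insert_size_profile(mkal(rep(300, 10)))$pass)
  pr117 <- insert_size_profile(mkal(rep(117, 10)))
  expect_true(pr117$pass)  # closed interval at the boundary
  empty <- mkal(300)[0, ]
  expect_error(insert_size_profile(empty), "undefined|no proper")
})

test_that("local sequence entropy and GC respond to composition", {
  v1 <- compute_pileup(strrep("A", 100),
                       random_pileup_instance(9)$al[0, ])$values
  expect_true(all(v1[, "seq_window_entropy"] == 0))
  expect_true(all(v1[, "seq_window_gc"] == 0))
  # a 48 bp window on a perfectly periodic sequence is exactly balanced
  v2 <- compute_pileup(strrep("ACGT", 50),
                       random_pileup_instance(9)$al[0, ],
                       window = 48L)$values
  expect_equal(unname(v2[50, "seq_window_entropy"]), 2, tolerance = 1e-9)
  expect_equal(unname(v2[50, "seq_window_gc"]), 0.5, tolerance = 1e-9)
})
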