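#' Simulate a labeled contig dataset with aligned reads and features
#'
#' The desk-scale analogue of a full community-simulation / assembly /
#' alignment / truth-labeling pipeline. A pool of random reference genomes
#' is generated; each contig is either a clean substring of one genome or
#' carries an injected misassembly (relocation, inversion, translocation or
#' interspecies translocation) with known breakpoints. Paired-end reads are
#' simulated from the *source genome regions* of each contig (the regions
#' extended by the insert span), so reads crossing a misassembly junction
#' naturally disagree with the chimeric contig sequence: mismatches
#' accumulate beyond the junction, pairs become discordant or orphaned, and
#' coverage structure changes — the signal the model learns.
#'
#' @param n_contigs number of contigs.
#' @param misassembled_frac fraction of contigs carrying a misassembly.
#' @param coverage target mean per-contig read coverage.
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd insert-size distribution (bp).
#' @param profile an [error_profile()].
#' @param contig_len_range `c(min, max)` of contig lengths (uniform).
#' @param n_genomes size of the reference genome pool.
#' @param genome_len length of each reference genome (bp).
#' @param sigma lognormal abundance spread of the community (affects only
#'   the recorded community profile; per-contig read depth is held at
#'   `coverage` to emulate post-assembly alignment depth).
#' @param max_mean_cov coverage ceiling applied by read subsampling.
#' @param seed integer RNG seed.
#' @param normalize fit standardization statistics on the dataset and store
#'   normalized matrices (TRUE) or keep raw matrices (FALSE).
#' @return A list: `store` (a [feature_store()] with labels, breakpoints
#'   and stats), `contigs` (list of `contig_record`), `alignments` (list of
#'   alignment tables), `community`, `genomes`, `params`.
#' @export
simulate_contig_dataset <- function(n_contigs = 200L,
                                    misassembled_frac = 0.25,
                                    coverage = 10, read_len = 100L,
                                    insert_mean = 270, insert_sd = 50,
                                    profile = error_profile("uniform"),
                                    contig_len_range = c(400L, 900L),
                                    n_genomes = 8L, genome_len = 40000L,
                                    sigma = 1, max_mean_cov = 20,
                                    seed = 1L, normalize = TRUE) {
  stopifnot(n_contigs >= 1, misassembled_frac >= 0, misassembled_frac <= 1,
            coverage > 0, contig_len_range[1] >= 2 * read_len)
  withr_seed(seed)
  pool <- lapply(seq_len(n_genomes), function(i)
    generate_genome(genome_len, gc_fraction = runif(1, 0.35, 0.65),
                    seed = seed + 7919L * i, id = sprintf("g%03d", i)))
  names(pool) <- vapply(pool, `[[`, "", "id")
  community <- sample_community(pool, n_genomes, sigma = sigma,
                                seed = seed + 13L)

  withr_seed(seed + 29L)
  n_mis <- round(misassembled_frac * n_contigs)
  types <- c(rep("none", n_contigs - n_mis),
             sample(c("relocation", "inversion", "translocation",
                      "interspecies_translocation"), n_mis, replace = TRUE))
  types <- sample(types)
  lens <- sample(seq.int(contig_len_range[1], contig_len_range[2]),
                 n_contigs, replace = TRUE)

  margin <- ceiling(insert_mean + 4 * insert_sd)
  contigs <- vector("list", n_contigs)
  alignments <- vector("list", n_contigs)
  mats <- vector("list", n_contigs)
  labels <- integer(n_contigs)
  breakpoints <- vector("list", n_contigs)
  ids <- sprintf("contig_%04d", seq_len(n_contigs))

  for (i in seq_len(n_contigs)) {
    cs <- seed + 1000L + i
    ct <- inject_misassembly(pool, types[i], len = lens[i], seed = cs,
                             id = ids[i])
    reads <- simulate_contig_reads(ct, pool, coverage, read_len,
                                   insert_mean, insert_sd, profile,
                                   margin, seed = cs + 1L)
    al <- truth_align(reads, ct, insert_mean, insert_sd)
    al <- subsample_to_coverage(al, nchar(ct$sequence), max_mean_cov,
                                seed = cs + 2L)
    contigs[[i]] <- ct
    alignments[[i]] <- al
    mats[[i]] <- compute_pileup(ct, al)
    labels[i] <- ct$label
    breakpoints[[i]] <- ct$breakpoints
  }
  names(mats) <- ids
  names(labels) <- ids
  names(breakpoints) <- ids
  names(contigs) <- ids
  names(alignments) <- ids

  catalog <- feature_catalog()
  stats <- NULL
  if (normalize) {
    stats <- fit_normalization(mats, catalog)
    mats <- lapply(mats, apply_normalization, stats = stats,
                   catalog = catalog)
  }
  prof <- tryCatch(insert_size_profile(alignments), error = function(e) NULL)
  store <- feature_store(mats, labels = labels, catalog = catalog,
                         stats = stats, breakpoints = breakpoints,
                         insert_profile = prof)
  list(store = store, contigs = contigs, alignments = alignments,
       community = community, genomes = pool,
       params = list(n_contigs = n_contigs,
                     misassembled_frac = misassembled_frac,
                     coverage = coverage, read_len = read_len,
                     insert_mean = insert_mean, insert_sd = insert_sd,
                     profile = profile, contig_len_range = contig_len_range,
                     seed = seed))
}

# simulate reads for one contig from its source genome regions; the number
# of pairs is chosen so the contig reaches the target mean coverage
simulate_contig_reads <- function(contig, pool, coverage, read_len,
                                  insert_mean, insert_sd, profile, margin,
                                  seed) {
  src <- contig$sources
  glen <- vapply(pool, function(g) nchar(g$sequence), 0)
  regions <- lapply(seq_len(nrow(src)), function(si) {
    c(max(1L, src$g_start[si] - margin),
      min(glen[[src$genome_id[si]]], src$g_end[si] + margin))
  })
  genomes <- lapply(src$genome_id, function(id) pool[[id]])
  rlen <- vapply(regions, function(r) r[2] - r[1] + 1, 0)
  n_pairs <- max(1L, ceiling(coverage * sum(rlen) / (2 * read_len)))
  simulate_read_pairs(genomes, n_pairs, read_len, insert_mean, insert_sd,
                      profile, abundances = rep(1, length(genomes)),
                      regions = regions, seed = seed)
}
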