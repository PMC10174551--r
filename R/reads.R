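#' Sequencer error profiles
#'
#' A substitution-only error model: the per-base substitution probability
#' rises linearly from `r0` at cycle 1 to `r1` at the last cycle, emulating
#' the quality decay of Illumina-type instruments. Indels are not modeled.
#'
#' @param name profile name. The built-in profiles are `"HiSeq2500"`
#'   (0.1\% to 1\%), `"HiSeq2500-L150"` (0.05\% to 0.6\%), `"uniform"`
#'   (constant `r0`) and `"perfect"` (no errors); any name may be given
#'   together with explicit `r0`/`r1`.
#' @param r0,r1 substitution rates at the first and last cycle; override the
#'   built-in values when supplied.
#' @return An `error_profile`: list with `name`, `r0`, `r1`.
#' @export
error_profile <- function(name = "HiSeq2500", r0 = NULL, r1 = NULL) {
  builtin <- list(
    "HiSeq2500"      = c(0.001, 0.010),
    "HiSeq2500-L150" = c(0.0005, 0.006),
    "uniform"        = c(0.005, 0.005),
    "perfect"        = c(0, 0)
  )
  if (is.null(r0)) {
    if (!name %in% names(builtin))
      stop("unknown error profile: ", name, " (supply r0/r1 for custom)")
    r0 <- builtin[[name]][1]
    if (is.null(r1)) r1 <- builtin[[name]][2]
  }
  if (is.null(r1)) r1 <- r0
  stopifnot(r0 >= 0, r1 >= 0, r0 < 1, r1 < 1)
  structure(list(name = name, r0 = r0, r1 = r1), class = "error_profile")
}

# vectorized substitution injection; returns list(seq = chars, errs = positions)
apply_errors <- function(chars, rates) {
  hit <- which(runif(length(chars)) < rates)
  if (length(hit)) {
    repl <- vapply(chars[hit], function(b) sample(setdiff(BASES, b), 1L), "")
    chars[hit] <- repl
  }
  list(chars = chars, errs = hit)
}

#' Simulate paired-end reads from a set of genomes
#'
#' Pairs are allocated to genomes by a multinomial draw weighted by
#' `abundance * genome length`. For each pair, the fragment start is uniform
#' on the genome (or on the supplied per-genome `regions`), the fragment
#' length is Normal(`insert_mean`, `insert_sd`) truncated below at
#' `read_len` (resampled until valid, and capped at the genome/region
#' length). Mate 1 is the forward strand read starting at the fragment
#' start; mate 2 is the reverse-complement read ending at the fragment end.
#' Substitution errors follow the error profile, independently per mate.
#'
#' @param genomes list of `reference_genome` objects.
#' @param n_pairs total number of read pairs (> 0).
#' @param read_len read length in bp (both mates).
#' @param insert_mean,insert_sd fragment (insert) size distribution in bp.
#' @param profile an [error_profile()].
#' @param abundances optional per-genome weights (default equal).
#' @param regions optional list (parallel to `genomes`) of `c(start, end)`
#'   windows restricting fragment placement; fragments lie fully inside.
#' @param seed integer RNG seed.
#' @return A `data.table` with one row per pair: `pair_id`, `genome_id`,
#'   `frag_start`, `frag_end` (1-based closed genome coordinates),
#'   `seq1`, `seq2` (mate sequences; mate 2 reverse-complemented),
#'   `err1`, `err2` (list columns of error cycle positions).
#' @export
simulate_read_pairs <- function(genomes, n_pairs, read_len = 100L,
                                insert_mean = 270, insert_sd = 50,
                                profile = error_profile("uniform"),
                                abundances = NULL, regions = NULL,
                                seed = 1L) {
  stopifnot(n_pairs > 0, read_len > 0)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  glen <- vapply(genomes, function(g) nchar(g$sequence), 0)
  if (any(read_len > glen)) stop("read_len exceeds a genome length")
  if (is.null(abundances)) abundances <- rep(1, length(genomes))
  if (is.null(regions)) {
    regions <- lapply(glen, function(L) c(1L, L))
  }
  rlen <- vapply(regions, function(r) r[2] - r[1] + 1, 0)
  stopifnot(all(rlen >= read_len))
  withr_seed(seed)

  w <- abundances * rlen
  counts <- as.vector(stats::rmultinom(1, n_pairs, w / sum(w)))

  out <- vector("list", length(genomes))
  pair0 <- 0L
  lin_rates <- function(n) {
    if (n == 1) return(profile$r0)
    profile$r0 + (profile$r1 - profile$r0) * (seq_len(n) - 1) / (n - 1)
  }
  rates <- lin_rates(read_len)
  for (gi in seq_along(genomes)) {
    n <- counts[gi]
    if (n == 0) next
    g <- genomes[[gi]]
    reg <- regions[[gi]]
    span <- reg[2] - reg[1] + 1
    # truncated normal fragment lengths: >= read_len, <= span
    fl <- round(rnorm(n, insert_mean, insert_sd))
    bad <- which(fl < read_len | fl > span)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      fl[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
      bad <- which(fl < read_len | fl > span)
      guard <- guard + 1L
    }
    if (length(bad)) fl[bad] <- pmin(pmax(fl[bad], read_len), span)
    fs <- reg[1] + floor(runif(n) * (span - fl + 1))
    fe <- fs + fl - 1

    s1 <- substring(g$sequence, fs, fs + read_len - 1)
    s2raw <- substring(g$sequence, fe - read_len + 1, fe)
    s2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s2raw)))

    c1 <- strsplit(s1, "", fixed = TRUE)
    c2 <- strsplit(s2, "", fixed = TRUE)
    e1 <- vector("list", n); e2 <- vector("list", n)
    for (i in seq_len(n)) {
      a <- apply_errors(c1[[i]], rates)
      b <- apply_errors(c2[[i]], rates)
      c1[[i]] <- a$chars; e1[[i]] <- a$errs
      c2[[i]] <- b$chars; e2[[i]] <- b$errs
    }
    out[[gi]] <- data.table::data.table(
      pair_id = paste0("p", pair0 + seq_len(n)),
      genome_id = g$id,
      frag_start = as.integer(fs), frag_end = as.integer(fe),
      seq1 = vapply(c1, paste, "", collapse = ""),
      seq2 = vapply(c2, paste, "", collapse = ""),
      err1 = e1, err2 = e2
    )
    pair0 <- pair0 + n
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) stop("no reads generated")
  attr(res, "read_len") <- as.integer(read_len)
  attr(res, "insert_mean") <- insert_mean
  attr(res, "insert_sd") <- insert_sd
  res[]
}
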