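#' The per-position feature catalog
#'
#' Defines the ordered set of 23 per-position pileup channels and the subset
#' used as model input. Channel kinds: `count` channels are later normalized
#' by coverage, `numeric` channels are standardized against training
#' statistics, the single `categorical` channel (`ref_base`) is a small
#' integer code.
#'
#' The default 14 selected channels are `num_query_A/C/G/T`, `num_SNPs`,
#' `num_proper`, `num_orphan`, `num_proper_SNP`, `mean/min/stdev_al_score`,
#' `mean_mapq`, `coverage` and `min_insert_size` — at least one channel per
#' signal family (base composition, SNVs, pairing, alignment score, mapping
#' quality, coverage, insert size).
#'
#' @param selected character vector of selected channel names.
#' @return A `feature_catalog`: list with `channels` (data.frame of `name`,
#'   `kind`) and `selected`.
#' @export
feature_catalog <- function(selected = NULL) {
  channels <- data.frame(
    name = c("ref_base", "coverage",
             "num_query_A", "num_query_C", "num_query_G", "num_query_T",
             "num_SNPs", "num_discordant", "num_proper", "num_orphan",
             "num_proper_SNP", "num_pairs",
             "min_mapq", "mean_mapq", "stdev_mapq",
             "min_al_score", "mean_al_score", "stdev_al_score",
             "min_insert_size", "mean_insert_size", "stdev_insert_size",
             "seq_window_entropy", "seq_window_gc"),
    kind = c("categorical", "numeric",
             rep("count", 4),
             rep("count", 5), "count",
             rep("numeric", 9),
             "numeric", "numeric"),
    stringsAsFactors = FALSE
  )
  if (is.null(selected)) {
    selected <- c("num_query_A", "num_query_C", "num_query_G", "num_query_T",
                  "num_SNPs", "num_proper", "num_orphan", "num_proper_SNP",
                  "mean_al_score", "min_al_score", "stdev_al_score",
                  "mean_mapq", "coverage", "min_insert_size")
  }
  if (!all(selected %in% channels$name))
    stop("unknown selected channel(s): ",
         paste(setdiff(selected, channels$name), collapse = ", "))
  structure(list(channels = channels, selected = selected),
            class = "feature_catalog")
}

count_channels <- function(catalog)
  catalog$channels$name[catalog$channels$kind == "count"]
numeric_channels <- function(catalog)
  catalog$channels$name[catalog$channels$kind != "count"]

#' Subsample alignments to a maximum mean coverage
#'
#' If the mean per-position coverage of the contig exceeds `max_mean_cov`,
#' whole read pairs are dropped uniformly at random (mates together) until
#' the mean coverage is at or below the ceiling; otherwise the input is
#' returned unchanged. Deterministic for a fixed seed.
#'
#' @param alignments alignment table from [truth_align()].
#' @param contig_len contig length in bp (default: stored attribute).
#' @param max_mean_cov coverage ceiling (default 20).
#' @param seed integer RNG seed.
#' @return The (possibly) subset alignment table.
#' @export
subsample_to_coverage <- function(alignments, contig_len = NULL,
                                  max_mean_cov = 20, seed = 1L) {
  if (is.null(contig_len)) contig_len <- attr(alignments, "contig_len")
  stopifnot(!is.null(contig_len))
  if (nrow(alignments) == 0) return(alignments)
  total <- sum(alignments$qlen)
  if (total / contig_len <= max_mean_cov) return(alignments)
  withr_seed(seed)
  per_pair <- alignments[, .(bases = sum(qlen)), by = qname]
  per_pair <- per_pair[sample.int(nrow(per_pair))]
  keep_n <- findInterval(max_mean_cov * contig_len, cumsum(per_pair$bases))
  keep <- per_pair$qname[seq_len(keep_n)]
  out <- alignments[qname %in% keep]
  for (a in c("contig_len", "read_len", "insert_mean", "insert_sd"))
    attr(out, a) <- attr(alignments, a)
  out
}

base_code <- function(chars) match(chars, BASES)

#' Compute the raw per-position pileup feature matrix
#'
#' For every contig position: coverage, base composition of aligned reads,
#' SNV counts (aligned bases differing from the contig base), pairing
#' counts (proper / orphan / discordant / in-pair), min/mean/stdev of
#' mapping quality and alignment score over covering reads, min/mean/stdev
#' of observed insert size over covering proper-pair reads, the contig base
#' code, and local 50 bp sequence entropy (bits) and GC fraction. Numeric
#' statistics at uncovered positions are missing (`NA`); counts are 0.
#'
#' @param contig a `contig_record` (or plain character sequence).
#' @param alignments alignment table from [truth_align()].
#' @param window local sequence window size (bp, centered, truncated at
#'   contig ends).
#' @return A `feature_matrix`: list with `contig_id`, `values` (positions x
#'   23 matrix), `coverage`, `mask` (TRUE where covered).
#' @export
compute_pileup <- function(contig, alignments, window = 50L) {
  seqc <- if (inherits(contig, "contig_record")) contig$sequence else contig
  cid <- if (inherits(contig, "contig_record")) contig$id else "contig"
  L <- nchar(seqc)
  cat23 <- feature_catalog()
  vals <- matrix(NA_real_, nrow = L, ncol = nrow(cat23$channels),
                 dimnames = list(NULL, cat23$channels$name))

  cchars <- strsplit(seqc, "", fixed = TRUE)[[1]]
  vals[, "ref_base"] <- base_code(cchars)
  sw <- seq_window_stats(cchars, window)
  vals[, "seq_window_entropy"] <- sw$entropy
  vals[, "seq_window_gc"] <- sw$gc

  n <- nrow(alignments)
  if (n > 0) {
    if (any(alignments$pos < 1L) ||
        any(alignments$pos + alignments$qlen - 1L > L)) {
      bad <- which(alignments$pos < 1L |
                   alignments$pos + alignments$qlen - 1L > L)[1]
      stop("alignment out of contig bounds: ", alignments$qname[bad])
    }
    rl <- alignments$qlen
    stopifnot(length(unique(rl)) >= 1)
    posv <- rep(alignments$pos, rl) + sequence(rl) - 1L
    basev <- unlist(strsplit(alignments$seq, "", fixed = TRUE))

    cov <- tabulate(posv, L)
    vals[, "coverage"] <- cov
    for (b in BASES)
      vals[, paste0("num_query_", b)] <- tabulate(posv[basev == b], L)

    mm <- as.integer(unlist(alignments$nm_pos))
    vals[, "num_SNPs"] <- tabulate(mm, L)
    vals[, "num_proper_SNP"] <- tabulate(
      as.integer(unlist(alignments$nm_pos[alignments$is_proper])), L)

    flagtab <- function(flag) tabulate(posv[rep(flag, rl)], L)
    vals[, "num_proper"] <- flagtab(alignments$is_proper)
    vals[, "num_orphan"] <- flagtab(alignments$is_orphan)
    vals[, "num_discordant"] <- flagtab(alignments$is_discordant)
    vals[, "num_pairs"] <- flagtab(!alignments$is_orphan)

    dt <- data.table::data.table(
      p = posv,
      mapq = rep(as.numeric(alignments$mapq), rl),
      al = rep(as.numeric(alignments$al_score), rl)
    )
    st <- dt[, .(n = .N,
                 min_mapq = min(mapq), s_q = sum(mapq),
                 ss_q = sum(mapq * mapq),
                 min_al_score = min(al), s_a = sum(al),
                 ss_a = sum(al * al)), by = p]
    vals[st$p, "min_mapq"] <- st$min_mapq
    vals[st$p, "mean_mapq"] <- st$s_q / st$n
    vals[st$p, "stdev_mapq"] <- grouped_sd(st$s_q, st$ss_q, st$n)
    vals[st$p, "min_al_score"] <- st$min_al_score
    vals[st$p, "mean_al_score"] <- st$s_a / st$n
    vals[st$p, "stdev_al_score"] <- grouped_sd(st$s_a, st$ss_a, st$n)

    prop <- alignments$is_proper
    if (any(prop)) {
      dtp <- data.table::data.table(
        p = rep(alignments$pos[prop], rl[prop]) + sequence(rl[prop]) - 1L,
        ins = rep(as.numeric(alignments$isize[prop]), rl[prop])
      )
      stp <- dtp[, .(n = .N, min_insert_size = min(ins), s = sum(ins),
                     ss = sum(ins * ins)), by = p]
      vals[stp$p, "min_insert_size"] <- stp$min_insert_size
      vals[stp$p, "mean_insert_size"] <- stp$s / stp$n
      vals[stp$p, "stdev_insert_size"] <- grouped_sd(stp$s, stp$ss, stp$n)
    }
  } else {
    cov <- rep(0L, L)
    vals[, "coverage"] <- 0
    for (cn in count_channels(cat23)) vals[, cn] <- 0
  }
  for (cn in count_channels(cat23)) {
    x <- vals[, cn]; x[is.na(x)] <- 0; vals[, cn] <- x
  }

  structure(list(contig_id = cid, values = vals, coverage = cov,
                 mask = cov > 0),
            class = "feature_matrix")
}

# stdev that is 0 (not NA) for a single observation
sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)

# sample sd from grouped sum / sum of squares; 0 for single observations
grouped_sd <- function(s, ss, n) {
  out <- numeric(length(n))
  multi <- n > 1L
  v <- (ss[multi] - s[multi]^2 / n[multi]) / (n[multi] - 1L)
  out[multi] <- sqrt(pmax(v, 0))
  out
}

# rolling sequence entropy (bits) and GC over a centered, truncated window
seq_window_stats <- function(cchars, window) {
  L <- length(cchars)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  ind <- matrix(0L, nrow = L, ncol = 4L)
  code <- base_code(cchars)
  ind[cbind(seq_len(L), code)] <- 1L
  cs <- apply(ind, 2, cumsum)
  lo <- pmax(1L, seq_len(L) - half_lo)
  hi <- pmin(L, seq_len(L) + half_hi)
  cnt <- cs[hi, , drop = FALSE] -
    rbind(0L, cs)[lo, , drop = FALSE]
  tot <- rowSums(cnt)
  p <- cnt / tot
  plogp <- ifelse(p > 0, p * log2(p), 0)
  list(entropy = -rowSums(plogp), gc = (cnt[, 2] + cnt[, 3]) / tot)
}

#' Insert-size profile of a dataset
#'
#' Quantiles (0.05, 0.50, 0.95) of the observed insert sizes of proper
#' pairs, with a pass/fail verdict against the configured applicability
#' bounds of the trained model (closed interval; defaults 117 and 493).
#'
#' @param alignments one alignment table or a list of them.
#' @param bounds numeric lower/upper applicability bounds.
#' @return A list: `q05`, `q50`, `q95`, `pass`, `bounds`, `n_pairs`.
#' @export
insert_size_profile <- function(alignments, bounds = c(117, 493)) {
  if (data.table::is.data.table(alignments)) alignments <- list(alignments)
  ins <- unlist(lapply(alignments, function(al) {
    if (nrow(al) == 0) return(numeric(0))
    al[al$is_proper & al$mate == 1L, ]$isize
  }))
  if (length(ins) == 0) stop("no proper pairs: insert-size profile undefined")
  q <- unname(quantile(ins, c(0.05, 0.5, 0.95)))
  list(q05 = q[1], q50 = q[2], q95 = q[3],
       pass = q[1] >= bounds[1] && q[3] <= bounds[2],
       bounds = bounds, n_pairs = length(ins))
}
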