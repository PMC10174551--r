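#' Align simulated reads to a contig using ground truth
#'
#' Replaces a real aligner: each mate's true genome coordinates are mapped
#' onto the contig through the contig's source segments (the segment with
#' maximal overlap anchors the read), then the read is placed full-length
#' with an all-match CIGAR and mismatches are determined by direct base
#' comparison against the contig. Reads spanning a misassembly junction thus
#' accumulate mismatches on the far side of the junction; reads whose
#' placement falls outside the contig produce no record.
#'
#' Pairing semantics: a pair is *proper* iff both mates map in FR
#' orientation with an observed insert inside `insert_mean +/- 3 insert_sd`;
#' a mapped mate whose mate is unmapped is an *orphan*; a mapped non-proper
#' pair is *discordant*.
#'
#' @param reads read-pair table from [simulate_read_pairs()].
#' @param contig a `contig_record`.
#' @param insert_mean,insert_sd insert-size distribution used for the
#'   proper-pair window (defaults: the values stored on `reads`).
#' @param mapq_unique mapping-quality surrogate for placed reads.
#' @param mismatch_penalty alignment-score penalty per mismatch (the score
#'   is `0 - mismatch_penalty * mismatches`, Bowtie2-like).
#' @return A `data.table` with one row per mapped mate: `qname`, `mate`,
#'   `contig_id`, `pos` (1-based), `strand`, `seq` (contig-forward
#'   orientation), `qlen`, `mapq`, `al_score`, `n_mismatch`, `nm_pos`
#'   (list of contig positions), `is_proper`, `is_orphan`, `is_discordant`,
#'   `isize` (observed insert of the pair; NA unless both mates map),
#'   `mate_pos`.
#' @export
truth_align <- function(reads, contig, insert_mean = NULL, insert_sd = NULL,
                        mapq_unique = 42L, mismatch_penalty = 6) {
  stopifnot(inherits(contig, "contig_record"))
  if (is.null(insert_mean)) insert_mean <- attr(reads, "insert_mean")
  if (is.null(insert_sd)) insert_sd <- attr(reads, "insert_sd")
  stopifnot(!is.null(insert_mean), !is.null(insert_sd))
  rl <- attr(reads, "read_len")
  if (is.null(rl)) rl <- nchar(reads$seq1[1])
  clen <- nchar(contig$sequence)

  src <- contig$sources
  seg_len <- src$g_end - src$g_start + 1L
  c_start <- c(1L, cumsum(seg_len)[-length(seg_len)] + 1L)

  n <- nrow(reads)
  # mate genome intervals and genome-orientation
  a1 <- reads$frag_start; b1 <- a1 + rl - 1L
  a2 <- reads$frag_end - rl + 1L; b2 <- reads$frag_end

  place <- function(a, b, gid) {
    # returns contig start position and segment strand, NA when unanchored;
    # the segment with maximal overlap anchors the read (earlier wins ties)
    pos <- rep(NA_integer_, length(a)); sstr <- rep(NA_character_, length(a))
    best <- rep(0L, length(a))
    for (si in seq_len(nrow(src))) {
      ov <- pmin(b, src$g_end[si]) - pmax(a, src$g_start[si]) + 1L
      ov[gid != src$genome_id[si]] <- 0L
      better <- ov > 0L & ov > best
      if (any(better)) {
        if (src$strand[si] == "+") {
          pos[better] <- c_start[si] + (a[better] - src$g_start[si])
          sstr[better] <- "+"
        } else {
          pos[better] <- c_start[si] + (src$g_end[si] - b[better])
          sstr[better] <- "-"
        }
        best[better] <- ov[better]
      }
    }
    list(pos = pos, sstr = sstr)
  }

  p1 <- place(a1, b1, reads$genome_id)
  p2 <- place(a2, b2, reads$genome_id)

  in_bounds <- function(p) !is.na(p$pos) & p$pos >= 1L & p$pos + rl - 1L <= clen
  m1 <- in_bounds(p1); m2 <- in_bounds(p2)

  # contig-forward sequences: mate1 is genome-forward, mate2 genome-reverse
  fwd1 <- reads$seq1
  fwd2 <- rc_vec(reads$seq2)                 # genome-forward version of mate 2
  cseq1 <- ifelse(!is.na(p1$sstr) & p1$sstr == "-", rc_vec(fwd1), fwd1)
  cseq2 <- ifelse(!is.na(p2$sstr) & p2$sstr == "-", reads$seq2, fwd2)
  # contig strand: mate1 "+" on "+" segments; mate2 the opposite
  str1 <- ifelse(p1$sstr == "-", "-", "+")
  str2 <- ifelse(p2$sstr == "-", "+", "-")

  build <- function(mate, mapped, pos, strand, cs, other_mapped, other_pos) {
    idx <- which(mapped)
    if (!length(idx)) return(NULL)
    data.table::data.table(
      qname = reads$pair_id[idx], mate = mate, contig_id = contig$id,
      pos = pos[idx], strand = strand[idx], seq = cs[idx], qlen = rl,
      om = other_mapped[idx], mate_pos = other_pos[idx]
    )
  }
  al <- data.table::rbindlist(list(
    build(1L, m1, p1$pos, str1, cseq1, m2, p2$pos),
    build(2L, m2, p2$pos, str2, cseq2, m1, p1$pos)
  ))
  if (nrow(al) == 0) {
    return(empty_alignments(contig$id, insert_mean, insert_sd, rl))
  }

  # mismatches vs the contig by direct comparison
  cchars <- utf8ToInt(contig$sequence)
  nm_pos <- vector("list", nrow(al))
  n_mm <- integer(nrow(al))
  for (i in seq_len(nrow(al))) {
    rchars <- utf8ToInt(al$seq[i])
    span <- al$pos[i]:(al$pos[i] + rl - 1L)
    mm <- span[rchars != cchars[span]]
    nm_pos[[i]] <- mm
    n_mm[i] <- length(mm)
  }
  al[, `:=`(nm_pos = nm_pos, n_mismatch = n_mm,
            mapq = mapq_unique, al_score = -mismatch_penalty * n_mm)]

  # pairing flags
  pair <- al[, .(both = any(mate == 1L) && any(mate == 2L),
                 lo = min(pos), hi = max(pos + qlen - 1L),
                 fr = {
                   pp <- pos[strand == "+"]; pm <- pos[strand == "-"]
                   length(pp) == 1L && length(pm) == 1L && pp <= pm
                 }), by = qname]
  pair[, isize := ifelse(both, hi - lo + 1L, NA_integer_)]
  lowI <- insert_mean - 3 * insert_sd
  highI <- insert_mean + 3 * insert_sd
  pair[, proper := both & fr & !is.na(isize) & isize >= lowI & isize <= highI]
  al <- merge(al, pair[, .(qname, both, isize, proper)],
              by = "qname", sort = FALSE)
  al[, `:=`(is_proper = proper & om,
            is_orphan = !om,
            is_discordant = om & both & !proper)]
  al[, c("om", "both", "proper") := NULL]
  attr(al, "contig_len") <- clen
  attr(al, "read_len") <- rl
  attr(al, "insert_mean") <- insert_mean
  attr(al, "insert_sd") <- insert_sd
  al[]
}

rc_vec <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

empty_alignments <- function(contig_id, insert_mean, insert_sd, rl) {
  al <- data.table::data.table(
    qname = character(), mate = integer(), contig_id = character(),
    pos = integer(), strand = character(), seq = character(),
    qlen = integer(), mate_pos = integer(), nm_pos = list(),
    n_mismatch = integer(), mapq = integer(), al_score = numeric(),
    isize = integer(), is_proper = logical(), is_orphan = logical(),
    is_discordant = logical()
  )
  attr(al, "read_len") <- rl
  attr(al, "insert_mean") <- insert_mean
  attr(al, "insert_sd") <- insert_sd
  al
}
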