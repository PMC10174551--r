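#' Write sequences as FASTA
#'
#' @param seqs named character vector (or list of `reference_genome` /
#'   `contig_record` objects) of A/C/G/T sequences.
#' @param path output path.
#' @param width line wrap width (default 60).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.list(seqs) && !is.null(seqs[[1]]$sequence)) {
    nm <- vapply(seqs, `[[`, "", "id")
    seqs <- setNames(vapply(seqs, `[[`, "", "sequence"), nm)
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write simulated read pairs as paired FASTQ
#'
#' Mate files `<prefix>_R1.fastq` / `<prefix>_R2.fastq` with constant
#' Phred+33 quality.
#'
#' @param reads read table from [simulate_read_pairs()].
#' @param prefix output path prefix.
#' @param quality_char constant quality character (default `"I"`, Q40).
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix, quality_char = "I") {
  rl <- nchar(reads$seq1[1])
  qual <- strrep(quality_char, rl)
  write_one <- function(seqs, ids, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  }
  p1 <- paste0(prefix, "_R1.fastq")
  p2 <- paste0(prefix, "_R2.fastq")
  write_one(reads$seq1, paste0(reads$pair_id, "/1"), p1)
  write_one(reads$seq2, paste0(reads$pair_id, "/2"), p2)
  invisible(c(p1, p2))
}

# SAM flag bits: 0x1 paired, 0x2 proper, 0x8 mate unmapped, 0x10 reverse,
# 0x20 mate reverse, 0x40 first in pair, 0x80 second in pair
sam_flag <- function(mate, strand, mate_strand, is_proper, is_orphan) {
  flag <- 1L +
    ifelse(is_proper, 2L, 0L) +
    ifelse(is_orphan, 8L, 0L) +
    ifelse(strand == "-", 16L, 0L) +
    ifelse(!is_orphan & mate_strand == "-", 32L, 0L) +
    ifelse(mate == 1L, 64L, 128L)
  as.integer(flag)
}

#' Write alignments as SAM
#'
#' Emits `@HD`/`@SQ` headers and one record per mapped mate with 1-based
#' positions, an all-match CIGAR, flags set from the pairing semantics
#' (paired / proper / mate-unmapped / strand / first-second), the mapping
#' quality and `AS`/`NM` tags.
#'
#' @param alignments one alignment table (or list of them) from
#'   [truth_align()].
#' @param contigs list of `contig_record` (for `@SQ` lines).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, contigs, path) {
  if (data.table::is.data.table(alignments)) alignments <- list(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ct in contigs)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ct$id, nchar(ct$sequence)), con)
  for (al in alignments) {
    if (nrow(al) == 0) next
    al2 <- data.table::as.data.table(al)
    ms <- al2$strand[match(paste(al2$qname, 3L - al2$mate),
                           paste(al2$qname, al2$mate))]
    ms[is.na(ms)] <- "+"
    flag <- sam_flag(al2$mate, al2$strand, ms, al2$is_proper, al2$is_orphan)
    tlen <- ifelse(is.na(al2$isize), 0L,
                   ifelse(al2$strand == "+", al2$isize, -al2$isize))
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t*\tAS:i:%d\tNM:i:%d",
                   al2$qname, flag, al2$contig_id, al2$pos, al2$mapq,
                   al2$qlen,
                   ifelse(al2$is_orphan, "*", "="),
                   ifelse(al2$is_orphan, 0L, al2$mate_pos),
                   tlen, al2$seq, as.integer(al2$al_score), al2$n_mismatch)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write / read truth labels as TSV
#'
#' Columns: `contig_id`, `label`, `misassembly_type`, `breakpoints`
#' (comma-separated, empty for correctly assembled contigs).
#'
#' @param contigs list of `contig_record`.
#' @param path output path.
#' @return `read_labels` returns a data.frame with `breakpoints` as a list
#'   column of integer vectors.
#' @export
write_labels <- function(contigs, path) {
  df <- data.frame(
    contig_id = vapply(contigs, `[[`, "", "id"),
    label = vapply(contigs, `[[`, 0L, "label"),
    misassembly_type = vapply(contigs, `[[`, "", "misassembly_type"),
    breakpoints = vapply(contigs, function(ct)
      paste(ct$breakpoints, collapse = ","), "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "character", "character"))
  df$breakpoints <- lapply(strsplit(df$breakpoints, ","), function(x)
    as.integer(x[nzchar(x)]))
  df
}

#' Read / write a run configuration as YAML
#'
#' The configuration round-trips through serialization; every stage seed is
#' derived from the single top-level seed.
#'
#' @param config named list of run settings.
#' @param path YAML path.
#' @return `read_run_config` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Derive a reproducible per-stage seed
#'
#' Hashes `(top seed, stage name)` into a 31-bit integer so that each
#' pipeline stage is independently reproducible from the run seed.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
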