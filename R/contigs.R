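#' Construct a contig record
#'
#' A `contig_record` carries the contig sequence, its ground-truth label,
#' breakpoint positions and provenance. `sources` is a data.frame with one
#' row per source segment (in contig order): `genome_id`, `g_start`, `g_end`
#' (1-based closed coordinates on the source genome) and `strand`
#' (`"+"`/`"-"`). Segments tile the contig exactly; breakpoints are recorded
#' as the number of contig bases before each junction (so a 5000 + 5000
#' chimera has breakpoint 5000). `label` is 1 iff there is at least one
#' breakpoint.
#'
#' @param id contig identifier.
#' @param sequence contig sequence (A/C/G/T).
#' @param misassembly_type one of `"none"`, `"relocation"`, `"inversion"`,
#'   `"translocation"`, `"interspecies_translocation"`.
#' @param sources data.frame of source segments (see above).
#' @return A `contig_record`.
#' @export
contig_record <- function(id, sequence, misassembly_type, sources) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  lens <- sources$g_end - sources$g_start + 1L
  if (sum(lens) != nchar(sequence))
    stop("source segments do not tile the contig: ", id)
  bp <- cumsum(lens)
  bp <- bp[-length(bp)]
  label <- as.integer(misassembly_type != "none")
  if (label == 1L && length(bp) == 0L)
    stop("misassembled contig without breakpoints: ", id)
  if (label == 0L) bp <- integer(0)
  structure(list(id = id, sequence = sequence, label = label,
                 misassembly_type = misassembly_type,
                 breakpoints = as.integer(bp), sources = sources),
            class = "contig_record")
}

src_row <- function(genome_id, g_start, g_end, strand = "+") {
  data.frame(genome_id = genome_id, g_start = as.integer(g_start),
             g_end = as.integer(g_end), strand = strand,
             stringsAsFactors = FALSE)
}

seg_seq <- function(genomes, row) {
  g <- genomes[[row$genome_id]]
  s <- substring(g$sequence, row$g_start, row$g_end)
  if (row$strand == "-") s <- revcomp(s) else s
}

#' Build a contig carrying a known misassembly
#'
#' Assembles a contig from segments of the supplied genomes according to the
#' misassembly class, recording every junction as a breakpoint:
#' \describe{
#'   \item{none}{a contiguous substring of one genome; label 0.}
#'   \item{inversion}{a window of one genome whose internal segment is
#'     reverse-complemented in place; two breakpoints.}
#'   \item{relocation}{two non-adjacent segments of the same genome joined;
#'     one breakpoint.}
#'   \item{translocation}{segments of two genomes of the same community
#'     member pool joined (different replicon emulation); one breakpoint.}
#'   \item{interspecies_translocation}{segments of two different genomes
#'     joined; one breakpoint.}
#' }
#'
#' @param genomes named list of `reference_genome` objects (names = ids).
#'   Translocation types require at least 2 genomes.
#' @param type misassembly class (see above).
#' @param geometry list of segment positions; see Details. When omitted,
#'   segments are drawn at random with total length `len`.
#' @param len target contig length used when `geometry` is `NULL`.
#' @param seed integer RNG seed for random geometry.
#' @param id contig identifier.
#' @details For explicit control pass `geometry`: for `"none"`
#'   `list(genome, start, end)`; for `"inversion"` `list(genome, start, end,
#'   inv_start, inv_end)` (inverted segment given in contig-local
#'   coordinates, 1-based closed); for the join types `list(genome1, start1,
#'   end1, genome2, start2, end2)` (`genome2 = genome1` for relocation).
#' @return A `contig_record`.
#' @export
inject_misassembly <- function(genomes, type = c("none", "relocation",
                               "inversion", "translocation",
                               "interspecies_translocation"),
                               geometry = NULL, len = 1000L, seed = NULL,
                               id = "contig1") {
  type <- match.arg(type)
  if (!is.null(names(genomes)) && any(names(genomes) == "")) names(genomes) <- NULL
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  withr_seed(seed)
  glen <- vapply(genomes, function(g) nchar(g$sequence), 0)

  if (is.null(geometry)) geometry <- random_geometry(genomes, glen, type, len)

  chk <- function(gid, s, e) {
    if (!gid %in% names(genomes)) stop("unknown genome: ", gid)
    if (s < 1 || e > glen[[gid]] || s > e)
      stop("segment [", s, ", ", e, "] out of range for genome ", gid)
  }

  if (type == "none") {
    gid <- geometry[[1]]; s <- geometry[[2]]; e <- geometry[[3]]
    chk(gid, s, e)
    sources <- src_row(gid, s, e)
  } else if (type == "inversion") {
    gid <- geometry[[1]]; s <- geometry[[2]]; e <- geometry[[3]]
    is_ <- geometry[[4]]; ie <- geometry[[5]]
    chk(gid, s, e)
    if (is_ <= 1 || ie >= e - s + 1 || is_ > ie)
      stop("inverted segment must be internal to the contig window")
    sources <- rbind(
      src_row(gid, s, s + is_ - 2L),
      src_row(gid, s + is_ - 1L, s + ie - 1L, strand = "-"),
      src_row(gid, s + ie, e)
    )
  } else {
    g1 <- geometry[[1]]; s1 <- geometry[[2]]; e1 <- geometry[[3]]
    g2 <- geometry[[4]]; s2 <- geometry[[5]]; e2 <- geometry[[6]]
    chk(g1, s1, e1); chk(g2, s2, e2)
    if (type == "relocation") {
      if (g1 != g2) stop("relocation joins segments of one genome")
      if (s2 <= e1 + 1 && e2 >= s1 - 1)
        stop("relocation segments must be non-adjacent")
    }
    if (type %in% c("translocation", "interspecies_translocation") && g1 == g2)
      stop(type, " requires two distinct genomes")
    sources <- rbind(src_row(g1, s1, e1), src_row(g2, s2, e2))
  }

  seqs <- vapply(seq_len(nrow(sources)), function(i)
    seg_seq(genomes, sources[i, ]), "")
  contig_record(id, paste(seqs, collapse = ""), type, sources)
}

# draw random segment geometry for a misassembly class
random_geometry <- function(genomes, glen, type, len) {
  ids <- names(genomes)
  pick_seg <- function(gid, L) {
    s <- sample.int(glen[[gid]] - L + 1L, 1L)
    c(s, s + L - 1L)
  }
  if (type == "none") {
    gid <- sample(ids, 1L)
    se <- pick_seg(gid, min(len, glen[[gid]]))
    list(gid, se[1], se[2])
  } else if (type == "inversion") {
    gid <- sample(ids, 1L)
    L <- min(len, glen[[gid]])
    se <- pick_seg(gid, L)
    # internal inverted segment between 25% and 75% of the window
    a <- max(2L, floor(L * 0.25)); b <- min(L - 1L, ceiling(L * 0.75))
    list(gid, se[1], se[2], a, b)
  } else if (type == "relocation") {
    gid <- sample(ids, 1L)
    L1 <- floor(len / 2); L2 <- len - L1
    gap <- 2000L
    if (glen[[gid]] < L1 + L2 + gap + 2L) gap <- max(2L, glen[[gid]] - L1 - L2 - 2L)
    s1 <- sample.int(max(1L, glen[[gid]] - L1 - gap - L2), 1L)
    e1 <- s1 + L1 - 1L
    s2 <- e1 + gap + 1L
    list(gid, s1, e1, gid, s2, s2 + L2 - 1L)
  } else {
    if (length(ids) < 2L) stop(type, " requires at least 2 genomes")
    gs <- sample(ids, 2L)
    L1 <- floor(len / 2); L2 <- len - L1
    se1 <- pick_seg(gs[1], min(L1, glen[[gs[1]]]))
    se2 <- pick_seg(gs[2], min(L2, glen[[gs[2]]]))
    list(gs[1], se1[1], se1[2], gs[2], se2[1], se2[2])
  }
}

#' Re-derive breakpoints from a contig's source segments
#'
#' @param contig a `contig_record`.
#' @return Integer vector of junction positions (bases before each junction).
#' @export
derive_breakpoints <- function(contig) {
  lens <- contig$sources$g_end - contig$sources$g_start + 1L
  bp <- cumsum(lens)
  as.integer(bp[-length(bp)])
}
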