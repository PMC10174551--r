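#' Simulation parameter grid
#'
#' A `sim_grid` describes the full factorial design of a community simulation
#' study: community richness, lognormal abundance spread (sigma), replicate
#' genome draws, read length, insert-size distribution, sequencer error
#' profile, sequencing depth (read pairs) and assembler label. Enumerating the
#' grid yields one `SimParams` row per sample to simulate.
#'
#' @param richness integer vector of community sizes (number of genomes).
#' @param sigma numeric vector of lognormal scale parameters.
#' @param replicates number of replicate genome subsamples (replicates differ
#'   only by the genome-subsampling seed).
#' @param read_lengths integer vector of read lengths (bp).
#' @param inserts list of `c(mean, sd)` insert-size specifications (bp).
#' @param error_profiles character vector of error-profile names.
#' @param depths numeric vector of sequencing depths (read pairs per sample).
#' @param assemblers character vector of assembler labels.
#' @return An object of class `sim_grid`.
#' @seealso [enumerate_grid()], [default_sim_grid()]
#' @export
sim_grid <- function(richness, sigma, replicates, read_lengths, inserts,
                     error_profiles, depths, assemblers) {
  stopifnot(is.numeric(richness), is.numeric(sigma),
            length(replicates) == 1L, replicates >= 1,
            is.numeric(read_lengths), is.list(inserts),
            is.character(error_profiles), is.numeric(depths),
            is.character(assemblers))
  axes <- list(richness = richness, sigma = sigma,
               read_lengths = read_lengths, inserts = inserts,
               error_profiles = error_profiles, depths = depths,
               assemblers = assemblers)
  empty <- vapply(axes, length, 1L) == 0L
  if (any(empty))
    stop("empty grid axis: ", paste(names(axes)[empty], collapse = ", "))
  if (any(depths <= 0)) stop("depths must be > 0")
  for (ins in inserts) {
    if (length(ins) != 2L || ins[1] <= 0 || ins[2] <= 0)
      stop("each insert spec must be c(mean > 0, sd > 0)")
  }
  structure(list(richness = as.integer(richness), sigma = as.numeric(sigma),
                 replicates = as.integer(replicates),
                 read_lengths = as.integer(read_lengths), inserts = inserts,
                 error_profiles = error_profiles, depths = depths,
                 assemblers = assemblers),
            class = "sim_grid")
}

#' The study-design simulation grid
#'
#' Richness 50/1000/3000/5000, lognormal sigma 0.5/1/2, three replicate genome
#' draws, read lengths 100 and 150 bp, four insert-size distributions
#' (190&75, 270&50, 350&75, 450&120), two HiSeq-type error profiles, five
#' sequencing depths (0.5M to 20M read pairs) and two assemblers.
#'
#' @return A `sim_grid`.
#' @export
default_sim_grid <- function() {
  sim_grid(
    richness = c(50L, 1000L, 3000L, 5000L),
    sigma = c(0.5, 1, 2),
    replicates = 3L,
    read_lengths = c(100L, 150L),
    inserts = list(c(190, 75), c(270, 50), c(350, 75), c(450, 120)),
    error_profiles = c("HiSeq2500", "HiSeq2500-L150"),
    depths = c(0.5e6, 2e6, 8e6, 12e6, 20e6),
    assemblers = c("megahit", "metaspades")
  )
}

#' Per-insert-size grid restrictions of the study design
#'
#' The training design was not a uniform factorial: for insert 350&75 only 3
#' replicates of the "HiSeq2500-L150" profile and 1 replicate of the
#' "HiSeq2500" profile were generated, and insert 450&120 used only the
#' "HiSeq2500-L150" profile. Returns a list keyed by "mean&sd" whose elements
#' map profile name -> allowed replicate indices.
#'
#' @return A named list of restriction rules for [enumerate_grid()].
#' @export
default_grid_restrictions <- function() {
  list(
    `350&75` = list(`HiSeq2500-L150` = 1:3, `HiSeq2500` = 1L),
    `450&120` = list(`HiSeq2500-L150` = 1:3)
  )
}

insert_key <- function(ins) paste0(ins[1], "&", ins[2])

#' Enumerate a simulation grid into per-sample parameter sets
#'
#' Forms the Cartesian product of all grid axes (including the replicate
#' index), then applies per-insert-size restriction rules: for an insert size
#' listed in `restrictions`, only the listed error profiles are kept, each
#' with its listed replicate subset. The result order is deterministic.
#'
#' @param grid a [sim_grid()].
#' @param restrictions optional named list (key `"mean&sd"`) of lists mapping
#'   error-profile name to allowed replicate indices; see
#'   [default_grid_restrictions()].
#' @return A `data.frame` with one row per simulated sample: `richness`,
#'   `sigma`, `replicate`, `read_len`, `insert_mean`, `insert_sd`,
#'   `error_profile`, `depth`, `assembler`.
#' @examples
#' nrow(enumerate_grid(default_sim_grid(), default_grid_restrictions())) # 4560
#' @export
enumerate_grid <- function(grid, restrictions = NULL) {
  stopifnot(inherits(grid, "sim_grid"))
  ins_mean <- vapply(grid$inserts, `[`, 0, 1)
  ins_sd <- vapply(grid$inserts, `[`, 0, 2)
  g <- expand.grid(
    assembler = grid$assemblers,
    depth = grid$depths,
    error_profile = grid$error_profiles,
    insert_idx = seq_along(grid$inserts),
    read_len = grid$read_lengths,
    replicate = seq_len(grid$replicates),
    sigma = grid$sigma,
    richness = grid$richness,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$insert_mean <- ins_mean[g$insert_idx]
  g$insert_sd <- ins_sd[g$insert_idx]
  if (!is.null(restrictions)) {
    keys <- paste0(g$insert_mean, "&", g$insert_sd)
    keep <- rep(TRUE, nrow(g))
    for (k in names(restrictions)) {
      rule <- restrictions[[k]]
      sel <- keys == k
      if (!any(sel)) next
      ok <- rep(FALSE, nrow(g))
      for (prof in names(rule)) {
        ok <- ok | (g$error_profile == prof & g$replicate %in% rule[[prof]])
      }
      keep[sel] <- ok[sel]
    }
    g <- g[keep, , drop = FALSE]
  }
  g <- g[, c("richness", "sigma", "replicate", "read_len", "insert_mean",
             "insert_sd", "error_profile", "depth", "assembler")]
  g <- g[order(g$richness, g$sigma, g$replicate, g$read_len, g$insert_mean,
               g$insert_sd, g$error_profile, g$depth, g$assembler), ]
  rownames(g) <- NULL
  g
}
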