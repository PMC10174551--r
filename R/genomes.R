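#' @importFrom stats rnorm runif rlnorm rbinom quantile sd cor median setNames
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")

#' Generate a random reference genome
#'
#' Bases are i.i.d. with the requested GC content; a stand-in for a real
#' bacterial/archaeal reference when only the statistical structure of
#' downstream reads and contigs matters.
#'
#' @param length genome length in bp (> 0).
#' @param gc_fraction target GC fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param id genome identifier.
#' @param taxon_tag optional taxon label (used for novelty splits).
#' @return A `reference_genome`: list with `id`, `sequence`, `taxon_tag`.
#' @export
generate_genome <- function(length, gc_fraction = 0.5, seed = 1L,
                            id = "genome1", taxon_tag = NA_character_) {
  stopifnot(length > 0, gc_fraction >= 0, gc_fraction <= 1)
  withr_seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  seq <- paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  structure(list(id = id, sequence = seq, taxon_tag = taxon_tag),
            class = "reference_genome")
}

withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Derive a strain by random substitutions
#'
#' Each position is substituted with probability `substitution_rate`; a
#' substituted base is replaced by one of the three other bases uniformly.
#' Emulates intra-species diversity between closely related genomes.
#'
#' @param genome a `reference_genome`.
#' @param substitution_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer RNG seed.
#' @param id identifier for the strain.
#' @return A `reference_genome` differing from `genome` only by substitutions.
#' @export
mutate_strain <- function(genome, substitution_rate, seed = 1L,
                          id = paste0(genome$id, "_strain")) {
  stopifnot(inherits(genome, "reference_genome"),
            substitution_rate >= 0, substitution_rate < 1)
  s <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  if (substitution_rate > 0) {
    withr_seed(seed)
    hit <- which(runif(length(s)) < substitution_rate)
    if (length(hit)) {
      repl <- vapply(s[hit], function(b) sample(setdiff(BASES, b), 1L), "")
      s[hit] <- repl
    }
  }
  structure(list(id = id, sequence = paste(s, collapse = ""),
                 taxon_tag = genome$taxon_tag),
            class = "reference_genome")
}

#' Sample a lognormal community abundance profile
#'
#' Draws `richness` genomes from the pool without replacement and assigns
#' relative abundances proportional to lognormal(meanlog = mu, sdlog = sigma)
#' draws, normalized to sum to one. Larger `sigma` gives a less even
#' community; only relative abundances matter after normalization, so `mu`
#' is a free location parameter.
#'
#' @param pool list of `reference_genome` objects.
#' @param richness number of genomes to draw (<= pool size).
#' @param sigma lognormal sdlog.
#' @param mu lognormal meanlog (default 10).
#' @param seed integer RNG seed.
#' @return A `community_profile`: list with `genome_ids`, `rel_abundances`,
#'   `mu`, `sigma`, and the drawn `genomes`.
#' @export
sample_community <- function(pool, richness, sigma, mu = 10, seed = 1L) {
  stopifnot(length(pool) >= 1, sigma >= 0)
  if (richness > length(pool))
    stop("richness (", richness, ") exceeds pool size (", length(pool), ")")
  withr_seed(seed)
  idx <- sample.int(length(pool), richness)
  ab <- rlnorm(richness, meanlog = mu, sdlog = sigma)
  ab <- ab / sum(ab)
  structure(list(genome_ids = vapply(pool[idx], `[[`, "", "id"),
                 rel_abundances = ab, mu = mu, sigma = sigma,
                 genomes = pool[idx]),
            class = "community_profile")
}

#' Pielou evenness of an abundance vector
#'
#' `H / log(S)` where `H` is Shannon entropy (natural log) and `S` the number
#' of taxa; 1 for a perfectly even community.
#'
#' @param abundances positive abundances (relative or absolute).
#' @return Evenness in `(0, 1]`.
#' @export
pielou_evenness <- function(abundances) {
  p <- abundances / sum(abundances)
  h <- -sum(p * log(p))
  h / log(length(p))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

substr_many <- function(seq, start, end) substring(seq, start, end)
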