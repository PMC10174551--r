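# Independent brute-force oracles used across the suite. These deliberately
# use naive loops and base R so they share no code path with the package.

# per-read accumulation pileup oracle: counts and covering-read statistics
brute_force_pileup <- function(contig_seq, al) {
  L <- nchar(contig_seq)
  ref <- strsplit(contig_seq, "")[[1]]
  cov <- integer(L)
  bases <- matrix(0L, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  snp <- integer(L); psnp <- integer(L)
  prop <- integer(L); orph <- integer(L); disc <- integer(L); prs <- integer(L)
  mq <- vector("list", L); as_ <- vector("list", L); ins <- vector("list", L)
  if (nrow(al) > 0) for (i in seq_len(nrow(al))) {
    chars <- strsplit(al$seq[i], "")[[1]]
    for (k in seq_along(chars)) {
      p <- al$pos[i] + k - 1L
      cov[p] <- cov[p] + 1L
      bases[p, chars[k]] <- bases[p, chars[k]] + 1L
      if (chars[k] != ref[p]) {
        snp[p] <- snp[p] + 1L
        if (al$is_proper[i]) psnp[p] <- psnp[p] + 1L
      }
      if (al$is_proper[i]) prop[p] <- prop[p] + 1L
      if (al$is_orphan[i]) orph[p] <- orph[p] + 1L
      if (al$is_discordant[i]) disc[p] <- disc[p] + 1L
      if (!al$is_orphan[i]) prs[p] <- prs[p] + 1L
      mq[[p]] <- c(mq[[p]], al$mapq[i])
      as_[[p]] <- c(as_[[p]], al$al_score[i])
      if (al$is_proper[i]) ins[[p]] <- c(ins[[p]], al$isize[i])
    }
  }
  list(coverage = cov, bases = bases, num_SNPs = snp, num_proper_SNP = psnp,
       num_proper = prop, num_orphan = orph, num_discordant = disc,
       num_pairs = prs, mapq = mq, al_score = as_, insert = ins)
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else stats::sd(x)

# exhaustive-threshold AUPRC oracle: plain loop over distinct thresholds
brute_force_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# N50 oracle: accumulate sorted lengths until half the total is reached
brute_force_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s); acc <- 0
  for (x in s) {
    acc <- acc + x
    if (acc >= tot / 2) return(x)
  }
}

# random but reproducible alignment instance for pileup property tests:
# synthetic reads placed directly on a random contig (no genome layer)
random_pileup_instance <- function(seed) {
  set.seed(seed)
  L <- sample(200:2000, 1)
  n <- sample(5:50, 1)
  contig <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  rl <- sample(c(30L, 50L, 80L), 1)
  pos <- sample.int(L - rl + 1L, n, replace = TRUE)
  seqs <- vapply(pos, function(p) {
    s <- strsplit(substring(contig, p, p + rl - 1L), "")[[1]]
    nmut <- rbinom(1, rl, 0.05)
    if (nmut > 0) {
      at <- sample.int(rl, nmut)
      s[at] <- vapply(s[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    paste(s, collapse = "")
  }, "")
  is_orphan <- runif(n) < 0.2
  is_proper <- !is_orphan & runif(n) < 0.8
  is_disc <- !is_orphan & !is_proper
  ref <- strsplit(contig, "")[[1]]
  nm_pos <- lapply(seq_len(n), function(i) {
    chars <- strsplit(seqs[i], "")[[1]]
    span <- pos[i]:(pos[i] + rl - 1L)
    span[chars != ref[span]]
  })
  nmm <- lengths(nm_pos)
  al <- data.table::data.table(
    qname = paste0("r", seq_len(n)), mate = 1L, contig_id = "c",
    pos = pos, strand = "+", seq = seqs, qlen = rl,
    mate_pos = pos, nm_pos = nm_pos, n_mismatch = nmm,
    mapq = sample(c(1L, 42L), n, TRUE), al_score = -6 * nmm,
    isize = ifelse(is_proper, sample(150:400, n, TRUE), NA_integer_),
    is_proper = is_proper, is_orphan = is_orphan,
    is_discordant = is_disc)
  list(contig = contig, al = al)
}

# small model configuration for fast network tests
tiny_config <- function(Cin = 3L) {
  model_config(in_channels = Cin, initial_filters = 2L, initial_kernel = 3L,
               group_blocks = c(1L, 1L, 1L, 1L),
               group_filters = c(2L, 4L, 8L, 16L),
               kernel_size = 3L, dense_units = 4L, max_input_length = 500L)
}

# calibrate a freshly built model's batch-norm moving statistics with a few
# training-mode forward passes (no weight updates), so inference-mode
# activations are in a sane range even before any training
warm_model <- function(model, L = 450L, B = 4L, iters = 5L, seed = 1L) {
  set.seed(seed)
  C <- model$cfg$in_channels
  for (i in seq_len(iters)) {
    X <- matrix(rnorm(C * L * B), nrow = C)
    fwd <- model_forward(model, X, rep(L, B), training = TRUE)
    model$state[names(fwd$state_out)] <- fwd$state_out
  }
  model
}

# lightweight genome pool stub (ids only matter for community sampling)
stub_pool <- function(n) {
  lapply(seq_len(n), function(i)
    structure(list(id = sprintf("s%04d", i), sequence = "ACGTACGT",
                   taxon_tag = NA_character_), class = "reference_genome"))
}
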