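#' Inference configuration
#'
#' @param window_len chunk length in bp for long contigs.
#' @param chunk_overlap overlap between consecutive chunks in bp.
#' @param score_threshold score above which a contig is called misassembled.
#' @return An `inference_config`.
#' @export
inference_config <- function(window_len = 20000L, chunk_overlap = 500L,
                             score_threshold = 0.8) {
  stopifnot(chunk_overlap > 0, chunk_overlap < window_len,
            score_threshold > 0, score_threshold < 1)
  structure(list(window_len = as.integer(window_len),
                 chunk_overlap = as.integer(chunk_overlap),
                 score_threshold = score_threshold),
            class = "inference_config")
}

#' Split a contig into scoring chunks
#'
#' A contig at most `window_len` long is one chunk. Longer contigs are
#' covered by windows of `window_len` advancing by `window_len - overlap`,
#' with the final window anchored at the contig end (it may overlap its
#' predecessor by more than `overlap`), so the union of chunks always
#' covers every position.
#'
#' @param length contig length (bp).
#' @param window_len chunk length (bp).
#' @param overlap overlap between consecutive chunks (bp).
#' @return Integer matrix with columns `start`, `end` (1-based closed).
#' @export
chunk_contig <- function(length, window_len = 20000L, overlap = 500L) {
  stopifnot(length > 0)
  if (length <= window_len)
    return(cbind(start = 1L, end = as.integer(length)))
  stride <- window_len - overlap
  starts <- seq.int(1L, length - window_len, by = stride)
  last <- length - window_len + 1L
  if (utils::tail(starts, 1L) != last) starts <- c(starts, last)
  cbind(start = as.integer(starts),
        end = as.integer(starts + window_len - 1L))
}

#' Score contigs with a trained model
#'
#' Each contig is split into chunks ([chunk_contig()]), every chunk is
#' scored, and the contig score is the maximum over its chunks.
#'
#' @param model a `contiguard_model`.
#' @param store a `feature_store` of normalized matrices.
#' @param contig_ids contigs to score (default: all in the store).
#' @param config an [inference_config()].
#' @param batch_size chunks per forward pass.
#' @return A `data.table`: `contig_id`, `length`, `n_chunks`, `score`,
#'   with the per-chunk intervals and scores in the list columns `chunks`
#'   and `chunk_scores`.
#' @export
predict_contigs <- function(model, store, contig_ids = NULL,
                            config = inference_config(),
                            batch_size = 200L) {
  stopifnot(inherits(store, "feature_store"))
  if (is.null(contig_ids)) contig_ids <- names(store$matrices)
  missing_ids <- setdiff(contig_ids, names(store$matrices))
  if (length(missing_ids))
    stop("contig(s) not in store: ", paste(missing_ids, collapse = ", "))
  selected <- store$catalog$selected
  min_len <- min_input_length(model$cfg)

  # flatten all chunks, score in batches, then aggregate per contig
  chunk_tab <- data.table::rbindlist(lapply(contig_ids, function(id) {
    L <- nrow(store$matrices[[id]]$values)
    ch <- chunk_contig(L, config$window_len, config$chunk_overlap)
    data.table::data.table(contig_id = id, length = L,
                           start = ch[, "start"], end = ch[, "end"])
  }))
  mats <- lapply(seq_len(nrow(chunk_tab)), function(i)
    slice_matrix(store$matrices[[chunk_tab$contig_id[i]]],
                 c(chunk_tab$start[i], chunk_tab$end[i])))
  chunk_tab$score <- predict_matrices(model, mats, selected, min_len,
                                      batch_size)
  res <- chunk_tab[, .(
    length = length[1], n_chunks = .N, score = max(score),
    chunks = list(cbind(start = start, end = end)),
    chunk_scores = list(score)
  ), by = contig_id]
  res[match(contig_ids, res$contig_id)]
}

# ---- evaluation ----------------------------------------------------------

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) integration: scores are swept from high to
#' low over distinct values and each recall increment is weighted by the
#' precision at that threshold. The expected value for uninformative scores
#' equals the positive-class prevalence.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 truth labels.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels == 1)
  if (pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  # merge ties: keep the last entry of each distinct score
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / pos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Computed from the rank statistic (equivalent to the Mann-Whitney U),
#' with ties handled by mid-ranks.
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Precision-recall and ROC curves with areas
#'
#' @inheritParams auprc
#' @return List: `auprc`, `auroc` (NA when one class is absent), `pr`
#'   (data.frame of threshold, precision, recall), `roc` (data.frame of
#'   threshold, fpr, tpr).
#' @export
evaluate_scores <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == 0)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]; thr <- sc[keep]
  pr <- data.frame(threshold = thr, precision = tp / (tp + fp),
                   recall = if (pos > 0) tp / pos else NA_real_)
  roc <- data.frame(threshold = thr,
                    fpr = if (neg > 0) fp / neg else NA_real_,
                    tpr = if (pos > 0) tp / pos else NA_real_)
  list(auprc = auprc(scores, labels),
       auroc = if (pos > 0 && neg > 0) auroc(scores, labels) else NA_real_,
       pr = pr, roc = roc)
}

# ---- assembly reporting and filtering ------------------------------------

#' N50 of a set of contig lengths
#'
#' The length of the shortest contig among the largest contigs that
#' together contain at least half of the assembled bases.
#'
#' @param lengths positive contig lengths.
#' @return The N50 (a length present in `lengths`).
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Summary statistics of an assembly
#'
#' @param lengths contig lengths (bp).
#' @param labels optional 0/1 truth labels (misassembled = 1).
#' @return An `assembly_report`: list with `n_contigs`, `total_bases`,
#'   `n50`, `mean_length`, `median_length`, and with labels also
#'   `misassembly_rate` (fraction of contigs) and `misassemblies_length`
#'   (misassembled bases / total bases).
#' @export
assembly_report <- function(lengths, labels = NULL) {
  out <- list(n_contigs = length(lengths), total_bases = sum(lengths),
              n50 = n50(lengths), mean_length = mean(lengths),
              median_length = median(lengths))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(lengths))
    out$misassembly_rate <- mean(labels == 1)
    out$misassemblies_length <- sum(lengths[labels == 1]) / sum(lengths)
  }
  structure(out, class = "assembly_report")
}

#' Filter an assembly by misassembly score
#'
#' Discards contigs whose score strictly exceeds the threshold and reports
#' assembly statistics before and after. With truth labels the true error
#' rate of both sets is included.
#'
#' @param lengths contig lengths (bp).
#' @param scores per-contig scores.
#' @param threshold score threshold (default 0.8).
#' @param labels optional 0/1 truth labels.
#' @return List: `kept` (logical vector), `before`, `after` (two
#'   [assembly_report()]s).
#' @export
filter_assembly <- function(lengths, scores, threshold = 0.8,
                            labels = NULL) {
  stopifnot(length(lengths) == length(scores))
  kept <- scores <= threshold
  if (!any(kept)) stop("filtering removed every contig")
  list(kept = kept,
       before = assembly_report(lengths, labels),
       after = assembly_report(lengths[kept],
                               if (is.null(labels)) NULL else labels[kept]))
}

#' Estimate the misassembly rate of a contig set
#'
#' The fraction of contigs scoring strictly above the threshold.
#'
#' @param scores per-contig scores (non-empty).
#' @param threshold score threshold (default 0.8).
#' @return Fraction in `[0, 1]`.
#' @export
estimate_misassembly_rate <- function(scores, threshold = 0.8) {
  if (length(scores) == 0) stop("no scores")
  mean(scores > threshold)
}

#' Rank assemblies by estimated misassembly rate
#'
#' @param estimated per-assembly estimated misassembly rates (named).
#' @param true_rates optional true rates for correlation.
#' @return List: `ranking` (assembly order, best first), `estimated`, and
#'   with truth `pearson` and `spearman` correlations.
#' @export
rank_assemblies <- function(estimated, true_rates = NULL) {
  stopifnot(length(estimated) >= 2)
  ord <- order(estimated)
  out <- list(ranking = if (is.null(names(estimated))) ord else
    names(estimated)[ord], estimated = estimated)
  if (!is.null(true_rates)) {
    if (length(true_rates) != length(estimated))
      stop("estimated and true rate vectors differ in length")
    out$pearson <- cor(estimated, true_rates, method = "pearson")
    out$spearman <- cor(estimated, true_rates, method = "spearman")
  }
  out
}

#' Insert-size applicability guard
#'
#' A dataset is flagged for exclusion when the 0.05 or 0.95 quantile of its
#' observed proper-pair insert sizes lies outside the training bounds
#' (closed interval). On exclusion a warning explains that predictions may
#' be less accurate.
#'
#' @param profile output of [insert_size_profile()].
#' @param bounds training applicability bounds (defaults 117 and 493).
#' @return `"pass"` or `"exclude"` (invisibly returns the decision and
#'   warns on exclusion).
#' @export
insert_size_guard <- function(profile, bounds = c(117, 493)) {
  excl <- profile$q05 < bounds[1] || profile$q95 > bounds[2]
  if (excl)
    warning(sprintf(paste0(
      "insert-size distribution (q05 = %.0f, q95 = %.0f) lies outside ",
      "the training range [%.0f, %.0f]; predictions may be less accurate"),
      profile$q05, profile$q95, bounds[1], bounds[2]))
  if (excl) "exclude" else "pass"
}
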