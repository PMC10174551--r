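#' Fit standardization statistics on training feature matrices
#'
#' Computes per-channel mean and standard deviation over all *covered*
#' positions of all training contigs, for every non-count channel (count
#' channels are coverage-normalized instead and carry no statistics). A
#' channel with zero variance (or a single observation) stores `sd = 1`
#' with a warning, so that standardizing a constant channel yields zeros.
#'
#' @param matrices list of raw `feature_matrix` objects (training data).
#' @param catalog a [feature_catalog()].
#' @return A `feature_stats`: list with `mean`, `sd` (named numeric
#'   vectors) and `channels`.
#' @export
fit_normalization <- function(matrices, catalog = feature_catalog()) {
  if (inherits(matrices, "feature_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1)
  chans <- numeric_channels(catalog)
  stacked <- do.call(rbind, lapply(matrices, function(m)
    m$values[m$mask, chans, drop = FALSE]))
  if (nrow(stacked) == 0) stop("no covered positions in training data")
  mu <- colMeans(stacked, na.rm = TRUE)
  sdv <- apply(stacked, 2, sd, na.rm = TRUE)
  degenerate <- !is.finite(sdv) | sdv == 0
  if (any(degenerate)) {
    warning("zero-variance channel(s), storing sd = 1: ",
            paste(chans[degenerate], collapse = ", "))
    sdv[degenerate] <- 1
  }
  mu[!is.finite(mu)] <- 0
  structure(list(mean = mu, sd = sdv, channels = chans),
            class = "feature_stats")
}

#' Write / read standardization statistics
#'
#' Serialization round-trips exactly (bitwise-identical transforms).
#'
#' @param stats a `feature_stats`.
#' @param path file path.
#' @return `read_feature_stats` returns the `feature_stats`.
#' @export
write_feature_stats <- function(stats, path) {
  stopifnot(inherits(stats, "feature_stats"))
  saveRDS(stats, path)
  invisible(path)
}

#' @rdname write_feature_stats
#' @export
read_feature_stats <- function(path) {
  stats <- readRDS(path)
  stopifnot(inherits(stats, "feature_stats"))
  stats
}

#' Apply preprocessing to a raw feature matrix
#'
#' Count channels are divided position-wise by coverage (giving values in
#' `[0, 1]`); non-count channels are standardized with the training mean
#' and sd; missing values (uncovered positions, undefined statistics) become
#' 0 — the new mean — and rows with zero coverage are entirely zero.
#'
#' @param matrix a raw `feature_matrix`.
#' @param stats a `feature_stats` from [fit_normalization()].
#' @param catalog a [feature_catalog()].
#' @return A normalized `feature_matrix` (with `normalized = TRUE`).
#' @export
apply_normalization <- function(matrix, stats, catalog = feature_catalog()) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(stats, "feature_stats"))
  vals <- matrix$values
  cov <- matrix$coverage
  cc <- count_channels(catalog)
  nc <- numeric_channels(catalog)
  if (!all(nc %in% names(stats$mean)))
    stop("stats do not cover all non-count channels")
  covered <- cov > 0
  covdiv <- ifelse(covered, cov, 1)
  vals[, cc] <- vals[, cc, drop = FALSE] / covdiv
  vals[, nc] <- sweep(sweep(vals[, nc, drop = FALSE], 2, stats$mean[nc]),
                      2, stats$sd[nc], "/")
  vals[is.na(vals)] <- 0
  vals[!covered, ] <- 0
  out <- matrix
  out$values <- vals
  out$normalized <- TRUE
  out
}

#' An in-memory feature store with serialization
#'
#' Bundles normalized (or raw) feature matrices with the catalog, the
#' standardization statistics and the truth labels, and supports random
#' access by contig id and position window. [feature_store_write()] /
#' [feature_store_read()] round-trip the store losslessly through a single
#' serialized file.
#'
#' @param matrices named list of `feature_matrix` objects (names = contig
#'   ids; taken from the matrices when unnamed).
#' @param labels optional named integer vector of truth labels (0/1).
#' @param catalog a [feature_catalog()].
#' @param stats optional `feature_stats`.
#' @param breakpoints optional named list of integer breakpoint vectors.
#' @param insert_profile optional [insert_size_profile()] of the dataset.
#' @return A `feature_store`.
#' @export
feature_store <- function(matrices, labels = NULL,
                          catalog = feature_catalog(), stats = NULL,
                          breakpoints = NULL, insert_profile = NULL) {
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, `[[`, "", "contig_id")
  structure(list(matrices = matrices, labels = labels, catalog = catalog,
                 stats = stats, breakpoints = breakpoints,
                 insert_profile = insert_profile),
            class = "feature_store")
}

#' @param store a `feature_store`.
#' @param path file path.
#' @rdname feature_store
#' @export
feature_store_write <- function(store, path) {
  stopifnot(inherits(store, "feature_store"))
  saveRDS(store, path)
  invisible(path)
}

#' @param contig_ids optional character vector restricting the read.
#' @param window optional `c(start, end)` (1-based closed) row window
#'   applied to every returned matrix.
#' @rdname feature_store
#' @export
feature_store_read <- function(path, contig_ids = NULL, window = NULL) {
  store <- readRDS(path)
  stopifnot(inherits(store, "feature_store"))
  if (!is.null(contig_ids)) {
    missing_ids <- setdiff(contig_ids, names(store$matrices))
    if (length(missing_ids))
      stop("contig(s) not in store: ", paste(missing_ids, collapse = ", "))
    store$matrices <- store$matrices[contig_ids]
    if (!is.null(store$labels)) store$labels <- store$labels[contig_ids]
    if (!is.null(store$breakpoints))
      store$breakpoints <- store$breakpoints[contig_ids]
  }
  if (!is.null(window)) {
    store$matrices <- lapply(store$matrices, function(m) {
      rows <- window[1]:min(window[2], nrow(m$values))
      m$values <- m$values[rows, , drop = FALSE]
      m$coverage <- m$coverage[rows]
      m$mask <- m$mask[rows]
      m
    })
  }
  store
}

#' Slice a window out of one stored matrix
#'
#' @param store a `feature_store`.
#' @param contig_id contig to slice.
#' @param window `c(start, end)`, 1-based closed.
#' @return The sliced `feature_matrix`.
#' @export
store_window <- function(store, contig_id, window) {
  if (!contig_id %in% names(store$matrices))
    stop("contig not in store: ", contig_id)
  m <- store$matrices[[contig_id]]
  rows <- window[1]:min(window[2], nrow(m$values))
  m$values <- m$values[rows, , drop = FALSE]
  m$coverage <- m$coverage[rows]
  m$mask <- m$mask[rows]
  m
}
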