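#' Assign bins to clusters from fitted factors
#'
#' Each bin (row of `U(t)`) is assigned to its most dominant latent
#' feature: `c_i(t) = argmax_j U(t)[i, j]`. Ties are broken by the smallest
#' column index. Rows whose entries are all at (or below) the HALS floor,
#' including masked bins, are reported as unassigned (`NA`).
#'
#' @param factors A `FactorSet` from [mvnmf_fit()].
#' @param task Task index in `1..T`.
#' @param chrom,bin_size Optional bin metadata carried into the track.
#' @return A `ClusterTrack`: list with `labels` (integer vector, `NA` =
#'   unassigned), `k`, `chrom`, `bin_size`.
#' @export
assign_clusters <- function(factors, task, chrom = NA_character_,
                            bin_size = 10000L) {
  if (task < 1 || task > factors$tasks) {
    stop("task index out of range", call. = FALSE)
  }
  u <- factors$U[[task]]
  eps <- 1e-16
  labels <- apply(u, 1L, which.max)   # which.max ties -> smallest index
  dead <- apply(u, 1L, function(r) all(r <= eps))
  if (!is.null(factors$mask)) dead <- dead | factors$mask
  labels[dead] <- NA_integer_
  structure(list(labels = as.integer(labels), k = factors$rank,
                 chrom = chrom, bin_size = as.integer(bin_size)),
            class = "ClusterTrack")
}

#' Call dynamic and static blocks from two cluster tracks
#'
#' Scans the two per-bin label sequences for maximal runs over which both
#' labels are constant. A run of at least `min_bins` bins where the two
#' conditions disagree is a dynamic block; one where they agree is a static
#' block. Runs shorter than `min_bins`, and bins that are unassigned in
#' either track, form the noise set: every bin belongs to exactly one of a
#' dynamic block, a static block, or the noise set. At the default 10 kb
#' bin size, `min_bins = 5` corresponds to the 50 kb minimum block span.
#'
#' @param track_a,track_b `ClusterTrack` objects of equal length for the
#'   same chromosome and bin size.
#' @param min_bins Minimum run length in bins (default 5).
#' @return A data.frame of blocks with columns `chrom`, `start_bin`,
#'   `end_bin` (inclusive, 1-based), `start`, `end` (bp), `kind`
#'   (`"dynamic"`/`"static"`), `label_a`, `label_b`, `span`; plus attribute
#'   `"noise_bins"` (integer vector of noise bin indices).
#' @export
call_blocks <- function(track_a, track_b, min_bins = 5L) {
  a <- track_a$labels
  b <- track_b$labels
  if (length(a) != length(b)) {
    stop("cluster tracks have different lengths", call. = FALSE)
  }
  if (!identical(track_a$bin_size, track_b$bin_size)) {
    stop("cluster tracks have different bin sizes", call. = FALSE)
  }
  bin_size <- track_a$bin_size
  chrom <- track_a$chrom
  n <- length(a)
  # runs over the joint (a, b) label pair; unassigned bins break runs
  key <- ifelse(is.na(a) | is.na(b), NA_character_, paste(a, b))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  noise <- integer(0)
  for (i in seq_along(r$lengths)) {
    if (is.na(r$values[i]) || r$lengths[i] < min_bins) {
      noise <- c(noise, seq.int(starts[i], ends[i]))
      next
    }
    la <- a[starts[i]]; lb <- b[starts[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start_bin = starts[i], end_bin = ends[i],
      start = (starts[i] - 1L) * as.numeric(bin_size),
      end = ends[i] * as.numeric(bin_size),
      kind = if (la == lb) "static" else "dynamic",
      label_a = la, label_b = lb,
      span = r$lengths[i] * as.numeric(bin_size),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start_bin = integer(),
               end_bin = integer(), start = numeric(), end = numeric(),
               kind = character(), label_a = integer(), label_b = integer(),
               span = numeric(), stringsAsFactors = FALSE)
  attr(out, "noise_bins") <- noise
  out
}

#' Count-difference statistics for called blocks
#'
#' For every block, collects all contact counts over bin pairs `(i, j)`,
#' `i <= j`, inside the block in each condition, and reports the sum of
#' absolute count differences, a two-sample t-test p-value, and an unpaired
#' Wilcoxon rank-sum p-value comparing the two count samples. Dynamic
#' blocks are expected to show larger differences than static blocks when
#' the underlying organization truly changed. Diagonal pairs are included
#' by default (`include_diagonal = FALSE` restricts to off-diagonal pairs).
#'
#' @param blocks Block table from [call_blocks()].
#' @param X_a,X_b The two conditions' [contact_matrix()] objects.
#' @param include_diagonal Include `i == j` pairs (default TRUE).
#' @return `blocks` with columns `abs_count_diff_sum`, `t_test_p`,
#'   `rank_sum_p` appended.
#' @export
block_count_stats <- function(blocks, X_a, X_b, include_diagonal = TRUE) {
  ca <- if (is_contact_matrix(X_a)) X_a$counts else as.matrix(X_a)
  cb <- if (is_contact_matrix(X_b)) X_b$counts else as.matrix(X_b)
  n <- nrow(ca)
  res <- blocks
  res$abs_count_diff_sum <- NA_real_
  res$t_test_p <- NA_real_
  res$rank_sum_p <- NA_real_
  for (i in seq_len(nrow(blocks))) {
    s <- blocks$start_bin[i]; e <- blocks$end_bin[i]
    if (s < 1 || e > n) stop("block lies outside the matrix", call. = FALSE)
    idx <- s:e
    ut <- upper.tri(ca[idx, idx, drop = FALSE], diag = include_diagonal)
    va <- ca[idx, idx, drop = FALSE][ut]
    vb <- cb[idx, idx, drop = FALSE][ut]
    res$abs_count_diff_sum[i] <- sum(abs(va - vb))
    res$t_test_p[i] <- tryCatch(stats::t.test(va, vb)$p.value,
                                error = function(e) NA_real_)
    res$rank_sum_p[i] <- tryCatch(
      suppressWarnings(stats::wilcox.test(va, vb)$p.value),
      error = function(e) NA_real_)
  }
  res
}
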