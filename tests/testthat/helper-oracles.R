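# independent brute-force oracles, deliberately written as plain loops

# per-row sort oracle for knn localization
oracle_knn <- function(w, k) {
  n <- nrow(w)
  p <- matrix(0, n, n)
  for (i in 1:n) {
    row <- w[i, ]
    row[i] <- 0
    if (all(row == 0)) next
    ord <- order(-row, seq_len(n))[1:k]
    ord <- ord[row[ord] > 0]
    p[i, ord] <- row[ord] / sum(row[ord])
  }
  p
}

# term-by-term objective summation over every matrix entry
oracle_objective <- function(X, U, V, Vc, alpha) {
  total <- 0
  for (t in seq_along(X)) {
    R <- X[[t]] - U[[t]] %*% t(V[[t]])
    for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
      total <- total + R[i, j]^2
    }
    D <- V[[t]] - Vc
    for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) {
      total <- total + alpha * D[i, j]^2
    }
  }
  total
}

# exhaustive pair-counting Rand index
oracle_rand_index <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1L
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1L
  }
  agree / total
}

# run-length enumeration of block calls
oracle_blocks <- function(a, b, min_bins = 5) {
  n <- length(a)
  kinds <- rep(NA_character_, n)
  i <- 1
  out <- list()
  while (i <= n) {
    if (is.na(a[i]) || is.na(b[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(a[j + 1]) && !is.na(b[j + 1]) &&
           a[j + 1] == a[i] && b[j + 1] == b[i]) j <- j + 1
    if (j - i + 1 >= min_bins) {
      out[[length(out) + 1]] <- data.frame(
        start_bin = i, end_bin = j,
        kind = if (a[i] == b[i]) "static" else "dynamic",
        label_a = a[i], label_b = b[i])
    }
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# per-stratum mean/sd enumeration of the z filter
oracle_zfilter <- function(rec, stratum_width = 50000, max_distance = 1e6,
                           z_min = 1) {
  keep_rows <- integer(0)
  zs <- numeric(0)
  rec$.row <- seq_len(nrow(rec))
  rec <- rec[rec$distance <= max_distance, , drop = FALSE]
  n_strata <- ceiling(max_distance / stratum_width)
  for (dir in unique(rec$direction)) {
    for (s in 0:(n_strata - 1)) {
      lo <- s * stratum_width
      hi <- lo + stratum_width
      in_s <- rec$direction == dir &
        ((rec$distance >= lo & rec$distance < hi) |
           (s == n_strata - 1 & rec$distance == max_distance))
      idx <- rec$.row[in_s]
      if (length(idx) == 0) next
      sub <- rec[in_s, , drop = FALSE]
      delta <- ifelse(sub$direction == "within_higher",
                      sub$count_within - sub$count_outside,
                      sub$count_outside - sub$count_within)
      if (length(idx) < 2) {
        keep_rows <- c(keep_rows, idx)
        zs <- c(zs, NA_real_)
        next
      }
      sdv <- sd(delta)
      if (sdv == 0) next
      z <- (delta - mean(delta)) / sdv
      sel <- z > z_min
      keep_rows <- c(keep_rows, idx[sel])
      zs <- c(zs, z[sel])
    }
  }
  ord <- order(keep_rows)
  list(rows = keep_rows[ord], z = zs[ord])
}

# exhaustive double loop over (gene bin, record anchor) combinations
oracle_link_genes <- function(records, genes, bin_size = 10000) {
  hits <- list()
  for (gi in seq_len(nrow(genes))) {
    gb <- seq(floor(genes$start[gi] / bin_size),
              floor((genes$end[gi] - 1) / bin_size)) * bin_size
    for (ri in seq_len(nrow(records))) {
      if (records$chrom[ri] != genes$chrom[gi]) next
      for (anchor in c("bin1", "bin2")) {
        if (records[[anchor]][ri] %in% gb) {
          hits[[length(hits) + 1]] <- data.frame(
            gene_name = genes$gene_name[gi],
            gene_bin = records[[anchor]][ri],
            bin1 = records$bin1[ri], bin2 = records$bin2[ri])
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  unique(do.call(rbind, hits))
}

# exhaustive triple loop for locus -> record -> gene links
oracle_map_loci <- function(loci, records, genes, bin_size = 10000) {
  hits <- list()
  for (li in seq_len(nrow(loci))) {
    lb <- seq(floor(loci$start[li] / bin_size),
              floor((loci$end[li] - 1) / bin_size)) * bin_size
    for (ri in seq_len(nrow(records))) {
      if (records$chrom[ri] != loci$chrom[li]) next
      for (anchor in c("bin1", "bin2")) {
        if (!records[[anchor]][ri] %in% lb) next
        other <- if (anchor == "bin1") records$bin2[ri] else records$bin1[ri]
        for (gi in seq_len(nrow(genes))) {
          if (genes$chrom[gi] != records$chrom[ri]) next
          gb <- seq(floor(genes$start[gi] / bin_size),
                    floor((genes$end[gi] - 1) / bin_size)) * bin_size
          if (other %in% gb) {
            hits[[length(hits) + 1]] <- data.frame(
              snp_name = loci$snp_name[li],
              locus_bin = records[[anchor]][ri],
              gene_name = genes$gene_name[gi],
              gene_bin = other,
              condition = if (records$direction[ri] == "within_higher")
                "within" else "outside")
          }
        }
      }
    }
  }
  if (!length(hits)) return(NULL)
  unique(do.call(rbind, hits))
}
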