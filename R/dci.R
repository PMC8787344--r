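#' Build the differential-interaction union from two external callers
#'
#' Differential chromatin interactions (DCIs) are assembled as the union of
#' two sources: Selfish-style records kept at `p < selfish_p`, and
#' Fit-Hi-C-style differentials, defined as bin pairs significant
#' (`q < fithic_q`) in exactly one of the two conditions. The union is
#' deduplicated on the bin pair, with `source = "both"` on overlap, and the
#' direction of each record is set by the larger count
#' (`within_higher` / `outside_higher`). Self-pairs (`bin1 == bin2`) are
#' excluded: a self-pair is not a loop.
#'
#' @param selfish_records data.frame with columns `chrom`, `bin1`, `bin2`,
#'   `count_within`, `count_outside`, `p_value`.
#' @param fithic_within,fithic_outside data.frames with columns `chrom`,
#'   `bin1`, `bin2`, `count_within`, `count_outside`, `q_value` — each
#'   condition's significance calls.
#' @param selfish_p Selfish p-value cutoff (default 1e-4).
#' @param fithic_q Fit-Hi-C q-value cutoff (default 0.05).
#' @param bin_size Bin width in bp (default 10000).
#' @return data.frame of `InteractionRecord`s: `chrom`, `bin1`, `bin2`
#'   (bin start coordinates, `bin1 <= bin2`), `distance`, `count_within`,
#'   `count_outside`, `direction`, `source`, `z` (NA until [zfilter()]).
#' @export
union_dcis <- function(selfish_records, fithic_within, fithic_outside,
                       selfish_p = 1e-4, fithic_q = 0.05, bin_size = 10000L) {
  need <- function(df, col, what) {
    if (!col %in% names(df)) {
      stop("missing column '", col, "' in ", what, " table", call. = FALSE)
    }
  }
  canon <- function(df) {
    lo <- pmin(df$bin1, df$bin2); hi <- pmax(df$bin1, df$bin2)
    df$bin1 <- lo; df$bin2 <- hi
    df[df$bin1 != df$bin2, , drop = FALSE]
  }
  cols <- c("chrom", "bin1", "bin2", "count_within", "count_outside")

  need(selfish_records, "p_value", "selfish")
  for (cc in cols) need(selfish_records, cc, "selfish")
  sel <- canon(selfish_records[selfish_records$p_value < selfish_p, ,
                               drop = FALSE])

  need(fithic_within, "q_value", "fithic_within")
  need(fithic_outside, "q_value", "fithic_outside")
  for (cc in cols) {
    need(fithic_within, cc, "fithic_within")
    need(fithic_outside, cc, "fithic_outside")
  }
  fw <- canon(fithic_within[fithic_within$q_value < fithic_q, , drop = FALSE])
  fo <- canon(fithic_outside[fithic_outside$q_value < fithic_q, ,
                             drop = FALSE])
  pkey <- function(df) paste(df$chrom, df$bin1, df$bin2)
  # significant in one condition but not the other
  fit <- rbind(fw[!pkey(fw) %in% pkey(fo), cols, drop = FALSE],
               fo[!pkey(fo) %in% pkey(fw), cols, drop = FALSE])

  sel <- sel[, cols, drop = FALSE]
  sel$source <- if (nrow(sel)) "selfish" else character(0)
  fit$source <- if (nrow(fit)) "fithic" else character(0)
  all <- rbind(sel, fit)
  if (nrow(all) == 0) {
    return(data.frame(chrom = character(), bin1 = numeric(), bin2 = numeric(),
                      distance = numeric(), count_within = numeric(),
                      count_outside = numeric(), direction = character(),
                      source = character(), z = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- pkey(all)
  first <- !duplicated(key)
  dup_sources <- tapply(all$source, key, function(s) {
    if (length(unique(s)) > 1) "both" else s[1]
  })
  out <- all[first, , drop = FALSE]
  out$source <- as.character(dup_sources[pkey(out)])
  out$distance <- abs(out$bin2 - out$bin1)
  out$direction <- ifelse(out$count_within >= out$count_outside,
                          "within_higher", "outside_higher")
  out$z <- NA_real_
  rownames(out) <- NULL
  out[, c("chrom", "bin1", "bin2", "distance", "count_within",
          "count_outside", "direction", "source", "z")]
}

# half-open 50 kb strata [d, d + w) with the final stratum closed at
# max_distance, so distance == 1 Mb falls in the last stratum
stratum_index <- function(distance, stratum_width, max_distance) {
  n_strata <- ceiling(max_distance / stratum_width)
  pmin(floor(distance / stratum_width), n_strata - 1L)
}

#' Distance-stratified z-score filter for differential interactions
#'
#' Records farther apart than `max_distance` are dropped. The remaining
#' records are grouped by direction and by distance stratum
#' (`stratum_width` intervals, half-open, with the final stratum closed at
#' `max_distance`). Within each group the favored-direction count
#' difference `delta` (`count_within - count_outside` for `within_higher`
#' records, reversed otherwise) is standardized, `z = (delta - mean) / sd`,
#' and only records with `z > z_min` are kept (`two_sided = TRUE` keeps
#' `|z| > z_min`). Groups with fewer than 2 records pass through unfiltered
#' with `z` unset; groups with zero spread drop all their records (the
#' z-score is undefined). Both situations are reported via `message()`.
#' The filter is a strict subset operation but not idempotent: re-running
#' it recomputes stratum statistics on the survivors.
#'
#' @param records Interaction table from [union_dcis()].
#' @param stratum_width Distance stratum width in bp (default 50000).
#' @param max_distance Maximum genomic distance in bp (default 1e6).
#' @param z_min z-score threshold (default 1.0).
#' @param two_sided Threshold `|z|` instead of `z` (default FALSE).
#' @return The surviving records with their `z` values filled in, plus a
#'   `"stratum_stats"` attribute (per-group mean/sd table).
#' @export
zfilter <- function(records, stratum_width = 50000, max_distance = 1e6,
                    z_min = 1.0, two_sided = FALSE) {
  rec <- records[records$distance <= max_distance, , drop = FALSE]
  if (nrow(rec) == 0) {
    rec$z <- numeric(0)
    return(rec)
  }
  delta <- ifelse(rec$direction == "within_higher",
                  rec$count_within - rec$count_outside,
                  rec$count_outside - rec$count_within)
  stratum <- stratum_index(rec$distance, stratum_width, max_distance)
  grp <- paste(rec$direction, stratum)
  keep <- logical(nrow(rec))
  zval <- rep(NA_real_, nrow(rec))
  stats_rows <- list()
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 2) {
      message("zfilter: stratum '", g,
              "' has < 2 records; passed through unfiltered")
      keep[sel] <- TRUE
      next
    }
    mu <- mean(delta[sel])
    sdv <- stats::sd(delta[sel])
    stats_rows[[g]] <- data.frame(group = g, n = length(sel), mean = mu,
                                  sd = sdv, stringsAsFactors = FALSE)
    if (sdv == 0) {
      message("zfilter: stratum '", g,
              "' has zero spread; all records dropped")
      next
    }
    z <- (delta[sel] - mu) / sdv
    zval[sel] <- z
    keep[sel] <- if (two_sided) abs(z) > z_min else z > z_min
  }
  out <- rec[keep, , drop = FALSE]
  out$z <- zval[keep]
  rownames(out) <- NULL
  attr(out, "stratum_stats") <- if (length(stats_rows))
    do.call(rbind, c(stats_rows, make.row.names = FALSE)) else NULL
  out
}

# genomic interval [start, end) -> the 10 kb bin start coordinates it touches
interval_bins <- function(start, end, bin_size) {
  if (end <= start) stop("interval with end <= start", call. = FALSE)
  seq(floor(start / bin_size), floor((end - 1) / bin_size)) * bin_size
}

#' Link interaction anchors to genes
#'
#' Each gene is rasterized to the set of fixed-size bins intersecting its
#' `[start, end)` interval (a gene touching a bin by at least 1 bp claims
#' it). A record links to a gene when either of its anchor bins lies in the
#' gene's bin set; the opposite anchor is reported as the putative
#' regulatory end. Per-gene DCI counts are derivable from the output (e.g.
#' to select genes associated with 5 or more same-direction DCIs).
#'
#' @param records Interaction table ([union_dcis()] / [zfilter()] output).
#' @param genes Gene annotation data.frame from [read_genes()] (columns
#'   `chrom`, `start`, `end`, `gene_name`, optionally `de_label`).
#' @param bin_size Bin width in bp (default 10000).
#' @return data.frame with one row per (gene, record, anchor) link:
#'   `gene_name`, `chrom`, `gene_bin` (the anchor overlapping the gene),
#'   `regulatory_bin` (the other anchor), `bin1`, `bin2`, `distance`,
#'   `count_within`, `count_outside`, `direction`.
#' @export
link_genes <- function(records, genes, bin_size = 10000L) {
  if (any(genes$end <= genes$start)) {
    stop("gene with end <= start in annotation", call. = FALSE)
  }
  out <- list()
  for (gi in seq_len(nrow(genes))) {
    gbins <- interval_bins(genes$start[gi], genes$end[gi], bin_size)
    on_chrom <- records$chrom == genes$chrom[gi]
    hit1 <- on_chrom & records$bin1 %in% gbins
    hit2 <- on_chrom & records$bin2 %in% gbins
    for (spec in list(list(hit = hit1, gene_end = "bin1", reg_end = "bin2"),
                      list(hit = hit2, gene_end = "bin2", reg_end = "bin1"))) {
      idx <- which(spec$hit)
      if (!length(idx)) next
      out[[length(out) + 1L]] <- data.frame(
        gene_name = genes$gene_name[gi],
        chrom = records$chrom[idx],
        gene_bin = records[[spec$gene_end]][idx],
        regulatory_bin = records[[spec$reg_end]][idx],
        bin1 = records$bin1[idx], bin2 = records$bin2[idx],
        distance = records$distance[idx],
        count_within = records$count_within[idx],
        count_outside = records$count_outside[idx],
        direction = records$direction[idx],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(gene_name = character(), chrom = character(),
                      gene_bin = numeric(), regulatory_bin = numeric(),
                      bin1 = numeric(), bin2 = numeric(),
                      distance = numeric(), count_within = numeric(),
                      count_outside = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  unique(res)
}

#' Distance-stratified mean count difference between gene sets
#'
#' For interactions linked to two disjoint gene sets (e.g. genes
#' up-regulated within vs outside the condition of interest), computes the
#' mean per-interaction count difference `count_within - count_outside` in
#' each distance stratum for each set, and an overall two-sample t-test
#' between the two sets' per-interaction differences.
#'
#' @param gene_links Link table from [link_genes()].
#' @param gene_set_up_within,gene_set_up_outside Disjoint character vectors
#'   of gene names.
#' @param stratum_width Distance stratum width in bp (default 50000).
#' @param max_distance Maximum distance for stratification (default 1e6).
#' @return List with `strata` (data.frame: stratum bounds, per-set mean
#'   difference and n; `NA` mean for empty strata) and `t_test_p`.
#' @export
distance_stratified_mean_diff <- function(gene_links, gene_set_up_within,
                                          gene_set_up_outside,
                                          stratum_width = 50000,
                                          max_distance = 1e6) {
  if (length(intersect(gene_set_up_within, gene_set_up_outside)) > 0) {
    stop("gene sets must be disjoint", call. = FALSE)
  }
  gl <- gene_links[gene_links$distance <= max_distance, , drop = FALSE]
  gl$diff <- gl$count_within - gl$count_outside
  gl$set <- ifelse(gl$gene_name %in% gene_set_up_within, "up_within",
                   ifelse(gl$gene_name %in% gene_set_up_outside,
                          "up_outside", NA))
  gl <- gl[!is.na(gl$set), , drop = FALSE]
  n_strata <- ceiling(max_distance / stratum_width)
  gl$stratum <- stratum_index(gl$distance, stratum_width, max_distance)
  strata <- data.frame(stratum = seq_len(n_strata) - 1L)
  strata$dist_lo <- strata$stratum * stratum_width
  strata$dist_hi <- pmin(strata$dist_lo + stratum_width, max_distance)
  for (s in c("up_within", "up_outside")) {
    m <- rep(NA_real_, n_strata)
    cnt <- rep(0L, n_strata)
    for (i in seq_len(n_strata)) {
      v <- gl$diff[gl$set == s & gl$stratum == strata$stratum[i]]
      cnt[i] <- length(v)
      if (length(v)) m[i] <- mean(v)
    }
    strata[[paste0("mean_diff_", s)]] <- m
    strata[[paste0("n_", s)]] <- cnt
  }
  x <- gl$diff[gl$set == "up_within"]
  y <- gl$diff[gl$set == "up_outside"]
  # degenerate zero-variance samples: identical means carry no evidence of
  # a difference (p = 1); distinct constant means are trivially separated
  p <- tryCatch(stats::t.test(x, y)$p.value, error = function(e) NaN)
  if (is.nan(p) && length(x) && length(y)) {
    p <- if (mean(x) == mean(y)) 1 else 0
  }
  list(strata = strata, t_test_p = p)
}

#' Map GWAS loci onto interaction anchors and their gene partners
#'
#' A (lifted-over) locus matches an interaction when its interval
#' intersects either anchor bin `[bin, bin + bin_size)`. The opposite
#' anchor is then linked to genes by the [link_genes()] rasterization, and
#' each resulting locus-gene pair is reported with the condition implied by
#' the record's direction. Gene names are matched case-insensitively on
#' their common name. Loci on chromosomes absent from the records are
#' skipped with a message.
#'
#' @param loci data.frame from [read_loci()] (`chrom`, `start`, `end`,
#'   `snp_name`).
#' @param records Interaction table ([zfilter()] output).
#' @param genes Gene annotation data.frame.
#' @param bin_size Bin width in bp (default 10000).
#' @return data.frame of locus-gene links: `snp_name`, `chrom`,
#'   `locus_bin`, `gene_name`, `gene_bin`, `condition`
#'   (`"within"`/`"outside"`).
#' @export
map_loci <- function(loci, records, genes, bin_size = 10000L) {
  out <- list()
  for (li in seq_len(nrow(loci))) {
    if (!loci$chrom[li] %in% records$chrom) {
      message("map_loci: locus '", loci$snp_name[li], "' on chromosome '",
              loci$chrom[li], "' absent from records; skipped")
      next
    }
    lbins <- interval_bins(loci$start[li], loci$end[li], bin_size)
    on_chrom <- records$chrom == loci$chrom[li]
    for (spec in list(c(locus = "bin1", other = "bin2"),
                      c(locus = "bin2", other = "bin1"))) {
      idx <- which(on_chrom & records[[spec[["locus"]]]] %in% lbins)
      for (ri in idx) {
        other_bin <- records[[spec[["other"]]]][ri]
        gsel <- genes[genes$chrom == records$chrom[ri], , drop = FALSE]
        for (gi in seq_len(nrow(gsel))) {
          gbins <- interval_bins(gsel$start[gi], gsel$end[gi], bin_size)
          if (other_bin %in% gbins) {
            out[[length(out) + 1L]] <- data.frame(
              snp_name = loci$snp_name[li],
              chrom = records$chrom[ri],
              locus_bin = records[[spec[["locus"]]]][ri],
              gene_name = gsel$gene_name[gi],
              gene_bin = other_bin,
              condition = if (records$direction[ri] == "within_higher")
                "within" else "outside",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(snp_name = character(), chrom = character(),
                      locus_bin = numeric(), gene_name = character(),
                      gene_bin = numeric(), condition = character(),
                      stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
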