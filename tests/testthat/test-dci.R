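mk_selfish <- function(bin1, bin2, p, cw = 10, co = 5, chrom = "chr1") {
  data.frame(chrom = chrom, bin1 = bin1, bin2 = bin2, count_within = cw,
             count_outside = co, p_value = p, stringsAsFactors = FALSE)
}
mk_fithic <- function(bin1, bin2, q, cw = 10, co = 5, chrom = "chr1") {
  data.frame(chrom = chrom, bin1 = bin1, bin2 = bin2, count_within = cw,
             count_outside = co, q_value = q, stringsAsFactors = FALSE)
}

test_that("union_dcis deduplicates overlapping sources as 'both'", {
  sel <- mk_selfish(0, 50000, 1e-6)
  fw <- mk_fithic(0, 50000, 0.01)
  fo <- mk_fithic(0, 50000, 0.9)   # not significant outside
  u <- union_dcis(sel, fw, fo)
  expect_equal(nrow(u), 1)
  expect_equal(u$source, "both")
  expect_equal(u$direction, "within_higher")
  expect_equal(u$distance, 50000)
})

test_that("pairs significant in both conditions are not differential", {
  sel <- mk_selfish(0, 50000, 0.5)        # fails selfish cutoff
  fw <- mk_fithic(0, 50000, 0.01)
  fo <- mk_fithic(0, 50000, 0.02)         # significant in both
  u <- union_dcis(sel, fw, fo)
  expect_equal(nrow(u), 0)
})

test_that("union size equals a brute-force set union over pair keys", {
  set.seed(91)
  n <- 50
  bins <- sample(seq(0, 5e5, 1e4), n, replace = TRUE)
  offs <- sample(seq(1e4, 3e5, 1e4), n, replace = TRUE)
  sel <- mk_selfish(bins, bins + offs, runif(n, 0, 2e-4))
  fw <- mk_fithic(bins + 1e4, bins + offs, runif(n, 0, 0.1))
  fo <- mk_fithic(bins + 1e4, bins + offs, runif(n, 0, 0.1))
  u <- union_dcis(sel, fw, fo)
  # brute-force set algebra over pair keys
  key <- function(df, keep) unique(paste(df$bin1, df$bin2)[keep &
                                                             df$bin1 != df$bin2])
  sel_keys <- key(sel, sel$p_value < 1e-4)
  sig_w <- key(fw, fw$q_value < 0.05)
  sig_o <- key(fo, fo$q_value < 0.05)
  fit_keys <- union(setdiff(sig_w, sig_o), setdiff(sig_o, sig_w))
  expect_equal(nrow(u), length(union(sel_keys, fit_keys)))
  expect_error(union_dcis(sel[, -6], fw, fo), "missing column")
})

test_that("self-pairs are excluded from the DCI union", {
  sel <- mk_selfish(c(0, 10000), c(0, 20000), 1e-6)
  u <- union_dcis(sel, mk_fithic(0, 0, 1)[0, ], mk_fithic(0, 0, 1)[0, ])
  expect_equal(nrow(u), 1)
  expect_equal(u$bin1, 10000)
})

test_that("zfilter applies the distance gate and stratum z-score", {
  rec <- random_records(5, seed = 2)
  rec$distance[1] <- 1.2e6
  rec$bin2[1] <- rec$bin1[1] + 1.2e6
  out <- zfilter(rec)
  expect_false(any(out$distance > 1e6))

  # hand-computed stratum: deltas {1,1,1,1,10}, z of 10 = (10-2.8)/4.0249 ~ 1.79
  st <- data.frame(chrom = "chr1", bin1 = 0, bin2 = 30000, distance = 30000,
                   count_within = c(11, 11, 11, 11, 20),
                   count_outside = 10, direction = "within_higher",
                   source = "selfish", z = NA_real_)
  kept <- zfilter(st)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$count_within, 20)
  expect_equal(kept$z, (10 - mean(c(1, 1, 1, 1, 10))) / sd(c(1, 1, 1, 1, 10)))

  # zero spread: all dropped with a log message
  same <- st; same$count_within <- 11
  expect_message(out0 <- zfilter(same), "zero spread")
  expect_equal(nrow(out0), 0)

  # stratum with < 2 records passes through with z unset
  one <- st[5, ]
  expect_message(out1 <- zfilter(one), "< 2 records")
  expect_true(is.na(out1$z))
})

test_that("zfilter equals the brute-force per-stratum enumeration", {
  rec <- random_records(300, seed = 12)
  out <- suppressMessages(zfilter(rec))
  orc <- oracle_zfilter(rec)
  expect_equal(sort(paste(out$bin1, out$bin2, out$direction)),
               sort(paste(rec$bin1[orc$rows], rec$bin2[orc$rows],
                          rec$direction[orc$rows])))
  # survivors satisfy the contract against their own stratum statistics
  expect_true(all(out$distance <= 1e6))
  expect_true(all(is.na(out$z) | out$z > 1))
  # output is a subset of the input
  expect_true(all(paste(out$bin1, out$bin2) %in% paste(rec$bin1, rec$bin2)))
})

test_that("genes rasterize to the bins they touch", {
  genes <- data.frame(chrom = "chr1", start = 15001, end = 18000,
                      gene_name = "G1", de_label = "none")
  rec <- random_records(1, seed = 3)
  rec$bin1 <- 10000; rec$bin2 <- 300000; rec$distance <- 290000
  links <- link_genes(rec, genes)
  expect_equal(nrow(links), 1)   # gene occupies exactly bin 10000
  expect_equal(links$gene_bin, 10000)
  expect_equal(links$regulatory_bin, 300000)

  genes2 <- data.frame(chrom = "chr1", start = 520000, end = 525000,
                       gene_name = "G2", de_label = "none")
  rec2 <- rec; rec2$bin1 <- 20000; rec2$bin2 <- 520000
  l2 <- link_genes(rec2, genes2)
  expect_equal(l2$regulatory_bin, 20000)
  expect_error(link_genes(rec, transform(genes, end = 100)), "end <= start")
})

test_that("link_genes matches exhaustive intersection on random fixtures", {
  set.seed(14)
  genes <- data.frame(chrom = "chr1",
                      start = sample(seq(0, 1.9e6, 1e3), 30),
                      gene_name = paste0("g", 1:30),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(seq(2e3, 8e4, 1e3), 30, replace = TRUE)
  rec <- random_records(200, seed = 15)
  links <- link_genes(rec, genes)
  orc <- oracle_link_genes(rec, genes)
  expect_equal(sort(paste(links$gene_name, links$gene_bin, links$bin1,
                          links$bin2)),
               sort(paste(orc$gene_name, orc$gene_bin, orc$bin1, orc$bin2)))
})

test_that("distance-stratified mean differences match hand arithmetic", {
  gl <- data.frame(gene_name = c("a", "a", "a", "b", "b", "b"),
                   chrom = "chr1", gene_bin = 0, regulatory_bin = 1,
                   bin1 = 0, bin2 = 1,
                   distance = c(1e4, 2e4, 6e4, 1e4, 3e4, 7e4),
                   count_within = c(5, 7, 9, 4, 4, 4),
                   count_outside = c(1, 1, 1, 6, 6, 6),
                   direction = "within_higher")
  res <- distance_stratified_mean_diff(gl, "a", "b")
  expect_equal(res$strata$mean_diff_up_within[1], mean(c(4, 6)))
  expect_equal(res$strata$mean_diff_up_within[2], 8)
  expect_equal(res$strata$mean_diff_up_outside[1], -2)
  expect_true(is.na(res$strata$mean_diff_up_within[3]))

  same <- gl; same$count_outside <- same$count_within
  res0 <- distance_stratified_mean_diff(same, "a", "b")
  expect_true(all(res0$strata$mean_diff_up_within %in% c(0, NA)))
  expect_gt(res0$t_test_p, 0.9)
  expect_error(distance_stratified_mean_diff(gl, "a", "a"), "disjoint")
})

test_that("a planted within-condition boost is detected per stratum", {
  set.seed(16)
  n <- 200
  gl <- data.frame(gene_name = rep(c("win", "out"), each = n),
                   chrom = "chr1", gene_bin = 0, regulatory_bin = 1,
                   bin1 = 0, bin2 = 1,
                   distance = sample(seq(1e4, 9.9e5, 1e4), 2 * n,
                                     replace = TRUE),
                   count_within = rpois(2 * n, 10),
                   count_outside = rpois(2 * n, 10),
                   direction = "within_higher")
  gl$count_within[1:n] <- gl$count_within[1:n] + 2
  res <- distance_stratified_mean_diff(gl, "win", "out")
  ok <- !is.na(res$strata$mean_diff_up_within)
  expect_gt(mean(res$strata$mean_diff_up_within[ok] -
                   ifelse(is.na(res$strata$mean_diff_up_outside[ok]), 0,
                          res$strata$mean_diff_up_outside[ok])), 0)
  expect_lt(res$t_test_p, 0.01)
})

test_that("map_loci reproduces the anchor/gene-bin linking structure", {
  # a within-condition record whose far anchor overlaps the Igfbp5 gene
  rec <- data.frame(chrom = "9", bin1 = 80160000, bin2 = 80440000,
                    distance = 280000, count_within = 30, count_outside = 10,
                    direction = "within_higher", source = "both", z = 1.5)
  genes <- data.frame(chrom = "9", start = 80160234, end = 80169000,
                      gene_name = "Igfbp5", de_label = "none")
  loci <- data.frame(chrom = "9", start = 80440000, end = 80440050,
                     snp_name = "rs13387042")
  lg <- map_loci(loci, rec, genes)
  expect_equal(nrow(lg), 1)
  expect_equal(lg$gene_name, "Igfbp5")
  expect_equal(lg$gene_bin, 80160000)
  expect_equal(lg$locus_bin, 80440000)
  expect_equal(lg$condition, "within")

  # a locus that misses both anchors links nothing
  miss <- data.frame(chrom = "9", start = 90000000, end = 90000050,
                     snp_name = "rsX")
  expect_equal(nrow(map_loci(miss, rec, genes)), 0)
  off <- data.frame(chrom = "12", start = 1, end = 50, snp_name = "rsY")
  expect_message(out <- map_loci(off, rec, genes), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("map_loci matches the exhaustive triple loop on random fixtures", {
  set.seed(18)
  rec <- random_records(100, seed = 19)
  genes <- data.frame(chrom = "chr1",
                      start = sample(seq(0, 1.9e6, 1e3), 20),
                      gene_name = paste0("g", 1:20), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(seq(2e3, 6e4, 1e3), 20, replace = TRUE)
  loci <- data.frame(chrom = "chr1",
                     start = sample(seq(0, 2e6, 500), 10),
                     snp_name = paste0("rs", 1:10), stringsAsFactors = FALSE)
  loci$end <- loci$start + 50
  lg <- map_loci(loci, rec, genes)
  orc <- oracle_map_loci(loci, rec, genes)
  key <- function(d) sort(paste(d$snp_name, d$locus_bin, d$gene_name,
                                d$gene_bin, d$condition))
  if (is.null(orc)) {
    expect_equal(nrow(lg), 0)
  } else {
    expect_equal(key(lg), key(orc))
  }
})
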