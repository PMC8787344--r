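#' Read a HiC-Pro sparse matrix for one chromosome
#'
#' Reads the bins BED file (chrom, start, end, bin_id) and the matching
#' triplet file (bin_id1, bin_id2, count) produced by HiC-Pro, and returns
#' the dense intra-chromosomal contact matrix for the requested chromosome.
#' Triplets listing only one triangle are mirrored; if both triangles of a
#' pair are present their counts must agree. Inter-chromosomal triplets are
#' ignored.
#'
#' @param bins_path Path to the bins BED file (>= 4 whitespace-delimited
#'   columns: chrom, start, end, id).
#' @param triplets_path Path to the triplet file (3 columns: id1, id2, count).
#' @param chrom Chromosome to extract.
#' @return A [contact_matrix()].
#' @seealso [write_hicpro()]
#' @export
read_hicpro <- function(bins_path, triplets_path, chrom) {
  bins <- utils::read.table(bins_path, header = FALSE,
                            colClasses = c("character", "numeric", "numeric",
                                           "integer"),
                            col.names = c("chrom", "start", "end", "id"))
  if (anyDuplicated(bins$id)) {
    stop("duplicate bin_ids in bins file", call. = FALSE)
  }
  sel <- bins[bins$chrom == chrom, , drop = FALSE]
  if (nrow(sel) == 0) {
    stop("chromosome '", chrom, "' not present in bins file", call. = FALSE)
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  bin_size <- sel$end[1] - sel$start[1]
  n <- nrow(sel)
  idx <- stats::setNames(seq_len(n), as.character(sel$id))

  trip <- if (file.size(triplets_path) == 0) {
    data.frame(id1 = integer(), id2 = integer(), count = numeric())
  } else {
    utils::read.table(triplets_path, header = FALSE,
                      col.names = c("id1", "id2", "count"))
  }
  if (nrow(trip) > 0 && !is.numeric(trip$count)) {
    stop("triplet counts must be numeric", call. = FALSE)
  }
  chrom_ids <- as.character(sel$id)
  all_ids <- as.character(bins$id)
  in1 <- as.character(trip$id1) %in% all_ids
  in2 <- as.character(trip$id2) %in% all_ids
  if (any(!in1) || any(!in2)) {
    stop("triplet file references unknown bin_id", call. = FALSE)
  }
  keep <- as.character(trip$id1) %in% chrom_ids &
    as.character(trip$id2) %in% chrom_ids
  trip <- trip[keep, , drop = FALSE]

  m <- matrix(0, n, n)
  if (nrow(trip) > 0) {
    i <- idx[as.character(trip$id1)]
    j <- idx[as.character(trip$id2)]
    # canonical upper-triangle key to detect conflicting duplicates
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- paste(lo, hi)
    agg <- tapply(trip$count, key, function(v) {
      if (length(unique(v)) > 1) NA_real_ else v[1]
    })
    if (anyNA(agg)) {
      stop("conflicting duplicate triplet values for the same bin pair",
           call. = FALSE)
    }
    kk <- strsplit(names(agg), " ", fixed = TRUE)
    li <- as.integer(vapply(kk, `[`, "", 1L))
    hi2 <- as.integer(vapply(kk, `[`, "", 2L))
    m[cbind(li, hi2)] <- as.numeric(agg)
    m[cbind(hi2, li)] <- as.numeric(agg)
  }
  contact_matrix(m, chrom = chrom, bin_size = bin_size,
                 bin_starts = sel$start)
}

#' Write a contact matrix in HiC-Pro sparse format
#'
#' Emits a bins BED file and a triplet file holding the nonzero entries of
#' the upper triangle (diagonal included). `read_hicpro()` on the output
#' reproduces the input matrix exactly for integer counts.
#'
#' @param matrix A [contact_matrix()].
#' @param bins_path Output path for the bins BED file.
#' @param triplets_path Output path for the triplet file.
#' @param first_id Integer id assigned to the first bin (HiC-Pro ids are
#'   treated as opaque keys; 1 by default).
#' @return Invisibly, `NULL`.
#' @export
write_hicpro <- function(matrix, bins_path, triplets_path, first_id = 1L) {
  stopifnot(is_contact_matrix(matrix))
  n <- n_bins(matrix)
  ids <- seq_len(n) + first_id - 1L
  bins <- data.frame(chrom = matrix$chrom,
                     start = format(matrix$bin_starts, scientific = FALSE,
                                    trim = TRUE),
                     end = format(matrix$bin_starts + matrix$bin_size,
                                  scientific = FALSE, trim = TRUE),
                     id = ids)
  utils::write.table(bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ut <- which(upper.tri(matrix$counts, diag = TRUE) & matrix$counts != 0,
              arr.ind = TRUE)
  trip <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                     count = matrix$counts[ut])
  trip <- trip[order(trip$id1, trip$id2), , drop = FALSE]
  utils::write.table(trip, triplets_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a gene annotation table
#'
#' Tab-separated columns: chrom, start, end, gene_name, and optionally a
#' differential-expression label in `{up_within, up_outside, none}`.
#'
#' @param path Path to the TSV (lines starting with `#` are skipped).
#' @return A data.frame with columns `chrom`, `start`, `end`, `gene_name`,
#'   `de_label`.
#' @export
read_genes <- function(path) {
  g <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(g) < 4) stop("gene table needs >= 4 columns", call. = FALSE)
  names(g)[1:4] <- c("chrom", "start", "end", "gene_name")
  g$de_label <- if (ncol(g) >= 5) as.character(g[[5]]) else "none"
  g$de_label[is.na(g$de_label) | g$de_label == ""] <- "none"
  if (any(g$end <= g$start)) {
    stop("gene with end <= start in annotation", call. = FALSE)
  }
  g[, c("chrom", "start", "end", "gene_name", "de_label")]
}

#' Read a BED file of (lifted-over) GWAS loci
#'
#' @param path Path to a BED file with columns chrom, start, end, snp_name.
#' @return A data.frame with columns `chrom`, `start`, `end`, `snp_name`.
#' @export
read_loci <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(b) < 4) stop("loci BED needs >= 4 columns", call. = FALSE)
  names(b)[1:4] <- c("chrom", "start", "end", "snp_name")
  b[, c("chrom", "start", "end", "snp_name")]
}

# TSV writer shared by the CLI and pipeline: header line prefixed with '#'
write_tsv_commented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

read_tsv_commented <- function(path, col_names) {
  first <- readLines(path, n = 1L)
  df <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (startsWith(first, "#")) {
    names(df) <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  } else if (!missing(col_names)) {
    names(df) <- col_names
  }
  df
}
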