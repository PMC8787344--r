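#' Scale the consensus weight to the data magnitude
#'
#' The consensus penalty `alpha * ||V(t) - V(c)||_F^2` competes with the
#' reconstruction term `||X - U V^T||_F^2`, which scales with the square of
#' the counts while `||V||^2` scales linearly with them. A transferable
#' regularization level is therefore expressed relative to the mean count:
#' `alpha = base * mean(X)`. The default base of 1e4 gives a strong
#' consensus pull (task V factors nearly shared, cluster identities matched
#' across conditions) while leaving the per-task U factors free to express
#' condition-specific structure.
#'
#' @param X List of [contact_matrix()] objects or matrices.
#' @param base Dimensionless regularization level (default 1e4).
#' @return A single alpha value.
#' @export
scale_alpha <- function(X, base = 1e4) {
  mats <- lapply(X, function(x) if (is_contact_matrix(x)) x$counts else
    as.matrix(x))
  base * mean(vapply(mats, mean, 0))
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with its default. All values are echoed
#' into a provenance JSON next to the outputs when [run_pipeline()] writes
#' files.
#'
#' @param chrom Chromosome to analyze.
#' @param bin_size Bin width in bp.
#' @param ice Apply ICE balancing before enhancement (default TRUE).
#' @param ice_max_iter,ice_tol,low_coverage_fraction ICE parameters, see
#'   [ice_normalize()].
#' @param enhance Apply network enhancement (default TRUE).
#' @param k_neighbors,diffusion_weight,ne_mode NE parameters, see
#'   [ne_config()].
#' @param rank `"auto"` (the [choose_rank()] heuristic) or an integer.
#' @param alpha `"auto"` ([scale_alpha()] at `alpha_base`) or a number.
#' @param alpha_base Base level for `alpha = "auto"` (default 1e4).
#' @param max_iter,tol HALS parameters, see [mvnmf_fit()].
#' @param min_bins Minimum block length in bins (default 5).
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A list of class `RunConfig`.
#' @export
pipeline_config <- function(chrom = "chrS", bin_size = 10000L, ice = TRUE,
                            ice_max_iter = 100L, ice_tol = 1e-5,
                            low_coverage_fraction = 0.02, enhance = TRUE,
                            k_neighbors = NULL, diffusion_weight = 0.9,
                            ne_mode = "closed_form", rank = "auto",
                            alpha = "auto", alpha_base = 1e4,
                            max_iter = 300L, tol = 1e-6, min_bins = 5L,
                            seed = 13L, out_dir = NULL) {
  structure(list(chrom = chrom, bin_size = as.integer(bin_size), ice = ice,
                 ice_max_iter = ice_max_iter, ice_tol = ice_tol,
                 low_coverage_fraction = low_coverage_fraction,
                 enhance = enhance, k_neighbors = k_neighbors,
                 diffusion_weight = diffusion_weight, ne_mode = ne_mode,
                 rank = rank, alpha = alpha, alpha_base = alpha_base,
                 max_iter = max_iter, tol = tol, min_bins = min_bins,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "RunConfig")
}

#' Run the block-detection pipeline on a pair of contact matrices
#'
#' Executes the full per-chromosome analysis: optional ICE balancing of
#' each condition, network enhancement, joint consensus-regularized
#' factorization, per-bin cluster assignment, dynamic/static block calling,
#' and block count-difference statistics (computed on the pre-enhancement
#' matrices, where counts retain their original scale). When
#' `config$out_dir` is set, the blocks table, cluster labels, factor
#' matrices, objective trace, and a provenance file recording every
#' parameter are written there as TSV/JSON.
#'
#' @param X_a,X_b The two conditions' [contact_matrix()] objects.
#' @param config A [pipeline_config()].
#' @return List with `blocks` (augmented block table), `factors`
#'   (`FactorSet`), `track_a`, `track_b`, `enhanced` (list of the two
#'   enhanced matrices), `config`.
#' @export
run_pipeline <- function(X_a, X_b, config = pipeline_config()) {
  stopifnot(inherits(config, "RunConfig"))
  stats_input <- list(X_a, X_b)
  if (isTRUE(config$ice)) {
    X_a <- ice_normalize(X_a, max_iter = config$ice_max_iter,
                         tol = config$ice_tol,
                         low_coverage_fraction = config$low_coverage_fraction)
    X_b <- ice_normalize(X_b, max_iter = config$ice_max_iter,
                         tol = config$ice_tol,
                         low_coverage_fraction = config$low_coverage_fraction)
  }
  if (isTRUE(config$enhance)) {
    nec <- ne_config(k_neighbors = config$k_neighbors,
                     diffusion_weight = config$diffusion_weight,
                     mode = config$ne_mode)
    X_a <- network_enhance(X_a, nec)
    X_b <- network_enhance(X_b, nec)
  }
  k <- if (identical(config$rank, "auto")) {
    choose_rank(n_bins(X_a), config$bin_size)
  } else as.integer(config$rank)
  alpha <- if (identical(config$alpha, "auto")) {
    scale_alpha(list(X_a, X_b), base = config$alpha_base)
  } else as.numeric(config$alpha)
  factors <- mvnmf_fit(list(X_a, X_b), rank = k, alpha = alpha,
                       max_iter = config$max_iter, tol = config$tol,
                       seed = config$seed)
  track_a <- assign_clusters(factors, 1L, chrom = config$chrom,
                             bin_size = config$bin_size)
  track_b <- assign_clusters(factors, 2L, chrom = config$chrom,
                             bin_size = config$bin_size)
  blocks <- call_blocks(track_a, track_b, min_bins = config$min_bins)
  blocks <- block_count_stats(blocks, stats_input[[1]], stats_input[[2]])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_outputs(config$out_dir, blocks, factors,
                           track_a, track_b, config)
  }
  list(blocks = blocks, factors = factors, track_a = track_a,
       track_b = track_b, enhanced = list(X_a, X_b), config = config)
}

write_pipeline_outputs <- function(out_dir, blocks, factors, track_a,
                                   track_b, config) {
  bl <- blocks
  bl$start <- format(bl$start, scientific = FALSE, trim = TRUE)
  bl$end <- format(bl$end, scientific = FALSE, trim = TRUE)
  write_tsv_commented(bl, file.path(out_dir, "blocks.tsv"))
  labs <- data.frame(bin = seq_along(track_a$labels),
                     start = (seq_along(track_a$labels) - 1L) *
                       as.numeric(config$bin_size),
                     label_a = track_a$labels, label_b = track_b$labels)
  write_tsv_commented(labs, file.path(out_dir, "clusters.tsv"))
  for (t in seq_len(factors$tasks)) {
    u <- as.data.frame(factors$U[[t]])
    names(u) <- paste0("factor", seq_len(ncol(u)))
    write_tsv_commented(cbind(bin = seq_len(nrow(u)), u),
                        file.path(out_dir, sprintf("U_task%d.tsv", t)))
  }
  write_tsv_commented(
    data.frame(sweep = seq_along(factors$objective_trace) - 1L,
               objective = factors$objective_trace),
    file.path(out_dir, "objective_trace.tsv"))
  prov <- unclass(config)
  prov$out_dir <- NULL
  prov$resolved_rank <- factors$rank
  prov$resolved_alpha <- factors$alpha
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Jaccard overlap between two bin intervals
#'
#' Used to compare called blocks against planted ground truth:
#' `|intersection| / |union|` of the two inclusive bin ranges.
#'
#' @param start1,end1,start2,end2 Inclusive bin indices.
#' @return A number in `[0, 1]`.
#' @export
jaccard_bins <- function(start1, end1, start2, end2) {
  inter <- max(0, min(end1, end2) - max(start1, start2) + 1)
  uni <- (end1 - start1 + 1) + (end2 - start2 + 1) - inter
  inter / uni
}
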