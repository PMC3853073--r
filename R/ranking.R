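#' Rank SNPs by information-gain importance
#'
#' Orders SNPs by decreasing importance; rank 1 is the most important SNP
#' and ties receive the average of the ranks they span.  Rows are sorted by
#' importance, with ties ordered by SNP id for a deterministic table.
#'
#' @param importance named numeric vector of importance scores, a tibble
#'   with columns `snp_id` and `importance`, or an `mvrf_forest`.
#' @return Tibble with columns `snp_id`, `importance`, `rank`.
#' @examples
#' rank_snps(c(a = 3, b = 1, c = 2))
#' @export
rank_snps <- function(importance) {
  if (inherits(importance, "mvrf_forest")) importance <- importance$importance
  if (is.data.frame(importance)) {
    imp <- setNames(importance$importance, importance$snp_id)
  } else {
    imp <- importance
  }
  if (length(imp) == 0L) stop("empty importance map")
  if (is.null(names(imp))) names(imp) <- paste0("snp_", seq_along(imp))
  out <- tibble::tibble(
    snp_id = names(imp),
    importance = unname(imp),
    rank = rank(-unname(imp), ties.method = "average")
  )
  dplyr::arrange(out, dplyr::desc(.data$importance), .data$snp_id)
}

top_k_set <- function(ranking, k) {
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$importance),
                            .data$snp_id)
  ranking$snp_id[seq_len(min(k, nrow(ranking)))]
}

#' Jaccard agreement between two top-k SNP sets
#'
#' `|top_k(a) intersect top_k(b)| / |top_k(a) union top_k(b)|`, the measure
#' used to monitor ranking stability as trees accumulate.
#'
#' @param ranking_a,ranking_b rankings from [rank_snps()].
#' @param k top-set size.
#' @return Scalar in `[0, 1]`; 1 iff the two top-k sets coincide.
#' @export
jaccard_topk <- function(ranking_a, ranking_b, k) {
  if (k <= 0) stop("`k` must be positive")
  a <- top_k_set(ranking_a, k)
  b <- top_k_set(ranking_b, k)
  length(intersect(a, b)) / length(union(a, b))
}

#' Ranking stability as the forest grows
#'
#' Replays the forest's per-tree split records in blocks of `block_size`
#' trees and, after each block, computes the Jaccard agreement of the
#' cumulative top-`k` ranking with the previous cumulative ranking.  The
#' curve trends towards 1 as the ranking stabilises; the forest is large
#' enough when it plateaus near 1.
#'
#' @param forest an `mvrf_forest`.
#' @param block_size trees per block (500 in large genome-wide runs).
#' @param k top-set size monitored (5000 in genome-wide runs; clamp to P).
#' @return Tibble with columns `ntree` (cumulative trees) and `jaccard`
#'   (agreement with the previous block's cumulative ranking); empty when
#'   fewer than two blocks are available.
#' @export
stability_curve <- function(forest, block_size = 500, k = 5000) {
  stopifnot(inherits(forest, "mvrf_forest"))
  k <- min(k, forest$n_snps)
  ids <- vapply(forest$tree_gains, `[[`, integer(1), "tree_id")
  gains <- forest$tree_gains[order(ids)]
  blocks <- split(gains, ceiling(seq_along(gains) / block_size))
  if (length(blocks) < 2L) {
    return(tibble::tibble(ntree = integer(0), jaccard = numeric(0)))
  }
  snp_ids <- names(forest$importance)
  cum <- setNames(numeric(length(snp_ids)), snp_ids)
  prev_rank <- NULL
  out <- vector("list", length(blocks))
  n_done <- 0L
  for (b in seq_along(blocks)) {
    for (rec in blocks[[b]]) {
      if (length(rec$snp)) {
        part <- rowsum(rec$gain, rec$snp)
        idx <- as.integer(rownames(part))
        cum[idx] <- cum[idx] + part[, 1]
      }
    }
    n_done <- n_done + length(blocks[[b]])
    cur_rank <- rank_snps(cum)
    if (!is.null(prev_rank)) {
      out[[b]] <- tibble::tibble(
        ntree = n_done, jaccard = jaccard_topk(prev_rank, cur_rank, k)
      )
    }
    prev_rank <- cur_rank
  }
  dplyr::bind_rows(out)
}

#' Map SNPs to genes within a window
#'
#' A SNP maps to a gene when its (1-based) position falls within the gene
#' body extended by `window` bases on both sides; the 10 kb default is the
#' conventional cis window.  Gene intervals follow BED conventions
#' (0-based, half-open) as returned by [read_gene_bed()]; positions follow
#' VCF conventions (1-based); the conversion is internal.  A SNP may map
#' to several genes; genes with no mapped SNP are dropped with a message.
#'
#' @param snp_info tibble with columns `snp_id`, `chrom`, `pos`.
#' @param genes tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `gene_id`.
#' @param window symmetric extension in bases (inclusive boundary: a SNP
#'   exactly `window` bases from the gene edge is mapped).
#' @return Tibble with columns `gene_id`, `snp_id`.
#' @export
map_snps_to_genes <- function(snp_info, genes, window = 10000) {
  snp_info <- tibble::as_tibble(snp_info)
  genes <- tibble::as_tibble(genes)
  if (length(intersect(unique(snp_info$chrom), unique(genes$chrom))) == 0L) {
    warning("no shared chromosome names between SNPs and genes")
    return(tibble::tibble(gene_id = character(0), snp_id = character(0)))
  }
  snp_gr <- GenomicRanges::GRanges(
    snp_info$chrom, IRanges::IRanges(snp_info$pos, snp_info$pos)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start + 1 - window, 1), genes$end + window)
  )
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  out <- tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    snp_id = snp_info$snp_id[S4Vectors::queryHits(hits)]
  )
  out <- dplyr::distinct(dplyr::arrange(out, .data$gene_id, .data$snp_id))
  dropped <- setdiff(genes$gene_id, out$gene_id)
  if (length(dropped)) {
    message(length(dropped), " gene(s) with no mapped SNP dropped")
  }
  out
}

#' Gene-rank permutation test
#'
#' Scores each gene by the mean rank of its mapped SNPs (small mean rank =
#' highly ranked gene) and tests it against an empirical null obtained by
#' jointly permuting the rank vector over all P SNPs `n_perm` times; the
#' one permutation stream is shared across genes.  The p-value is
#' lower-tailed with add-one smoothing,
#' `p = (1 + #\{s_perm <= s_obs\}) / (1 + n_perm)`, so it is never zero.
#' Significance is called by Benjamini-Hochberg FDR control at level `q`.
#'
#' @param ranking tibble from [rank_snps()].
#' @param gene_map tibble from [map_snps_to_genes()].
#' @param n_perm number of permutations (10000 in genome-wide runs; a
#'   warning is issued below 100).
#' @param q FDR level for the significance call.
#' @return Tibble with columns `gene_id`, `n_snps`, `mean_rank`,
#'   `p_value`, `fdr_significant`.
#' @export
gene_rank_permutation_test <- function(ranking, gene_map, n_perm = 10000,
                                       q = 0.10) {
  if (n_perm < 100) warning("fewer than 100 permutations: unstable p-values")
  ranks <- setNames(ranking$rank, ranking$snp_id)
  miss <- setdiff(gene_map$snp_id, names(ranks))
  if (length(miss)) stop("gene_map contains SNPs absent from the ranking")
  sets <- split(match(gene_map$snp_id, names(ranks)), gene_map$gene_id)
  obs <- vapply(sets, function(i) mean(ranks[i]), numeric(1))
  hits <- integer(length(sets))
  p_len <- length(ranks)
  for (b in seq_len(n_perm)) {
    perm <- ranks[sample.int(p_len)]
    s_perm <- vapply(sets, function(i) mean(perm[i]), numeric(1))
    hits <- hits + (s_perm <= obs)
  }
  p <- (1 + hits) / (1 + n_perm)
  tibble::tibble(
    gene_id = names(sets),
    n_snps = lengths(sets),
    mean_rank = unname(obs),
    p_value = unname(p),
    fdr_significant = bh_fdr(unname(p), q = q)
  )
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up false-discovery-rate control: a p-value is significant when its
#' BH-adjusted value is at most `q`.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @param q FDR level.
#' @return Logical vector of significance decisions.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.9, 0.95), q = 0.1)
#' @export
bh_fdr <- function(p_values, q = 0.10) {
  if (length(p_values) == 0L) return(logical(0))
  stopifnot(all(p_values > 0 & p_values <= 1))
  p.adjust(p_values, method = "BH") <= q
}
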