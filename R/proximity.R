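#' Convert a proximity matrix to a genetic distance matrix
#'
#' The forest proximity `p_ij` is the fraction of trees in which samples
#' `i` and `l` share a leaf; `d_ij = 1 - p_ij` is the corresponding
#' genetic distance (0 diagonal).
#'
#' @param proximity symmetric matrix with entries in `[0, 1]` and unit
#'   diagonal, or an `mvrf_forest`.
#' @return Distance matrix with attribute `label = "genetic"`.
#' @export
proximity_to_distance <- function(proximity) {
  if (inherits(proximity, "mvrf_forest")) proximity <- proximity$proximity
  if (!isSymmetric(unname(proximity), tol = 1e-10)) {
    stop("proximity matrix must be symmetric")
  }
  if (any(proximity < -1e-12 | proximity > 1 + 1e-12)) {
    stop("proximity entries must lie in [0, 1]")
  }
  d <- 1 - proximity
  diag(d) <- 0
  d[d < 0] <- 0
  attr(d, "label") <- "genetic"
  d
}

#' Phenotypic distance matrix
#'
#' Plain Euclidean distances between sample phenotype vectors, as a dense
#' symmetric matrix labelled `"phenotypic"` for use alongside the genetic
#' distance in [mantel_test()] and [classical_mds()].
#'
#' @param phenotypes numeric matrix, samples in rows.
#' @return Distance matrix with attribute `label = "phenotypic"`.
#' @export
phenotype_distance <- function(phenotypes) {
  d <- sqrt(pairwise_phenotype_distance(phenotypes))
  attr(d, "label") <- "phenotypic"
  attr(d, "metric_name") <- NULL
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix in `n_dims` Euclidean dimensions through the
#' eigen-decomposition of the double-centred matrix `-D^2 / 2`.  Negative
#' eigenvalues (distances that are not exactly Euclidean, as forest
#' distances typically are) are truncated to zero and their absolute share
#' of the spectrum is recorded; when fewer than `n_dims` positive
#' eigenvalues exist the remaining coordinates are zero-padded with a
#' warning.  Coordinates are centred at the origin.
#'
#' @param distance symmetric distance matrix (zero diagonal).
#' @param n_dims embedding dimension, typically 2 (visualisation and
#'   clustering) or 3 (severity scoring).
#' @return `N x n_dims` coordinate matrix with attributes `eig` (full
#'   eigenvalue vector) and `negative_share` (share of the spectrum lost
#'   to truncation).
#' @export
classical_mds <- function(distance, n_dims = 2) {
  n <- nrow(distance)
  if (n <= n_dims) stop("need more samples than embedding dimensions")
  fit <- suppressWarnings(cmdscale(distance, k = n_dims, eig = TRUE))
  pts <- fit$points
  n_pos <- sum(fit$eig > max(fit$eig) * 1e-12)
  if (n_pos < n_dims) {
    warning("only ", n_pos, " positive eigenvalue(s); zero-padding to ",
            n_dims, " dimension(s)")
    if (ncol(pts) < n_dims) {
      pts <- cbind(pts, matrix(0, n, n_dims - ncol(pts)))
    }
    pts[, seq(n_pos + 1, n_dims)] <- 0
  }
  pts <- sweep(pts, 2, colMeans(pts), "-")
  colnames(pts) <- paste0("dim", seq_len(n_dims))
  rownames(pts) <- rownames(distance)
  attr(pts, "eig") <- fit$eig
  attr(pts, "negative_share") <- sum(abs(pmin(fit$eig, 0))) / sum(abs(fit$eig))
  pts
}

#' Mantel test of association between two distance matrices
#'
#' Pearson correlation `r` between the upper-triangle entries of the two
#' matrices, with a one-sided permutation null obtained by simultaneously
#' permuting the rows and columns of the second matrix:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`.  Wraps
#' \code{vegan::\link[vegan]{mantel}}; seed with `set.seed()`.
#'
#' @param d1,d2 symmetric distance matrices over the same samples in the
#'   same order.
#' @param n_perm number of permutations.
#' @return Tibble with columns `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000) {
  if (!all(dim(d1) == dim(d2))) stop("distance matrices must match in size")
  if (nrow(d1) < 4) stop("Mantel test needs at least 4 samples")
  fit <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       method = "pearson", permutations = n_perm)
  tibble::tibble(r = unname(fit$statistic), p_value = fit$signif,
                 n_perm = n_perm)
}

#' Hierarchical severity clusters on an MDS embedding
#'
#' Ward-linkage agglomerative clustering of the embedded samples, cut at
#' `n_clusters` groups and relabelled `C1..Ck` along the dominant (first)
#' embedding axis.  By default C1 is the cluster at the low end of axis 1;
#' when a logical `reference` vector marks known low-severity samples
#' (e.g. healthy controls), the labelling is oriented so that C1 is the
#' cluster most enriched for them.
#'
#' @param coords `N x k` coordinate matrix from [classical_mds()].
#' @param n_clusters number of clusters (4 in the severity analysis).
#' @param reference optional logical vector marking low-severity samples.
#' @return Factor of labels `C1..Ck`, one per sample.
#' @export
hierarchical_clusters <- function(coords, n_clusters = 4, reference = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < n_clusters) stop("need at least `n_clusters` samples")
  raw <- cutree(hclust(dist(coords), method = "ward.D2"), k = n_clusters)
  axis_mean <- tapply(coords[, 1], raw, mean)
  ord <- order(axis_mean)
  if (!is.null(reference)) {
    ref_frac <- tapply(reference, raw, mean)
    if (ref_frac[ord[length(ord)]] > ref_frac[ord[1]]) ord <- rev(ord)
  }
  labels <- factor(match(raw, ord), levels = seq_len(n_clusters),
                   labels = paste0("C", seq_len(n_clusters)))
  labels
}

#' Severity distances relative to the reference cluster
#'
#' Two per-sample severity indicators read off the embedding: the
#' Euclidean distance to the centroid of the reference cluster C1, and the
#' scalar projection onto the disease-progression axis (the unit vector
#' from the C1 centroid to the centroid of the opposite extreme cluster).
#' Projections can be negative for samples behind the C1 centroid.
#'
#' @param coords `N x k` coordinate matrix (k = 3 in the severity
#'   analysis).
#' @param labels cluster factor from [hierarchical_clusters()].
#' @return Tibble with columns `sample`, `cluster`, `euclidean_severity`,
#'   `projected_severity`.
#' @export
severity_distances <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.factor(labels)
  lv <- levels(labels)
  c1 <- lv[1]
  c4 <- lv[length(lv)]
  if (!any(labels == c1) || !any(labels == c4)) {
    stop("both extreme clusters must be non-empty")
  }
  cen1 <- colMeans(coords[labels == c1, , drop = FALSE])
  cen4 <- colMeans(coords[labels == c4, , drop = FALSE])
  axis <- cen4 - cen1
  axis_len <- sqrt(sum(axis^2))
  if (axis_len == 0) stop("extreme cluster centroids coincide")
  u <- axis / axis_len
  centred <- sweep(coords, 2, cen1, "-")
  tibble::tibble(
    sample = if (is.null(rownames(coords))) as.character(seq_len(nrow(coords)))
             else rownames(coords),
    cluster = labels,
    euclidean_severity = sqrt(rowSums(centred^2)),
    projected_severity = as.numeric(centred %*% u)
  )
}

#' Count mutated states over the top-ranked SNPs
#'
#' With the major allele as the reference state and the minor allele as
#' the mutated state, counts for each sample the loci among the `k`
#' top-ranked SNPs at which it carries at least one minor allele
#' (genotype 1 or 2).
#'
#' @param genotypes additive 0/1/2 genotype matrix.
#' @param ranking tibble from [rank_snps()].
#' @param k number of top-ranked SNPs considered (clamped to P).
#' @return Tibble with columns `sample`, `mutated_states`.
#' @export
count_mutated_states <- function(genotypes, ranking, k = 1000) {
  top <- top_k_set(ranking, min(k, ncol(genotypes)))
  tibble::tibble(
    sample = rownames(genotypes),
    mutated_states = as.integer(
      rowSums(genotypes[, top, drop = FALSE] >= 1L)
    )
  )
}

#' Mine mutation patterns enriched near the severe cluster
#'
#' A mutation pattern is an unordered pair of (SNP, mutated-state) items,
#' with states 1 (heterozygote) or 2 (minor-allele homozygote) over two
#' distinct top-ranked SNPs; homozygous two-major-allele genotypes carry
#' no item.  A sample carries a pattern when it has exactly those states
#' at both SNPs.  Retained patterns must reach frequency `min_freq` over
#' all samples and be significantly more frequent in the severe cluster
#' C4 than overall (one-sided proportion z-test at level `alpha`).
#'
#' @param genotypes additive 0/1/2 genotype matrix.
#' @param ranking tibble from [rank_snps()].
#' @param labels cluster factor from [hierarchical_clusters()]; the last
#'   level is the severe cluster.
#' @param top_n number of top-ranked SNPs mined (100 in the severity
#'   analysis).
#' @param min_freq minimum overall pattern frequency.
#' @param alpha nominal level of the enrichment test.
#' @return List with `patterns` (tibble: snp_a, state_a, snp_b, state_b,
#'   freq_all, freq_c4, p_value) and `sample_counts` (tibble: sample,
#'   pattern_count = retained patterns carried).
#' @export
mine_mutation_patterns <- function(genotypes, ranking, labels, top_n = 100,
                                   min_freq = 0.05, alpha = 0.05) {
  labels <- as.factor(labels)
  severe <- levels(labels)[nlevels(labels)]
  in_c4 <- labels == severe
  if (!any(in_c4)) stop("severe cluster is empty")
  top <- top_k_set(ranking, min(top_n, ncol(genotypes)))
  if (length(top) < 2L) {
    return(list(
      patterns = tibble::tibble(
        snp_a = character(0), state_a = integer(0), snp_b = character(0),
        state_b = integer(0), freq_all = numeric(0), freq_c4 = numeric(0),
        p_value = numeric(0)
      ),
      sample_counts = tibble::tibble(sample = rownames(genotypes),
                                     pattern_count = integer(nrow(genotypes)))
    ))
  }
  g <- genotypes[, top, drop = FALSE]
  n <- nrow(g)
  n4 <- sum(in_c4)
  # item indicator matrix: one column per (SNP, state in {1, 2})
  items <- cbind(g == 1L, g == 2L)
  item_snp <- rep(seq_along(top), 2)
  item_state <- rep(c(1L, 2L), each = length(top))
  storage.mode(items) <- "numeric"
  cnt_all <- crossprod(items)
  cnt_c4 <- crossprod(items[in_c4, , drop = FALSE])
  keep <- which(upper.tri(cnt_all) &
                  outer(item_snp, item_snp, "!=") &
                  cnt_all / n >= min_freq, arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    pat <- tibble::tibble(
      snp_a = character(0), state_a = integer(0), snp_b = character(0),
      state_b = integer(0), freq_all = numeric(0), freq_c4 = numeric(0),
      p_value = numeric(0)
    )
    return(list(patterns = pat,
                sample_counts = tibble::tibble(
                  sample = rownames(genotypes),
                  pattern_count = integer(n))))
  }
  i <- keep[, 1]; j <- keep[, 2]
  p_all <- cnt_all[keep] / n
  p_c4 <- cnt_c4[keep] / n4
  z <- (p_c4 - p_all) / sqrt(p_all * (1 - p_all) / n4)
  p_val <- 1 - pnorm(z)
  retained <- p_val <= alpha
  pat <- tibble::tibble(
    snp_a = top[item_snp[i]], state_a = item_state[i],
    snp_b = top[item_snp[j]], state_b = item_state[j],
    freq_all = p_all, freq_c4 = p_c4, p_value = p_val
  )[retained, ]
  pat <- dplyr::arrange(pat, .data$p_value, .data$snp_a, .data$snp_b)
  carried <- if (any(retained)) {
    ik <- i[retained]; jk <- j[retained]
    counts <- integer(n)
    for (s in seq_along(ik)) {
      counts <- counts + (items[, ik[s]] * items[, jk[s]] > 0)
    }
    as.integer(counts)
  } else {
    integer(n)
  }
  list(
    patterns = pat,
    sample_counts = tibble::tibble(sample = rownames(genotypes),
                                   pattern_count = carried)
  )
}

#' Correlation between a mutation burden and disease severity
#'
#' Pearson correlation and simple linear-regression slope (with a
#' two-sided t-test p-value) of a per-sample count against a severity
#' indicator, optionally restricted to a subset of samples (e.g. cases
#' only).  Zero-variance input yields an undefined correlation, reported
#' as `NA` with a warning.
#'
#' @param counts numeric per-sample counts (mutated states or patterns).
#' @param severity numeric per-sample severity values.
#' @param mask optional logical vector selecting the samples analysed.
#' @return Tibble with columns `r`, `slope`, `p_value`, `n`.
#' @export
severity_correlation <- function(counts, severity, mask = NULL) {
  if (is.data.frame(counts)) counts <- counts[[ncol(counts)]]
  if (is.null(mask)) mask <- rep(TRUE, length(counts))
  x <- counts[mask]
  y <- severity[mask]
  if (length(x) < 3) stop("need at least 3 samples")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance: correlation undefined")
    return(tibble::tibble(r = NA_real_, slope = NA_real_,
                          p_value = NA_real_, n = length(x)))
  }
  fit <- summary(lm(y ~ x))
  tibble::tibble(
    r = cor(x, y),
    slope = fit$coefficients["x", "Estimate"],
    p_value = fit$coefficients["x", "Pr(>|t|)"],
    n = length(x)
  )
}

#' Scatter plot of an MDS embedding
#'
#' @param coords coordinate matrix from [classical_mds()].
#' @param labels optional grouping (clusters, diagnosis) mapped to colour.
#' @return A ggplot.
#' @export
plot_mds <- function(coords, labels = NULL) {
  d <- tibble::as_tibble(coords[, 1:2, drop = FALSE], .name_repair = "minimal")
  names(d) <- c("dim1", "dim2")
  if (!is.null(labels)) d$group <- labels
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$dim1, .data$dim2))
  if (is.null(labels)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}
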