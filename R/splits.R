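#' Node sum of squares under the covariance-weighted criterion
#'
#' Computes `sum_i (y_i - ybar)' V^-1 (y_i - ybar)` over a node's sample
#' multiset, with `V` either the identity or a diagonal matrix of per-trait
#' variances.  This is the quantity whose reduction a split maximises.
#'
#' @param phenos numeric matrix of the node's phenotype rows (bootstrap
#'   duplicates repeated).
#' @param cov a node covariance as returned by [estimate_node_covariance()],
#'   or `NULL` for the identity.
#' @return Non-negative scalar; 0 iff all rows are identical.
#' @export
node_ss_standard <- function(phenos, cov = NULL) {
  phenos <- rbind(phenos)
  if (nrow(phenos) < 1L) stop("empty node")
  dev <- sweep(phenos, 2, colMeans(phenos), "-")
  if (is.null(cov) || isTRUE(cov$identity)) return(sum(dev^2))
  sum(sweep(dev^2, 2, cov$diag, "/"))
}

#' Node sum of squares from pairwise squared distances
#'
#' Evaluates the same node heterogeneity as [node_ss_standard()] with
#' identity covariance, but from a precomputed matrix of squared pairwise
#' phenotype distances: `(1 / 2 N(j)) * sum_{i,l in D(j)} d2[i, l]`, with
#' bootstrap duplicates counted with multiplicity.  The number of traits
#' never enters: the cost depends only on the node size.
#'
#' @param d2 squared-distance matrix from [pairwise_phenotype_distance()].
#' @param node_indices integer multiset of row indices at the node.
#' @return Non-negative scalar equal (to numerical tolerance) to the
#'   identity-covariance standard sum of squares on the same rows.
#' @export
node_ss_distance <- function(d2, node_indices) {
  n <- length(node_indices)
  if (n < 1L) stop("empty node")
  sum(d2[node_indices, node_indices]) / (2 * n)
}

#' Estimate a (diagonal) node covariance
#'
#' The split function keeps the covariance fixed while scoring candidate
#' splits: daughters are evaluated under the parent's estimate, which keeps
#' the gain non-negative.  Only the identity and a diagonal parametrization
#' (per-trait sample variances, denominator `n - 1`, floored at `var_floor`)
#' are supported; with a few hundred samples and many traits a full
#' covariance estimate would be singular.
#'
#' @inheritParams node_ss_standard
#' @param parametrization `"identity"` or `"diagonal"`.
#' @param var_floor strictly positive floor applied to each variance.
#' @return A list with elements `identity` (flag) and `diag` (per-trait
#'   variances, `NULL` under the identity).
#' @export
estimate_node_covariance <- function(phenos,
                                     parametrization = c("identity", "diagonal"),
                                     var_floor = 1e-8) {
  parametrization <- match.arg(parametrization)
  if (parametrization == "identity") {
    return(list(identity = TRUE, diag = NULL))
  }
  phenos <- rbind(phenos)
  if (nrow(phenos) < 2L) stop("diagonal covariance needs at least 2 rows")
  v <- pmax(apply(phenos, 2, var), var_floor)
  list(identity = FALSE, diag = v)
}

#' Allowable ordinal splits of a 0/1/2 genotype column
#'
#' With additive coding a binary split is an ordinal threshold: left branch
#' `genotype <= t`, right branch `genotype > t`, for `t` in `{0, 1}`.  A
#' threshold is allowable when both sides are non-empty at the node; when
#' no heterozygotes are present the two thresholds induce the same
#' partition and only `t = 0` is kept.
#'
#' @param geno_column_values integer vector of the node's genotype values.
#' @return Integer vector of allowable thresholds (possibly empty).
#' @export
enumerate_splits <- function(geno_column_values) {
  g <- geno_column_values
  stopifnot(all(g %in% 0:2))
  n <- length(g)
  n0 <- sum(g == 0L); n1 <- sum(g == 1L); n2 <- sum(g == 2L)
  out <- integer(0)
  if (n0 >= 1L && n0 < n) out <- c(out, 0L)
  if (n2 >= 1L && n2 < n && n1 > 0L) out <- c(out, 1L)
  out
}

#' Best split of a node over a candidate SNP set
#'
#' Reference (pure R) split search: scores every allowable threshold of
#' every candidate SNP by the reduction in the node sum of squares,
#' `phi(j) = SS(j) - SS(j)_left - SS(j)_right`, with daughters evaluated
#' under the parent's covariance.  Ties are broken towards the lowest SNP
#' index, then the lowest threshold; the first strictly positive maximum
#' wins.  This is the scalar oracle for the vectorised C++ tree grower.
#'
#' @param node_indices integer multiset of sample indices at the node.
#' @param candidate_snps integer vector of candidate SNP column indices.
#' @param data an [mvrf_data] object.
#' @param criterion `"standard"` or `"distance"`.
#' @param covariance `"identity"` or `"diagonal"` (standard criterion).
#' @param d2 squared-distance matrix (required for `criterion =
#'   "distance"`).
#' @param var_floor variance floor for the diagonal parametrization.
#' @return `NULL` if no allowable split has positive gain, else a list
#'   `(snp_index, threshold, gain, left_size, right_size)`.
#' @export
best_split <- function(node_indices, candidate_snps, data,
                       criterion = c("standard", "distance"),
                       covariance = c("identity", "diagonal"),
                       d2 = NULL, var_floor = 1e-8) {
  criterion <- match.arg(criterion)
  covariance <- match.arg(covariance)
  x <- data$genotypes
  y <- data$phenotypes
  if (criterion == "distance" && is.null(d2)) {
    d2 <- pairwise_phenotype_distance(y)
  }
  cov <- NULL
  if (criterion == "standard") {
    cov <- estimate_node_covariance(
      y[node_indices, , drop = FALSE],
      parametrization = covariance, var_floor = var_floor
    )
  }
  ss_node <- if (criterion == "standard") {
    node_ss_standard(y[node_indices, , drop = FALSE], cov)
  } else {
    node_ss_distance(d2, node_indices)
  }
  # ties within floating-point error of the node SS (two SNPs inducing the
  # same partition) resolve to the lowest (snp, threshold): a challenger
  # must beat the incumbent by a tolerance scaled to the node SS
  tol <- 1e-9 * ss_node
  best <- NULL
  for (j in sort(candidate_snps)) {
    gj <- x[node_indices, j]
    for (t in enumerate_splits(gj)) {
      li <- node_indices[gj <= t]
      ri <- node_indices[gj > t]
      ss_lr <- if (criterion == "standard") {
        node_ss_standard(y[li, , drop = FALSE], cov) +
          node_ss_standard(y[ri, , drop = FALSE], cov)
      } else {
        node_ss_distance(d2, li) + node_ss_distance(d2, ri)
      }
      gain <- ss_node - ss_lr
      if (gain > tol && (is.null(best) || gain > best$gain + tol)) {
        best <- list(snp_index = j, threshold = t, gain = gain,
                     left_size = length(li), right_size = length(ri))
      }
    }
  }
  best
}
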