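#' Draw a bootstrap sample and its out-of-bag complement
#'
#' Samples `n_samples` indices with replacement; the indices never drawn
#' form the out-of-bag (OOB) set used as the tree's test set.  On average a
#' fraction `1 - (1 - 1/N)^N` (about 63.2% for a few hundred samples) of
#' subjects are distinct in the bag.  Uses R's RNG; seed with `set.seed()`.
#'
#' @param n_samples number of samples `N`.
#' @return List with `in_bag` (length-`N` index multiset) and `oob`
#'   (sorted index set absent from the bag).
#' @examples
#' set.seed(1)
#' b <- bootstrap_sample(10)
#' sort(unique(c(b$in_bag, b$oob)))
#' @export
bootstrap_sample <- function(n_samples) {
  if (length(n_samples) != 1L || is.na(n_samples) || n_samples < 1) {
    stop("`n_samples` must be a positive integer")
  }
  in_bag <- sample.int(n_samples, n_samples, replace = TRUE)
  list(in_bag = in_bag, oob = setdiff(seq_len(n_samples), in_bag))
}

#' Grow a single regression tree
#'
#' Grows one binary regression tree on a bootstrap multiset of the data:
#' at each node of size at least `min_node_size` a fresh random subset of
#' `mtry` candidate SNPs is drawn without replacement, every allowable
#' ordinal threshold split is scored by the reduction in the node sum of
#' squares, and the best strictly positive gain wins (ties towards the
#' lowest SNP index, then the lowest threshold).  Trees are grown to
#' maximal depth with no pruning.  The per-tree random stream is derived
#' deterministically from `(master_seed, tree_id)`, so the same pair always
#' reproduces the same tree, independent of R's RNG state.
#'
#' @param data an [mvrf_data] object (genotypes must be complete; run
#'   [impute_missing()] first).
#' @param config an [mvrf_config] object.
#' @param tree_id integer tree identifier (also the RNG key).
#' @param d2 optional precomputed squared-distance matrix for the distance
#'   criterion; computed on the fly when absent.
#' @return An object of class `mvrf_tree`: node table (SNP, threshold,
#'   gain, children, size), per-leaf in-bag multisets and mean vectors,
#'   the leaf assignment of every sample, and the OOB index set.
#' @export
grow_tree <- function(data, config, tree_id = 1L, d2 = NULL) {
  stopifnot(inherits(data, "mvrf_data"))
  config <- check_config(config, data)
  if (anyNA(data$genotypes)) {
    stop("genotypes contain missing calls; run impute_missing() before growth")
  }
  if (config$criterion == "distance" && is.null(d2)) {
    d2 <- pairwise_phenotype_distance(
      data$phenotypes,
      metric = if (config$distance == "euclidean") "euclidean" else "standardized"
    )
  }
  raw <- .grow_trees_cpp(
    data$genotypes, data$phenotypes,
    if (is.null(d2)) matrix(0, 0, 0) else d2,
    as.integer(tree_id), as.integer(config$master_seed),
    if (config$criterion == "standard") 0L else 1L,
    if (config$covariance == "diagonal") 1L else 0L,
    as.integer(config$mtry), as.integer(config$min_node_size),
    config$var_floor
  )[[1]]
  new_mvrf_tree(raw, data, config)
}

new_mvrf_tree <- function(raw, data, config) {
  nodes <- raw$nodes
  structure(
    list(
      tree_id = raw$tree_id,
      nodes = nodes,
      gain = raw$gain,
      leaf_means = raw$leaf_means,
      leaf_bag = raw$leaf_bag,
      leaf_assign = raw$leaf_assign,
      oob = raw$oob,
      inbag_count = raw$inbag_count,
      snp_ids = colnames(data$genotypes),
      master_seed = config$master_seed
    ),
    class = "mvrf_tree"
  )
}

#' @method print mvrf_tree
#' @export
print.mvrf_tree <- function(x, ...) {
  cat("<mvrf_tree> id ", x$tree_id, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$leaf_means), " leaves, ", length(x$oob), " OOB samples\n",
      sep = "")
  invisible(x)
}

route_to_leaf <- function(tree, geno) {
  geno <- rbind(geno)
  nodes <- tree$nodes
  vapply(seq_len(nrow(geno)), function(i) {
    k <- 1L
    while (nodes[k, "leaf"] == 0L) {
      k <- if (geno[i, nodes[k, "snp"]] <= nodes[k, "threshold"]) {
        nodes[k, "left"]
      } else {
        nodes[k, "right"]
      }
    }
    nodes[k, "leaf"]
  }, integer(1))
}

#' Predict phenotype vectors with a single tree
#'
#' Routes genotype rows down the tree (left branch when the split SNP's
#' genotype is at most the threshold) and returns the mean phenotype
#' vector of the reached leaf's in-bag multiset.
#'
#' @param tree an `mvrf_tree`.
#' @param geno_row a genotype vector of length `P`, or an `n x P` matrix.
#' @return A `Q`-vector, or an `n x Q` matrix for matrix input.
#' @export
predict_tree <- function(tree, geno_row) {
  leaves <- route_to_leaf(tree, geno_row)
  out <- tree$leaf_means[leaves, , drop = FALSE]
  if (is.null(dim(geno_row)) || nrow(rbind(geno_row)) == 1L) out[1, ] else out
}

#' Leaf assignment of genotype rows
#'
#' Same routing as [predict_tree()], but returns the stable integer leaf
#' identifier instead of the leaf mean; two samples share a leaf exactly
#' when their identifiers agree, which is what the proximity matrix counts.
#'
#' @inheritParams predict_tree
#' @return Integer leaf id(s).
#' @export
leaf_assignment <- function(tree, geno_row) {
  route_to_leaf(tree, geno_row)
}
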