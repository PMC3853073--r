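#' Forest configuration
#'
#' Collects the tuning parameters of the forest.  `mtry` defaults to
#' `ceiling(P / 3)` and the minimum node size to 5 for a univariate trait
#' and 20 for multivariate traits.  The split criterion is either
#' `"standard"` (covariance-weighted sum of squares, identity or per-node
#' diagonal covariance) or `"distance"` (pairwise squared phenotype
#' distances, plain or root-standardized Euclidean); the two are
#' equivalent for identity covariance / Euclidean distance.
#'
#' @param ntree number of trees.
#' @param mtry candidate SNPs drawn (without replacement) at each node;
#'   clamped to `P` with a warning when larger.
#' @param min_node_size nodes smaller than this are not split.
#' @param criterion `"standard"` or `"distance"`.
#' @param covariance `"identity"` or `"diagonal"` (standard criterion only).
#' @param distance `"euclidean"` or `"standardized"` (distance criterion).
#' @param master_seed integer seeding every per-tree random stream.
#' @param n_workers number of map batches the tree ids are partitioned
#'   into; results are invariant to this.
#' @param proximity `"all"` routes every sample down every tree (counts
#'   over `Ntree`); `"oob"` counts only pairs jointly out of bag (counts
#'   over the number of trees where both are OOB).
#' @param var_floor positive floor for per-trait variance estimates.
#' @return An object of class `mvrf_config`.
#' @export
mvrf_config <- function(ntree = 200, mtry = NULL, min_node_size = NULL,
                        criterion = c("standard", "distance"),
                        covariance = c("identity", "diagonal"),
                        distance = c("euclidean", "standardized"),
                        master_seed = 1L, n_workers = 1L,
                        proximity = c("all", "oob"), var_floor = 1e-8) {
  if (ntree < 1) stop("`ntree` must be at least 1")
  structure(
    list(
      ntree = as.integer(ntree), mtry = mtry, min_node_size = min_node_size,
      criterion = match.arg(criterion), covariance = match.arg(covariance),
      distance = match.arg(distance), master_seed = as.integer(master_seed),
      n_workers = as.integer(n_workers), proximity = match.arg(proximity),
      var_floor = var_floor
    ),
    class = "mvrf_config"
  )
}

check_config <- function(config, data) {
  stopifnot(inherits(config, "mvrf_config"))
  p <- ncol(data$genotypes)
  q <- ncol(data$phenotypes)
  if (is.null(config$mtry)) config$mtry <- ceiling(p / 3)
  if (config$mtry > p) {
    warning("mtry (", config$mtry, ") exceeds the number of SNPs; clamped to ", p)
    config$mtry <- p
  }
  if (config$mtry < 1) stop("`mtry` must be at least 1")
  if (is.null(config$min_node_size)) {
    config$min_node_size <- if (q == 1L) 5L else 20L
  }
  if (config$min_node_size < 2) stop("`min_node_size` must be at least 2")
  config
}

#' Map phase: grow a batch of trees and emit keyed streams
#'
#' The map side of the forest's map/shuffle/reduce contract.  Each worker
#' holds the full data set and grows the trees whose ids it was assigned;
#' for every tree it emits (1) OOB sample predictions, (2) one
#' `(snp, gain)` record per accepted split, and (3) the leaf assignment of
#' every sample (the sparse encoding of the co-leaf pair stream).  Because
#' each tree is keyed by `(master_seed, tree_id)`, the merged emissions do
#' not depend on how tree ids are batched over workers.
#'
#' @inheritParams grow_tree
#' @param tree_ids integer vector of tree ids to grow.
#' @return An object of class `mvrf_emissions`: a list of per-tree records.
#' @export
map_build_trees <- function(data, tree_ids, config, d2 = NULL) {
  stopifnot(inherits(data, "mvrf_data"))
  config <- check_config(config, data)
  if (anyNA(data$genotypes)) {
    stop("genotypes contain missing calls; run impute_missing() before growth")
  }
  if (length(tree_ids) == 0L) {
    return(structure(list(), class = "mvrf_emissions"))
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
    as.integer(tree_ids), as.integer(config$master_seed),
    if (config$criterion == "standard") 0L else 1L,
    if (config$covariance == "diagonal") 1L else 0L,
    as.integer(config$mtry), as.integer(config$min_node_size),
    config$var_floor
  )
  recs <- lapply(raw, function(tr) {
    internal <- tr$nodes[, "leaf"] == 0L
    oob <- tr$oob
    yhat <- tr$leaf_means[tr$leaf_assign[oob], , drop = FALSE]
    list(
      tree_id = tr$tree_id,
      oob = oob,
      oob_pred = yhat,
      gains = list(snp = tr$nodes[internal, "snp"], gain = tr$gain[internal]),
      leaf_assign = tr$leaf_assign
    )
  })
  structure(recs, class = "mvrf_emissions")
}

merge_emissions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "mvrf_emissions")) {
    parts <- parts[[1]]
  }
  out <- do.call(c, lapply(unname(parts), unclass))
  out <- unname(out[order(vapply(out, `[[`, integer(1), "tree_id"))])
  structure(out, class = "mvrf_emissions")
}

#' Shuffle phase: group keyed emission values
#'
#' Groups a stream of `(key, value)` pairs by key, preserving the value
#' multiset and emitting keys in canonical (sorted) order — the in-process
#' analogue of the shuffle between map and reduce.
#'
#' @param keys vector of keys.
#' @param values vector (or list) of values, same length.
#' @return Named list, one element per distinct key, sorted by key.
#' @examples
#' shuffle_group(c("s1", "s2", "s1"), c(2, 7, 4))
#' @export
shuffle_group <- function(keys, values) {
  stopifnot(length(keys) == length(values))
  if (length(keys) == 0L) return(setNames(list(), character(0)))
  split(values, factor(keys, levels = sort(unique(keys))))
}

#' Reduce phase: out-of-bag prediction error
#'
#' For each sample, the OOB prediction is the element-wise mean of its
#' predictions over the trees in which it was out of bag (summed in tree-id
#' order, so the result is worker-invariant); the per-sample error is the
#' per-trait-averaged squared distance `(1/Q) * ||y_i - yhat_i||^2`, and the
#' overall OOB error is the mean over samples that were OOB at least once.
#'
#' @param emissions an `mvrf_emissions` object.
#' @param phenotypes the `N x Q` phenotype matrix.
#' @return List with `per_sample` (tibble: sample, n_oob, error) and
#'   `oob_error` (scalar).
#' @export
reduce_oob <- function(emissions, phenotypes) {
  n <- nrow(phenotypes)
  q <- ncol(phenotypes)
  pred_sum <- matrix(0, n, q)
  n_oob <- integer(n)
  for (rec in emissions) {
    idx <- rec$oob
    pred_sum[idx, ] <- pred_sum[idx, , drop = FALSE] + rec$oob_pred
    n_oob[idx] <- n_oob[idx] + 1L
  }
  covered <- n_oob > 0L
  if (!any(covered)) {
    stop("no sample was ever out of bag; increase ntree")
  }
  err <- rep(NA_real_, n)
  yhat <- pred_sum[covered, , drop = FALSE] / n_oob[covered]
  err[covered] <- rowSums((phenotypes[covered, , drop = FALSE] - yhat)^2) / q
  list(
    per_sample = tibble::tibble(
      sample = if (is.null(rownames(phenotypes))) as.character(seq_len(n))
               else rownames(phenotypes),
      n_oob = n_oob, error = err
    ),
    oob_error = mean(err[covered])
  )
}

#' Reduce phase: information-gain SNP importance
#'
#' Sums the split-function reduction `phi(j)` over every split made on each
#' SNP across all trees; SNPs never selected score 0.  Summation follows
#' tree-id order, so partial sums over tree blocks add up to the total.
#'
#' @param emissions an `mvrf_emissions` object.
#' @param snp_ids character vector of all SNP identifiers.
#' @return Named numeric vector of importance scores (one per SNP).
#' @export
reduce_importance <- function(emissions, snp_ids) {
  imp <- setNames(numeric(length(snp_ids)), snp_ids)
  for (rec in emissions) {
    g <- rec$gains
    if (length(g$snp) == 0L) next
    part <- rowsum(g$gain, g$snp)
    idx <- as.integer(rownames(part))
    imp[idx] <- imp[idx] + part[, 1]
  }
  imp
}

#' Reduce phase: proximity matrix
#'
#' Counts, for every unordered sample pair, the trees in which the two
#' samples share a leaf, and divides by the number of trees (mode
#' `"all"`: every sample routed down every tree) or by the number of trees
#' in which both samples were out of bag (mode `"oob"`; pairs never
#' jointly OOB get 0).  The diagonal is 1 by convention.
#'
#' @param emissions an `mvrf_emissions` object.
#' @param n_samples number of samples `N`.
#' @param mode `"all"` or `"oob"`.
#' @return Symmetric `N x N` proximity matrix with unit diagonal.
#' @export
reduce_proximity <- function(emissions, n_samples, mode = c("all", "oob")) {
  mode <- match.arg(mode)
  counts <- matrix(0, n_samples, n_samples)
  if (mode == "all") {
    for (rec in emissions) {
      la <- rec$leaf_assign
      counts <- counts + outer(la, la, "==")
    }
    prox <- counts / length(emissions)
  } else {
    denom <- matrix(0, n_samples, n_samples)
    for (rec in emissions) {
      o <- rec$oob
      la <- rec$leaf_assign[o]
      counts[o, o] <- counts[o, o] + outer(la, la, "==")
      denom[o, o] <- denom[o, o] + 1
    }
    prox <- ifelse(denom > 0, counts / pmax(denom, 1), 0)
  }
  if (any(prox > 1 + 1e-12)) stop("corrupted co-leaf stream: count exceeds ntree")
  diag(prox) <- 1
  (prox + t(prox)) / 2
}

#' Grow a forest through the map/shuffle/reduce contract
#'
#' Partitions tree ids `1..ntree` into `n_workers` contiguous batches, maps
#' [map_build_trees()] over the batches, merges the emission streams in
#' tree-id order, and reduces them into the three forest outputs: OOB
#' prediction error, information-gain SNP importance, and the sample
#' proximity matrix.  Because every tree is keyed by `(master_seed,
#' tree_id)` and reduction follows canonical tree order, the result is
#' bit-identical for any worker count.
#'
#' @inheritParams grow_tree
#' @param keep_emissions keep the raw per-tree emissions in the result
#'   (needed for OOB convergence curves; off by default).
#' @return An object of class `mvrf_forest` with elements `importance`
#'   (named vector), `oob` (list from [reduce_oob()]), `proximity`,
#'   `tree_gains` (per-tree split records, for [stability_curve()]),
#'   `ntree`, and `config`.
#' @seealso [mvrf()] for the data-first interface.
#' @export
run_forest <- function(data, config, keep_emissions = FALSE) {
  stopifnot(inherits(data, "mvrf_data"))
  config <- check_config(config, data)
  d2 <- NULL
  if (config$criterion == "distance") {
    d2 <- pairwise_phenotype_distance(
      data$phenotypes,
      metric = if (config$distance == "euclidean") "euclidean" else "standardized"
    )
  }
  ids <- seq_len(config$ntree)
  batches <- split(ids, ceiling(ids * min(config$n_workers, config$ntree) /
                                  config$ntree))
  parts <- lapply(batches, function(ids) map_build_trees(data, ids, config, d2))
  emissions <- merge_emissions(parts)
  oob <- reduce_oob(emissions, data$phenotypes)
  importance <- reduce_importance(emissions, colnames(data$genotypes))
  proximity <- reduce_proximity(emissions, nrow(data$genotypes),
                                mode = config$proximity)
  dimnames(proximity) <- list(rownames(data$genotypes),
                              rownames(data$genotypes))
  structure(
    list(
      importance = importance,
      oob = oob,
      oob_error = oob$oob_error,
      proximity = proximity,
      tree_gains = lapply(emissions, function(r) {
        list(tree_id = r$tree_id, snp = r$gains$snp, gain = r$gains$gain)
      }),
      emissions = if (keep_emissions) emissions else NULL,
      ntree = config$ntree,
      n_samples = nrow(data$genotypes),
      n_snps = ncol(data$genotypes),
      n_traits = ncol(data$phenotypes),
      config = config
    ),
    class = "mvrf_forest"
  )
}

#' Random-forest regression of multivariate traits on genotypes
#'
#' Convenience wrapper assembling an [mvrf_config()] and calling
#' [run_forest()].
#'
#' @inheritParams mvrf_data
#' @inheritDotParams mvrf_config
#' @return An `mvrf_forest`; see [run_forest()].
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   n_samples = 60, n_snps = 40, n_traits = 5, master_seed = 7
#' ))
#' fit <- mvrf(sim$data$genotypes, sim$data$phenotypes, ntree = 25)
#' glance(fit)
#' head(tidy(fit))
#' @export
mvrf <- function(genotypes, phenotypes, snp_info = NULL, ...) {
  run_forest(mvrf_data(genotypes, phenotypes, snp_info), mvrf_config(...))
}

#' @method print mvrf_forest
#' @export
print.mvrf_forest <- function(x, ...) {
  cat("<mvrf_forest> ", x$ntree, " trees (", x$config$criterion,
      " criterion), ", x$n_samples, " samples, ", x$n_snps, " SNPs, ",
      x$n_traits, " traits\n", sep = "")
  cat("  OOB error: ", format(x$oob_error, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @describeIn mvrf Importance ranking as a tibble (snp_id, importance, rank).
#' @param x an `mvrf_forest`.
#' @export
tidy.mvrf_forest <- function(x, ...) {
  rank_snps(x$importance)
}

#' @describeIn mvrf One-row model summary.
#' @export
glance.mvrf_forest <- function(x, ...) {
  tibble::tibble(
    ntree = x$ntree, n = x$n_samples, p = x$n_snps, q = x$n_traits,
    criterion = x$config$criterion, oob_error = x$oob_error
  )
}

#' @describeIn mvrf Bar chart of the top-`n` SNP importances.
#' @param object an `mvrf_forest`.
#' @param n number of top SNPs shown.
#' @export
autoplot.mvrf_forest <- function(object, n = 20, ...) {
  d <- head(rank_snps(object$importance), n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$snp_id, .data$importance)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "information-gain importance", y = NULL)
}
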