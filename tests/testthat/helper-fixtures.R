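# Fixtures built in code: tiny hand-checkable data sets and small helpers.

# Three samples with phenotypes (0,0), (1,0), (0,2): node SS 10/3 under the
# identity covariance; pairwise squared distances {1, 5, 4}.
tiny_phenos <- function() {
  matrix(c(0, 1, 0,
           0, 0, 2), ncol = 2,
         dimnames = list(paste0("s", 1:3), c("t1", "t2")))
}

# Matching 3-sample genotype matrix: snp_a splits {s1,s2} | {s3} at t = 0,
# snp_b is constant, snp_c duplicates snp_a (tie-break probe).
tiny_data <- function() {
  g <- matrix(c(0L, 0L, 1L,
                1L, 1L, 1L,
                0L, 0L, 1L), ncol = 3,
              dimnames = list(paste0("s", 1:3), c("snp_a", "snp_b", "snp_c")))
  mvrf_data(g, tiny_phenos())
}

# A data set in which one SNP perfectly separates two phenotype clusters.
separable_data <- function(n_per_group = 10, q = 3, shift = 50, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per_group
  g <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  g[, 3] <- rep(c(0L, 2L), each = n_per_group)
  storage.mode(g) <- "integer"
  y <- matrix(rnorm(n * q, sd = 0.1), n, q)
  y[(n_per_group + 1):n, ] <- y[(n_per_group + 1):n, ] + shift
  mvrf_data(g, y)
}

small_sim <- function(seed, n = 70, p = 90, q = 8, ...) {
  simulate_dataset(simulation_config(
    n_samples = n, n_snps = p, n_traits = q, master_seed = seed, ...
  ))
}

# Multiset of the sample indices reaching each node, reconstructed from the
# per-leaf in-bag bags (leaves partition the bag; internal nodes are unions).
node_multisets <- function(tree) {
  nodes <- tree$nodes
  out <- vector("list", nrow(nodes))
  recurse <- function(k) {
    if (nodes[k, "leaf"] > 0L) {
      out[[k]] <<- sort(tree$leaf_bag[[nodes[k, "leaf"]]])
    } else {
      recurse(nodes[k, "left"])
      recurse(nodes[k, "right"])
      out[[k]] <<- sort(c(out[[nodes[k, "left"]]], out[[nodes[k, "right"]]]))
    }
  }
  recurse(1L)
  out
}

# Least-squares Procrustes residual after centring, optimal rotation /
# reflection and no scaling mismatch beyond what the fit allows.
procrustes_residual <- function(x, y) {
  x <- scale(x, scale = FALSE)
  y <- scale(y, scale = FALSE)
  s <- svd(crossprod(y, x))
  rot <- s$u %*% t(s$v)
  sqrt(sum((x - y %*% rot)^2))
}

# Structure of a fitted tree, stripped of floating-point gain values: used
# for bit-identity comparisons across split criteria.
tree_shape <- function(emission_or_tree) {
  x <- emission_or_tree
  if (inherits(x, "mvrf_tree")) {
    list(nodes = x$nodes, leaf = x$leaf_assign, oob = x$oob)
  } else {
    list(leaf = x$leaf_assign, oob = x$oob, snp = x$gains$snp)
  }
}
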