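test_that("bootstrap sample covers all indices and matches closed-form OOB rate", {
  expect_error(bootstrap_sample(0), "positive")
  set.seed(1)
  b1 <- bootstrap_sample(1)
  expect_identical(b1$in_bag, 1L)
  expect_length(b1$oob, 0)

  # E[OOB fraction] = (1 - 1/N)^N; Monte Carlo at N = 4 over 1e5 draws
  set.seed(42)
  n_rep <- 1e5
  oob_frac <- vapply(seq_len(n_rep),
                     function(i) length(bootstrap_sample(4)$oob) / 4,
                     numeric(1))
  expect_equal(mean(oob_frac), (3 / 4)^4, tolerance = 0.01)

  set.seed(7)
  b <- bootstrap_sample(100)
  expect_length(b$in_bag, 100)
  expect_setequal(c(b$in_bag, b$oob), 1:100)
})

test_that("node sum of squares agrees between direct and distance evaluation", {
  y <- tiny_phenos()
  expect_equal(node_ss_standard(y), 10 / 3)
  expect_equal(node_ss_standard(y[1, , drop = FALSE]), 0)
  expect_equal(node_ss_standard(y[c(2, 2, 2), ]), 0)

  d2 <- pairwise_phenotype_distance(y)
  expect_equal(sort(d2[upper.tri(d2)]), c(1, 4, 5))
  expect_equal(node_ss_distance(d2, 1:3), 10 / 3)
  expect_equal(node_ss_distance(d2, 2L), 0)
  expect_equal(node_ss_distance(d2, rep(3L, 5)), 0)
  expect_error(node_ss_distance(d2, integer(0)), "empty")
  expect_error(node_ss_standard(y[0, , drop = FALSE]), "empty")
})

test_that("identity-covariance SS and pairwise-distance SS agree on random multisets", {
  set.seed(99)
  for (q in c(1, 5, 100)) {
    y <- matrix(rnorm(40 * q), 40, q)
    d2 <- pairwise_phenotype_distance(y)
    for (rep in 1:100) {
      idx <- sample.int(40, sample(2:40, 1), replace = TRUE)
      a <- node_ss_standard(y[idx, , drop = FALSE])
      b <- node_ss_distance(d2, idx)
      expect_equal(b, a, tolerance = 1e-10)
    }
  }
})

test_that("node covariance estimation floors variances and honours the identity", {
  idcov <- estimate_node_covariance(tiny_phenos(), "identity")
  expect_true(idcov$identity)
  rows <- matrix(c(0, 2, 0, 0), ncol = 2)
  dg <- estimate_node_covariance(rows, "diagonal")
  expect_equal(dg$diag, c(2, 1e-8))
  expect_error(estimate_node_covariance(rows[1, , drop = FALSE], "diagonal"),
               "at least 2")
  # weighting by the diagonal rescales per-trait contributions
  expect_equal(node_ss_standard(rows, dg), 2 / 2 + 0)
})

test_that("allowable splits are ordinal thresholds, de-duplicated", {
  expect_identical(enumerate_splits(c(0L, 1L, 2L)), c(0L, 1L))
  expect_identical(enumerate_splits(c(0L, 2L, 2L)), 0L)
  expect_identical(enumerate_splits(c(1L, 1L, 1L)), integer(0))
  expect_identical(enumerate_splits(c(1L, 2L)), 1L)
  expect_identical(enumerate_splits(c(0L, 1L)), 0L)
})

test_that("best_split maximises the SS reduction with deterministic tie-breaks", {
  d <- tiny_data()
  bs <- best_split(1:3, 1:2, d)
  expect_equal(bs$snp_index, 1)
  expect_equal(bs$threshold, 0)
  expect_equal(bs$gain, 10 / 3 - 0.5, tolerance = 1e-12)
  expect_equal(bs$left_size, 2)
  expect_equal(bs$right_size, 1)

  # identical partitions: the lower SNP index wins
  tie <- best_split(1:3, c(1, 3), d)
  expect_equal(tie$snp_index, 1)

  # constant candidates admit no split
  expect_null(best_split(1:3, 2L, d))

  # distance criterion scores the same split identically
  bd <- best_split(1:3, 1:2, d, criterion = "distance")
  expect_equal(bd$snp_index, 1)
  expect_equal(bd$gain, bs$gain, tolerance = 1e-10)
})

test_that("grow_tree splits a perfectly separating SNP at the root", {
  d <- separable_data()
  cfg <- mvrf_config(ntree = 1, mtry = 6, min_node_size = 2, master_seed = 3)
  tr <- grow_tree(d, cfg, tree_id = 1)
  expect_equal(unname(tr$nodes[1, "snp"]), 3)
  # exhaustive oracle: the root gain must equal the best over all SNPs
  bag <- sort(unlist(tr$leaf_bag))
  oracle <- best_split(bag, 1:6, d)
  expect_equal(oracle$snp_index, 3)
  expect_equal(tr$gain[1], oracle$gain, tolerance = 1e-8)
})

test_that("large min_node_size yields a single-leaf tree predicting the bag mean", {
  d <- tiny_data()
  cfg <- mvrf_config(ntree = 1, mtry = 3, min_node_size = 10, master_seed = 5)
  tr <- grow_tree(d, cfg)
  expect_equal(nrow(tr$nodes), 1L)
  bag <- tr$leaf_bag[[1]]
  expect_equal(unname(predict_tree(tr, c(2L, 2L, 2L))),
               unname(colMeans(d$phenotypes[bag, , drop = FALSE])))
})

test_that("tree growth is deterministic in (master_seed, tree_id)", {
  d <- small_sim(21)$data
  cfg <- mvrf_config(ntree = 1, master_seed = 77)
  t1 <- grow_tree(d, cfg, tree_id = 9)
  t2 <- grow_tree(d, cfg, tree_id = 9)
  expect_identical(t1[names(t1) != "tree_id"], t2[names(t2) != "tree_id"])
  t3 <- grow_tree(d, cfg, tree_id = 10)
  expect_false(identical(t1$leaf_assign, t3$leaf_assign))
})

test_that("mtry above P is clamped with a warning", {
  d <- tiny_data()
  expect_warning(
    grow_tree(d, mvrf_config(ntree = 1, mtry = 50, min_node_size = 2)),
    "clamped"
  )
})

test_that("prediction and leaf assignment route deterministically", {
  d <- separable_data()
  cfg <- mvrf_config(ntree = 1, mtry = 6, min_node_size = 5, master_seed = 13)
  tr <- grow_tree(d, cfg)
  g_low <- d$genotypes[1, ]
  g_high <- d$genotypes[15, ]
  p_low <- predict_tree(tr, g_low)
  p_high <- predict_tree(tr, g_high)
  # cluster means are ~0 and ~50: routing must recover the right side
  expect_lt(max(abs(p_low)), 5)
  expect_gt(min(p_high), 45)
  expect_identical(leaf_assignment(tr, g_low), leaf_assignment(tr, g_low))
  expect_false(leaf_assignment(tr, g_low) == leaf_assignment(tr, g_high))
  # samples routed to the same leaf get identical predictions
  same <- leaf_assignment(tr, d$genotypes)
  i <- which(same == same[1])
  preds <- predict_tree(tr, d$genotypes[i, , drop = FALSE])
  expect_true(all(apply(preds, 2, function(v) max(v) - min(v)) == 0))
})

test_that("recorded split gains match the pure-R split scorer on every node", {
  sim <- small_sim(31)
  d <- sim$data
  for (crit in c("standard", "distance")) {
    cfg <- mvrf_config(ntree = 1, criterion = crit, min_node_size = 8,
                       master_seed = 101)
    tr <- grow_tree(d, cfg)
    sets <- node_multisets(tr)
    internal <- which(tr$nodes[, "leaf"] == 0L)
    expect_gt(length(internal), 2)
    d2 <- pairwise_phenotype_distance(d$phenotypes)
    root_ss <- node_ss_distance(d2, sets[[1]])
    leaf_ss <- sum(vapply(which(tr$nodes[, "leaf"] > 0L),
                          function(k) node_ss_distance(d2, sets[[k]]),
                          numeric(1)))
    expect_lte(leaf_ss, root_ss + 1e-8)
    for (k in internal) {
      expect_gt(tr$gain[k], 0) # phi(j) >= 0 for accepted splits
      ref <- best_split(sets[[k]], tr$nodes[k, "snp"], d, criterion = crit,
                        d2 = d2)
      expect_equal(ref$threshold, unname(tr$nodes[k, "threshold"]))
      expect_equal(tr$gain[k], ref$gain, tolerance = 1e-8)
      # the accepted gain never beats the exhaustive best over all SNPs
      global <- best_split(sets[[k]], seq_len(ncol(d$genotypes)), d,
                           criterion = crit, d2 = d2)
      expect_lte(tr$gain[k], global$gain + 1e-8)
    }
  }
})
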