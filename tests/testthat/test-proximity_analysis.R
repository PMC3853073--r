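test_that("proximity converts to a genetic distance", {
  p <- matrix(c(1, 0.25, 0.25, 1), 2, 2)
  d <- proximity_to_distance(p)
  expect_equal(d[1, 2], 0.75)
  expect_equal(diag(d), c(0, 0))
  expect_equal(proximity_to_distance(diag(3))[1, 2], 1)
  bad <- p; bad[1, 2] <- 0.5
  expect_error(proximity_to_distance(bad), "symmetric")
  expect_error(proximity_to_distance(p * 2), "\\[0, 1\\]")
})

test_that("classical MDS recovers Euclidean-embeddable configurations", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1))
  d <- as.matrix(dist(pts))
  coords <- classical_mds(d, n_dims = 2)
  expect_lt(procrustes_residual(pts, coords), 1e-8)
  expect_equal(colMeans(coords), c(dim1 = 0, dim2 = 0))

  # all-equal distances embed as an equilateral triangle
  eq <- classical_mds(matrix(1, 3, 3) - diag(3), n_dims = 2)
  de <- dist(eq)
  expect_equal(max(de) - min(de), 0, tolerance = 1e-10)

  # duplicated samples land on identical coordinates
  d4 <- as.matrix(dist(rbind(pts, c(0, 0))))
  c4 <- classical_mds(d4, n_dims = 2)
  expect_equal(unname(c4[1, ]), unname(c4[4, ]), tolerance = 1e-10)

  # embedded pairwise distances reproduce the input to high accuracy
  set.seed(8)
  x <- matrix(rnorm(30), 10, 3)
  dd <- as.matrix(dist(x))
  cc <- classical_mds(dd, n_dims = 3)
  expect_lt(max(abs(as.matrix(dist(cc)) - dd)), 1e-8)

  # asking for more dimensions than positive eigenvalues pads with zeros
  expect_warning(cp <- classical_mds(as.matrix(dist(cbind(1:5))), n_dims = 3),
                 "padding")
  expect_equal(unname(cp[, 3]), rep(0, 5))
  expect_error(classical_mds(d, n_dims = 3), "more samples")
})

test_that("Mantel r is the upper-triangle correlation with a one-sided null", {
  set.seed(20)
  x <- matrix(rnorm(24), 8, 3)
  d1 <- as.matrix(dist(x))
  res <- mantel_test(d1, d1, n_perm = 200)
  expect_equal(res$r, 1)
  expect_lte(res$p_value, 0.05)
  expect_error(mantel_test(d1[1:3, 1:3], d1[1:3, 1:3]), "at least 4")
  expect_error(mantel_test(d1, d1[1:4, 1:4]), "match"
  )
})

test_that("hierarchical clusters recover well-separated clouds, ordered on axis 1", {
  set.seed(30)
  centers <- cbind(c(-9, -3, 3, 9), 0)
  truth <- rep(1:4, each = 10)
  coords <- centers[truth, ] + matrix(rnorm(80, sd = 0.3), 40, 2)
  lab <- hierarchical_clusters(coords, 4)
  expect_equal(as.integer(table(truth, lab) > 0), as.integer(diag(4) > 0))
  expect_identical(levels(lab), paste0("C", 1:4))
  # C1 sits at the low end of the dominant axis
  expect_lt(mean(coords[lab == "C1", 1]), mean(coords[lab == "C4", 1]))
  # a reference marker can flip the orientation
  ref <- truth == 4
  lab_ref <- hierarchical_clusters(coords, 4, reference = ref)
  expect_true(all(lab_ref[truth == 4] == "C1"))
  # permuting sample order permutes labels but not the partition
  perm <- sample(40)
  lab_p <- hierarchical_clusters(coords[perm, ], 4)
  expect_equal(as.character(lab_p), as.character(lab[perm]))
  # n_clusters = N gives singletons
  expect_equal(length(unique(hierarchical_clusters(coords[1:5, ], 5))), 5)
})

test_that("severity distances follow centroid geometry", {
  coords <- rbind(
    c(0, 0, 0), c(0, 0, 0),      # C1 centroid at origin
    c(1, 1, 0), c(2, 0, 1),      # middle clusters
    c(4, 0, 0), c(4, 0, 0)       # C4 centroid at (4, 0, 0)
  )
  labels <- factor(c("C1", "C1", "C2", "C3", "C4", "C4"),
                   levels = paste0("C", 1:4))
  sev <- severity_distances(coords, labels)
  expect_equal(sev$euclidean_severity[1], 0)
  expect_equal(sev$projected_severity[1], 0)
  expect_equal(sev$euclidean_severity[5], 4)
  expect_equal(sev$projected_severity[5], 4)
  # a point orthogonal to the C1->C4 axis: euclidean h, projection 0
  sev_h <- severity_distances(rbind(coords, c(0, 3, 0)),
                              factor(c(as.character(labels), "C2"),
                                     levels = paste0("C", 1:4)))
  expect_equal(sev_h$euclidean_severity[7], 3)
  expect_equal(sev_h$projected_severity[7], 0)
  expect_error(severity_distances(coords, factor(rep("C2", 6),
                                                 levels = paste0("C", 1:4))),
               "non-empty")
})

test_that("mutated-state counts follow the minor-allele rule", {
  g <- rbind(a = c(0L, 1L, 2L, 0L), b = c(0L, 0L, 0L, 0L),
             c = c(2L, 2L, 2L, 2L))
  colnames(g) <- paste0("s", 1:4)
  ranking <- rank_snps(setNames(4:1, paste0("s", 1:4)))
  counts <- count_mutated_states(g, ranking, k = 4)
  expect_equal(counts$mutated_states, c(2L, 0L, 4L))
  expect_equal(count_mutated_states(g, ranking, k = 2)$mutated_states[1], 1L)
})

test_that("pattern mining retains frequent, C4-enriched pairs", {
  # 10 samples; SNPs s1, s2 jointly heterozygous in 6, all of them in C4
  g <- matrix(0L, 10, 3, dimnames = list(paste0("i", 1:10),
                                         c("s1", "s2", "s3")))
  g[1:6, 1] <- 1L
  g[1:6, 2] <- 1L
  g[c(1, 7), 3] <- 2L
  labels <- factor(rep(c("C4", "C1"), c(6, 4)), levels = c("C1", "C4"))
  ranking <- rank_snps(c(s1 = 3, s2 = 2, s3 = 1))
  res <- mine_mutation_patterns(g, ranking, labels, top_n = 3)
  pat <- res$patterns
  hit <- pat[pat$snp_a == "s1" & pat$snp_b == "s2" &
               pat$state_a == 1 & pat$state_b == 1, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$freq_all, 0.6)
  expect_equal(hit$freq_c4, 1)
  # one-sided z against the overall rate: z = (1 - 0.6)/sqrt(0.6*0.4/6) = 2
  expect_equal(hit$p_value, 1 - pnorm(2), tolerance = 1e-12)
  # the exact binomial tail agrees on the direction of the call
  expect_lte(pbinom(5, 6, 0.6, lower.tail = FALSE), 0.05)
  expect_equal(res$sample_counts$pattern_count[1:6],
               rep(1L, 6))

  # a pattern below the frequency gate is excluded regardless of enrichment
  sparse <- mine_mutation_patterns(g, ranking, labels, top_n = 3,
                                   min_freq = 0.7)
  expect_equal(nrow(sparse$patterns), 0)

  # a pattern equally frequent in C4 and overall is not retained
  labels2 <- factor(rep(c("C4", "C1"), 5), levels = c("C1", "C4"))
  g2 <- g
  g2[, 1] <- rep(c(1L, 1L, 0L, 0L, 1L), 2)
  g2[, 2] <- g2[, 1]
  res2 <- mine_mutation_patterns(g2, ranking, labels2, top_n = 2)
  expect_equal(nrow(res2$patterns), 0)
})

test_that("pattern retention is monotone in min_freq and alpha", {
  sim <- small_sim(91, n = 80, p = 30, q = 4)
  g <- sim$data$genotypes
  set.seed(91)
  labels <- factor(sample(rep(paste0("C", 1:4), each = 20)),
                   levels = paste0("C", 1:4))
  ranking <- rank_snps(setNames(runif(30), colnames(g)))
  base <- mine_mutation_patterns(g, ranking, labels, top_n = 20,
                                 min_freq = 0.05, alpha = 0.2)
  key <- function(p) paste(p$snp_a, p$state_a, p$snp_b, p$state_b)
  tighter_freq <- mine_mutation_patterns(g, ranking, labels, top_n = 20,
                                         min_freq = 0.2, alpha = 0.2)
  tighter_alpha <- mine_mutation_patterns(g, ranking, labels, top_n = 20,
                                          min_freq = 0.05, alpha = 0.05)
  expect_true(all(key(tighter_freq$patterns) %in% key(base$patterns)))
  expect_true(all(key(tighter_alpha$patterns) %in% key(base$patterns)))
})

test_that("severity correlation reports r, slope and its t-test", {
  sev <- seq(0, 5, length.out = 20)
  res <- suppressWarnings(severity_correlation(2 * sev, sev))
  expect_equal(res$r, 1)
  expect_equal(res$slope, 0.5)
  expect_lt(res$p_value, 1e-10)
  expect_warning(flat <- severity_correlation(rep(1, 10), rnorm(10)),
                 "zero variance")
  expect_true(is.na(flat$r))
  mask <- rep(c(TRUE, FALSE), 10)
  expect_equal(suppressWarnings(severity_correlation(2 * sev, sev, mask))$n, 10)
})

test_that("forest genetic distance predicts phenotypic distance when genetics drives the trait", {
  sim <- simulate_dataset(simulation_config(
    n_samples = 120, n_snps = 200, n_traits = 10, n_causal = 20,
    target_var_explained = 0.5, covariance = "identity", master_seed = 314
  ))
  f <- run_forest(sim$data, mvrf_config(ntree = 300, criterion = "distance",
                                        master_seed = 315))
  d_gen <- proximity_to_distance(f$proximity)
  d_phe <- phenotype_distance(sim$data$phenotypes)
  set.seed(316)
  res <- mantel_test(d_gen, d_phe, n_perm = 10000)
  expect_gt(res$r, 0)
  expect_lte(res$p_value, 0.01)
})
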