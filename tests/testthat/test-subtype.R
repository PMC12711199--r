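test_that("log transform is exact log2(x + 1)", {
  m <- matrix(c(0, 1, 3, 7), nrow = 2,
              dimnames = list(c("A", "B"), c("S1", "S2")))
  got <- log_transform_expression(m)
  expect_equal(unname(got), matrix(c(0, 1, 2, 3), nrow = 2))
  expect_error(log_transform_expression(m - 1),
               class = "memoryscreen_negative_value")
})

test_that("Ward clustering recovers separated blobs and names them low-to-high", {
  set.seed(71)
  n_per <- 30
  centers <- c(1, 5, 9)
  m <- do.call(cbind, lapply(centers, function(cc) {
    matrix(rnorm(4 * n_per, mean = cc, sd = 0.3), nrow = 4)
  }))
  rownames(m) <- paste0("HUB", 1:4)
  colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  truth <- rep(1:3, each = n_per)

  groups <- cluster_by_hub_genes(m, k = 3)
  expect_equal(adjusted_rand_index(groups$cluster, truth), 1)
  # low/medium/high naming: cluster 1 is the low-expression blob
  expect_true(all(groups$cluster[truth == 1] == 1))
  expect_true(all(groups$cluster[truth == 3] == 3))

  # deterministic across reruns
  expect_identical(as.data.frame(groups),
                   as.data.frame(cluster_by_hub_genes(m, k = 3)))

  # permuting sample columns permutes labels identically
  perm <- sample(ncol(m))
  g2 <- cluster_by_hub_genes(m[, perm], k = 3)
  expect_equal(g2$cluster, groups$cluster[perm])
})

test_that("k = n forces singleton clusters and k > n errors", {
  m <- matrix(c(1, 2, 10, 11, 20, 21), nrow = 2,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  g <- cluster_by_hub_genes(m, k = 3)
  expect_equal(sort(unique(g$cluster)), 1:3)
  expect_error(cluster_by_hub_genes(m, k = 4),
               class = "memoryscreen_invalid_parameter")
})

test_that("TMB counts qualifying records per sample and zero-fills", {
  mut <- data.frame(
    gene = c("TP53", "TP53", "KRAS", "EGFR", "TP53"),
    sample = c("S1", "S1", "S1", "S1", "S2"),
    variant_class = c("Missense_Mutation", "Missense_Mutation",
                      "Missense_Mutation", "Silent", "Nonsense_Mutation"))
  tmb <- compute_tmb(mut, c("S1", "S2", "S3"))
  expect_equal(tmb$tmb_count, c(3L, 1L, 0L))   # silent excluded, S3 zero-filled
  tmb_mb <- compute_tmb(mut, c("S1", "S2"), capture_size_mb = 38)
  expect_equal(tmb_mb$tmb_per_mb, c(3, 1) / 38)
  # additive over disjoint partitions of the table
  part1 <- mut[1:2, ]; part2 <- mut[3:5, ]
  expect_equal(compute_tmb(part1, c("S1", "S2"))$tmb_count +
                 compute_tmb(part2, c("S1", "S2"))$tmb_count,
               compute_tmb(mut, c("S1", "S2"))$tmb_count)
})

test_that("TMB on a 20-record toy table matches a hand tally", {
  set.seed(83)
  classes <- c("Missense_Mutation", "Silent", "Nonsense_Mutation")
  mut <- data.frame(gene = sample(LETTERS[1:5], 20, replace = TRUE),
                    sample = sample(c("S1", "S2", "S3"), 20, replace = TRUE),
                    variant_class = sample(classes, 20, replace = TRUE))
  tally <- vapply(c("S1", "S2", "S3"), function(s) {
    sum(mut$sample == s & mut$variant_class != "Silent")
  }, integer(1))
  expect_equal(compute_tmb(mut, c("S1", "S2", "S3"))$tmb_count,
               unname(tally))
})

test_that("differential mutation reproduces the exhaustive Fisher enumeration", {
  groups <- data.frame(sample_id = sprintf("S%02d", 1:20),
                       cluster = rep(c(1L, 2L), each = 10))
  carriers <- c(sprintf("S%02d", 1:8), "S11")   # 8/10 vs 1/10
  mut <- data.frame(gene = "KRAS", sample = carriers,
                    variant_class = "Missense_Mutation")
  res <- differential_mutation(mut, groups, pair = c(1L, 2L))
  expect_equal(res$p_value, fisher_enumeration(8, 2, 1, 9), tolerance = 1e-9)
  expect_equal(res$carriers_1, 8L)
  expect_equal(res$carriers_2, 1L)

  # identical carrier proportions -> p = 1
  mut2 <- data.frame(gene = "TP53",
                     sample = c(sprintf("S%02d", 1:5), sprintf("S%02d", 11:15)),
                     variant_class = "Missense_Mutation")
  expect_equal(differential_mutation(mut2, groups, c(1L, 2L))$p_value, 1)

  # swapping the two clusters leaves p unchanged
  expect_equal(differential_mutation(mut, groups, c(2L, 1L))$p_value,
               res$p_value, tolerance = 1e-12)

  expect_error(differential_mutation(mut, groups, c(1L, 9L)),
               class = "memoryscreen_invalid_parameter")
})

test_that("BH adjustment spans the genes tested and degenerate genes are skipped", {
  set.seed(91)
  groups <- data.frame(sample_id = sprintf("S%02d", 1:30),
                       cluster = rep(c(1L, 2L), each = 15))
  mut <- do.call(rbind, lapply(1:6, function(i) {
    carriers <- sample(groups$sample_id, sample(3:12, 1))
    data.frame(gene = paste0("G", i), sample = carriers,
               variant_class = "Missense_Mutation")
  }))
  res <- differential_mutation(mut, groups, c(1L, 2L))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  # a gene mutated only outside the two clusters contributes nothing
  mut3 <- rbind(mut, data.frame(gene = "GX", sample = "S99",
                                variant_class = "Missense_Mutation"))
  expect_false("GX" %in% differential_mutation(mut3, groups, c(1L, 2L))$gene)
})
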