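test_that("SAS matches direct substitution into its defining formula", {
  # disjoint significance: c = 0
  expect_equal(sas_score(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # a = 1, b = 1, c = 1 -> 1 / (1 + 1 - 2 + 1) = 1
  expect_equal(sas_score(c(1, 0, 0), c(1, 0, 0)), 1)
  # a = 3, b = 2, c = 1 -> 1 / (3 + 2 - 2 + 1) = 0.25
  expect_equal(sas_score(c(1, 1, 1, 0, 0), c(1, 0, 0, 1, 0)), 0.25)
  # a = b = c = 2 -> 2 / (2 + 2 - 4 + 1) = 2: the printed formula exceeds 1
  # on perfectly concordant vectors; kept as defined.
  expect_equal(sas_score(c(1, 1, 0, 0), c(1, 1, 0, 0)), 2)
  # bounded variant for the same vectors
  expect_equal(sas_score(c(1, 1, 0, 0), c(1, 1, 0, 0), normalized = TRUE), 1)
  expect_error(sas_score(c(1, 0), c(1, 0, 0)), class = "memoryscreen_invalid_format")
})

test_that("SAS is symmetric and equals the brute-force count on exhaustive small vectors", {
  for (len in 2:5) {
    grid <- expand.grid(rep(list(0:1), len))
    for (i in seq_len(nrow(grid))) {
      for (j in seq_len(nrow(grid))) {
        va <- as.numeric(grid[i, ]); vb <- as.numeric(grid[j, ])
        expect_identical(sas_score(va, vb), sas_score(vb, va))
        expect_identical(sas_score(va, vb), sas_bruteforce(va, vb))
      }
    }
  }
})

test_that("candidate pair enumeration covers GEAR-to-all with unordered dedup", {
  set.seed(41)
  k <- array(rbinom(1 * 4 * 20, 1, 0.5), dim = c(1, 4, 20))
  tensor <- structure(list(k = k, sizes = 8L,
                           gene_ids = c("G1", "G2", "G3", "G4"), n_perm = 20L),
                      class = "significance_tensor")
  edges <- compute_sas_edges(tensor, c("G1", "G2"))
  # 2 GEARs x 3 partners = 6 ordered pairs, minus the duplicated G1-G2 pair
  expect_equal(nrow(edges), 5L)
  expect_true(all(edges$gene_u < edges$gene_v))
  expect_error(compute_sas_edges(tensor, character()),
               class = "memoryscreen_empty_gears")

  # scores equal the naive double loop
  for (r in seq_len(nrow(edges))) {
    va <- k[1, match(edges$gene_u[r], tensor$gene_ids), ]
    vb <- k[1, match(edges$gene_v[r], tensor$gene_ids), ]
    expect_equal(edges$sas[r], sas_bruteforce(va, vb))
  }
})

test_that("an all-zero first gradient yields all-zero SAS", {
  k <- array(0L, dim = c(1, 3, 10))
  tensor <- structure(list(k = k, sizes = 5L, gene_ids = c("A", "B", "C"),
                           n_perm = 10L), class = "significance_tensor")
  edges <- compute_sas_edges(tensor, "A")
  expect_true(all(edges$sas == 0))
})

test_that("CSN keeps the top-k edges under a deterministic total order", {
  edges <- data.frame(
    gene_u = c("A", "A", "B", "B", "C"),
    gene_v = c("B", "C", "C", "D", "D"),
    sas = c(0.9, 0.5, 0.5, 0.2, 0.1),
    c = c(9, 5, 5, 2, 1), a = 1, b = 1)
  csn <- build_csn(edges, top_k = 3)
  expect_equal(nrow(csn$edges), 3L)
  expect_equal(csn$edges$sas, c(0.9, 0.5, 0.5))
  # tie at the cutoff between A-C and B-C (same sas, same c): lexicographic
  # order keeps A-C first; with top_k = 2 only A-C survives
  csn2 <- build_csn(edges, top_k = 2)
  expect_identical(csn2$edges$gene_u, c("A", "A"))
  expect_identical(csn2$edges$gene_v, c("B", "C"))

  # degrees equal a brute-force incidence count
  inc <- table(c(csn$edges$gene_u, csn$edges$gene_v))
  expect_equal(as.integer(csn$degree[names(inc)]), as.integer(inc))
})

test_that("graph construction is a pure function of the edge collection", {
  set.seed(61)
  genes <- paste0("G", 1:12)
  edges <- data.frame(gene_u = sample(genes, 30, replace = TRUE),
                      gene_v = sample(genes, 30, replace = TRUE),
                      sas = runif(30), c = rpois(30, 3), a = 1, b = 1)
  edges <- edges[edges$gene_u != edges$gene_v, ]
  u <- pmin(edges$gene_u, edges$gene_v); v <- pmax(edges$gene_u, edges$gene_v)
  edges$gene_u <- u; edges$gene_v <- v
  edges <- edges[!duplicated(paste(u, v)), ]
  c1 <- build_csn(edges, top_k = 10)
  c2 <- build_csn(edges[sample(nrow(edges)), ], top_k = 10)
  expect_identical(c1$edges, c2$edges)
  expect_identical(c1$degree, c2$degree)
})

test_that("hub selection enforces GEAR membership, the strict TPM floor and tie order", {
  expr <- matrix(10, nrow = 4, ncol = 3,
                 dimnames = list(c("A", "B", "C", "D"), c("S1", "S2", "S3")))
  expr["A", ] <- c(30, 30, 30)     # mean 30
  expr["B", ] <- c(10, 10, 10)     # mean exactly 10 -> excluded (strict >)
  expr["C", ] <- c(11, 11, 11)
  expr["D", ] <- c(50, 50, 50)     # not a GEAR -> ineligible
  edges <- data.frame(gene_u = c("A", "A", "B", "C"),
                      gene_v = c("B", "C", "C", "D"),
                      sas = c(0.9, 0.8, 0.7, 0.6), c = c(9, 8, 7, 6),
                      a = 1, b = 1)
  csn <- build_csn(edges, top_k = 10)
  hubs <- select_hub_genes(csn, expr, gears = c("A", "B", "C"), top_n = 10)
  expect_identical(hubs$gene, c("C", "A"))   # C: degree 3, A: degree 2
  expect_false("B" %in% hubs$gene)
  expect_false("D" %in% hubs$gene)

  # degree tie resolved by strength, then gene id
  expr2 <- matrix(20, nrow = 3, ncol = 2,
                  dimnames = list(c("X", "Y", "Z"), c("S1", "S2")))
  edges2 <- data.frame(gene_u = c("X", "Y"), gene_v = c("Z", "Z"),
                       sas = c(0.5, 0.9), c = c(5, 9), a = 1, b = 1)
  csn2 <- build_csn(edges2, top_k = 10)
  hubs2 <- select_hub_genes(csn2, expr2, gears = c("X", "Y"), top_n = 1)
  expect_identical(hubs2$gene, "Y")          # same degree, higher strength
})

test_that("correlated planted genes score higher SAS than independent nulls", {
  # two noisy copies of one prognostic signal versus unrelated null genes,
  # compared over several seeds at the volatile first gradient
  wins <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 100
    signal <- rlnorm(n, 2, 1)
    X <- rbind(P1 = signal * rlnorm(n, 0, 0.2),
               P2 = signal * rlnorm(n, 0, 0.2),
               N1 = rlnorm(n, 2, 1), N2 = rlnorm(n, 2, 1))
    colnames(X) <- sprintf("S%03d", 1:n)
    high <- signal > median(signal)
    haz <- 0.002 * ifelse(high, 3, 1)
    te <- rexp(n, haz); tc <- runif(n, 0, 2000)
    surv <- data.frame(sample_id = colnames(X), time = pmax(pmin(te, tc), 1e-9),
                       event = as.integer(te <= tc))
    tensor <- run_permutation_screen(X, surv, n_perm = 60, seed = seed + 100)
    V <- tensor$k[1, , ]
    planted <- sas_score(V["P1", ], V["P2", ])
    null <- sas_score(V["N1", ], V["N2", ])
    wins <- wins + (planted > null)
  }
  expect_gte(wins, 4L)
})
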