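# Fixture builders shared across test files. Everything is generated in code
# at test time; files go to tempdirs.

write_expression_fixture <- function(path, m = NULL) {
  if (is.null(m)) {
    m <- matrix(c(1.5, 2, 0, 7,
                  3, 0.5, 12, 4,
                  10, 10, 10, 10), nrow = 3, byrow = TRUE,
                dimnames = list(c("TP53", "EGFR", "MYC"),
                                c("S1", "S2", "S3", "S4")))
  }
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  m
}

write_survival_fixture <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     time = c(10, 20, 30, 40), event = c(1, 0, 1, 0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

write_maf_fixture <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(Hugo_Symbol = c("TP53", "TP53", "KRAS", "EGFR", "EGFR"),
                     Tumor_Sample_Barcode = c("S1", "S2", "S1", "S3", "S3"),
                     Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                                                "Missense_Mutation", "Silent",
                                                "Frame_Shift_Del"))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

# Small screened cohort reused by network/screen tests (kept cheap).
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_samples = 80, n_genes = 30, n_prognostic = 4,
                          hazard_ratio = 3, seed = 5)
      coh <- generate_cohort(spec)
      tensor <- run_permutation_screen(coh$expression, coh$survival,
                                       n_perm = 40, seed = 9)
      cache <<- list(spec = spec, cohort = coh, tensor = tensor)
    }
    cache
  }
})

# Independent brute-force SAS oracle: explicit per-position counting loop.
sas_bruteforce <- function(va, vb) {
  a <- 0L; b <- 0L; cc <- 0L
  for (i in seq_along(va)) {
    if (va[i] == 1) a <- a + 1L
    if (vb[i] == 1) b <- b + 1L
    if (va[i] == 1 && vb[i] == 1) cc <- cc + 1L
  }
  cc / (a + b - 2 * cc + 1)
}

# Exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins and sum probabilities <= the observed table's.
fisher_enumeration <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Two-group dependency fixture with group means pinned exactly, so
# closed-form D_m / S_dm checks hold to rounding error.
make_dep_fixture <- function(mean_m, mean_wt, sd = 0.01, n = 10, seed = 1) {
  set.seed(seed)
  lines <- sprintf("LINE%02d", 1:(2 * n))
  s <- c(rnorm(n, mean_m, sd), rnorm(n, mean_wt, sd))
  s[1:n] <- s[1:n] - mean(s[1:n]) + mean_m
  s[(n + 1):(2 * n)] <- s[(n + 1):(2 * n)] - mean(s[(n + 1):(2 * n)]) + mean_wt
  scores <- matrix(s, ncol = 1, dimnames = list(lines, "G1"))
  list(scores = scores, mutant = lines[1:n])
}

# Adjusted Rand index for clustering-recovery checks.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
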