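# Survival-analysis similarity (SAS) and the core survival network (CSN).
# SAS compares two genes' binary significance vectors from the FIRST sampling
# gradient, where subsamples are small and significance is volatile: genes
# tracking the same prognostic signal co-fluctuate across permutations.

#' Survival-analysis similarity between two significance vectors
#'
#' With a and b the per-gene significant counts and c the number of
#' permutations in which both genes are significant, SAS = c / (a + b - 2c + 1).
#' The formula is implemented exactly as defined; note that when the two
#' vectors agree perfectly (a = b = c) it evaluates to c, i.e. it is not
#' bounded by 1 despite its Jaccard-like shape. A bounded variant
#' c / (a + b - c) is available with `normalized = TRUE`.
#'
#' @param vec_a,vec_b binary (0/1 or logical) vectors of equal length.
#' @param normalized use the bounded Jaccard form instead (default FALSE).
#' @return non-negative similarity value.
#' @export
sas_score <- function(vec_a, vec_b, normalized = FALSE) {
  if (length(vec_a) != length(vec_b)) {
    ms_error("memoryscreen_invalid_format", "significance vectors must have equal length")
  }
  a <- sum(vec_a == 1)
  b <- sum(vec_b == 1)
  cc <- sum(vec_a == 1 & vec_b == 1)
  if (normalized) {
    if (a + b - cc == 0) return(0)
    cc / (a + b - cc)
  } else {
    cc / (a + b - 2 * cc + 1)
  }
}

#' Pairwise SAS edges between GEARs and all genes
#'
#' Candidate pairs are every unordered (GEAR, gene) pair with distinct
#' members; SAS is computed from the first-gradient significance vectors.
#' All candidates are returned with their scores; ranking/thresholding is
#' [build_csn()]'s job.
#'
#' @param tensor `significance_tensor`.
#' @param gears `gear_set` (or character vector of gene ids).
#' @param gradient gradient index providing the vectors (default 1).
#' @param normalized passed to the SAS formula (default FALSE: as defined).
#' @return data.frame with columns `gene_u`, `gene_v` (lexicographically
#'   ordered within each pair), `sas`, `c`, `a`, `b`.
#' @export
compute_sas_edges <- function(tensor, gears, gradient = 1L, normalized = FALSE) {
  stopifnot(inherits(tensor, "significance_tensor"))
  gear_ids <- if (is.data.frame(gears)) gears$gene else as.character(gears)
  if (!length(gear_ids)) {
    ms_error("memoryscreen_empty_gears", "GEAR set is empty; no SAS edges to compute")
  }
  V <- tensor$k[gradient, , , drop = TRUE]          # genes x perms
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  storage.mode(V) <- "double"
  genes <- tensor$gene_ids
  rownames(V) <- genes
  gear_ids <- intersect(gear_ids, genes)

  a_all <- rowSums(V)
  Vg <- V[gear_ids, , drop = FALSE]
  C <- Vg %*% t(V)                                   # joint significant counts

  u <- rep(gear_ids, each = length(genes))
  v <- rep(genes, times = length(gear_ids))
  keep <- u != v
  df <- data.frame(gene_u = pmin(u[keep], v[keep]),
                   gene_v = pmax(u[keep], v[keep]),
                   c = as.vector(t(C))[keep],
                   a = a_all[u[keep]],
                   b = a_all[v[keep]],
                   stringsAsFactors = FALSE)
  # unordered dedup (GEAR-GEAR pairs appear twice)
  df <- df[!duplicated(paste(df$gene_u, df$gene_v, sep = "\r")), , drop = FALSE]
  # a/b follow the (u,v) relabelling: recompute from the canonical order
  df$a <- a_all[df$gene_u]
  df$b <- a_all[df$gene_v]
  df$sas <- if (normalized) {
    ifelse(df$a + df$b - df$c == 0, 0, df$c / (df$a + df$b - df$c))
  } else {
    df$c / (df$a + df$b - 2 * df$c + 1)
  }
  rownames(df) <- NULL
  df[, c("gene_u", "gene_v", "sas", "c", "a", "b")]
}

#' Build the core survival network from ranked SAS edges
#'
#' Edges are put in a deterministic total order — SAS descending, joint count
#' c descending, then lexicographic pair id — and the first `top_k` retained,
#' so ties at the cutoff resolve identically on every run.
#'
#' @param edges data.frame from [compute_sas_edges()].
#' @param top_k number of edges to keep (default 1000).
#' @return list of class `csn_graph`: `graph` (igraph object), `edges`
#'   (retained, ordered), `degree` and `strength` (SAS-weighted degree),
#'   both named by gene.
#' @export
build_csn <- function(edges, top_k = 1000L) {
  if (!nrow(edges)) ms_error("memoryscreen_empty_edges", "no edges supplied")
  ord <- order(-edges$sas, -edges$c, edges$gene_u, edges$gene_v)
  kept <- edges[ord, , drop = FALSE][seq_len(min(top_k, nrow(edges))), , drop = FALSE]
  rownames(kept) <- NULL
  g <- igraph::graph_from_data_frame(kept[, c("gene_u", "gene_v")],
                                     directed = FALSE)
  igraph::E(g)$weight <- kept$sas
  deg <- igraph::degree(g)
  stren <- igraph::strength(g)
  structure(list(graph = g, edges = kept,
                 degree = deg[order(names(deg))],
                 strength = stren[order(names(stren))]),
            class = "csn_graph")
}

#' Select hub genes from the core survival network
#'
#' Candidates are GEAR nodes of the network whose mean expression over the
#' full aligned cohort strictly exceeds `min_tpm`. They are ranked by degree
#' (descending), then SAS-weighted degree (descending), then gene id, and the
#' first `top_n` returned.
#'
#' @param csn `csn_graph` from [build_csn()].
#' @param expr full genes x samples TPM matrix (untransformed).
#' @param gears `gear_set` or character vector of GEAR ids.
#' @param top_n number of hubs (default 10).
#' @param min_tpm mean-TPM floor, strict (default 10).
#' @return data.frame of class `hub_gene_set` with columns `gene`, `degree`,
#'   `strength`, `mean_tpm`.
#' @export
select_hub_genes <- function(csn, expr, gears, top_n = 10L, min_tpm = 10) {
  stopifnot(inherits(csn, "csn_graph"))
  gear_ids <- if (is.data.frame(gears)) gears$gene else as.character(gears)
  nodes <- names(csn$degree)
  cand <- intersect(nodes, gear_ids)
  cand <- cand[cand %in% rownames(expr)]
  mean_tpm <- rowMeans(expr[cand, , drop = FALSE])
  cand <- cand[mean_tpm > min_tpm]
  if (!length(cand)) {
    message("select_hub_genes: no candidate passes the mean-TPM filter")
    return(structure(data.frame(gene = character(), degree = integer(),
                                strength = numeric(), mean_tpm = numeric()),
                     class = c("hub_gene_set", "data.frame")))
  }
  df <- data.frame(gene = cand,
                   degree = as.integer(csn$degree[cand]),
                   strength = as.numeric(csn$strength[cand]),
                   mean_tpm = rowMeans(expr[cand, , drop = FALSE]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, -df$strength, df$gene), , drop = FALSE]
  df <- df[seq_len(min(top_n, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("hub_gene_set", "data.frame"))
}
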