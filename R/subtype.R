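# Hub-gene molecular subtyping and subgroup genomic comparison.

#' log2(x + 1) transform of an expression matrix
#'
#' Pseudo-count of 1 then log2, the usual variance-compressing transform
#' before clustering TPM values.
#'
#' @param m non-negative expression matrix.
#' @return transformed matrix of the same shape.
#' @export
log_transform_expression <- function(m) {
  if (any(m < 0)) ms_error("memoryscreen_negative_value", "expression must be >= 0")
  log2(m + 1)
}

#' Cluster samples by hub-gene expression profiles
#'
#' Agglomerative hierarchical clustering of samples on Euclidean distance
#' between hub-gene expression profiles with Ward's minimum-variance linkage
#' (the squared-distance `ward.D2` convention), cut to exactly `k` clusters.
#' Clusters are then renamed 1..k by ascending mean expression across hub
#' genes, giving them stable low/medium/high semantics independent of
#' dendrogram orientation.
#'
#' @param m_hub hub-genes x samples matrix, normally already
#'   log2(TPM + 1)-transformed via [log_transform_expression()].
#' @param k number of clusters (default 3).
#' @return data.frame of class `subgroup_assignment` with columns `sample_id`
#'   and `cluster`; attribute `hclust` holds the tree, `cluster_means` the
#'   per-cluster mean expression used for renaming.
#' @export
cluster_by_hub_genes <- function(m_hub, k = 3L) {
  if (ncol(m_hub) < k) {
    ms_error("memoryscreen_invalid_parameter",
             sprintf("need at least k = %d samples, got %d", k, ncol(m_hub)))
  }
  if (nrow(m_hub) < 1L) {
    ms_error("memoryscreen_invalid_parameter", "need at least one hub gene")
  }
  d <- stats::dist(t(m_hub), method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  # rename clusters by ascending mean hub-gene expression
  means <- vapply(seq_len(k), function(cl) mean(m_hub[, raw == cl, drop = FALSE]),
                  numeric(1))
  relabel <- match(seq_len(k), order(means))
  cluster <- relabel[raw]
  if (length(unique(cluster)) < k) {
    message("cluster_by_hub_genes: fewer than k non-empty clusters")
  }
  out <- data.frame(sample_id = colnames(m_hub), cluster = as.integer(cluster),
                    stringsAsFactors = FALSE)
  structure(out, class = c("subgroup_assignment", "data.frame"),
            hclust = tree, cluster_means = sort(means), k = as.integer(k))
}

#' Per-sample tumor mutation burden
#'
#' Counts qualifying mutation records per sample; samples absent from the
#' mutation table get 0. By default only non-silent variant classes count
#' (see [nonsilent_classes()]). An optional per-megabase rate is reported
#' when `capture_size_mb` is given.
#'
#' @param mut mutation data.frame (gene, sample, variant_class).
#' @param samples sample ids to report (drives the zero-filling).
#' @param variant_filter allow-list of variant classes; NULL counts all.
#' @param capture_size_mb optional exome capture size for mutations/Mb.
#' @return data.frame with `sample_id`, `tmb_count` and, when requested,
#'   `tmb_per_mb`.
#' @export
compute_tmb <- function(mut, samples, variant_filter = nonsilent_classes(),
                        capture_size_mb = NULL) {
  if (!is.null(variant_filter)) {
    mut <- mut[mut$variant_class %in% variant_filter, , drop = FALSE]
  }
  counts <- table(factor(mut$sample, levels = samples))
  out <- data.frame(sample_id = samples, tmb_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!is.null(capture_size_mb)) out$tmb_per_mb <- out$tmb_count / capture_size_mb
  rownames(out) <- NULL
  out
}

#' Differential mutation frequency between two subgroups
#'
#' For each gene mutated in either subgroup, carriers versus non-carriers are
#' tabulated in a 2x2 table and tested with a two-sided Fisher exact test;
#' p-values are Benjamini-Hochberg adjusted across the genes tested. A sample
#' is a carrier when it has at least one qualifying record for the gene.
#'
#' @param mut mutation data.frame (gene, sample, variant_class).
#' @param groups `subgroup_assignment` (or data.frame sample_id/cluster).
#' @param pair two cluster labels to compare.
#' @param variant_filter allow-list of variant classes; NULL counts all.
#' @return data.frame with per-gene carrier counts in each subgroup, subgroup
#'   sizes, odds ratio, `p_value` and BH-adjusted `q_value`, ordered by
#'   p-value.
#' @export
differential_mutation <- function(mut, groups, pair,
                                  variant_filter = nonsilent_classes()) {
  if (length(pair) != 2L) {
    ms_error("memoryscreen_invalid_parameter", "pair must name exactly two clusters")
  }
  if (!all(pair %in% groups$cluster)) {
    ms_error("memoryscreen_invalid_parameter",
             sprintf("cluster label(s) absent from assignment: %s",
                     paste(setdiff(pair, groups$cluster), collapse = ", ")))
  }
  s1 <- groups$sample_id[groups$cluster == pair[1L]]
  s2 <- groups$sample_id[groups$cluster == pair[2L]]
  if (!is.null(variant_filter)) {
    mut <- mut[mut$variant_class %in% variant_filter, , drop = FALSE]
  }
  mut <- mut[mut$sample %in% c(s1, s2), , drop = FALSE]
  genes <- sort(unique(mut$gene))
  if (!length(genes)) {
    message("differential_mutation: no mutated genes in the two subgroups")
  }
  rows <- lapply(genes, function(g) {
    carriers <- unique(mut$sample[mut$gene == g])
    a1 <- sum(s1 %in% carriers); a2 <- sum(s2 %in% carriers)
    if (a1 + a2 == 0) return(NULL)  # degenerate table, skip
    tab <- matrix(c(a1, length(s1) - a1, a2, length(s2) - a2), nrow = 2L)
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(gene = g,
               carriers_1 = a1, n_1 = length(s1),
               carriers_2 = a2, n_2 = length(s2),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene = character(), carriers_1 = integer(), n_1 = integer(),
               carriers_2 = integer(), n_2 = integer(), odds_ratio = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  out
}
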