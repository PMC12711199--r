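# Mutation effects on tumor-cell viability from CRISPR dependency scores.
# For each mutated gene the dependency score S of mutant cell lines is
# compared with wild-type lines: D_m = |mean_m - mean_wt| and its
# scale-standardized form S_dm = 2 (mean_m - mean_wt) / (mean_m + mean_wt).

#' Compare dependency scores between mutant and wild-type cell lines
#'
#' Computes group means, the absolute mean difference D_m, the standardized
#' difference S_dm, and a two-sample t-test p-value (Welch by default). S_dm
#' divides by the mean-sum; because dependency scores are routinely negative,
#' a non-positive mean-sum inverts or destroys the sign and S_dm is then
#' reported NA with the `indeterminate_scale` flag set — such genes never
#' pass the S_dm criterion silently.
#'
#' @param scores cell-lines x genes dependency matrix.
#' @param mutant_lines cell-line ids carrying a mutation in `target_gene`.
#' @param target_gene gene whose dependency column is compared.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list of class `dependency_comparison`: gene, n_m, n_wt, mean_m,
#'   mean_wt, d_m, s_dm, p_value, indeterminate_scale.
#' @export
compare_dependency <- function(scores, mutant_lines, target_gene,
                               var_equal = FALSE) {
  if (!target_gene %in% colnames(scores)) {
    ms_error("memoryscreen_unknown_gene",
             sprintf("gene %s absent from dependency matrix", target_gene))
  }
  s <- scores[, target_gene]
  is_m <- rownames(scores) %in% mutant_lines
  sm <- s[is_m]; swt <- s[!is_m]
  if (length(sm) < 2L || length(swt) < 2L) {
    ms_error("memoryscreen_group_too_small",
             "need >= 2 mutant and >= 2 wild-type cell lines")
  }
  mean_m <- mean(sm); mean_wt <- mean(swt)
  d_m <- abs(mean_m - mean_wt)
  denom <- mean_m + mean_wt
  indeterminate <- denom <= 0
  s_dm <- if (indeterminate) NA_real_ else 2 * (mean_m - mean_wt) / denom
  p <- stats::t.test(sm, swt, var.equal = var_equal)$p.value
  structure(list(gene = target_gene, n_m = length(sm), n_wt = length(swt),
                 mean_m = mean_m, mean_wt = mean_wt, d_m = d_m, s_dm = s_dm,
                 p_value = p, indeterminate_scale = indeterminate),
            class = "dependency_comparison")
}

#' Categorize a mutation by its dependency effect
#'
#' A mutation is functional when the mutant/wild-type difference is
#' significant (p strictly < `alpha`) AND the standardized difference S_dm
#' strictly exceeds `s_dm_threshold`; boundary values fail. A functional
#' mutation is promoted to subtype-associated when a supplied cross-subtype
#' frequency test is itself significant. An indeterminate S_dm (non-positive
#' mean-sum) classifies non-functional.
#'
#' @param comparison `dependency_comparison` from [compare_dependency()].
#' @param subtype_enrichment_p optional p-value of a cross-subtype carrier
#'   frequency test.
#' @param alpha significance level (default 0.05, strict).
#' @param s_dm_threshold S_dm cutoff (default 0.1, strict).
#' @return one of "functional", "subtype-associated functional",
#'   "non-functional".
#' @export
classify_mutation <- function(comparison, subtype_enrichment_p = NULL,
                              alpha = 0.05, s_dm_threshold = 0.1) {
  functional <- !comparison$indeterminate_scale &&
    !is.na(comparison$s_dm) &&
    comparison$p_value < alpha &&
    comparison$s_dm > s_dm_threshold
  if (!functional) return("non-functional")
  if (!is.null(subtype_enrichment_p) && !is.na(subtype_enrichment_p) &&
      subtype_enrichment_p < alpha) {
    return("subtype-associated functional")
  }
  "functional"
}

#' Screen every mutated gene for dependency effects
#'
#' Builds the mutant cell-line set per gene from the cell-line mutation
#' table, runs [compare_dependency()] and [classify_mutation()] for each gene
#' with valid group sizes, and records a skip reason for the rest.
#'
#' @param scores cell-lines x genes dependency matrix.
#' @param cell_line_mutations mutation data.frame (gene, sample,
#'   variant_class) with cell-line ids in `sample`.
#' @param subtype_enrichment optional named numeric vector of per-gene
#'   cross-subtype frequency-test p-values.
#' @param var_equal passed to [compare_dependency()].
#' @param alpha,s_dm_threshold passed to [classify_mutation()].
#' @return data.frame, one row per mutated gene: group sizes, means, d_m,
#'   s_dm, p_value, category, skip_reason (NA when analyzed).
#' @export
screen_all_mutations <- function(scores, cell_line_mutations,
                                 subtype_enrichment = NULL,
                                 var_equal = FALSE, alpha = 0.05,
                                 s_dm_threshold = 0.1) {
  shared <- intersect(rownames(scores), unique(cell_line_mutations$sample))
  if (!length(shared)) {
    ms_error("memoryscreen_no_overlap",
             "no cell-line ids shared between scores and mutation table")
  }
  mut <- cell_line_mutations[cell_line_mutations$sample %in% rownames(scores), ,
                             drop = FALSE]
  genes <- sort(unique(mut$gene))
  rows <- lapply(genes, function(g) {
    base <- data.frame(gene = g, n_m = NA_integer_, n_wt = NA_integer_,
                       mean_m = NA_real_, mean_wt = NA_real_, d_m = NA_real_,
                       s_dm = NA_real_, p_value = NA_real_,
                       category = NA_character_, skip_reason = NA_character_,
                       stringsAsFactors = FALSE)
    if (!g %in% colnames(scores)) {
      base$skip_reason <- "gene absent from dependency matrix"
      return(base)
    }
    mutant <- unique(mut$sample[mut$gene == g])
    n_m <- sum(rownames(scores) %in% mutant)
    n_wt <- nrow(scores) - n_m
    if (n_m < 2L || n_wt < 2L) {
      base$n_m <- n_m; base$n_wt <- n_wt
      base$skip_reason <- "fewer than 2 cell lines in a group"
      return(base)
    }
    cmp <- compare_dependency(scores, mutant, g, var_equal = var_equal)
    enr <- if (!is.null(subtype_enrichment)) subtype_enrichment[g] else NULL
    data.frame(gene = g, n_m = cmp$n_m, n_wt = cmp$n_wt,
               mean_m = cmp$mean_m, mean_wt = cmp$mean_wt,
               d_m = cmp$d_m, s_dm = cmp$s_dm, p_value = cmp$p_value,
               category = classify_mutation(cmp, enr, alpha = alpha,
                                            s_dm_threshold = s_dm_threshold),
               skip_reason = if (cmp$indeterminate_scale) "indeterminate-scale" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
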