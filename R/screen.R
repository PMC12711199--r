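# The multi-gradient permutation screen: the package's core.

#' Build the gradient plan of subsample sizes
#'
#' Sizes are round-half-up of j * n_total / n_gradients for j = 1..n_gradients,
#' floored at `min_size`, with the final gradient forced to the full cohort.
#' The result is non-decreasing by construction.
#'
#' @param n_total aligned cohort size.
#' @param n_gradients number of gradients (default 10, i.e. ~10%..100%).
#' @param min_size smallest admissible subsample (default 10).
#' @return integer vector of subsample sizes, class `gradient_plan`.
#' @export
build_gradient_plan <- function(n_total, n_gradients = 10L, min_size = 10L) {
  if (n_total < min_size) {
    ms_error("memoryscreen_cohort_too_small",
             sprintf("cohort size %d below minimum subsample size %d", n_total, min_size))
  }
  if (n_gradients < 1L) {
    ms_error("memoryscreen_invalid_parameter", "n_gradients must be >= 1")
  }
  j <- seq_len(n_gradients)
  sizes <- floor(j * n_total / n_gradients + 0.5)   # round half up
  sizes <- pmax(sizes, min_size)
  sizes[n_gradients] <- n_total
  sizes <- as.integer(cummax(sizes))
  structure(sizes, class = "gradient_plan", n_total = as.integer(n_total))
}

#' Run the multi-gradient permutation survival screen
#'
#' For every gradient j and permutation n, one subsample of size k_j is drawn
#' without replacement from the aligned cohort and shared by all genes. Each
#' gene is median-dichotomized within the drawn subset and scored 1 when its
#' two-group log-rank p-value is strictly below `alpha`, 0 otherwise.
#' Degenerate genes (constant in the subset) and undefined tests (zero events
#' in the subset, or zero log-rank variance) are scored 0 and counted in the
#' diagnostics.
#'
#' Randomness is controlled by a single master seed: a fixed-length vector of
#' per-(gradient, permutation) sub-seeds is derived from it up front, so the
#' draw for any (j, n) cell does not depend on evaluation order.
#'
#' @param expr genes x samples TPM matrix.
#' @param surv survival data.frame (sample_id, time, event).
#' @param plan gradient plan from [build_gradient_plan()]; built from the
#'   aligned cohort size when NULL.
#' @param n_perm permutations per gradient (default 1000).
#' @param alpha significance level for the log-rank test (default 0.05,
#'   strict inequality).
#' @param seed master RNG seed.
#' @return object of class `significance_tensor`: list with the binary array
#'   `k` (gradients x genes x permutations), `sizes`, `gene_ids`,
#'   `sample_ids`, `seed`, `alpha` and a `diagnostics` data.frame of
#'   degenerate/undefined counts per gradient.
#' @export
run_permutation_screen <- function(expr, surv, plan = NULL, n_perm = 1000L,
                                   alpha = 0.05, seed = 1L) {
  if (n_perm < 1L) ms_error("memoryscreen_invalid_parameter", "n_perm must be >= 1")
  if (alpha <= 0 || alpha >= 1) {
    ms_error("memoryscreen_invalid_parameter", "alpha must be in (0, 1)")
  }
  al <- align_cohort(validate_expression(expr), validate_survival(surv))
  X <- al$expression
  time <- al$survival$time
  event <- al$survival$event
  n <- ncol(X)
  G <- nrow(X)
  if (is.null(plan)) plan <- build_gradient_plan(n)
  if (max(plan) > n) {
    ms_error("memoryscreen_invalid_parameter", "gradient plan exceeds aligned cohort size")
  }
  J <- length(plan)

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, J * n_perm)

  k <- array(0L, dim = c(J, G, n_perm),
             dimnames = list(gradient = NULL, gene = rownames(X), perm = NULL))
  diag_deg <- integer(J)
  diag_undef <- integer(J)

  half <- function(sz) ceiling(sz / 2)
  for (j in seq_len(J)) {
    sz <- plan[j]
    thr <- half(sz)
    for (p in seq_len(n_perm)) {
      set.seed(sub_seeds[(j - 1L) * n_perm + p])
      idx <- sample.int(n, sz, replace = FALSE)
      Xs <- X[, idx, drop = FALSE]
      tt <- time[idx]; ee <- event[idx]

      # rank-based median split per gene; stable tie handling
      R <- apply(Xs, 1L, rank, ties.method = "first")   # sz x G
      Z <- t(R > thr)                                    # G x sz, TRUE = high
      degenerate <- (apply(Xs, 1L, max) - apply(Xs, 1L, min)) == 0
      diag_deg[j] <- diag_deg[j] + sum(degenerate)

      if (sum(ee) == 0) {
        diag_undef[j] <- diag_undef[j] + G
        next
      }
      res <- logrank_chisq_matrix(tt, ee, Z)
      pval <- stats::pchisq(res$chisq, df = 1, lower.tail = FALSE)
      undef <- is.na(pval)
      diag_undef[j] <- diag_undef[j] + sum(undef & !degenerate)
      sig <- !undef & !degenerate & pval < alpha
      k[j, , p] <- as.integer(sig)
    }
  }

  structure(list(k = k,
                 sizes = as.integer(plan),
                 gene_ids = rownames(X),
                 sample_ids = colnames(X),
                 n_perm = as.integer(n_perm),
                 alpha = alpha,
                 seed = as.integer(seed),
                 diagnostics = data.frame(gradient = seq_len(J),
                                          size = as.integer(plan),
                                          degenerate = diag_deg,
                                          undefined = diag_undef)),
            class = "significance_tensor")
}

#' Significance-probability matrix from a significance tensor
#'
#' Entry (i, j) is the fraction of permutations in which gene i's median-split
#' log-rank test was significant at gradient j: the exact mean of the binary
#' tensor along the permutation axis.
#'
#' @param tensor `significance_tensor` from [run_permutation_screen()].
#' @return numeric matrix, genes x gradients, values in \[0, 1\].
#' @export
significance_probability <- function(tensor) {
  stopifnot(inherits(tensor, "significance_tensor"))
  A <- t(rowMeans(tensor$k, dims = 2L))    # genes x gradients
  rownames(A) <- tensor$gene_ids
  colnames(A) <- paste0("g", seq_along(tensor$sizes))
  A
}

#' Find the saturation gradient
#'
#' The smallest gradient whose column of the significance-probability matrix
#' attains 1, i.e. some gene is significant in every permutation. When no
#' column attains 1 the last gradient is returned with a warning and the
#' `saturated` attribute set FALSE.
#'
#' @param A genes x gradients significance-probability matrix.
#' @return integer gradient index with attribute `saturated`.
#' @export
find_saturation_gradient <- function(A) {
  maxima <- apply(A, 2L, max)
  hit <- which(maxima == 1)
  if (length(hit)) {
    structure(as.integer(hit[1L]), saturated = TRUE)
  } else {
    warning("no gradient reached saturation (no column maximum equals 1); ",
            "using the last gradient")
    structure(ncol(A), saturated = FALSE)
  }
}

#' Extract GEARs (genes steadily associated with prognosis)
#'
#' Mode `"saturation"` (default): genes whose significance probability at the
#' saturation gradient strictly exceeds `threshold`. Mode `"sustained"`:
#' genes that cross `threshold` at some gradient and stay strictly above it
#' at every later gradient.
#'
#' @param A significance-probability matrix (genes x gradients).
#' @param j_star saturation gradient index.
#' @param threshold probability cutoff (default 0.8, strict).
#' @param mode `"saturation"` or `"sustained"`.
#' @return data.frame of class `gear_set` with columns `gene` and
#'   `probability` (A at the saturation gradient), attributes
#'   `saturation_gradient`, `threshold`, `mode`.
#' @export
extract_gears <- function(A, j_star, threshold = 0.8, mode = c("saturation", "sustained")) {
  mode <- match.arg(mode)
  j_star <- as.integer(j_star)
  if (j_star < 1L || j_star > ncol(A)) {
    ms_error("memoryscreen_invalid_parameter", "saturation gradient out of range")
  }
  if (threshold <= 0 || threshold > 1) {
    ms_error("memoryscreen_invalid_parameter", "threshold must be in (0, 1]")
  }
  if (mode == "saturation") {
    keep <- A[, j_star] > threshold
  } else {
    keep <- apply(A, 1L, function(row) {
      cross <- which(row > threshold)
      length(cross) > 0 && all(row[cross[1L]:length(row)] > threshold)
    })
  }
  genes <- rownames(A)[keep]
  out <- data.frame(gene = genes, probability = unname(A[keep, j_star]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$probability, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gear_set", "data.frame"),
            saturation_gradient = j_star, threshold = threshold, mode = mode)
}
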