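# Mantel-Haenszel two-group log-rank, scalar and gene-vectorized forms.
# The vectorized form is what makes the permutation screen feasible: one
# subsample draw is shared by all genes, so the at-risk bookkeeping collapses
# into two matrix products per draw.

#' Split a numeric vector at its median into equal-sized groups
#'
#' Rank-based dichotomization: samples are ordered ascending by value (ties
#' broken by input position, i.e. a stable sort) and the first ceiling(n/2)
#' are labelled low, the remainder high, so group sizes differ by at most one.
#' A vector whose values are all identical carries no grouping information and
#' is flagged degenerate; callers record such genes as non-significant.
#'
#' @param values numeric vector, length >= 4.
#' @return list with `high` (logical vector, TRUE = high-expression group)
#'   and `degenerate` (logical flag).
#' @export
dichotomize_by_median <- function(values) {
  n <- length(values)
  if (n < 4L) {
    ms_error("memoryscreen_too_few_samples", "median dichotomization needs >= 4 values")
  }
  if (anyNA(values)) {
    ms_error("memoryscreen_non_finite", "dichotomization input contains NA")
  }
  r <- rank(values, ties.method = "first")
  list(high = r > ceiling(n / 2), degenerate = diff(range(values)) == 0)
}

#' Two-group Mantel-Haenszel log-rank test
#'
#' Classic observed-minus-expected log-rank on one degree of freedom. At each
#' distinct event time the contribution to the statistic is
#' \eqn{O_1 - E_1 = d_1 - d \cdot n_1 / n} with hypergeometric variance
#' \eqn{d (n_1/n) (1 - n_1/n) (n - d)/(n - 1)}; the chi-square is the squared
#' summed O-E over the summed variance, with an upper-tail p-value.
#'
#' The test is undefined when either group is empty or no events occur; that
#' is reported via the `undefined` flag (and treated as non-significant by
#' the screen) rather than as an error.
#'
#' @param time positive follow-up times.
#' @param event event indicator, 1 = event, 0 = censored.
#' @param group logical or two-level vector assigning each subject to a group.
#' @return list with `statistic` (chi-square), `p_value`, and `undefined`.
#' @export
logrank_pvalue <- function(time, event, group) {
  if (length(unique(c(length(time), length(event), length(group)))) != 1L) {
    ms_error("memoryscreen_invalid_format", "time, event and group must have equal length")
  }
  g <- if (is.logical(group)) group else group == sort(unique(group))[2L]
  if (length(unique(g)) < 2L || sum(event) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, undefined = TRUE))
  }
  res <- logrank_chisq_matrix(time, event, matrix(g, nrow = 1L))
  if (is.na(res$chisq[1L])) {
    return(list(statistic = NA_real_, p_value = NA_real_, undefined = TRUE))
  }
  list(statistic = res$chisq[1L],
       p_value = stats::pchisq(res$chisq[1L], df = 1, lower.tail = FALSE),
       undefined = FALSE)
}

# Vectorized Mantel-Haenszel log-rank over many group assignments sharing one
# (time, event) cohort. Z: G x n logical/0-1 matrix, one row per gene, TRUE =
# high group. Returns chisq per row (NA where the variance is zero, e.g. a
# constant row). Internal.
logrank_chisq_matrix <- function(time, event, Z) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]
  e_s <- event[ord] == 1
  Zs <- Z[, ord, drop = FALSE]
  storage.mode(Zs) <- "double"

  # distinct death times and pooled counts
  death_pos <- which(e_s)
  if (!length(death_pos)) {
    return(list(chisq = rep(NA_real_, nrow(Z))))
  }
  ut <- unique(t_s[death_pos])
  first_idx <- match(ut, t_s)              # first position with time == ut (at-risk start)
  d_t <- vapply(ut, function(u) sum(e_s & t_s == u), numeric(1))
  n_t <- n - first_idx + 1                 # pooled at-risk just before each death time

  # per-gene at-risk in group 1 at each death time: reverse cumulative sums
  # realized as matrix products against indicator matrices
  D <- length(ut)
  at_risk_ind <- matrix(0, n, D)           # [i, m] = 1 if sample i at risk at ut[m]
  for (m in seq_len(D)) at_risk_ind[first_idx[m]:n, m] <- 1
  death_ind <- matrix(0, n, D)             # [i, m] = 1 if sample i dies at ut[m]
  for (m in seq_len(D)) death_ind[which(e_s & t_s == ut[m]), m] <- 1

  N1 <- Zs %*% at_risk_ind                 # G x D group-1 at-risk counts
  D1 <- Zs %*% death_ind                   # G x D group-1 death counts

  frac <- sweep(N1, 2, n_t, "/")
  OmE <- rowSums(D1 - sweep(frac, 2, d_t, "*"))
  vc <- d_t * ifelse(n_t > 1, (n_t - d_t) / (n_t - 1), 0)
  V <- rowSums(sweep(frac * (1 - frac), 2, vc, "*"))

  chisq <- ifelse(V > 0, OmE^2 / V, NA_real_)
  list(chisq = chisq, o_minus_e = OmE, var = V)
}
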