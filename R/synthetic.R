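# Synthetic cohorts with the statistical structure the screen assumes:
# log-normal TPM expression, exponential event times under proportional
# hazards modulated by planted prognostic genes, uniform right-censoring,
# subtype-enriched binary mutations, and mutation-shifted dependency scores.

#' Specify a synthetic cohort
#'
#' Each planted prognostic gene multiplies a sample's hazard by its hazard
#' ratio when the sample's expression is above that gene's cohort median, so
#' planted effects are exactly what the screen's median-split log-rank
#' targets. With `n_prognostic` planted genes the hazard spread across
#' samples is prod(HR) wide; when `baseline_hazard` is NULL it is calibrated
#' so the geometric-mean sample (half the planted indicators on) has hazard
#' `target_hazard`, keeping the censoring window meaningful regardless of how
#' many effects are planted.
#'
#' @param n_samples cohort size.
#' @param n_genes number of genes.
#' @param n_prognostic number of planted prognostic genes.
#' @param hazard_ratio per-gene hazard ratio for the high-expression group
#'   (scalar or length `n_prognostic`).
#' @param baseline_hazard events/day for a sample with every planted
#'   indicator off; NULL (default) auto-calibrates (see above).
#' @param target_hazard geometric-mean hazard used by the calibration
#'   (default 0.001/day, i.e. median survival around two years).
#' @param censor_max upper bound of the uniform censoring window, days
#'   (default 3000, an ~8-year accrual window giving roughly 30% censoring
#'   in the null model).
#' @param meanlog_mean,meanlog_sd,sdlog per-gene log-normal expression
#'   parameters: gene meanlogs are drawn N(meanlog_mean, meanlog_sd), all
#'   genes share `sdlog`.
#' @param seed RNG seed.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300L, n_genes = 500L, n_prognostic = 20L,
                        hazard_ratio = 3, baseline_hazard = NULL,
                        target_hazard = 0.001, censor_max = 3000,
                        meanlog_mean = 2, meanlog_sd = 1, sdlog = 1,
                        seed = 1L) {
  if (n_prognostic > n_genes) {
    ms_error("memoryscreen_invalid_parameter", "n_prognostic must be <= n_genes")
  }
  if (any(hazard_ratio <= 0)) {
    ms_error("memoryscreen_invalid_parameter", "hazard ratios must be > 0")
  }
  if (censor_max <= 0) {
    ms_error("memoryscreen_invalid_parameter", "censoring window must be > 0")
  }
  hr <- rep_len(hazard_ratio, n_prognostic)
  if (is.null(baseline_hazard)) {
    baseline_hazard <- target_hazard / prod(sqrt(hr))
  }
  if (baseline_hazard <= 0) {
    ms_error("memoryscreen_invalid_parameter", "baseline hazard must be > 0")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_prognostic = as.integer(n_prognostic),
                 hazard_ratio = hr,
                 baseline_hazard = baseline_hazard,
                 censor_max = censor_max,
                 meanlog_mean = meanlog_mean, meanlog_sd = meanlog_sd,
                 sdlog = sdlog, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic expression + survival cohort
#'
#' Expression is log-normal per gene. Each sample's hazard is
#' baseline * prod over planted genes of HR^(above-median indicator); event
#' times are exponential with that hazard, censoring times uniform on
#' (0, censor_max), observed time the minimum with the usual event indicator.
#' Deterministic for a given spec (the seed lives in the spec).
#'
#' @param spec `cohort_spec`.
#' @return list with `expression` (genes x samples), `survival` (data.frame),
#'   and `truth` (planted gene ids with hazard ratios, per-sample hazards,
#'   censoring fraction).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; G <- spec$n_genes
  genes <- sprintf("GENE%04d", seq_len(G))
  samples <- sprintf("SAMP%04d", seq_len(n))
  meanlog <- stats::rnorm(G, spec$meanlog_mean, spec$meanlog_sd)
  X <- matrix(stats::rlnorm(G * n, meanlog = rep(meanlog, times = n),
                            sdlog = spec$sdlog),
              nrow = G, ncol = n, dimnames = list(genes, samples))

  planted <- genes[seq_len(spec$n_prognostic)]
  log_hazard <- rep(log(spec$baseline_hazard), n)
  if (spec$n_prognostic > 0L) {
    for (i in seq_len(spec$n_prognostic)) {
      high <- X[planted[i], ] > stats::median(X[planted[i], ])
      log_hazard <- log_hazard + high * log(spec$hazard_ratio[i])
    }
  }
  hazard <- exp(log_hazard)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, spec$censor_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, .Machine$double.eps)  # guard strict positivity

  surv <- data.frame(sample_id = samples, time = time, event = event,
                     stringsAsFactors = FALSE)
  truth <- list(prognostic_genes = planted,
                hazard_ratios = stats::setNames(spec$hazard_ratio, planted),
                hazard = stats::setNames(hazard, samples),
                censoring_fraction = mean(event == 0))
  list(expression = X, survival = surv, truth = truth)
}

#' Expected censoring fraction under a cohort spec
#'
#' Analytic check of the generator's censoring regime: for a sample with
#' hazard h and uniform(0, B) censoring, P(censored) = (1 - exp(-hB)) / (hB).
#' Sample hazards are baseline * prod(HR^z) with independent fair-coin
#' indicators z, so the expectation enumerates the planted-indicator counts
#' (binomial weights) for the equal-HR case, or falls back to Monte Carlo
#' averaging over indicator draws for heterogeneous HRs.
#'
#' @param spec `cohort_spec`.
#' @return expected censoring fraction in \[0, 1\].
#' @export
expected_censoring <- function(spec) {
  pc <- function(h) {
    x <- h * spec$censor_max
    (1 - exp(-x)) / x
  }
  k <- spec$n_prognostic
  if (k == 0L) return(pc(spec$baseline_hazard))
  if (length(unique(spec$hazard_ratio)) == 1L) {
    hr <- spec$hazard_ratio[1L]
    counts <- 0:k
    w <- stats::dbinom(counts, k, 0.5)
    sum(w * pc(spec$baseline_hazard * hr^counts))
  } else {
    set.seed(spec$seed + 1L)
    z <- matrix(stats::rbinom(2000L * k, 1L, 0.5), ncol = k)
    mean(pc(spec$baseline_hazard * exp(z %*% log(spec$hazard_ratio))))
  }
}

#' Generate subtype-enriched binary mutation profiles
#'
#' Carrier status per (gene, sample) is Bernoulli with the sample's
#' cluster-specific probability; carriers are emitted as missense records in
#' the minimal MAF layout the rest of the package consumes.
#'
#' @param groups `subgroup_assignment` (sample_id, cluster).
#' @param enriched_genes named list: gene -> numeric vector of per-cluster
#'   carrier probabilities (indexed by cluster label).
#' @param seed RNG seed.
#' @return mutation data.frame (gene, sample, variant_class).
#' @export
generate_mutation_profiles <- function(groups, enriched_genes, seed = 1L) {
  probs_ok <- vapply(enriched_genes, function(p) all(p >= 0 & p <= 1), logical(1))
  if (!all(probs_ok)) {
    ms_error("memoryscreen_invalid_parameter", "carrier probabilities must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  recs <- lapply(names(enriched_genes), function(g) {
    p <- enriched_genes[[g]][groups$cluster]
    carrier <- stats::rbinom(nrow(groups), 1L, p) == 1L
    if (!any(carrier)) return(NULL)
    data.frame(gene = g, sample = groups$sample_id[carrier],
               variant_class = "Missense_Mutation", stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  out <- if (length(recs)) do.call(rbind, recs) else {
    data.frame(gene = character(), sample = character(),
               variant_class = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Generate a synthetic dependency screen
#'
#' Wild-type dependency scores are Normal(mu_g, noise_sd) per gene; cell
#' lines carrying a mutation (Bernoulli `mutation_rate` per gene and line)
#' have their score shifted by the gene's planted effect (0 for unlisted
#' genes).
#'
#' @param n_lines number of cell lines.
#' @param genes gene ids to simulate.
#' @param planted_effects named numeric vector: gene -> mean shift in mutant
#'   lines.
#' @param noise_sd score standard deviation (> 0).
#' @param mutation_rate per-(gene, line) mutation probability.
#' @param gene_means optional named baseline means (default 0).
#' @param seed RNG seed.
#' @return list with `scores` (cell lines x genes) and `mutations`
#'   (data.frame gene/sample/variant_class).
#' @export
generate_dependency_screen <- function(n_lines, genes, planted_effects = NULL,
                                       noise_sd = 0.1, mutation_rate = 0.3,
                                       gene_means = NULL, seed = 1L) {
  if (noise_sd <= 0) {
    ms_error("memoryscreen_invalid_parameter", "noise_sd must be > 0")
  }
  set.seed(as.integer(seed))
  lines <- sprintf("LINE%03d", seq_len(n_lines))
  mu <- stats::setNames(rep(0, length(genes)), genes)
  if (!is.null(gene_means)) mu[names(gene_means)] <- gene_means
  S <- matrix(stats::rnorm(n_lines * length(genes), mean = rep(mu, each = n_lines),
                           sd = noise_sd),
              nrow = n_lines, dimnames = list(lines, genes))
  mut_status <- matrix(stats::rbinom(n_lines * length(genes), 1L, mutation_rate) == 1L,
                       nrow = n_lines, dimnames = list(lines, genes))
  if (!is.null(planted_effects)) {
    for (g in intersect(names(planted_effects), genes)) {
      S[mut_status[, g], g] <- S[mut_status[, g], g] + planted_effects[[g]]
    }
  }
  idx <- which(mut_status, arr.ind = TRUE)
  mut <- data.frame(gene = colnames(mut_status)[idx[, "col"]],
                    sample = rownames(mut_status)[idx[, "row"]],
                    variant_class = "Missense_Mutation",
                    stringsAsFactors = FALSE)
  mut <- mut[order(mut$gene, mut$sample), , drop = FALSE]
  rownames(mut) <- NULL
  list(scores = S, mutations = mut)
}
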