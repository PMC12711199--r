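# Orchestration: one configured, logged, manifest-producing run of
# screen -> network -> hubs -> classify -> mutation/dependency stages.

ms_config_defaults <- function() {
  list(expression = NULL, survival = NULL, mutations = NULL,
       dependency = NULL, cell_line_mutations = NULL,
       gradients = 10L, permutations = 1000L, alpha = 0.05,
       gear_threshold = 0.8, gear_mode = "saturation",
       top_edges = 1000L, top_hubs = 10L, min_tpm = 10,
       k_clusters = 3L, min_size = 10L, seed = 1L, out_dir = "memory_out")
}

#' Build a validated pipeline configuration
#'
#' Any omitted field takes its documented default (1000 permutations, 10
#' gradients, alpha 0.05, GEAR threshold 0.8, 1000 edges, 10 hubs, min TPM
#' 10, k = 3).
#'
#' @param ... configuration fields (see [ms_config_defaults] names).
#' @return list of class `memory_config`.
#' @export
memory_config <- function(...) {
  user <- list(...)
  defaults <- ms_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    ms_error("memoryscreen_unknown_key",
             sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, user)
  chk <- function(ok, msg) if (!ok) ms_error("memoryscreen_invalid_parameter", msg)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(cfg$gear_threshold > 0 && cfg$gear_threshold <= 1, "gear_threshold must be in (0, 1]")
  chk(cfg$gear_mode %in% c("saturation", "sustained"), "gear_mode must be saturation or sustained")
  chk(cfg$permutations >= 1, "permutations must be >= 1")
  chk(cfg$gradients >= 1, "gradients must be >= 1")
  chk(cfg$top_edges >= 1, "top_edges must be >= 1")
  chk(cfg$top_hubs >= 1, "top_hubs must be >= 1")
  chk(cfg$min_tpm >= 0, "min_tpm must be >= 0")
  chk(cfg$k_clusters >= 1, "k_clusters must be >= 1")
  structure(cfg, class = "memory_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; unknown keys and out-of-range values raise errors,
#' omitted keys take their defaults. The on-disk form round-trips losslessly
#' through [yaml::write_yaml()].
#'
#' @param path YAML config file.
#' @return `memory_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    ms_error("memoryscreen_missing_file", sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(memory_config, vals)
}

#' Run the full screen-to-report pipeline
#'
#' Stages: load + align inputs, permutation screen, significance-probability
#' matrix, saturation + GEAR extraction, SAS edges + core survival network +
#' hub genes, hub-gene subtype clustering, and — when their inputs are
#' present — TMB/differential mutation and dependency scoring. Every stage's
#' artifacts are written as TSV under `out_dir`, and a JSON manifest records
#' the config, per-stage timing, diagnostics and output checksums. Identical
#' config + seed gives byte-identical outputs.
#'
#' @param config `memory_config`; input paths may be replaced by in-memory
#'   objects via `inputs`.
#' @param inputs optional named list (expression, survival, mutations,
#'   dependency, cell_line_mutations) of in-memory objects overriding the
#'   configured paths.
#' @return the manifest, invisibly (also written to `out_dir/manifest.json`).
#' @export
run_memory_pipeline <- function(config, inputs = list()) {
  stopifnot(inherits(config, "memory_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  outputs <- character()
  stage <- function(name, fn) {
    st <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      ms_error("memoryscreen_stage_error",
               sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    res
  }
  emit <- function(obj, file, id_col = "id") {
    path <- file.path(out_dir, file)
    write_table(obj, path, id_col = id_col)
    outputs <<- c(outputs, path)
    path
  }

  get_input <- function(name, reader) {
    if (!is.null(inputs[[name]])) return(inputs[[name]])
    if (is.null(config[[name]])) return(NULL)
    reader(config[[name]])
  }

  expr <- stage("load", function() get_input("expression", read_expression))
  surv <- get_input("survival", read_survival)
  if (is.null(expr) || is.null(surv)) {
    ms_error("memoryscreen_missing_file", "expression and survival inputs are required")
  }
  al <- align_cohort(validate_expression(expr), validate_survival(surv))
  plan <- build_gradient_plan(ncol(al$expression), config$gradients, config$min_size)

  tensor <- stage("screen", function() {
    run_permutation_screen(al$expression, al$survival, plan,
                           n_perm = config$permutations, alpha = config$alpha,
                           seed = config$seed)
  })
  A <- significance_probability(tensor)
  emit(A, "significance_probability.tsv", id_col = "gene")

  j_star <- find_saturation_gradient(A)
  gears <- stage("gears", function() {
    extract_gears(A, j_star, threshold = config$gear_threshold,
                  mode = config$gear_mode)
  })
  emit(as.data.frame(gears), "gears.tsv")
  message(sprintf("pipeline: %d gene(s) screened, saturation gradient %d (size %d), %d GEAR(s)",
                  nrow(A), as.integer(j_star), tensor$sizes[j_star], nrow(gears)))

  hubs <- NULL
  groups <- NULL
  if (nrow(gears) > 0L) {
    net <- stage("network", function() {
      edges <- compute_sas_edges(tensor, gears)
      csn <- build_csn(edges, top_k = config$top_edges)
      list(edges = edges, csn = csn)
    })
    emit(net$csn$edges[, c("gene_u", "gene_v", "sas", "c")], "csn_edges.tsv")
    emit(data.frame(gene = names(net$csn$degree),
                    degree = as.integer(net$csn$degree),
                    strength = as.numeric(net$csn$strength),
                    stringsAsFactors = FALSE), "csn_degrees.tsv")
    hubs <- stage("hubs", function() {
      select_hub_genes(net$csn, al$expression, gears,
                       top_n = config$top_hubs, min_tpm = config$min_tpm)
    })
    emit(as.data.frame(hubs), "hub_genes.tsv")
    message(sprintf("pipeline: %d edge(s) kept, %d hub gene(s)",
                    nrow(net$csn$edges), nrow(hubs)))
  }

  if (!is.null(hubs) && nrow(hubs) > 0L) {
    groups <- stage("classify", function() {
      m_hub <- log_transform_expression(al$expression[hubs$gene, , drop = FALSE])
      cluster_by_hub_genes(m_hub, k = config$k_clusters)
    })
    emit(as.data.frame(groups), "subtype_assignment.tsv")
  }

  mut <- get_input("mutations", read_mutations)
  if (!is.null(mut) && !is.null(groups)) {
    stage("mutation", function() {
      tmb <- compute_tmb(mut, groups$sample_id)
      emit(tmb, "tmb.tsv")
      labs <- sort(unique(groups$cluster))
      for (i in seq_along(labs)) for (j in seq_along(labs)) {
        if (i < j) {
          dm <- differential_mutation(mut, groups, c(labs[i], labs[j]))
          emit(dm, sprintf("diff_mutation_%d_vs_%d.tsv", labs[i], labs[j]))
        }
      }
      NULL
    })
  }

  dep <- get_input("dependency", read_dependency)
  clm <- get_input("cell_line_mutations", read_mutations)
  if (!is.null(dep) && !is.null(clm)) {
    depres <- stage("dependency", function() {
      screen_all_mutations(dep, clm)
    })
    emit(depres, "dependency_screen.tsv")
  }

  manifest <- list(
    package = "memoryscreen",
    version = as.character(utils::packageVersion("memoryscreen")),
    config = unclass(config),
    gradient_sizes = tensor$sizes,
    saturation_gradient = as.integer(j_star),
    saturated = isTRUE(attr(j_star, "saturated")),
    n_gears = nrow(gears),
    diagnostics = tensor$diagnostics,
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
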