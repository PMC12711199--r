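# Typed conditions -------------------------------------------------------

ms_error <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "memoryscreen_error"), call = call))
}

#' Read a TPM expression matrix
#'
#' Reads a tab-delimited genes-by-samples table: first column gene symbols,
#' header row of sample identifiers, remaining cells TPM values. The matrix is
#' validated on the way in: every value must be finite and non-negative, and
#' gene and sample identifiers must be unique. Missing values are rejected,
#' not imputed: TPM matrices from standard pipelines are dense, and silent
#' imputation would distort the median dichotomization the screen rests on.
#'
#' @param path path to the expression file.
#' @param delimiter field separator (default tab).
#' @return numeric matrix (genes x samples) with gene symbols as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    ms_error("memoryscreen_missing_file", sprintf("expression file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, comment.char = "")
  if (ncol(df) < 3L) {
    ms_error("memoryscreen_invalid_format",
             "expression table needs a gene-id column and at least 2 sample columns")
  }
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    ms_error("memoryscreen_non_numeric",
             sprintf("non-numeric expression values in column(s): %s",
                     paste(names(vals)[non_num], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  validate_expression(m)
}

#' Validate an expression matrix
#'
#' @param m numeric matrix, genes x samples, rownames = gene ids,
#'   colnames = sample ids.
#' @return the matrix, invisibly unchanged, if valid.
#' @export
validate_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    ms_error("memoryscreen_invalid_format", "expression must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    ms_error("memoryscreen_invalid_format", "expression matrix needs gene rownames and sample colnames")
  }
  if (nrow(m) < 1L || ncol(m) < 2L) {
    ms_error("memoryscreen_invalid_format", "expression needs >= 1 gene and >= 2 samples")
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    ms_error("memoryscreen_duplicate_id",
             sprintf("duplicated gene identifier(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    ms_error("memoryscreen_duplicate_id",
             sprintf("duplicated sample identifier(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(m) || any(!is.finite(m))) {
    ms_error("memoryscreen_non_finite", "expression values must all be finite (no NA/Inf)")
  }
  if (any(m < 0)) {
    ms_error("memoryscreen_negative_value", "TPM expression values must be >= 0")
  }
  m
}

#' Read a clinical survival table
#'
#' Expects a tab-delimited table with (configurable) columns for sample id,
#' follow-up time and event indicator. Event semantics follow the usual
#' vital-status convention: 1 = event observed (death), 0 = right-censored.
#' Rows with missing time or event are dropped with a message.
#'
#' @param path path to the survival file.
#' @param id_col,time_col,event_col column names.
#' @return data.frame with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path, id_col = "sample_id", time_col = "time",
                          event_col = "event") {
  if (!file.exists(path)) {
    ms_error("memoryscreen_missing_file", sprintf("survival file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c(id_col, time_col, event_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ms_error("memoryscreen_missing_column",
             sprintf("survival table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- data.frame(sample_id = as.character(df[[id_col]]),
                    time = as.numeric(df[[time_col]]),
                    event = as.numeric(df[[event_col]]),
                    stringsAsFactors = FALSE)
  drop <- is.na(out$time) | is.na(out$event)
  if (any(drop)) {
    message(sprintf("read_survival: dropped %d row(s) with missing time/event", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  validate_survival(out)
}

#' Validate a survival table
#' @param s data.frame with sample_id, time, event.
#' @return validated data.frame.
#' @export
validate_survival <- function(s) {
  if (!all(c("sample_id", "time", "event") %in% names(s))) {
    ms_error("memoryscreen_missing_column", "survival table needs sample_id/time/event")
  }
  if (anyDuplicated(s$sample_id)) {
    ms_error("memoryscreen_duplicate_id", "duplicated sample ids in survival table")
  }
  if (any(!is.finite(s$time)) || any(s$time <= 0)) {
    ms_error("memoryscreen_nonpositive_time", "follow-up times must be finite and > 0")
  }
  if (!all(s$event %in% c(0, 1))) {
    ms_error("memoryscreen_invalid_event", "event indicator must be 0 (censored) or 1 (event)")
  }
  rownames(s) <- NULL
  s
}

#' Non-silent variant classification allow-list
#'
#' Default set of MAF variant classes counted as non-silent for tumor
#' mutation burden and carrier status.
#' @return character vector of variant classes.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
    "Splice_Site", "Translation_Start_Site")
}

#' Read a minimal MAF-like mutation table
#'
#' Requires the three MAF columns `Hugo_Symbol`, `Tumor_Sample_Barcode` and
#' `Variant_Classification`. Records whose class is not in `allowed` are
#' reported; when `filter = TRUE` they are removed.
#'
#' @param path path to the tab-delimited MAF-minimal file.
#' @param allowed allow-list of variant classes; `NULL` accepts everything.
#' @param filter drop records outside the allow-list (default FALSE: keep and
#'   let downstream counting filter).
#' @return data.frame with columns gene, sample, variant_class.
#' @export
read_mutations <- function(path, allowed = NULL, filter = FALSE) {
  if (!file.exists(path)) {
    ms_error("memoryscreen_missing_file", sprintf("mutation file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "#")
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    ms_error("memoryscreen_missing_column",
             sprintf("mutation table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- data.frame(gene = as.character(df$Hugo_Symbol),
                    sample = as.character(df$Tumor_Sample_Barcode),
                    variant_class = as.character(df$Variant_Classification),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$gene)) || any(!nzchar(out$sample)) || any(!nzchar(out$variant_class))) {
    ms_error("memoryscreen_invalid_format", "mutation records must have no empty fields")
  }
  if (!is.null(allowed)) {
    unknown <- !(out$variant_class %in% allowed)
    if (any(unknown)) {
      message(sprintf("read_mutations: %d record(s) outside the variant allow-list", sum(unknown)))
      if (filter) out <- out[!unknown, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a cell-line x gene dependency-score matrix
#'
#' First column cell-line ids, header row gene symbols. Scores are real and
#' may be negative (essential genes score below zero in CRISPR screens).
#'
#' @param path path to CSV or TSV file.
#' @param delimiter field separator; guessed from the extension when NULL.
#' @return numeric matrix, cell lines x genes.
#' @export
read_dependency <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    ms_error("memoryscreen_missing_file", sprintf("dependency file not found: %s", path))
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    ms_error("memoryscreen_non_finite", "dependency scores must all be finite numerics")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    ms_error("memoryscreen_duplicate_id", "duplicated cell-line or gene identifiers")
  }
  m
}

#' Align expression and survival on shared samples
#'
#' Inner join on sample id; the aligned sample set is sorted lexicographically
#' so results do not depend on file row order.
#'
#' @param expr expression matrix (genes x samples).
#' @param surv survival data.frame.
#' @return list with `expression` (columns reordered) and `survival`
#'   (rows reordered), both restricted to the shared, sorted sample ids.
#' @export
align_cohort <- function(expr, surv) {
  shared <- sort(intersect(colnames(expr), surv$sample_id))
  if (length(shared) < 2L) {
    ms_error("memoryscreen_no_overlap", "fewer than 2 samples shared between expression and survival")
  }
  su <- surv[match(shared, surv$sample_id), , drop = FALSE]
  rownames(su) <- NULL
  list(expression = expr[, shared, drop = FALSE], survival = su)
}

#' Write a pipeline result as TSV
#'
#' Matrices are written with a leading id column (rownames); data.frames as-is.
#' Full double precision is kept so a read-back reproduces the values.
#'
#' @param object matrix or data.frame.
#' @param path output path.
#' @param id_col name for the rownames column when `object` is a matrix.
#' @return invisibly, the path.
#' @export
write_table <- function(object, path, id_col = "id") {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.matrix(object)) {
    df <- data.frame(rownames(object), object, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_col
  } else if (is.data.frame(object)) {
    df <- object
  } else {
    ms_error("memoryscreen_invalid_format", "write_table expects a matrix or data.frame")
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ms_error("memoryscreen_unwritable_path", sprintf("cannot write: %s", path))
  invisible(path)
}
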