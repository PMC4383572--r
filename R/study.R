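#' Construct and validate an expression study
#'
#' An expression study couples a probe x sample matrix of log2-scale
#' expression values with per-sample metadata. Metadata must contain the
#' columns `sample_id`, `treatment`, `time_hr` (2 or 24), `batch`, `role`
#' (`vehicle`, `reference` or `test`) and may carry an optional
#' `class_label` naming the treatment class of a sample's arm.
#'
#' @param values numeric probe x sample matrix with unique, non-empty
#'   dimnames; all values finite.
#' @param metadata data.frame covering exactly the sample set of `values`.
#' @return An object of class `expression_study` with elements `values` and
#'   `metadata` (metadata reordered to match the column order of `values`).
#' @export
expression_study <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values))
    abort("'values' must be a numeric matrix")
  probe_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    abort("'values' must have probe row names and sample column names")
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup))
    abort("duplicated probe id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    abort("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    abort("expression values must all be finite")

  required <- c("sample_id", "treatment", "time_hr", "batch", "role")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    abort("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    abort("duplicated sample id(s) in metadata")
  absent <- setdiff(sample_ids, metadata$sample_id)
  if (length(absent))
    abort("metadata has no row for sample(s): ", paste(absent, collapse = ", "))
  extra <- setdiff(metadata$sample_id, sample_ids)
  if (length(extra))
    abort("metadata row(s) without a matrix column: ", paste(extra, collapse = ", "))
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$time_hr %in% TIMEPOINTS))
    abort("'time_hr' must be one of: ", paste(TIMEPOINTS, collapse = ", "))
  if (!all(metadata$role %in% c("vehicle", "reference", "test")))
    abort("'role' must be vehicle, reference or test")

  # batch correction needs a vehicle anchor in every batch that has
  # treated samples
  for (b in unique(metadata$batch)) {
    in_b <- metadata$batch == b
    if (any(metadata$role[in_b] != "vehicle") &&
        !any(metadata$role[in_b] == "vehicle"))
      abort(sprintf("batch '%s' has treated samples but no vehicle sample", b))
  }

  structure(list(values = values, metadata = metadata),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "expression_study: %d probes x %d samples (%d treatments, %d batches)\n",
    nrow(x$values), ncol(x$values),
    length(unique(x$metadata$treatment)), length(unique(x$metadata$batch))
  ))
  invisible(x)
}

#' Read an expression study from tab-separated files
#'
#' The expression file has a header row `probe_id` followed by sample ids and
#' one row per probe; the metadata file is a tab-separated table with the
#' columns described in [expression_study()]. Files are UTF-8 with `.` as the
#' decimal separator. Missing values are rejected.
#'
#' @param expression_path,metadata_path paths to the two files.
#' @return An `expression_study`.
#' @export
load_study <- function(expression_path, metadata_path) {
  for (p in c(expression_path, metadata_path))
    if (!file.exists(p)) abort("file not found: ", p)
  expr <- utils::read.delim(expression_path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2L || names(expr)[1L] != "probe_id")
    abort("expression file must start with a 'probe_id' column")
  probe_ids <- as.character(expr[[1L]])
  mat <- as.matrix(expr[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(expr[-1L], is.numeric, logical(1)))
    abort("non-numeric expression value(s) in column(s): ",
          paste(names(expr)[-1L][bad], collapse = ", "))
  }
  if (anyNA(mat)) {
    bad <- probe_ids[rowSums(is.na(mat)) > 0]
    abort("missing expression value(s) for probe(s): ",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  rownames(mat) <- probe_ids
  metadata <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE,
                                colClasses = "character")
  if ("time_hr" %in% names(metadata))
    metadata$time_hr <- as.numeric(metadata$time_hr)
  expression_study(mat, metadata)
}

#' Write an expression study to tab-separated files
#'
#' Inverse of [load_study()]: values are written with 17 significant digits so
#' the round trip reproduces every double bit-exactly.
#'
#' @param study an `expression_study`.
#' @param expression_path,metadata_path output paths.
#' @return Invisibly, the study.
#' @export
write_study <- function(study, expression_path, metadata_path) {
  stopifnot(inherits(study, "expression_study"))
  vals <- study$values
  out <- data.frame(probe_id = rownames(vals),
                    apply(vals, 2L, format_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("probe_id", colnames(vals))
  utils::write.table(out, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(study$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(study)
}

#' Write / read an animal-level phenotype table
#'
#' Long-format tab-separated table with columns `animal_id`, `treatment`,
#' `endpoint`, `value`.
#'
#' @param phenotypes data.frame as produced by [simulate_phenotypes()].
#' @param path file path.
#' @return `write_phenotypes()` returns the table invisibly;
#'   `load_phenotypes()` returns the validated table.
#' @export
write_phenotypes <- function(phenotypes, path) {
  tab <- phenotypes
  tab$value <- format_full(tab$value)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(phenotypes)
}

#' @rdname write_phenotypes
#' @export
load_phenotypes <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("animal_id", "treatment", "endpoint", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    abort("phenotype table is missing column(s): ",
          paste(missing_cols, collapse = ", "))
  tab$value <- as.numeric(tab$value)
  if (anyNA(tab$value)) abort("non-numeric phenotype value(s)")
  validate_phenotypes(tab)
  tab
}

validate_phenotypes <- function(tab) {
  counts <- table(tab$treatment, tab$endpoint)
  if (any(counts > 0 & counts < 3))
    abort("every treatment x endpoint cell needs at least 3 animals")
  pct <- grepl("_pct_", tab$endpoint)
  if (any(tab$value[pct] < 0 | tab$value[pct] > 100))
    abort("percentage endpoints must lie in [0, 100]")
  invisible(tab)
}
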