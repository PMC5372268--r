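## Strict TSV dialects for expression, sample, clinical and annotation
## tables, plus the transcribed reference gene lists shipped with the
## package. Writers are deterministic: fixed column order, %.6g floats.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_tsv_strict <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_strict <- function(path, required) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(basename(path), ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write a simulated dataset to the package's TSV formats
#'
#' Persists an expression table (`probe_set_id`, `gene_id`, one column per
#' sample), a sample sheet (`sample_id`, `patient_id`, `time`), the clinical
#' table, and the ground truth as JSON.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  expr_df <- data.frame(sim$expr$col_meta[c("probe_set_id", "gene_id")],
                        t(sim$expr$values), check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv_strict(expr_df, paths["expression"])
  write_tsv_strict(sim$expr$row_meta, paths["samples"])
  write_tsv_strict(sim$clinical, paths["clinical"])
  jsonlite::write_json(
    list(dysregulated_genes = as.list(sim$truth$dysregulated_genes),
         predictive_genes = as.list(sim$truth$predictive_genes),
         true_patient_effects = as.list(sim$truth$true_patient_effects)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load an exon expression matrix from TSV files
#'
#' Reads the expression table (`probe_set_id`, `gene_id`, sample columns) and
#' the sample sheet (`sample_id`, `patient_id`, `time`), validating the full
#' matched-pair design.
#'
#' @param expression_path,samples_path TSV file paths.
#' @return an [exon_matrix()].
#' @export
load_expression <- function(expression_path, samples_path) {
  expr_df <- read_tsv_strict(expression_path, c("probe_set_id", "gene_id"))
  samples <- read_tsv_strict(samples_path,
                             c("sample_id", "patient_id", "time"))
  sample_cols <- setdiff(names(expr_df), c("probe_set_id", "gene_id"))
  missing <- setdiff(samples$sample_id, sample_cols)
  if (length(missing) > 0)
    stop("expression file lacks sample column(s): ",
         paste(missing, collapse = ", "))
  values <- t(as.matrix(expr_df[, samples$sample_id, drop = FALSE]))
  exon_matrix(values, samples,
              expr_df[c("probe_set_id", "gene_id")])
}

#' Load and validate a clinical table
#'
#' @param path TSV with columns `patient_id`, `egfr_mut`, `ds12`, `ts12`,
#'   `ttp_be`, `ttp_be_event`, `ttp_ct`, `ttp_ct_event`, `os`, `os_event`.
#' @return validated data.frame.
#' @export
load_clinical <- function(path) {
  need <- c("patient_id", "egfr_mut", "ds12", "ts12",
            "ttp_be", "ttp_be_event", "ttp_ct", "ttp_ct_event",
            "os", "os_event")
  cl <- read_tsv_strict(path, need)
  if (anyDuplicated(cl$patient_id))
    stop("clinical table: duplicated patient_id")
  for (v in c("ttp_be", "ttp_ct", "os"))
    if (any(cl[[v]] < 0, na.rm = TRUE))
      stop("clinical table: negative times in ", v)
  for (v in c("egfr_mut", "ds12", "ttp_be_event", "ttp_ct_event",
              "os_event"))
    if (!all(cl[[v]] %in% c(0, 1, NA)))
      stop("clinical table: ", v, " must be 0/1")
  cl
}

#' Load a probe-set annotation table
#'
#' @param path TSV with columns `probe_set_id`, `gene_id`, `category`.
#' @return data.frame suitable for [filter_probe_sets()].
#' @export
load_annotation <- function(path) {
  ann <- read_tsv_strict(path, c("probe_set_id", "gene_id", "category"))
  if (anyDuplicated(ann$probe_set_id))
    stop("annotation: duplicated probe_set_id")
  ann
}

#' Reference gene lists transcribed from the source study
#'
#' `ref_top100_genes()` returns the published list of the 100 genes most
#' dysregulated 24h after treatment initiation (Ensembl id, symbol,
#' direction: 54 up / 46 down). `ref_predictive_ttpbe_24h()` returns the 91
#' gene symbols whose 24h expression predicted time-to-progression under
#' treatment, i.e. the members of the 91-gene metagene. These are reference
#' fixtures for comparison and annotation exercises; they are not inputs to
#' any computation in this package.
#'
#' @return data.frame (`ensembl_id`, `symbol`, `direction`) or character
#'   vector of symbols.
#' @export
ref_top100_genes <- function() {
  path <- system.file("extdata", "top100_dysregulated_24h.tsv",
                      package = "exonDCCA", mustWork = TRUE)
  read_tsv_strict(path, c("ensembl_id", "symbol", "direction"))
}

#' @rdname ref_top100_genes
#' @export
ref_predictive_ttpbe_24h <- function() {
  path <- system.file("extdata", "predictive_ttpbe_24h.tsv",
                      package = "exonDCCA", mustWork = TRUE)
  read_tsv_strict(path, "symbol")$symbol
}

#' Write a screening table or enrichment table to TSV
#'
#' Deterministic writer (%.6g float format, fixed column order).
#'
#' @param x a `screen_result`, or any data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(x, path) {
  df <- if (inherits(x, "screen_result")) x$table else as.data.frame(x)
  write_tsv_strict(df, path)
}
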