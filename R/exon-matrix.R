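#' Paired exon-level expression container
#'
#' An `exon_matrix` holds nonnegative exon-level expression intensities for a
#' fully matched two-time-point design: rows are observations (one per patient
#' and time point, stacked), columns are exonic probe sets grouped into genes.
#' This is the input container for [correspondence_analysis()] and
#' [dcca_fit()].
#'
#' @param values numeric matrix of nonnegative intensities, observations in
#'   rows, probe sets in columns.
#' @param row_meta data.frame with columns `sample_id`, `patient_id`, `time`
#'   (`"baseline"` or `"h24"`), one row per row of `values`.
#' @param col_meta data.frame with columns `probe_set_id`, `gene_id` and
#'   optionally `category` (one of `"exonic"`, `"intronic"`, `"intergenic"`,
#'   `"unreliable"`), one row per column of `values`.
#'
#' @details Invariants enforced at construction: all intensities are
#'   nonnegative with a positive grand total; every patient appears exactly
#'   once per time level; every probe set maps to exactly one gene. Rows and
#'   columns are named by `sample_id` and `probe_set_id`.
#'
#' @return An object of class `exon_matrix`.
#' @seealso [simulate_dataset()], [filter_probe_sets()], [dcca_fit()]
#' @export
exon_matrix <- function(values, row_meta, col_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  row_meta <- as.data.frame(row_meta, stringsAsFactors = FALSE)
  col_meta <- as.data.frame(col_meta, stringsAsFactors = FALSE)

  need_row <- c("sample_id", "patient_id", "time")
  if (!all(need_row %in% names(row_meta)))
    stop("row_meta must have columns: ", paste(need_row, collapse = ", "))
  need_col <- c("probe_set_id", "gene_id")
  if (!all(need_col %in% names(col_meta)))
    stop("col_meta must have columns: ", paste(need_col, collapse = ", "))
  if (nrow(row_meta) != nrow(values))
    stop("row_meta has ", nrow(row_meta), " rows but values has ",
         nrow(values))
  if (nrow(col_meta) != ncol(values))
    stop("col_meta has ", nrow(col_meta), " rows but values has ",
         ncol(values), " columns")
  if (anyNA(values)) stop("expression values contain NA")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative expression values, e.g. at row ", neg[1, 1],
         " column ", neg[1, 2], "; correspondence analysis requires ",
         "nonnegative input")
  if (sum(values) <= 0) stop("grand total of expression values must be > 0")

  bad_time <- setdiff(unique(row_meta$time), c("baseline", "h24"))
  if (length(bad_time) > 0)
    stop("unknown time labels: ", paste(bad_time, collapse = ", "),
         " (expected 'baseline' or 'h24')")
  if (anyDuplicated(row_meta$sample_id))
    stop("duplicated sample ids: ",
         paste(unique(row_meta$sample_id[duplicated(row_meta$sample_id)]),
               collapse = ", "))
  check_pairing(row_meta)
  if (anyDuplicated(col_meta$probe_set_id))
    stop("duplicated probe set ids")

  if ("category" %in% names(col_meta)) {
    bad <- setdiff(unique(col_meta$category),
                   c("exonic", "intronic", "intergenic", "unreliable"))
    if (length(bad) > 0)
      stop("unknown probe set categories: ", paste(bad, collapse = ", "))
  }

  dimnames(values) <- list(row_meta$sample_id, col_meta$probe_set_id)
  structure(list(values = values, row_meta = row_meta, col_meta = col_meta),
            class = "exon_matrix")
}

# Every patient must occur exactly once per time level (fully matched pairs).
check_pairing <- function(row_meta) {
  tab <- table(row_meta$patient_id, row_meta$time)
  if (!all(c("baseline", "h24") %in% colnames(tab)) || any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    if (length(bad) == 0) bad <- "<all>"
    stop("unpaired design: patient(s) ", paste(bad, collapse = ", "),
         " do not have exactly one baseline and one h24 sample")
  }
  invisible(TRUE)
}

#' @export
print.exon_matrix <- function(x, ...) {
  cat("exon_matrix: ", nrow(x$values), " observations (",
      length(unique(x$row_meta$patient_id)), " patients x 2 times), ",
      ncol(x$values), " probe sets in ",
      length(unique(x$col_meta$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' @export
dim.exon_matrix <- function(x) dim(x$values)

#' Restrict an exon matrix to exonic probe sets
#'
#' Drops intronic, intergenic and unreliable probe sets according to a
#' probe-set annotation, keeping only the `exonic` category. This mirrors the
#' standard pre-analysis filter for exon arrays, where only probe sets mapping
#' reliably to annotated exons are carried into the analysis.
#'
#' @param x an [exon_matrix()].
#' @param annotation data.frame with columns `probe_set_id`, `gene_id`,
#'   `category`; every column of `x` must be present.
#' @return The filtered `exon_matrix` (columns restricted to exonic probe
#'   sets); retained/dropped counts are reported via [message()].
#' @export
filter_probe_sets <- function(x, annotation) {
  stopifnot(inherits(x, "exon_matrix"))
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("probe_set_id", "gene_id", "category")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(annotation$category),
                 c("exonic", "intronic", "intergenic", "unreliable"))
  if (length(bad) > 0)
    stop("unknown probe set categories: ", paste(bad, collapse = ", "))
  missing <- setdiff(x$col_meta$probe_set_id, annotation$probe_set_id)
  if (length(missing) > 0)
    stop("probe sets absent from annotation: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10) else "")
  idx <- match(x$col_meta$probe_set_id, annotation$probe_set_id)
  keep <- annotation$category[idx] == "exonic"
  if (!any(keep)) stop("no exonic probe sets remain after filtering")
  out <- exon_matrix(x$values[, keep, drop = FALSE],
                     x$row_meta,
                     x$col_meta[keep, , drop = FALSE])
  message(sprintf(
    "filter_probe_sets: retained %d exonic probe sets in %d genes, dropped %d",
    sum(keep), length(unique(out$col_meta$gene_id)), sum(!keep)))
  out
}
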