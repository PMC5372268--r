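## Correspondence analysis with dual linear constraints for the paired
## baseline/24h exon-array design.
##
## Notation used throughout: for a nonnegative table X with grand total N,
## P = X/N, row masses r = P1, column masses c = P'1, and the standardized
## residual matrix S with entries (p_ij - r_i c_j) / sqrt(r_i c_j). Plain CA
## is the SVD of S. Constraints act as projections of the chi-square-metric
## row (column) profiles onto indicator subspaces; on S these are ordinary
## orthogonal projections by D_r^{1/2} A (A'D_r A)^{-1} A' D_r^{1/2} (and the
## c-weighted analogue on the column side). For disjoint group indicators the
## projection reduces to a mass-weighted group average, which is how it is
## computed here: no dense projector is ever materialized.

#' Correspondence analysis of a nonnegative table
#'
#' Plain (unconstrained) correspondence analysis: decomposition of the
#' standardized chi-square residuals of a nonnegative table by SVD. Total
#' inertia equals the chi-square statistic of the table divided by its grand
#' total, and also the sum of squared singular values.
#'
#' @param x an [exon_matrix()] or a nonnegative numeric matrix.
#' @param n_axes number of axes to retain (>= 1).
#' @return A list of class `ca_decomposition`: `row_masses`, `col_masses`,
#'   `singular_values` (nonincreasing), `row_coords` and `col_coords`
#'   (principal coordinates, one column per retained axis), `total_inertia`.
#' @examples
#' correspondence_analysis(matrix(c(10, 0, 0, 10), 2, 2))$total_inertia  # 1
#' @export
correspondence_analysis <- function(x, n_axes = 2L) {
  v <- if (inherits(x, "exon_matrix")) x$values else as.matrix(x)
  if (n_axes < 1) stop("n_axes must be >= 1")
  ca <- ca_residuals(v)
  sv <- svd(ca$S)
  tol <- 1e-12 * max(sv$d, 0)
  d <- ifelse(sv$d <= tol, 0, sv$d)
  k <- min(n_axes, length(d))
  idx <- seq_len(k)
  row_coords <- sweep(sv$u[, idx, drop = FALSE] %*% diag(d[idx], k, k),
                      1, sqrt(ca$r), "/")
  col_coords <- sweep(sv$v[, idx, drop = FALSE] %*% diag(d[idx], k, k),
                      1, sqrt(ca$c), "/")
  rownames(row_coords) <- rownames(v)
  rownames(col_coords) <- colnames(v)
  structure(list(row_masses = ca$r, col_masses = ca$c,
                 singular_values = d,
                 row_coords = row_coords, col_coords = col_coords,
                 total_inertia = sum(d^2)),
            class = "ca_decomposition")
}

# Masses and standardized residuals; validates CA preconditions.
ca_residuals <- function(v) {
  if (anyNA(v)) stop("degenerate input: NA values")
  neg <- which(v < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("degenerate input: negative entry at row ", neg[1, 1],
         ", column ", neg[1, 2])
  n <- sum(v)
  if (n <= 0) stop("degenerate input: zero grand total")
  rs <- rowSums(v)
  cs <- colSums(v)
  if (any(rs == 0))
    stop("degenerate input: all-zero row(s): ",
         paste(utils::head(which(rs == 0), 5), collapse = ", "))
  if (any(cs == 0))
    stop("degenerate input: all-zero column(s): ",
         paste(utils::head(which(cs == 0), 5), collapse = ", "))
  p <- v / n
  r <- rs / n
  c <- cs / n
  S <- (p - tcrossprod(r, c)) / sqrt(tcrossprod(r, c))
  list(S = S, r = r, c = c, n = n)
}

#' Row-side constraint designs for the paired two-time design
#'
#' Builds the observation-wise indicator designs used by [dcca_fit()]: the
#' patient design (one indicator column per patient) is the negative
#' constraint whose span is partialled out, and the time design (baseline vs.
#' 24h) is the positive constraint whose span is retained.
#'
#' @param row_meta data.frame with `patient_id` and `time` columns satisfying
#'   the fully matched pairing invariant.
#' @return list with `patient` (n_obs x n_patients) and `time` (n_obs x 2)
#'   indicator matrices; each row of each design sums to 1.
#' @export
build_row_constraints <- function(row_meta) {
  check_pairing(row_meta)
  pat <- factor(row_meta$patient_id)
  tim <- factor(row_meta$time, levels = c("baseline", "h24"))
  patient <- stats::model.matrix(~ pat - 1)
  time <- stats::model.matrix(~ tim - 1)
  colnames(patient) <- levels(pat)
  colnames(time) <- levels(tim)
  list(patient = patient, time = time)
}

# Mass-weighted group-mean projection of the rows of Z onto the span of a
# disjoint group indicator (equivalently: replace each row by its group's
# weighted average). O(nnz) instead of a dense projector.
project_rows_onto_groups <- function(Z, groups, w) {
  gw <- rowsum(w, groups)[, 1]
  means <- rowsum(Z * w, groups) / gw
  means[as.character(groups), , drop = FALSE]
}

#' Dually constrained correspondence analysis of paired exon expression
#'
#' Fits the constrained ordination that isolates the 24h treatment effect in
#' a fully matched baseline/24h exon-level design. Starting from the
#' standardized residuals of plain correspondence analysis, three projections
#' are applied in order: (a) the span of the per-patient indicators is
#' removed under the row-mass inner product (within-patient partialling);
#' (b) the result is projected onto the span of the two time-level indicators
#' (between-time constraint; with two levels this leaves at most one axis);
#' (c) column profiles are projected onto the span of the per-gene indicators
#' under the column-mass inner product, so all exonic probe sets of a gene
#' share one score. The single remaining axis is extracted by SVD and
#' oriented so that the 24h class score is nonnegative: positive gene scores
#' mean 24h up-regulation.
#'
#' All projections are computed as mass-weighted group averages (patients,
#' time levels, genes), never as dense projector matrices, so the fit scales
#' linearly in the size of the table.
#'
#' @param x an [exon_matrix()] with at least 2 patients.
#' @param ranking `"coordinate"` (default) ranks genes by the absolute value
#'   of their constrained coordinate; `"contribution"` ranks by mass-weighted
#'   squared coordinate (a sensitivity-analysis alternative).
#' @return A list of class `dcca_result`:
#'   \describe{
#'     \item{gene_scores}{named signed score per gene (constrained column
#'       principal coordinate; equal across a gene's exons).}
#'     \item{exon_scores}{per probe set (each equal to its gene's score).}
#'     \item{time_class_scores}{row score of each time class on the
#'       constrained axis (`h24` >= 0 by convention).}
#'     \item{axis_row_scores}{per observation.}
#'     \item{singular_value, constrained_inertia, total_inertia,
#'       inertia_fraction}{inertia accounting of the constrained axis.}
#'     \item{ranked_genes}{data.frame `gene_id`, `score`, `direction`
#'       (up/down), ordered by ranking statistic, ties broken by gene id.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_patients = 8, n_genes = 30,
#'                                    exons_per_gene = c(2, 4),
#'                                    n_dysregulated = 3, n_predictive = 2,
#'                                    seed = 1))
#' fit <- dcca_fit(sim$expr)
#' head(fit$ranked_genes)
#' @export
dcca_fit <- function(x, ranking = c("coordinate", "contribution")) {
  stopifnot(inherits(x, "exon_matrix"))
  ranking <- match.arg(ranking)
  if (length(unique(x$row_meta$patient_id)) < 2)
    stop("dcca_fit requires at least 2 patients")
  if (length(unique(x$row_meta$time)) < 2)
    stop("fewer than 2 time levels present")
  check_pairing(x$row_meta)

  ca <- ca_residuals(x$values)
  r <- ca$r
  cc <- ca$c
  # Work on Z = P/(r c') - 1, whose weighted SVD (row weights r, column
  # weights c) is the CA of the table: S = D_r^{1/2} Z D_c^{1/2}.
  Z <- ca$S / sqrt(tcrossprod(r, cc))

  pat <- factor(x$row_meta$patient_id)
  tim <- factor(x$row_meta$time, levels = c("baseline", "h24"))
  gene <- factor(x$col_meta$gene_id)

  ## (a) remove within-patient span; (b) keep between-time span
  Z1 <- Z - project_rows_onto_groups(Z, pat, r)
  tw <- rowsum(r, tim)[, 1]                     # time-class masses
  Tmeans <- rowsum(Z1 * r, tim) / tw            # 2 x m, rows = time classes
  ## (c) gene-wise c-weighted average of columns
  gw <- rowsum(cc, gene)[, 1]                   # gene masses
  M <- t(rowsum(t(Tmeans) * cc, gene) / gw)     # 2 x G core table

  ## weighted SVD of the compressed core
  K <- sqrt(tw) * M %*% diag(sqrt(gw), length(gw))
  sv <- svd(K)
  tol <- 1e-12 * sqrt(sum(ca$S^2))
  d1 <- if (sv$d[1] > tol) sv$d[1] else 0

  if (d1 == 0) {
    u1 <- c(0, 0)
    v1 <- numeric(length(gw))
  } else {
    u1 <- sv$u[, 1]
    v1 <- sv$v[, 1]
    if (d1 * u1[which(levels(tim) == "h24")] / sqrt(tw[["h24"]]) < 0) {
      u1 <- -u1
      v1 <- -v1
    }
  }

  time_class_scores <- stats::setNames(d1 * u1 / sqrt(tw), levels(tim))
  gene_scores <- stats::setNames(d1 * v1 / sqrt(gw), levels(gene))
  exon_scores <- stats::setNames(gene_scores[as.character(gene)],
                                 x$col_meta$probe_set_id)
  axis_row_scores <- stats::setNames(
    time_class_scores[as.character(tim)], x$row_meta$sample_id)

  stat <- if (ranking == "coordinate") abs(gene_scores)
          else gw * gene_scores^2
  ord <- order(-stat, names(gene_scores))
  ranked <- data.frame(
    gene_id = names(gene_scores)[ord],
    score = unname(gene_scores[ord]),
    direction = ifelse(gene_scores[ord] > 0, "up",
                       ifelse(gene_scores[ord] < 0, "down", "none")),
    stringsAsFactors = FALSE)
  rownames(ranked) <- NULL

  structure(list(gene_scores = gene_scores,
                 exon_scores = exon_scores,
                 time_class_scores = time_class_scores,
                 axis_row_scores = axis_row_scores,
                 singular_value = d1,
                 constrained_inertia = d1^2,
                 total_inertia = sum(ca$S^2),
                 inertia_fraction = d1^2 / sum(ca$S^2),
                 ranking = ranking,
                 ranked_genes = ranked),
            class = "dcca_result")
}

#' @export
print.dcca_result <- function(x, ...) {
  cat("dcca_result: ", length(x$gene_scores), " genes, constrained inertia ",
      format(x$constrained_inertia, digits = 4), " (",
      format(100 * x$inertia_fraction, digits = 3),
      "% of total)\n", sep = "")
  cat("top genes:\n")
  print(utils::head(x$ranked_genes, 5))
  invisible(x)
}

#' Top dysregulated genes from a constrained fit
#'
#' Extracts the `k` genes with the largest absolute constrained-axis scores,
#' labelled `up` (positive score: 24h up-regulation) or `down`. Genes with a
#' score of exactly zero carry no direction and are excluded even if fewer
#' than `k` genes remain, with a warning.
#'
#' @param result a [dcca_fit()] result.
#' @param k number of genes requested (1 <= k <= number of genes).
#' @return data.frame `gene_id`, `score`, `direction`, `rank`.
#' @export
top_dysregulated <- function(result, k) {
  stopifnot(inherits(result, "dcca_result"))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(result$ranked_genes))
    stop("k exceeds the number of genes (", nrow(result$ranked_genes), ")")
  out <- result$ranked_genes[result$ranked_genes$score != 0, , drop = FALSE]
  if (nrow(out) < k)
    warning("only ", nrow(out), " genes have nonzero scores; returning ",
            nrow(out), " instead of ", k)
  out <- utils::head(out, k)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Permutation null distribution of the constrained inertia
#'
#' Reference distribution of the between-time constrained inertia obtained by
#' independently permuting the baseline/24h labels within each patient
#' (random pair swaps). Under no true 24h effect the observed constrained
#' inertia is exchangeable with this distribution.
#'
#' @param x an [exon_matrix()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return numeric vector of length `n_perm` of constrained inertias.
#' @export
dcca_permutation_null <- function(x, n_perm = 199L, seed = 1L) {
  stopifnot(inherits(x, "exon_matrix"))
  set.seed(seed)
  pats <- unique(x$row_meta$patient_id)
  vapply(seq_len(n_perm), function(i) {
    flip <- pats[stats::runif(length(pats)) < 0.5]
    rm2 <- x$row_meta
    swap <- rm2$patient_id %in% flip
    rm2$time[swap] <- ifelse(rm2$time[swap] == "baseline", "h24", "baseline")
    xp <- x
    xp$row_meta <- rm2
    dcca_fit(xp)$constrained_inertia
  }, numeric(1))
}
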