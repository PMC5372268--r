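#' Gene-level summary of an exon matrix
#'
#' Collapses exonic probe sets to gene level by the unweighted mean of a
#' gene's exon values at the requested time point; `"delta"` is the
#' per-patient 24h minus baseline difference of those gene-level values.
#'
#' @param x an [exon_matrix()].
#' @param timepoint one of `"baseline"`, `"h24"`, `"delta"`.
#' @return numeric matrix, patients in rows (named by patient id), genes in
#'   columns.
#' @export
gene_level_matrix <- function(x, timepoint = c("baseline", "h24", "delta")) {
  stopifnot(inherits(x, "exon_matrix"))
  timepoint <- match.arg(timepoint)
  gene <- factor(x$col_meta$gene_id)
  one_time <- function(tp) {
    keep <- x$row_meta$time == tp
    v <- x$values[keep, , drop = FALSE]
    rownames(v) <- x$row_meta$patient_id[keep]
    g <- t(rowsum(t(v), gene) / as.vector(table(gene)))
    g[order(rownames(g)), , drop = FALSE]
  }
  switch(timepoint,
         baseline = one_time("baseline"),
         h24 = one_time("h24"),
         delta = one_time("h24") - one_time("baseline"))
}

endpoint_model <- function(endpoint) {
  switch(endpoint,
         ds12 = "logistic",
         ts12 = "linear",
         ttp_be = , ttp_ct = , os = "cox",
         stop("unknown endpoint: ", endpoint))
}

# Single-gene fit; returns coefficient, SE, Wald p for the gene term.
fit_one_gene <- function(g, dat, model, adjust) {
  rhs <- if (adjust) "g + egfr_mut" else "g"
  dat$g <- g
  res <- list(coefficient = NA_real_, std_error = NA_real_, p_value = 1,
              converged = FALSE, flag = "")
  if (stats::sd(g) == 0) {
    res$flag <- "zero_variance"
    return(res)
  }
  out <- tryCatch({
    withCallingHandlers({
      if (model == "logistic") {
        fit <- stats::glm(stats::as.formula(paste("y ~", rhs)),
                          family = stats::binomial(), data = dat)
        co <- summary(fit)$coefficients
        list(co = co["g", ], conv = fit$converged)
      } else if (model == "linear") {
        fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
        co <- summary(fit)$coefficients
        list(co = co["g", ], conv = TRUE)
      } else {
        fit <- survival::coxph(
          stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
          data = dat, ties = "efron")
        co <- summary(fit)$coefficients
        list(co = co["g", c("coef", "se(coef)", "Pr(>|z|)")], conv = TRUE)
      }
    }, warning = function(w) {
      res$flag <<- "warning"
      invokeRestart("muffleWarning")
    })
  }, error = function(e) NULL)
  if (is.null(out)) {
    res$flag <- "fit_failed"
    return(res)
  }
  co <- out$co
  res$coefficient <- unname(co[1])
  res$std_error <- unname(co[2])
  res$p_value <- unname(co[length(co)])
  res$converged <- isTRUE(out$conv)
  if (!res$converged && res$flag == "") res$flag <- "not_converged"
  if (!is.finite(res$p_value)) {
    res$p_value <- 1
    res$flag <- paste0(res$flag, "+nonfinite_p")
  }
  res
}

#' Per-gene predictive screening against a clinical endpoint
#'
#' Fits, for every gene, a single-gene model of a clinical endpoint with
#' optional adjustment for mutation status: logistic regression for the
#' binary endpoint (`ds12`), linear regression for the continuous endpoint
#' (`ts12`), and Cox proportional hazards (Efron ties) for the time-to-event
#' endpoints (`ttp_be`, `ttp_ct`, `os`). The Wald p-value of the gene
#' coefficient is reported and genes with `p < alpha` are selected as
#' putative predictive markers. Non-converging or degenerate fits are flagged
#' and reported with `p = 1`, never dropped silently.
#'
#' @param expr patients x genes matrix (e.g. from [gene_level_matrix()]),
#'   rows named by patient id.
#' @param clinical clinical table with `patient_id`, `egfr_mut`, endpoint
#'   columns and, for time-to-event endpoints, `<endpoint>_event` (for `os`,
#'   `os_event`).
#' @param endpoint one of `ds12`, `ts12`, `ttp_be`, `ttp_ct`, `os`.
#' @param adjust_mutation include `egfr_mut` as covariate (default TRUE).
#' @param alpha selection threshold on the raw Wald p-value (default 0.001).
#'   No multiple-testing correction is applied to the selection; a
#'   Benjamini-Hochberg column `p_adjust` is emitted for information.
#' @param timepoint label recorded in the output table (does not affect the
#'   fit).
#' @return list of class `screen_result`: `table` (one row per gene:
#'   `gene_id`, `endpoint`, `timepoint`, `model`, `coefficient`, `std_error`,
#'   `p_value`, `p_adjust`, `n_used`, `converged`, `flag`) and `selected`
#'   (character vector of genes with `p_value < alpha`).
#' @export
screen <- function(expr, clinical, endpoint,
                   adjust_mutation = TRUE, alpha = 0.001,
                   timepoint = NA_character_) {
  expr <- as.matrix(expr)
  model <- endpoint_model(endpoint)
  idx <- match(rownames(expr), clinical$patient_id)
  if (anyNA(idx))
    stop("patients missing from clinical table: ",
         paste(utils::head(rownames(expr)[is.na(idx)], 5), collapse = ", "))
  cl <- clinical[idx, , drop = FALSE]
  if (model == "cox") {
    evcol <- paste0(endpoint, "_event")
    if (!evcol %in% names(cl)) stop("missing event indicator column: ", evcol)
    dat <- data.frame(time = cl[[endpoint]], event = cl[[evcol]],
                      egfr_mut = cl$egfr_mut)
    if (any(dat$time < 0)) stop("negative event times in ", endpoint)
  } else {
    dat <- data.frame(y = cl[[endpoint]], egfr_mut = cl$egfr_mut)
  }
  adjust <- adjust_mutation && stats::sd(cl$egfr_mut) > 0

  fits <- lapply(seq_len(ncol(expr)),
                 function(j) fit_one_gene(expr[, j], dat, model, adjust))
  tab <- data.frame(
    gene_id = colnames(expr),
    endpoint = endpoint,
    timepoint = timepoint,
    model = model,
    coefficient = vapply(fits, `[[`, numeric(1), "coefficient"),
    std_error = vapply(fits, `[[`, numeric(1), "std_error"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    n_used = nrow(dat),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  tab$p_adjust <- stats::p.adjust(tab$p_value, method = "BH")
  structure(list(table = tab,
                 selected = tab$gene_id[tab$p_value < alpha],
                 alpha = alpha, endpoint = endpoint,
                 adjusted = adjust_mutation),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", x$endpoint, "-", nrow(x$table), "genes,",
      length(x$selected), "selected at p <", x$alpha, "\n")
  invisible(x)
}

#' Screen the magnitude of the 24h expression change
#'
#' Applies [screen()] to the per-patient 24h-minus-baseline change of a
#' restricted gene list (by default the most dysregulated genes from the
#' constrained ordination), testing whether the magnitude of the early shift
#' predicts an endpoint.
#'
#' @param expr_delta patients x genes delta matrix
#'   (`gene_level_matrix(x, "delta")`).
#' @param clinical,endpoint,adjust_mutation,alpha as in [screen()].
#' @param genes gene ids to restrict to (default: all columns).
#' @return a `screen_result` (timepoint labelled `"delta"`).
#' @export
screen_change_magnitude <- function(expr_delta, clinical, endpoint,
                                    genes = colnames(expr_delta),
                                    adjust_mutation = TRUE, alpha = 0.001) {
  missing <- setdiff(genes, colnames(expr_delta))
  if (length(missing) > 0)
    stop("genes absent from delta matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  screen(expr_delta[, genes, drop = FALSE], clinical, endpoint,
         adjust_mutation = adjust_mutation, alpha = alpha,
         timepoint = "delta")
}

#' Mixed-effects screening across both time points
#'
#' For analyses that use baseline and 24h jointly, fits per gene a
#' patient-random-intercept model of a (binary or continuous) endpoint on
#' expression stacked over the two time points:
#' `endpoint ~ expression + egfr_mut + (1 | patient)`. Requires the `lme4`
#' package. Time-to-event endpoints are not supported here (use [screen()]
#' on a single time point).
#'
#' @param x an [exon_matrix()].
#' @param clinical,endpoint,adjust_mutation,alpha as in [screen()];
#'   `endpoint` must be `ds12` or `ts12`.
#' @return a `screen_result` with model `"mixed"`.
#' @export
screen_mixed <- function(x, clinical, endpoint,
                         adjust_mutation = TRUE, alpha = 0.001) {
  if (!requireNamespace("lme4", quietly = TRUE))
    stop("screen_mixed requires the lme4 package")
  if (!endpoint %in% c("ds12", "ts12"))
    stop("mixed-effects screening supports ds12 and ts12 only")
  gb <- gene_level_matrix(x, "baseline")
  gh <- gene_level_matrix(x, "h24")
  stopifnot(identical(rownames(gb), rownames(gh)))
  pid <- rep(rownames(gb), 2)
  idx <- match(pid, clinical$patient_id)
  if (anyNA(idx)) stop("patients missing from clinical table")
  dat0 <- data.frame(patient = pid,
                     y = clinical[[endpoint]][idx],
                     egfr_mut = clinical$egfr_mut[idx])
  adjust <- adjust_mutation && stats::sd(clinical$egfr_mut) > 0
  rhs <- if (adjust) "g + egfr_mut + (1 | patient)" else "g + (1 | patient)"
  binary <- endpoint == "ds12"
  fits <- lapply(seq_len(ncol(gb)), function(j) {
    dat <- dat0
    dat$g <- c(gb[, j], gh[, j])
    res <- list(coefficient = NA_real_, std_error = NA_real_, p_value = 1,
                converged = FALSE, flag = "")
    if (stats::sd(dat$g) == 0) {
      res$flag <- "zero_variance"
      return(res)
    }
    out <- tryCatch(suppressWarnings(suppressMessages({
      if (binary) {
        fit <- lme4::glmer(stats::as.formula(paste("y ~", rhs)), data = dat,
                           family = stats::binomial())
      } else {
        fit <- lme4::lmer(stats::as.formula(paste("y ~", rhs)), data = dat)
      }
      co <- stats::coef(summary(fit))["g", ]
      z <- co[[1]] / co[[2]]
      list(coefficient = co[[1]], std_error = co[[2]],
           p_value = 2 * stats::pnorm(-abs(z)), converged = TRUE,
           flag = "")
    })), error = function(e) NULL)
    if (is.null(out)) {
      res$flag <- "fit_failed"
      res
    } else out
  })
  tab <- data.frame(
    gene_id = colnames(gb),
    endpoint = endpoint,
    timepoint = "both",
    model = "mixed",
    coefficient = vapply(fits, `[[`, numeric(1), "coefficient"),
    std_error = vapply(fits, `[[`, numeric(1), "std_error"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    n_used = nrow(dat0),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  tab$p_adjust <- stats::p.adjust(tab$p_value, method = "BH")
  structure(list(table = tab,
                 selected = tab$gene_id[tab$p_value < alpha],
                 alpha = alpha, endpoint = endpoint,
                 adjusted = adjust_mutation),
            class = "screen_result")
}
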