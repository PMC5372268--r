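#' Configuration for the full analysis pipeline
#'
#' Assembles the stage parameters of [run_pipeline()]. Inputs are either a
#' simulation configuration (the default) or paths to expression/sample/
#' clinical TSV files; an optional probe-set annotation drives the exonic
#' filter and an optional GMT file drives enrichment.
#'
#' @param simulate a [sim_config()], or NULL when `expression_path` is given.
#' @param expression_path,samples_path,clinical_path TSV inputs (used when
#'   `simulate` is NULL).
#' @param annotation_path optional probe-set annotation TSV; when absent the
#'   filter stage is a no-op (all probe sets treated as exonic).
#' @param gmt_path optional GMT file for the enrichment stage.
#' @param k number of top dysregulated genes carried forward (default 100).
#' @param alpha screening significance threshold (default 0.001).
#' @param endpoints endpoints to screen (default all five).
#' @param screen_timepoints expression summaries to screen (default baseline
#'   and 24h).
#' @param metagene_endpoint time-to-event endpoint used to build and
#'   evaluate the metagene (default `ttp_be`).
#' @param metagene_timepoint expression summary whose selected genes feed
#'   the metagene (default `h24`).
#' @param seed integer seed recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(),
                            expression_path = NULL,
                            samples_path = NULL,
                            clinical_path = NULL,
                            annotation_path = NULL,
                            gmt_path = NULL,
                            k = 100L,
                            alpha = 0.001,
                            endpoints = c("ds12", "ts12", "ttp_be",
                                          "ttp_ct", "os"),
                            screen_timepoints = c("baseline", "h24"),
                            metagene_endpoint = "ttp_be",
                            metagene_timepoint = "h24",
                            seed = 1L) {
  if (is.null(simulate) &&
      (is.null(expression_path) || is.null(samples_path) ||
       is.null(clinical_path)))
    stop("either a simulation config or expression/samples/clinical paths ",
         "must be provided")
  structure(list(simulate = simulate,
                 expression_path = expression_path,
                 samples_path = samples_path,
                 clinical_path = clinical_path,
                 annotation_path = annotation_path,
                 gmt_path = gmt_path,
                 k = as.integer(k), alpha = alpha,
                 endpoints = endpoints,
                 screen_timepoints = screen_timepoints,
                 metagene_endpoint = metagene_endpoint,
                 metagene_timepoint = metagene_timepoint,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full paired exon-array analysis pipeline
#'
#' Executes the stages in order: input (simulate or load), probe-set filter,
#' constrained ordination (DCCA), top-k dysregulated gene extraction,
#' gene-set enrichment (when a GMT file is configured), per-gene endpoint
#' screening, metagene construction from the selected genes of the
#' configured endpoint, and survival evaluation of the metagene split. Every
#' intermediate table is persisted under `out_dir` and a JSON manifest
#' records parameters, seed and per-stage row counts. Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list of class `pipeline_result` with elements `expr`, `clinical`,
#'   `dcca`, `top_genes`, `enrichment` (or NULL), `screens` (named list),
#'   `metagene` (or NULL), `survival` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pipeline")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "exonDCCA",
                   version = as.character(utils::packageVersion("exonDCCA")),
                   seed = config$seed,
                   parameters = list(k = config$k, alpha = config$alpha,
                                     endpoints = config$endpoints,
                                     metagene_endpoint =
                                       config$metagene_endpoint),
                   stages = list())
  stage <- function(name, counts) {
    manifest$stages[[name]] <<- counts
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial state written to ", out_dir, ")", call. = FALSE)
    })
  }

  ## stage 1: input
  res <- run_stage("input", function() {
    if (!is.null(config$simulate)) {
      sim <- simulate_dataset(config$simulate)
      write_dataset(sim, file.path(out_dir, "input"))
      list(expr = sim$expr, clinical = sim$clinical, truth = sim$truth)
    } else {
      list(expr = load_expression(config$expression_path,
                                  config$samples_path),
           clinical = load_clinical(config$clinical_path),
           truth = NULL)
    }
  })
  expr <- res$expr
  clinical <- res$clinical
  stage("input", list(n_obs = nrow(expr$values),
                      n_probe_sets = ncol(expr$values),
                      n_patients = nrow(clinical)))

  ## stage 2: probe-set filter
  expr <- run_stage("filter", function() {
    if (is.null(config$annotation_path)) return(expr)
    filter_probe_sets(expr, load_annotation(config$annotation_path))
  })
  stage("filter", list(n_probe_sets = ncol(expr$values),
                       n_genes = length(unique(expr$col_meta$gene_id))))

  ## stage 3: DCCA
  fit <- run_stage("dcca", function() dcca_fit(expr))
  write_results(fit$ranked_genes, file.path(out_dir, "dcca_genes.tsv"))
  stage("dcca", list(n_genes = nrow(fit$ranked_genes),
                     constrained_inertia = fit$constrained_inertia,
                     inertia_fraction = fit$inertia_fraction))

  ## stage 4: top-k dysregulated genes
  k <- min(config$k, nrow(fit$ranked_genes))
  top <- run_stage("top_genes", function() top_dysregulated(fit, k))
  write_results(top, file.path(out_dir, "top_genes.tsv"))
  stage("top_genes", list(k = nrow(top),
                          n_up = sum(top$direction == "up"),
                          n_down = sum(top$direction == "down")))

  ## stage 5: enrichment of the top list
  enrichment <- run_stage("enrich", function() {
    if (is.null(config$gmt_path)) return(NULL)
    universe <- unique(expr$col_meta$gene_id)
    out <- enrich(top$gene_id, read_gmt(config$gmt_path), universe)
    write_results(out, file.path(out_dir, "enrichment.tsv"))
    out
  })
  stage("enrich", list(n_sets = if (is.null(enrichment)) 0L
                       else nrow(enrichment)))

  ## stage 6: per-gene endpoint screening
  screens <- run_stage("screen", function() {
    out <- list()
    for (tp in config$screen_timepoints) {
      g <- gene_level_matrix(expr, tp)
      for (ep in config$endpoints) {
        key <- paste(ep, tp, sep = ".")
        out[[key]] <- screen(g, clinical, ep, alpha = config$alpha,
                             timepoint = tp)
      }
    }
    all_tab <- do.call(rbind, lapply(out, function(s) s$table))
    write_results(all_tab, file.path(out_dir, "screen.tsv"))
    jsonlite::write_json(
      lapply(out, function(s) as.list(s$selected)),
      file.path(out_dir, "selected_genes.json"),
      auto_unbox = FALSE, digits = NA, pretty = TRUE)
    out
  })
  stage("screen", list(n_fits = sum(vapply(screens, function(s)
                         nrow(s$table), integer(1))),
                       n_selected = sum(vapply(screens, function(s)
                         length(s$selected), integer(1)))))

  ## stage 7: metagene and survival evaluation
  mg_key <- paste(config$metagene_endpoint, config$metagene_timepoint,
                  sep = ".")
  selected <- if (mg_key %in% names(screens)) screens[[mg_key]]$selected
              else character(0)
  metagene <- survcmp <- NULL
  if (length(selected) >= 1) {
    run_stage("metagene", function() {
      g <- gene_level_matrix(expr, config$metagene_timepoint)
      metagene <<- fit_metagene(g[, selected, drop = FALSE])
      survcmp <<- evaluate_survival(metagene, clinical,
                                    config$metagene_endpoint,
                                    adjust_mutation = TRUE)
      write_results(
        data.frame(patient_id = names(metagene$scores),
                   score = unname(metagene$scores),
                   risk_class = unname(survcmp$risk_class)),
        file.path(out_dir, "metagene_scores.tsv"))
      invisible(NULL)
    })
  }
  stage("metagene", list(
    n_genes = length(selected),
    hazard_ratio = if (is.null(survcmp)) NA else survcmp$hazard_ratio,
    logrank_p = if (is.null(survcmp)) NA else survcmp$logrank_p))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(expr = expr, clinical = clinical, dcca = fit,
                 top_genes = top, enrichment = enrichment,
                 screens = screens, metagene = metagene,
                 survival = survcmp, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(names(x$manifest$stages), collapse = ", "), "\n")
  invisible(x)
}
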