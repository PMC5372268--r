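#' Configuration for the paired exon-array simulator
#'
#' Builds and validates the parameter set of [simulate_dataset()]. Defaults
#' emulate a blood exon-array substudy of a targeted-therapy trial: 43
#' patients profiled at baseline and 24h after treatment initiation,
#' small-magnitude but consistent 24h expression shifts planted in a subset
#' of genes, within-gene exonic probe-set structure, roughly 12% prevalence
#' of an activating mutation, and censored time-to-event endpoints driven by
#' a planted proportional-hazards signal.
#'
#' @param n_patients number of patients (each yields two observations).
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)`; the number of exonic
#'   probe sets per gene is drawn uniformly from this range. The genome-wide
#'   platform average is about 11 probe sets per gene (range documented as
#'   `c(4, 18)`); desk-scale analyses typically use far smaller ranges.
#' @param n_dysregulated number of genes with a planted 24h shift.
#' @param effect_size_log2 magnitude of the planted 24h shift (log2 scale).
#' @param frac_up fraction of planted shifts that are up-regulations.
#' @param gene_sd between-gene SD of baseline expression (log2 scale).
#' @param patient_sd between-patient SD (log2 scale); within-patient
#'   correlation dominates the design, as in real paired profiles.
#' @param exon_sd between-exon-within-gene SD (log2 scale).
#' @param noise_sd residual SD (log2 scale).
#' @param baseline_mean grand mean intensity (log2 scale, > 0); the default 7
#'   is typical of RMA-normalized arrays and keeps intensities positive.
#' @param n_predictive number of genes whose centered 24h expression drives
#'   the hazard of the time-to-event endpoints.
#' @param log_hazard_per_unit log hazard ratio per unit of centered 24h
#'   expression, applied to each predictive gene.
#' @param censor_rate expected fraction of censored observations under the
#'   null (independent exponential censoring).
#' @param mutation_prev prevalence of the mutation covariate; default 5/43.
#' @param seed integer seed; the full dataset is a deterministic function of
#'   the configuration.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 43L,
                       n_genes = 500L,
                       exons_per_gene = c(4L, 18L),
                       n_dysregulated = 50L,
                       effect_size_log2 = 0.15,
                       frac_up = 0.5,
                       gene_sd = 0.3,
                       patient_sd = 0.5,
                       exon_sd = 0.25,
                       noise_sd = 0.2,
                       baseline_mean = 7,
                       n_predictive = 20L,
                       log_hazard_per_unit = 0.8,
                       censor_rate = 0.3,
                       mutation_prev = 5 / 43,
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_dysregulated = as.integer(n_dysregulated),
              effect_size_log2 = effect_size_log2,
              frac_up = frac_up,
              gene_sd = gene_sd,
              patient_sd = patient_sd,
              exon_sd = exon_sd,
              noise_sd = noise_sd,
              baseline_mean = baseline_mean,
              n_predictive = as.integer(n_predictive),
              log_hazard_per_unit = log_hazard_per_unit,
              censor_rate = censor_rate,
              mutation_prev = mutation_prev,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 2L) stop("invalid configuration: n_patients must be >= 2")
    if (n_genes < 1L) stop("invalid configuration: n_genes must be >= 1")
    if (length(exons_per_gene) != 2L || any(exons_per_gene < 1L) ||
        exons_per_gene[1] > exons_per_gene[2])
      stop("invalid configuration: exons_per_gene must be c(min, max), min >= 1")
    if (n_dysregulated < 0L || n_dysregulated > n_genes)
      stop("invalid configuration: n_dysregulated must be in [0, n_genes]")
    if (n_predictive < 0L || n_predictive > n_genes)
      stop("invalid configuration: n_predictive must be in [0, n_genes]")
    if (frac_up < 0 || frac_up > 1)
      stop("invalid configuration: frac_up must be in [0, 1]")
    if (any(c(gene_sd, patient_sd, exon_sd, noise_sd) < 0))
      stop("invalid configuration: SDs must be >= 0")
    if (baseline_mean <= 0)
      stop("invalid configuration: baseline_mean must be > 0")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("invalid configuration: censor_rate must be in [0, 1)")
    if (mutation_prev < 0 || mutation_prev > 1)
      stop("invalid configuration: mutation_prev must be in [0, 1]")
  })
  invisible(cfg)
}

# Deterministic per-block seeds so that, e.g., adding patients never perturbs
# the gene-level draws. Kept below 2^31 - 1 (R integers are 32-bit).
block_seed <- function(seed, block) {
  (as.double(seed) * 2654435761 + block * 40503) %% (2^31 - 1)
}

#' Simulate a paired exon-array dataset with linked clinical endpoints
#'
#' Generates exon-level intensities for a fully matched baseline/24h design
#' together with a clinical table and the ground truth of every planted
#' effect. The intensity of exon \eqn{e} of gene \eqn{g} for patient \eqn{p}
#' at time \eqn{t} is
#' \deqn{\mu + a_p + b_g + c_e + 1\{t = 24h\}\,\delta_g + \epsilon,}
#' clipped at 0.01, where \eqn{\delta_g = \pm} `effect_size_log2` for planted
#' genes and 0 otherwise. Time-to-event endpoints follow an exponential
#' proportional-hazards model whose linear predictor sums
#' `log_hazard_per_unit` times the centered 24h expression of each predictive
#' gene; censoring is independent exponential, calibrated to the requested
#' rate. The binary endpoint (disease stabilization, `ds12`) is Bernoulli
#' with logit decreasing in the same predictor; the continuous endpoint
#' (tumor shrinkage, `ts12`) is Gaussian around a decreasing linear function
#' of it. Mutation status is Bernoulli(`mutation_prev`).
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_dataset` with elements
#'   \describe{
#'     \item{expr}{an [exon_matrix()] (rows `patientXX_baseline`,
#'       `patientXX_h24`).}
#'     \item{clinical}{data.frame with `patient_id`, `egfr_mut`, `ds12`,
#'       `ts12`, `ttp_be`, `ttp_be_event`, `ttp_ct`, `ttp_ct_event`, `os`,
#'       `os_event`.}
#'     \item{truth}{list with `dysregulated_genes` (named sign vector, +1 up /
#'       -1 down), `predictive_genes` (named log-hazard coefficients),
#'       `true_patient_effects`, and `linear_predictor`.}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(n_patients = 6, n_genes = 20,
#'                                    exons_per_gene = c(2, 3),
#'                                    n_dysregulated = 4, n_predictive = 2,
#'                                    seed = 1))
#' sim$expr
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)

  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  patients <- sprintf("patient%03d", seq_len(config$n_patients))

  ## gene block: baseline gene effects, planted 24h shifts, predictive set
  set.seed(block_seed(config$seed, 1))
  gene_eff <- stats::rnorm(config$n_genes, 0, config$gene_sd)
  delta <- numeric(config$n_genes)
  dys_idx <- integer(0)
  if (config$n_dysregulated > 0) {
    dys_idx <- sort(sample.int(config$n_genes, config$n_dysregulated))
    n_up <- round(config$frac_up * config$n_dysregulated)
    sign_vec <- rep(-1, config$n_dysregulated)
    if (n_up > 0) sign_vec[seq_len(n_up)] <- 1
    sign_vec <- sign_vec[sample.int(config$n_dysregulated)]
    delta[dys_idx] <- sign_vec * config$effect_size_log2
  }
  pred_idx <- integer(0)
  if (config$n_predictive > 0)
    pred_idx <- sort(sample.int(config$n_genes, config$n_predictive))

  ## exon block: per-gene exon counts and exon effects
  set.seed(block_seed(config$seed, 2))
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    config$n_genes, replace = TRUE)
  gene_of_col <- rep(seq_len(config$n_genes), n_exons)
  m <- length(gene_of_col)
  exon_eff <- stats::rnorm(m, 0, config$exon_sd)

  ## patient block: patient effects and mutation status
  set.seed(block_seed(config$seed, 3))
  pat_eff <- stats::rnorm(config$n_patients, 0, config$patient_sd)
  egfr_mut <- stats::rbinom(config$n_patients, 1, config$mutation_prev)

  ## expression noise block
  set.seed(block_seed(config$seed, 4))
  n_obs <- 2L * config$n_patients
  noise <- matrix(stats::rnorm(n_obs * m, 0, config$noise_sd), n_obs, m)

  ## assemble: rows ordered patient-major (baseline, h24)
  time <- rep(c("baseline", "h24"), config$n_patients)
  patient_of_row <- rep(seq_len(config$n_patients), each = 2L)
  base <- config$baseline_mean + gene_eff[gene_of_col] + exon_eff
  values <- matrix(base, n_obs, m, byrow = TRUE) +
    pat_eff[patient_of_row] +
    outer(as.numeric(time == "h24"), delta[gene_of_col]) +
    noise
  values <- pmax(values, 0.01)

  row_meta <- data.frame(
    sample_id = paste0(patients[patient_of_row], "_", time),
    patient_id = patients[patient_of_row],
    time = time, stringsAsFactors = FALSE)
  col_meta <- data.frame(
    probe_set_id = paste0(genes[gene_of_col], "_ex",
                          sequence(n_exons)),
    gene_id = genes[gene_of_col], stringsAsFactors = FALSE)
  expr <- exon_matrix(values, row_meta, col_meta)

  ## linear predictor from centered 24h gene-level expression
  eta <- numeric(config$n_patients)
  if (length(pred_idx) > 0) {
    g24 <- gene_level_matrix(expr, "h24")[, genes[pred_idx], drop = FALSE]
    g24 <- scale(g24, center = TRUE, scale = FALSE)
    eta <- as.numeric(g24 %*% rep(config$log_hazard_per_unit,
                                  length(pred_idx)))
  }

  ## endpoint block: exponential PH survival, independent censoring,
  ## binary/continuous endpoints from the same predictor
  set.seed(block_seed(config$seed, 5))
  surv_endpoint <- function(base_median) {
    lam0 <- log(2) / base_median
    t_ev <- stats::rexp(config$n_patients, lam0 * exp(eta))
    if (config$censor_rate > 0) {
      lam_c <- lam0 * config$censor_rate / (1 - config$censor_rate)
      t_cn <- stats::rexp(config$n_patients, lam_c)
      list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn))
    } else {
      list(time = t_ev, event = rep(1L, config$n_patients))
    }
  }
  ttp_be <- surv_endpoint(4.0)   # months; typical progression under therapy
  ttp_ct <- surv_endpoint(2.6)
  os <- surv_endpoint(11.1)
  ds12 <- stats::rbinom(config$n_patients, 1, stats::plogis(0.14 - eta))
  ts12 <- 15.8 - 5 * eta + stats::rnorm(config$n_patients, 0, 15)

  clinical <- data.frame(
    patient_id = patients,
    egfr_mut = egfr_mut,
    ds12 = ds12,
    ts12 = ts12,
    ttp_be = ttp_be$time, ttp_be_event = ttp_be$event,
    ttp_ct = ttp_ct$time, ttp_ct_event = ttp_ct$event,
    os = os$time, os_event = os$event,
    stringsAsFactors = FALSE)

  truth <- list(
    dysregulated_genes = stats::setNames(sign(delta[dys_idx]),
                                         genes[dys_idx]),
    predictive_genes = stats::setNames(
      rep(config$log_hazard_per_unit, length(pred_idx)), genes[pred_idx]),
    true_patient_effects = stats::setNames(pat_eff, patients),
    linear_predictor = stats::setNames(eta, patients))

  structure(list(expr = expr, clinical = clinical, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", x$config$n_patients, "patients,",
      x$config$n_genes, "genes,", ncol(x$expr$values), "probe sets;",
      length(x$truth$dysregulated_genes), "dysregulated,",
      length(x$truth$predictive_genes), "predictive\n")
  invisible(x)
}
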