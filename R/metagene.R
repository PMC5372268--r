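#' Combine candidate genes into a metagene score
#'
#' Builds a single per-patient score from a candidate gene list by unscaled
#' (covariance-based) principal component analysis: the expression matrix is
#' column-centered without variance scaling, the first principal axis gives
#' the gene loadings (unit Euclidean norm), and each patient's score is the
#' projection of their centered profile on that axis. The sample median of
#' the scores defines a binary split into two near-equal classes; scores
#' equal to the median go to the `low` class. Class labels are provisional
#' until anchored to outcome by [evaluate_survival()] (the axis sign is
#' arbitrary, so "high risk" is defined by survival, not by sign).
#'
#' @param expr patients x genes numeric matrix restricted to the candidate
#'   genes; rows named by patient id; no missing values.
#' @return list of class `metagene_model`: `gene_ids`, `centering` (per-gene
#'   means), `loadings` (unit norm), `scores` (zero mean), `threshold`
#'   (median score), `risk_class` (`"low"`/`"high"`, named by patient),
#'   `variance_explained`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("p", 1:10), paste0("g", 1:4)))
#' fit_metagene(m)$variance_explained
#' @export
fit_metagene <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("fit_metagene requires at least 2 patients")
  if (anyNA(expr)) stop("fit_metagene does not accept missing values")
  centering <- colMeans(expr)
  xc <- sweep(expr, 2, centering)
  sv <- svd(xc)
  if (sv$d[1] <= 1e-12 * max(1, max(abs(expr))))
    stop("undefined axis: expression matrix is constant across patients")
  loadings <- sv$v[, 1]
  names(loadings) <- colnames(expr)
  scores <- as.numeric(xc %*% loadings)
  names(scores) <- rownames(expr)
  threshold <- stats::median(scores)
  risk <- ifelse(scores > threshold, "high", "low")
  structure(list(gene_ids = colnames(expr),
                 centering = centering,
                 loadings = loadings,
                 scores = scores,
                 threshold = threshold,
                 risk_class = risk,
                 variance_explained = sv$d[1]^2 / sum(sv$d^2)),
            class = "metagene_model")
}

#' @export
print.metagene_model <- function(x, ...) {
  cat("metagene_model:", length(x$gene_ids), "genes,",
      length(x$scores), "patients; first axis explains",
      format(100 * x$variance_explained, digits = 3), "% of variance\n")
  invisible(x)
}

km_median_table <- function(fit) {
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- rbind(tab)
  tab
}

#' Survival separation of metagene risk classes
#'
#' Evaluates a metagene median split against a time-to-event endpoint:
#' Kaplan-Meier curves per class with medians and log-log 95% confidence
#' intervals, the two-sample log-rank test, and a Cox proportional-hazards
#' fit of the binary class (optionally adjusted for mutation status) giving
#' the hazard ratio with Wald 95% CI. Risk labels are anchored to outcome:
#' the class with the shorter Kaplan-Meier median event time is called
#' `high` (ties, or both medians unreached, keep the provisional labels).
#' A class with zero events makes the hazard ratio non-estimable (reported
#' as `NA`); the log-rank test is still computed.
#'
#' @param model a [fit_metagene()] model.
#' @param clinical clinical table (`patient_id`, `egfr_mut`, endpoint and
#'   event columns).
#' @param endpoint a time-to-event endpoint: `ttp_be`, `ttp_ct` or `os`.
#' @param adjust_mutation also report a mutation-adjusted hazard ratio.
#' @return list of class `survival_comparison`: `hazard_ratio`, `ci_low`,
#'   `ci_high`, `cox_p`, `logrank_p`, `medians` (per-class data.frame with
#'   95% CI, `NA` = not reached), `n_per_group`, `events_per_group`,
#'   `risk_class` (anchored labels), `km_fit`, and when adjusted
#'   `adjusted_hr`, `adjusted_ci_low`, `adjusted_ci_high`, `adjusted_p`.
#' @export
evaluate_survival <- function(model, clinical, endpoint = "ttp_be",
                              adjust_mutation = FALSE) {
  stopifnot(inherits(model, "metagene_model"))
  if (!endpoint %in% c("ttp_be", "ttp_ct", "os"))
    stop("endpoint must be a time-to-event field (ttp_be, ttp_ct, os)")
  evcol <- paste0(endpoint, "_event")
  idx <- match(names(model$scores), clinical$patient_id)
  if (anyNA(idx)) stop("patients missing from clinical table")
  dat <- data.frame(time = clinical[[endpoint]][idx],
                    event = clinical[[evcol]][idx],
                    egfr_mut = clinical$egfr_mut[idx],
                    class = model$risk_class)

  ## anchor labels: shorter KM median event time = high risk
  fit0 <- survival::survfit(survival::Surv(time, event) ~ class, data = dat,
                            conf.type = "log-log")
  tab0 <- km_median_table(fit0)
  med0 <- tab0[, "median"]
  grp0 <- sub("^class=", "", rownames(tab0))
  if (all(!is.na(med0)) && length(unique(med0)) == 2) {
    if (grp0[which.min(med0)] != "high")
      dat$class <- ifelse(dat$class == "high", "low", "high")
  } else if (sum(is.na(med0)) == 1) {
    # only one median reached: that class progresses faster
    if (grp0[!is.na(med0)] != "high")
      dat$class <- ifelse(dat$class == "high", "low", "high")
  }
  dat$class <- factor(dat$class, levels = c("low", "high"))

  km <- survival::survfit(survival::Surv(time, event) ~ class, data = dat,
                          conf.type = "log-log")
  tab <- km_median_table(km)
  medians <- data.frame(class = sub("^class=", "", rownames(tab)),
                        n = tab[, "records"],
                        events = tab[, "events"],
                        median = tab[, "median"],
                        ci_low = tab[, "0.95LCL"],
                        ci_high = tab[, "0.95UCL"],
                        stringsAsFactors = FALSE)
  rownames(medians) <- NULL

  lr <- survival::survdiff(survival::Surv(time, event) ~ class, data = dat)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)

  events_per_group <- tapply(dat$event, dat$class, sum)
  hr <- ci_low <- ci_high <- cox_p <- NA_real_
  if (all(events_per_group > 0)) {
    cx <- survival::coxph(survival::Surv(time, event) ~ class, data = dat,
                          ties = "efron")
    sm <- summary(cx)
    hr <- unname(sm$coefficients[1, "exp(coef)"])
    ci_low <- unname(sm$conf.int[1, "lower .95"])
    ci_high <- unname(sm$conf.int[1, "upper .95"])
    cox_p <- unname(sm$coefficients[1, "Pr(>|z|)"])
  }

  out <- list(hazard_ratio = hr, ci_low = ci_low, ci_high = ci_high,
              cox_p = cox_p, logrank_p = logrank_p,
              medians = medians,
              n_per_group = table(dat$class),
              events_per_group = events_per_group,
              risk_class = stats::setNames(as.character(dat$class),
                                           names(model$scores)),
              endpoint = endpoint, km_fit = km)
  if (adjust_mutation) {
    out$adjusted_hr <- out$adjusted_ci_low <- out$adjusted_ci_high <-
      out$adjusted_p <- NA_real_
    if (all(events_per_group > 0) && stats::sd(dat$egfr_mut) > 0) {
      cxa <- survival::coxph(
        survival::Surv(time, event) ~ class + egfr_mut, data = dat,
        ties = "efron")
      sma <- summary(cxa)
      out$adjusted_hr <- unname(sma$coefficients["classhigh", "exp(coef)"])
      out$adjusted_ci_low <- unname(sma$conf.int["classhigh", "lower .95"])
      out$adjusted_ci_high <- unname(sma$conf.int["classhigh", "upper .95"])
      out$adjusted_p <- unname(sma$coefficients["classhigh", "Pr(>|z|)"])
    } else if (all(events_per_group > 0)) {
      # constant mutation status: adjusted fit equals the unadjusted one
      out$adjusted_hr <- hr
      out$adjusted_ci_low <- ci_low
      out$adjusted_ci_high <- ci_high
      out$adjusted_p <- cox_p
    }
  }
  structure(out, class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("survival_comparison (", x$endpoint, "): HR ",
      format(x$hazard_ratio, digits = 3), " [95% CI ",
      format(x$ci_low, digits = 3), "-", format(x$ci_high, digits = 3),
      "], log-rank p = ", format(x$logrank_p, digits = 3), "\n", sep = "")
  print(x$medians)
  invisible(x)
}
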