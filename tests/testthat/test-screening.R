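small_sim <- function(..., n_dysregulated = 2, n_predictive = 2)
  simulate_dataset(sim_config(..., n_dysregulated = n_dysregulated,
                              n_predictive = n_predictive))

test_that("gene-level summarization averages exons and forms deltas", {
  values <- rbind(c(4, 6, 10), c(8, 10, 20))   # gene A: 2 exons, gene B: 1
  x <- exon_matrix(values,
                   data.frame(sample_id = c("p1_baseline", "p1_h24"),
                              patient_id = "p1",
                              time = c("baseline", "h24")),
                   data.frame(probe_set_id = c("A_e1", "A_e2", "B_e1"),
                              gene_id = c("A", "A", "B")))
  gb <- gene_level_matrix(x, "baseline")
  expect_equal(gb["p1", "A"], 5)               # mean of 4 and 6
  expect_equal(gb["p1", "B"], 10)              # single exon: identity
  gd <- gene_level_matrix(x, "delta")
  expect_equal(gd["p1", "A"], 9 - 5)
  # identical time points give an all-zero delta
  x0 <- x
  x0$values[2, ] <- x0$values[1, ]
  expect_true(all(gene_level_matrix(x0, "delta") == 0))
})

test_that("endpoints map to their model families and fits are reported", {
  sim <- small_sim(n_patients = 30, n_genes = 12, exons_per_gene = c(1, 2),
                   n_predictive = 3, seed = 17)
  g <- gene_level_matrix(sim$expr, "h24")
  for (ep in c("ds12", "ts12", "ttp_be")) {
    res <- screen(g, sim$clinical, ep, timepoint = "h24")
    expect_s3_class(res, "screen_result")
    expect_equal(nrow(res$table), 12)
    expect_equal(unique(res$table$model),
                 switch(ep, ds12 = "logistic", ts12 = "linear", "cox"))
    expect_true(all(res$table$p_value > 0 & res$table$p_value <= 1))
  }
  expect_error(screen(g, sim$clinical, "nope"), "unknown endpoint")
})

test_that("zero-variance genes are flagged with p = 1, never selected", {
  sim <- small_sim(n_patients = 20, n_genes = 5, exons_per_gene = c(1, 1),
                   seed = 19)
  g <- gene_level_matrix(sim$expr, "h24")
  g[, 1] <- 3.14
  res <- screen(g, sim$clinical, "ttp_be")
  expect_equal(res$table$flag[1], "zero_variance")
  expect_equal(res$table$p_value[1], 1)
  expect_false(res$table$gene_id[1] %in% res$selected)
})

test_that("adjustment is a no-op when mutation status is constant", {
  sim <- small_sim(n_patients = 25, n_genes = 8, exons_per_gene = c(1, 2),
                   mutation_prev = 0, seed = 23)
  g <- gene_level_matrix(sim$expr, "baseline")
  rad <- screen(g, sim$clinical, "ttp_be", adjust_mutation = TRUE)
  run <- screen(g, sim$clinical, "ttp_be", adjust_mutation = FALSE)
  expect_equal(rad$table$coefficient, run$table$coefficient)
  expect_equal(rad$table$p_value, run$table$p_value)
})

test_that("p-values are invariant to affine gene rescaling", {
  sim <- small_sim(n_patients = 30, n_genes = 4, exons_per_gene = c(1, 2),
                   seed = 29)
  g <- gene_level_matrix(sim$expr, "h24")
  for (ep in c("ds12", "ts12", "os")) {
    r1 <- screen(g, sim$clinical, ep)
    g2 <- g
    g2[, 2] <- 2.5 * g2[, 2] + 7
    r2 <- screen(g2, sim$clinical, ep)
    expect_equal(r2$table$p_value[2], r1$table$p_value[2],
                 tolerance = 1e-6)
    expect_equal(r2$table$coefficient[2], r1$table$coefficient[2] / 2.5,
                 tolerance = 1e-6)
  }
})

test_that("planted predictive genes are enriched among Cox selections", {
  # few predictive genes and no shared patient effect keep the per-gene
  # marginal signal strong relative to the proportional-hazards frailty
  # induced by the other planted genes
  sim <- small_sim(n_patients = 80, n_genes = 100,
                   exons_per_gene = c(1, 1), n_dysregulated = 0,
                   n_predictive = 2, log_hazard_per_unit = 3,
                   patient_sd = 0, noise_sd = 0.3, censor_rate = 0.2,
                   seed = 31)
  g <- gene_level_matrix(sim$expr, "h24")
  res <- screen(g, sim$clinical, "ttp_be", alpha = 0.01)
  planted <- names(sim$truth$predictive_genes)
  expect_gt(mean(planted %in% res$selected), 0.5)
  # selections should be dominated by planted genes
  if (length(res$selected) > 0)
    expect_gt(mean(res$selected %in% planted), 0.5)
})

test_that("Cox p-values under permuted survival times are uniform", {
  # patient_sd = 0 keeps genes independent so that the empirical p-value
  # distribution over genes can be compared with the uniform
  sim <- small_sim(n_patients = 40, n_genes = 500,
                   exons_per_gene = c(1, 1), n_dysregulated = 0,
                   n_predictive = 0, patient_sd = 0, seed = 37)
  g <- gene_level_matrix(sim$expr, "h24")
  cl <- sim$clinical
  set.seed(37)
  perm <- sample(nrow(cl))
  cl$ttp_be <- cl$ttp_be[perm]
  cl$ttp_be_event <- cl$ttp_be_event[perm]
  res <- screen(g, cl, "ttp_be")
  ks <- suppressWarnings(stats::ks.test(res$table$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("change-magnitude screening restricts to the requested genes", {
  sim <- small_sim(n_patients = 30, n_genes = 20, exons_per_gene = c(1, 2),
                   seed = 41)
  d <- gene_level_matrix(sim$expr, "delta")
  res <- screen_change_magnitude(d, sim$clinical, "ttp_be",
                                 genes = colnames(d)[1:7])
  expect_equal(nrow(res$table), 7)
  expect_equal(unique(res$table$timepoint), "delta")
  expect_error(
    screen_change_magnitude(d, sim$clinical, "ttp_be", genes = "absent"),
    "absent")
  # an all-zero delta matrix yields no selections
  res0 <- screen_change_magnitude(d * 0, sim$clinical, "ttp_be")
  expect_length(res0$selected, 0)
  expect_true(all(res0$table$flag == "zero_variance"))
})

test_that("mixed-effects screening runs on patient-level endpoints", {
  skip_if_not_installed("lme4")
  sim <- small_sim(n_patients = 25, n_genes = 6, exons_per_gene = c(1, 2),
                   seed = 43)
  res <- screen_mixed(sim$expr, sim$clinical, "ts12")
  expect_equal(unique(res$table$model), "mixed")
  expect_equal(nrow(res$table), 6)
  expect_true(all(res$table$p_value > 0 & res$table$p_value <= 1))
  expect_error(screen_mixed(sim$expr, sim$clinical, "ttp_be"), "ds12")
})
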