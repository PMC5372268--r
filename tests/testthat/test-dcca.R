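test_that("plain correspondence analysis matches chi-square references", {
  # independence (rank-1) table: no inertia at all
  rank1 <- outer(c(1, 2, 3), c(4, 1, 2, 3))
  ca <- correspondence_analysis(rank1)
  expect_lt(ca$total_inertia, 1e-12)
  expect_lt(max(ca$singular_values), 1e-12)

  # perfect association of a 2x2 table: inertia = chi^2 / n = 1
  ca2 <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(ca2$total_inertia, 1.0, tolerance = 1e-12)

  # random tables: inertia == chi-square statistic / grand total
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(rpois(54, 8) + 1, 6, 9)
    ca <- correspondence_analysis(x)
    chi <- suppressWarnings(chisq.test(x))$statistic
    expect_equal(ca$total_inertia, unname(chi) / sum(x), tolerance = 1e-10)
  }
})

test_that("correspondence analysis agrees with an independent ordination
           implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  x <- matrix(rgamma(60, 4), 6, 10)
  ca <- correspondence_analysis(x, n_axes = 5)
  ref <- vegan::cca(x)
  expect_equal(ca$singular_values[1:5]^2,
               unname(ref$CA$eig[1:5]), tolerance = 1e-8)
  expect_equal(ca$total_inertia, unname(ref$tot.chi), tolerance = 1e-8)
})

test_that("correspondence analysis masses and centering invariants hold", {
  x <- random_exon_matrix(5, 8, seed = 21)
  ca <- correspondence_analysis(x, n_axes = 3)
  expect_equal(sum(ca$row_masses), 1)
  expect_equal(sum(ca$col_masses), 1)
  # mass-weighted mean of standard coordinates is 0 on every axis
  for (a in 1:3) {
    std_row <- ca$row_coords[, a] / max(ca$singular_values[a], 1e-300)
    expect_equal(sum(ca$row_masses * std_row), 0, tolerance = 1e-8)
  }
  expect_true(all(diff(ca$singular_values) <= 1e-12))
})

test_that("degenerate CA inputs are rejected with informative errors", {
  expect_error(correspondence_analysis(matrix(c(1, -1, 2, 3), 2, 2)),
               "negative")
  expect_error(correspondence_analysis(matrix(c(0, 0, 2, 3), 2, 2,
                                              byrow = TRUE)),
               "all-zero row")
  expect_error(correspondence_analysis(matrix(c(0, 0, 1, 3), 2, 2)),
               "all-zero column")
})

test_that("row constraint designs are valid indicator systems", {
  rm <- data.frame(sample_id = paste0("s", 1:6),
                   patient_id = rep(c("a", "b", "c"), each = 2),
                   time = rep(c("baseline", "h24"), 3))
  cons <- build_row_constraints(rm)
  expect_equal(dim(cons$patient), c(6, 3))
  expect_equal(dim(cons$time), c(6, 2))
  expect_true(all(rowSums(cons$patient) == 1))
  expect_true(all(rowSums(cons$time) == 1))
  expect_equal(qr(cons$time)$rank, 2)
  # weighted centering leaves a single time contrast
  w <- rep(1 / 6, 6)
  centered <- cons$time - outer(rep(1, 6), colSums(cons$time * w))
  expect_equal(qr(centered, tol = 1e-10)$rank, 1)
  # unpaired patient is rejected
  expect_error(build_row_constraints(rm[-1, ]), "unpaired")
})

test_that("dcca constrained inertia vanishes when 24h copies baseline", {
  x <- random_exon_matrix(6, 10, seed = 31)
  b <- x$row_meta$time == "baseline"
  x$values[!b, ] <- x$values[b, ][match(x$row_meta$patient_id[!b],
                                        x$row_meta$patient_id[b]), ]
  fit <- dcca_fit(x)
  expect_equal(fit$constrained_inertia, 0, tolerance = 1e-10)
  expect_true(all(abs(fit$gene_scores) <= 1e-10))
})

test_that("optimized dcca equals the dense-projector brute force", {
  set.seed(77)
  for (i in 1:12) {
    x <- random_exon_matrix(sample(3:12, 1), sample(2:30, 1),
                            max_exons = 5, seed = 100 + i)
    fit <- dcca_fit(x)
    ref <- dcca_oracle(x)
    expect_lt(max(abs(fit$gene_scores[names(ref$gene_scores)] -
                        ref$gene_scores)), 1e-10)
    expect_equal(fit$constrained_inertia, ref$constrained_inertia,
                 tolerance = 1e-10)
    # rank bound: the doubly constrained analysis has at most one axis
    expect_lt(ref$singular_values[2], 1e-10)
    # within-gene constancy of exon scores
    expect_lt(ref$exon_spread, 1e-10)
    spread <- tapply(fit$exon_scores, x$col_meta$gene_id,
                     function(z) diff(range(z)))
    expect_lt(max(spread), 1e-12)
  }
})

test_that("projection chain only ever removes inertia", {
  x <- random_exon_matrix(8, 12, seed = 41)
  fit <- dcca_fit(x)
  expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-12)
  expect_gte(fit$inertia_fraction, 0)
  expect_lte(fit$inertia_fraction, 1 + 1e-12)
})

test_that("a strongly planted gene dominates the ranking with correct sign", {
  sim <- simulate_dataset(sim_config(
    n_patients = 8, n_genes = 20, exons_per_gene = c(2, 4),
    n_dysregulated = 1, frac_up = 1, effect_size_log2 = 2,
    noise_sd = 0.05, seed = 13))
  fit <- dcca_fit(sim$expr)
  planted <- names(sim$truth$dysregulated_genes)
  expect_equal(fit$ranked_genes$gene_id[1], planted)
  expect_gt(fit$gene_scores[planted], 0)
  expect_gte(fit$time_class_scores[["h24"]], 0)   # sign anchor
})

test_that("dcca is invariant to positive rescaling of the whole table", {
  x <- random_exon_matrix(5, 8, seed = 51)
  f1 <- dcca_fit(x)
  x2 <- x
  x2$values <- x$values * 7.3
  f2 <- dcca_fit(x2)
  expect_equal(f1$gene_scores, f2$gene_scores, tolerance = 1e-10)
  expect_equal(f1$inertia_fraction, f2$inertia_fraction, tolerance = 1e-10)
})

test_that("top_dysregulated honors k, excludes zero scores, validates input", {
  sim <- simulate_dataset(sim_config(
    n_patients = 6, n_genes = 15, exons_per_gene = c(1, 2),
    n_dysregulated = 3, n_predictive = 2, seed = 6))
  fit <- dcca_fit(sim$expr)
  top5 <- top_dysregulated(fit, 5)
  expect_equal(nrow(top5), 5)
  expect_true(all(diff(abs(top5$score)) <= 1e-15))
  expect_true(all(top5$direction %in% c("up", "down")))
  expect_error(top_dysregulated(fit, 0), "positive")
  expect_error(top_dysregulated(fit, 999), "exceeds")

  # a null fit (24h == baseline) has only zero scores: warn and return none
  x <- sim$expr
  b <- x$row_meta$time == "baseline"
  x$values[!b, ] <- x$values[b, ][match(x$row_meta$patient_id[!b],
                                        x$row_meta$patient_id[b]), ]
  fit0 <- dcca_fit(x)
  expect_warning(out <- top_dysregulated(fit0, 3), "nonzero")
  expect_equal(nrow(out), 0)
})

test_that("contribution ranking is exposed and differs in statistic only", {
  x <- random_exon_matrix(6, 10, seed = 61)
  f1 <- dcca_fit(x, ranking = "coordinate")
  f2 <- dcca_fit(x, ranking = "contribution")
  expect_equal(f1$gene_scores, f2$gene_scores)
  expect_setequal(f1$ranked_genes$gene_id, f2$ranked_genes$gene_id)
})

test_that("unpaired designs are rejected", {
  x <- random_exon_matrix(4, 6, seed = 71)
  rm2 <- x$row_meta
  rm2$time[2] <- "baseline"   # patient 1 now has two baselines
  expect_error(exon_matrix(x$values, rm2, x$col_meta), "unpaired")
})
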