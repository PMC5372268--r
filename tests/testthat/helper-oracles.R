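# Independent brute-force references used across the suite. These
# deliberately materialize dense weighted projector matrices and explicit
# combinatorial sums -- the slow-but-transparent constructions the package
# itself avoids -- so that the optimized implementations are checked against
# a different computational route.

# Dense-projector dually constrained CA: builds the full standardized
# residual matrix, the r-weighted projectors onto (and off) the row
# constraint spans and the c-weighted projector onto the gene span as dense
# matrices, multiplies them explicitly, and reads coordinates off the SVD.
dcca_oracle <- function(x) {
  v <- x$values
  n <- sum(v)
  p <- v / n
  r <- rowSums(p)
  cc <- colSums(p)
  S <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  wproj <- function(A, w) {
    Wh <- diag(sqrt(w))
    M <- Wh %*% A
    M %*% solve(t(A) %*% diag(w) %*% A) %*% t(M)
  }
  A_pat <- stats::model.matrix(~ factor(x$row_meta$patient_id) - 1)
  A_tim <- stats::model.matrix(
    ~ factor(x$row_meta$time, levels = c("baseline", "h24")) - 1)
  B_gene <- stats::model.matrix(~ factor(x$col_meta$gene_id) - 1)
  Hp <- wproj(A_pat, r)
  Ht <- wproj(A_tim, r)
  Hg <- wproj(B_gene, cc)
  S3 <- Ht %*% (diag(length(r)) - Hp) %*% S %*% Hg
  sv <- svd(S3)
  d1 <- sv$d[1]
  v1 <- sv$v[, 1]
  rowc <- d1 * sv$u[, 1] / sqrt(r)
  h24 <- which(x$row_meta$time == "h24")[1]
  if (rowc[h24] < 0) v1 <- -v1
  colc <- d1 * v1 / sqrt(cc)
  gs <- tapply(colc, x$col_meta$gene_id, function(z) z[1])
  list(gene_scores = gs[sort(names(gs))],
       constrained_inertia = sum(sv$d^2),
       singular_values = sv$d,
       exon_spread = max(tapply(colc, x$col_meta$gene_id,
                                function(z) diff(range(z)))))
}

# Upper-tail hypergeometric probability by the explicit combinatorial sum
# P(X >= k) = sum_{i>=k} C(K,i) C(N-K,n-i) / C(N,n).
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- seq(k, min(K, n))
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sample log-rank chi-square statistic computed from first principles
# (observed minus expected events at each distinct event time, with the
# standard hypergeometric variance).
logrank_oracle_p <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1)
    n2 <- sum(at_risk & group == 2)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    nn <- n1 + n2
    if (nn < 2 || d == 0) next
    O <- O + d1
    E <- E + d * n1 / nn
    V <- V + d * (n1 / nn) * (n2 / nn) * (nn - d) / (nn - 1)
  }
  if (V == 0) return(1)
  stats::pchisq((O - E)^2 / V, df = 1, lower.tail = FALSE)
}

# Small random nonnegative exon matrix (no planted structure) for
# property-style loops.
random_exon_matrix <- function(n_patients, n_genes, max_exons = 5,
                               seed = 1) {
  set.seed(seed)
  n_ex <- sample(seq_len(max_exons), n_genes, replace = TRUE)
  gene <- rep(sprintf("g%03d", seq_len(n_genes)), n_ex)
  m <- length(gene)
  time <- rep(c("baseline", "h24"), n_patients)
  pid <- rep(sprintf("p%02d", seq_len(n_patients)), each = 2)
  values <- matrix(stats::rgamma(2 * n_patients * m, shape = 5, rate = 1),
                   2 * n_patients, m)
  exon_matrix(values,
              data.frame(sample_id = paste0(pid, "_", time),
                         patient_id = pid, time = time),
              data.frame(probe_set_id = paste0(gene, "_e",
                                               sequence(n_ex)),
                         gene_id = gene))
}
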