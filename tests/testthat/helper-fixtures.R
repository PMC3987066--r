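# Build a tidy expression table from per-sample two-column (R1, R2) matrices.
make_expr_table <- function(..., gene_ids = NULL) {
  samples <- list(...)
  n <- nrow(as.matrix(samples[[1]]))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n))
  purrr::imap_dfr(samples, function(m, s) {
    m <- as.matrix(m)
    tibble::tibble(
      gene_id = rep(gene_ids, 2),
      sample = s,
      replicate = rep(c("R1", "R2"), each = n),
      fpkm = c(m[, 1], m[, 2])
    )
  })
}

# Random small expression table: a few genes near/below the floor, the rest
# spread over a wide FPKM range.
random_expr_table <- function(n_genes, sample_labels, seed) {
  set.seed(seed)
  args <- lapply(sample_labels, function(s) {
    matrix(round(runif(2 * n_genes, 0, 30), 3), ncol = 2)
  })
  names(args) <- sample_labels
  do.call(make_expr_table, args)
}

# Independent brute-force re-implementation of the variability caller:
# naive loops, naive sort. Used only as an oracle.
brute_variability <- function(table, config) {
  samples <- unique(table$sample)
  divergence <- list()
  for (s in samples) {
    sub <- table[table$sample == s, ]
    reps <- sort(unique(sub$replicate))
    stopifnot(length(reps) == 2)
    genes <- unique(sub$gene_id)
    d <- numeric(0)
    for (g in genes) {
      v1 <- sub$fpkm[sub$gene_id == g & sub$replicate == reps[1]]
      v2 <- sub$fpkm[sub$gene_id == g & sub$replicate == reps[2]]
      if (v1 > config$fpkm_floor && v2 > config$fpkm_floor) {
        d[g] <- abs(log2(v1 + config$pseudocount) -
                      log2(v2 + config$pseudocount))
      }
    }
    divergence[[s]] <- d
  }
  d_ref <- divergence[[config$reference_sample]]
  n <- length(d_ref)
  k <- ceiling(config$reference_top_fraction * n)
  sorted <- sort(d_ref, decreasing = TRUE)
  cutoff <- if (k >= n) -Inf else sorted[[k + 1]]
  calls <- lapply(divergence, function(d) sort(names(d)[d > cutoff]))
  list(divergence = divergence, cutoff = cutoff, calls = calls)
}

# Brute-force balanced two-way ANOVA from cell means (textbook sums of
# squares); oracle for the adjusted-rank-transform interaction test.
brute_balanced_anova <- function(y, f_a, f_b) {
  f_a <- factor(f_a)
  f_b <- factor(f_b)
  a <- nlevels(f_a)
  b <- nlevels(f_b)
  n_cell <- length(y) / (a * b)
  grand <- mean(y)
  m_a <- tapply(y, f_a, mean)
  m_b <- tapply(y, f_b, mean)
  m_ab <- tapply(y, list(f_a, f_b), mean)
  ss_a <- b * n_cell * sum((m_a - grand)^2)
  ss_b <- a * n_cell * sum((m_b - grand)^2)
  ss_ab <- n_cell * sum((m_ab - outer(m_a, rep(1, b)) -
                           outer(rep(1, a), m_b) + grand)^2)
  sse <- sum((y - m_ab[cbind(as.integer(f_a), as.integer(f_b))])^2)
  df_e <- length(y) - a * b
  list(
    f_a = (ss_a / (a - 1)) / (sse / df_e),
    f_b = (ss_b / (b - 1)) / (sse / df_e),
    f_ab = (ss_ab / ((a - 1) * (b - 1))) / (sse / df_e),
    df_e = df_e
  )
}
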