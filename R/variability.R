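#' Configuration for the variability caller
#'
#' Bundles the tunable parameters of the between-replicate variability
#' analysis. Defaults follow the published procedure: genes are eligible in
#' a sample when FPKM exceeds 0.5 in both replicates; divergence is computed
#' on the log2(FPKM + 1) scale; the cutoff is the divergence of the top 1%
#' of eligible genes in the reference sample (the wild-type long-day sample);
#' the high-divergence subset keeps genes with at least a 3-fold
#' between-replicate difference.
#'
#' @param reference_sample Sample label whose top divergence fraction
#'   defines the cutoff.
#' @param fpkm_floor Non-negative expression floor; a gene is *passing* in a
#'   sample when FPKM is strictly above this in both replicates. Default 0.5.
#' @param pseudocount Positive pseudocount added before the log2 transform.
#'   Default 1.
#' @param reference_top_fraction Fraction (0, 1) of passing reference genes
#'   taken as the top set. Default 0.01.
#' @param high_divergence_fold Fold threshold (> 1) for the high-divergence
#'   subset, applied as divergence >= log2(fold). Default 3.
#' @param correlation_genes Gene set used by [replicate_correlation()] when
#'   none is given: `"passing"` (floor-passing genes, default) or `"all"`.
#' @return An object of class `variability_config`.
#' @export
variability_config <- function(reference_sample,
                               fpkm_floor = 0.5,
                               pseudocount = 1,
                               reference_top_fraction = 0.01,
                               high_divergence_fold = 3,
                               correlation_genes = c("passing", "all")) {
  if (missing(reference_sample) || !is.character(reference_sample) ||
      length(reference_sample) != 1) {
    abort("`reference_sample` must be a single sample label")
  }
  if (!is.numeric(fpkm_floor) || length(fpkm_floor) != 1 || fpkm_floor < 0 ||
      !is.finite(fpkm_floor)) {
    abort("`fpkm_floor` must be a single non-negative number")
  }
  check_positive_scalar(pseudocount, "pseudocount")
  if (!is.numeric(reference_top_fraction) || length(reference_top_fraction) != 1 ||
      reference_top_fraction <= 0 || reference_top_fraction >= 1) {
    abort("`reference_top_fraction` must be in (0, 1)")
  }
  if (!is.numeric(high_divergence_fold) || length(high_divergence_fold) != 1 ||
      high_divergence_fold <= 1) {
    abort("`high_divergence_fold` must be > 1")
  }
  structure(
    list(
      reference_sample = reference_sample,
      fpkm_floor = fpkm_floor,
      pseudocount = pseudocount,
      reference_top_fraction = reference_top_fraction,
      high_divergence_fold = high_divergence_fold,
      correlation_genes = match.arg(correlation_genes)
    ),
    class = "variability_config"
  )
}

#' @export
print.variability_config <- function(x, ...) {
  cat("<variability_config>\n")
  cat("  reference sample:  ", x$reference_sample, "\n", sep = "")
  cat("  FPKM floor:        > ", x$fpkm_floor, " in both replicates\n", sep = "")
  cat("  pseudocount:       ", x$pseudocount, "\n", sep = "")
  cat("  top fraction:      ", x$reference_top_fraction, "\n", sep = "")
  cat("  high-divergence:   >= log2(", x$high_divergence_fold, ")\n", sep = "")
  invisible(x)
}

#' Log-scale expression
#'
#' `log2(fpkm + pseudocount)`; with the default pseudocount of 1 this is the
#' log2(FPKM + 1) scale on which between-replicate divergence is defined.
#'
#' @param fpkm Non-negative numeric vector of FPKM values.
#' @param pseudocount Positive pseudocount. Default 1.
#' @return Numeric vector.
#' @export
log_expression <- function(fpkm, pseudocount = 1) {
  check_positive_scalar(pseudocount, "pseudocount")
  if (any(!is.finite(fpkm)) || any(fpkm < 0)) {
    abort("`fpkm` must be non-negative and finite")
  }
  log2(fpkm + pseudocount)
}

#' Between-replicate divergence for one sample
#'
#' For every gene with FPKM strictly above the floor in *both* replicates of
#' the sample (the passing genes), computes
#' \deqn{d_g = | \log_2(F_{g,R1} + 1) - \log_2(F_{g,R2} + 1) |.}
#' Genes failing the floor are absent from the result (not set to 0), so
#' they can never be called variable in that sample.
#'
#' @param table A valid expression table (long tibble).
#' @param sample Sample label; must have exactly two replicates.
#' @param config A [variability_config()].
#' @return Tibble with columns `gene_id`, `fpkm_r1`, `fpkm_r2`, `divergence`
#'   for passing genes only. Attributes: `sample`, `replicates`,
#'   `n_genes_total` (genes in the table before the floor).
#' @export
replicate_divergence <- function(table, sample, config) {
  validate_expression_table(table)
  stopifnot(inherits(config, "variability_config"))
  sub <- table[table$sample == sample, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("sample '%s' not found in expression table", sample))
  }
  reps <- sort(unique(sub$replicate))
  if (length(reps) != 2) {
    abort(sprintf(
      "sample '%s' has %d replicate(s); the divergence statistic requires exactly 2",
      sample, length(reps)
    ))
  }
  r1 <- sub[sub$replicate == reps[[1]], ]
  r2 <- sub[sub$replicate == reps[[2]], ]
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  passing <- r1$fpkm > config$fpkm_floor & r2$fpkm > config$fpkm_floor
  out <- tibble::tibble(
    gene_id = r1$gene_id[passing],
    fpkm_r1 = r1$fpkm[passing],
    fpkm_r2 = r2$fpkm[passing],
    divergence = abs(
      log_expression(r1$fpkm[passing], config$pseudocount) -
        log_expression(r2$fpkm[passing], config$pseudocount)
    )
  )
  attr(out, "sample") <- sample
  attr(out, "replicates") <- reps
  attr(out, "n_genes_total") <- nrow(r1)
  out
}

as_divergence_vector <- function(divergence) {
  if (is.data.frame(divergence)) {
    if (!all(c("gene_id", "divergence") %in% names(divergence))) {
      abort("divergence data frame needs columns gene_id and divergence")
    }
    return(setNames(divergence$divergence, divergence$gene_id))
  }
  if (is.numeric(divergence)) {
    if (length(divergence) == 0) {
      return(setNames(numeric(0), character(0)))
    }
    if (is.null(names(divergence))) {
      names(divergence) <- paste0("gene_", seq_along(divergence))
    }
    return(divergence)
  }
  abort("`divergence` must be a data frame or a named numeric vector")
}

#' Derive the variability cutoff from the reference sample
#'
#' Ranks the reference divergences in decreasing order, takes
#' `k = ceiling(fraction * N)` (N = number of passing reference genes), and
#' sets the cutoff to the (k+1)-th largest divergence, so that the strict
#' comparison `d > cutoff` recovers exactly the top k genes when there are
#' no ties at the cutoff value. If `k == N` the cutoff is `-Inf`. Ties at
#' the cutoff deflate the called set (never inflate); a message reports the
#' tie count when that happens.
#'
#' @param divergence Reference-sample divergences: output of
#'   [replicate_divergence()] or a named numeric vector.
#' @param fraction Top fraction in (0, 1). Default 0.01.
#' @return A list of class `variability_cutoff` with elements `cutoff`,
#'   `k` (intended top count), `top_genes` (genes strictly above the
#'   cutoff), `n_top` and `n_ties_at_cutoff`.
#' @export
derive_cutoff <- function(divergence, fraction = 0.01) {
  d <- as_divergence_vector(divergence)
  if (length(d) == 0) {
    abort("cannot derive a cutoff from an empty divergence map")
  }
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be in (0, 1)")
  }
  n <- length(d)
  k <- as.integer(ceiling(fraction * n))
  sorted <- sort(unname(d), decreasing = TRUE)
  cutoff <- if (k >= n) -Inf else sorted[[k + 1L]]
  top_genes <- names(d)[d > cutoff]
  n_ties <- if (is.finite(cutoff)) sum(d == cutoff) else 0L
  if (length(top_genes) < k) {
    inform(sprintf(
      "cutoff ties: %d gene(s) tied at the cutoff value %.6g; top set deflated to %d of intended %d",
      n_ties, cutoff, length(top_genes), k
    ))
  }
  structure(
    list(
      cutoff = cutoff,
      k = k,
      top_genes = top_genes,
      n_top = length(top_genes),
      n_ties_at_cutoff = as.integer(n_ties)
    ),
    class = "variability_cutoff"
  )
}

#' Call variable genes against a cutoff
#'
#' Returns the genes whose divergence is strictly greater than the cutoff.
#'
#' @param divergence Per-sample divergences (data frame or named vector).
#' @param cutoff Numeric cutoff or a [derive_cutoff()] result.
#' @return Character vector of gene ids.
#' @export
call_variable_genes <- function(divergence, cutoff) {
  if (inherits(cutoff, "variability_cutoff")) cutoff <- cutoff$cutoff
  if (!is.numeric(cutoff) || length(cutoff) != 1) {
    abort("`cutoff` must be a single number")
  }
  d <- as_divergence_vector(divergence)
  names(d)[d > cutoff]
}

#' Specific / shared / specific overlap counts
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return One-row tibble with `specific_a`, `shared`, `specific_b`.
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  tibble::tibble(
    specific_a = length(setdiff(a, b)),
    shared = length(intersect(a, b)),
    specific_b = length(setdiff(b, a))
  )
}

log_pair_for_sample <- function(table, sample, config, genes = NULL) {
  sub <- table[table$sample == sample, , drop = FALSE]
  if (nrow(sub) == 0) {
    abort(sprintf("sample '%s' not found in expression table", sample))
  }
  reps <- sort(unique(sub$replicate))
  if (length(reps) != 2) {
    abort(sprintf("sample '%s' must have exactly 2 replicates", sample))
  }
  r1 <- sub[sub$replicate == reps[[1]], ]
  r2 <- sub[sub$replicate == reps[[2]], ]
  r2 <- r2[match(r1$gene_id, r2$gene_id), ]
  if (is.null(genes)) {
    if (config$correlation_genes == "passing") {
      keep <- r1$fpkm > config$fpkm_floor & r2$fpkm > config$fpkm_floor
    } else {
      keep <- rep(TRUE, nrow(r1))
    }
  } else {
    keep <- r1$gene_id %in% genes
  }
  list(
    x = log_expression(r1$fpkm[keep], config$pseudocount),
    y = log_expression(r2$fpkm[keep], config$pseudocount),
    gene_id = r1$gene_id[keep]
  )
}

#' Pearson correlation between the two replicates of a sample
#'
#' Correlation of log2(FPKM + pseudocount) between replicate 1 and
#' replicate 2 over a gene set (by default the floor-passing genes, or all
#' genes if the config says so).
#'
#' @inheritParams replicate_divergence
#' @param genes Optional character vector restricting the gene set.
#' @return A single correlation in \[-1, 1\].
#' @export
replicate_correlation <- function(table, sample, config, genes = NULL) {
  validate_expression_table(table)
  p <- log_pair_for_sample(table, sample, config, genes)
  if (length(p$x) < 3) {
    abort("need at least 3 genes to compute a replicate correlation")
  }
  if (var(p$x) == 0 || var(p$y) == 0) {
    abort("replicate log-expression has zero variance; correlation undefined")
  }
  cor(p$x, p$y)
}

#' Coefficient of determination for a shared gene subset
#'
#' R-squared of the least-squares regression of replicate-2 log expression
#' on replicate-1 log expression, restricted to `genes`. Equals the squared
#' Pearson correlation on the same subset.
#'
#' @inheritParams replicate_correlation
#' @param genes Character vector of gene ids (at least 3 must be present).
#' @return R-squared in \[0, 1\].
#' @export
shared_gene_r2 <- function(table, sample, config, genes) {
  validate_expression_table(table)
  p <- log_pair_for_sample(table, sample, config, genes)
  if (length(p$x) < 3) {
    abort("need at least 3 genes to fit the replicate regression")
  }
  if (var(p$x) == 0) {
    abort("replicate-1 log-expression has zero variance; regression degenerate")
  }
  fit <- lm(p$y ~ p$x)
  1 - sum(fit$residuals^2) / sum((p$y - mean(p$y))^2)
}

#' High-divergence gene subset
#'
#' Genes whose between-replicate divergence corresponds to at least a
#' `fold`-fold expression difference on the pseudocounted scale:
#' `d >= log2(fold)` (inclusive boundary).
#'
#' @param divergence Per-sample divergences (data frame or named vector).
#' @param fold Fold threshold, must be > 1. Default 3.
#' @return Character vector of gene ids.
#' @export
high_divergence_subset <- function(divergence, fold = 3) {
  if (!is.numeric(fold) || length(fold) != 1 || fold <= 1) {
    abort("`fold` must be a single number > 1")
  }
  d <- as_divergence_vector(divergence)
  names(d)[d >= log2(fold)]
}

#' Run the full between-replicate variability analysis
#'
#' For every sample in the table: applies the FPKM floor, computes per-gene
#' divergence, derives the cutoff from the reference sample's top fraction,
#' calls variable genes in all samples with a strict comparison against that
#' cutoff, and summarizes pairwise overlaps, replicate correlations and
#' high-divergence subsets.
#'
#' @param table A valid expression table.
#' @param config A [variability_config()]; its `reference_sample` must be
#'   present in the table.
#' @return An object of class `variability_result`: a list with elements
#'   `config`, `divergence` (named list of per-sample tibbles), `cutoff`
#'   (a `variability_cutoff`), `calls` (named list of gene-id vectors),
#'   `high_divergence` (named list), `counts` (per-sample tibble),
#'   `overlaps` (pairwise tibble) and `correlations` (per-sample tibble).
#' @seealso [tidy.variability_result()], [glance.variability_result()],
#'   [autoplot.variability_result()]
#' @export
call_variability <- function(table, config) {
  validate_expression_table(table)
  stopifnot(inherits(config, "variability_config"))
  samples <- unique(table$sample)
  if (!config$reference_sample %in% samples) {
    abort(sprintf(
      "reference sample '%s' not present in expression table (samples: %s)",
      config$reference_sample, paste(samples, collapse = ", ")
    ))
  }
  divergence <- lapply(samples, function(s) replicate_divergence(table, s, config))
  names(divergence) <- samples

  cutoff <- derive_cutoff(
    divergence[[config$reference_sample]],
    config$reference_top_fraction
  )
  calls <- lapply(divergence, call_variable_genes, cutoff = cutoff$cutoff)
  high_div <- lapply(divergence, function(d) {
    intersect(call_variable_genes(d, cutoff$cutoff),
              high_divergence_subset(d, config$high_divergence_fold))
  })

  counts <- tibble::tibble(
    sample = samples,
    n_genes = unname(vapply(divergence, function(d) attr(d, "n_genes_total"),
                            integer(1))),
    n_passing = unname(vapply(divergence, nrow, integer(1))),
    n_variable = unname(vapply(calls, length, integer(1)))
  )
  counts$fraction_variable <- counts$n_variable / counts$n_passing

  pairs <- if (length(samples) >= 2) combn(samples, 2, simplify = FALSE) else list()
  overlaps <- purrr::map_dfr(pairs, function(p) {
    dplyr::bind_cols(
      tibble::tibble(sample_a = p[[1]], sample_b = p[[2]]),
      overlap_summary(calls[[p[[1]]]], calls[[p[[2]]]])
    )
  })

  correlations <- tibble::tibble(
    sample = samples,
    pearson_r = unname(vapply(samples, function(s) {
      replicate_correlation(table, s, config)
    }, numeric(1)))
  )

  structure(
    list(
      config = config,
      divergence = divergence,
      cutoff = cutoff,
      calls = calls,
      high_divergence = high_div,
      counts = counts,
      overlaps = overlaps,
      correlations = correlations
    ),
    class = "variability_result"
  )
}

#' @export
print.variability_result <- function(x, ...) {
  cat("<variability_result>\n")
  cat(sprintf(
    "  reference: %s  cutoff: %.4g  (top %d of %d passing genes)\n",
    x$config$reference_sample, x$cutoff$cutoff, x$cutoff$n_top,
    nrow(x$divergence[[x$config$reference_sample]])
  ))
  print(x$counts)
  invisible(x)
}

#' Tidy a variability result
#'
#' One row per passing (gene, sample) with the replicate FPKM values, the
#' divergence and the variable call.
#'
#' @param x A `variability_result`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample`, `fpkm_r1`, `fpkm_r2`,
#'   `divergence`, `variable`.
#' @method tidy variability_result
#' @export
tidy.variability_result <- function(x, ...) {
  purrr::map_dfr(names(x$divergence), function(s) {
    d <- x$divergence[[s]]
    tibble::tibble(
      gene_id = d$gene_id,
      sample = s,
      fpkm_r1 = d$fpkm_r1,
      fpkm_r2 = d$fpkm_r2,
      divergence = d$divergence,
      variable = d$gene_id %in% x$calls[[s]]
    )
  })
}

#' One-row summary of a variability result
#'
#' @param x A `variability_result`.
#' @param ... Unused.
#' @return A one-row tibble: reference sample, cutoff, intended and realized
#'   top counts, tie count, number of samples.
#' @method glance variability_result
#' @export
glance.variability_result <- function(x, ...) {
  tibble::tibble(
    reference_sample = x$config$reference_sample,
    cutoff = x$cutoff$cutoff,
    reference_top_count = x$cutoff$n_top,
    intended_top_count = x$cutoff$k,
    n_ties_at_cutoff = x$cutoff$n_ties_at_cutoff,
    n_samples = length(x$divergence)
  )
}
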