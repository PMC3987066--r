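#' Run the expression-variability pipeline and write report files
#'
#' End-to-end orchestration: floor filter, per-gene divergence, reference
#' cutoff, variable-gene calls, pairwise overlaps, replicate correlations
#' and the high-divergence subset. Writes, into `out_dir`:
#' per-sample variable-gene lists (`variable_genes_<sample>.txt`, one id per
#' line), per-sample high-divergence lists, a wide `divergence.tsv`
#' (gene x sample; empty where the gene fails the floor) and a versioned
#' machine-readable `summary.json`. Progress is narrated via messages
#' (passing-gene counts, cutoff, per-sample calls) so a run can be audited.
#'
#' @param table An expression table (tibble) or a path to a file readable by
#'   [read_expression_table()].
#' @param config A [variability_config()].
#' @param out_dir Output directory (created if needed).
#' @return The underlying `variability_result`, invisibly.
#' @export
run_expression_pipeline <- function(table, config, out_dir) {
  if (is.character(table) && length(table) == 1) {
    inform(sprintf("reading expression table from '%s'", table))
    table <- read_expression_table(table)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- call_variability(table, config)

  inform(sprintf(
    "reference '%s': %d passing genes, cutoff %.6g (top %d)",
    config$reference_sample,
    nrow(result$divergence[[config$reference_sample]]),
    result$cutoff$cutoff, result$cutoff$n_top
  ))
  for (s in names(result$calls)) {
    inform(sprintf(
      "sample '%s': %d passing, %d variable, %d high-divergence",
      s, nrow(result$divergence[[s]]), length(result$calls[[s]]),
      length(result$high_divergence[[s]])
    ))
    writeLines(result$calls[[s]],
               file.path(out_dir, paste0("variable_genes_", s, ".txt")))
    writeLines(result$high_divergence[[s]],
               file.path(out_dir, paste0("high_divergence_", s, ".txt")))
  }

  div_wide <- purrr::map_dfr(names(result$divergence), function(s) {
    d <- result$divergence[[s]]
    tibble::tibble(gene_id = d$gene_id, sample = s, divergence = d$divergence)
  }) |>
    tidyr::pivot_wider(names_from = "sample", values_from = "divergence") |>
    dplyr::arrange(.data$gene_id)
  readr::write_tsv(div_wide, file.path(out_dir, "divergence.tsv"),
                   progress = FALSE)

  summary <- list(
    schema_version = "1.0",
    config = list(
      reference_sample = config$reference_sample,
      fpkm_floor = config$fpkm_floor,
      pseudocount = config$pseudocount,
      reference_top_fraction = config$reference_top_fraction,
      high_divergence_fold = config$high_divergence_fold,
      correlation_genes = config$correlation_genes
    ),
    cutoff = result$cutoff$cutoff,
    reference_top_count = result$cutoff$n_top,
    intended_top_count = result$cutoff$k,
    n_ties_at_cutoff = result$cutoff$n_ties_at_cutoff,
    counts = result$counts,
    overlaps = result$overlaps,
    correlations = result$correlations,
    high_divergence_counts = lapply(result$high_divergence, length)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Run the phenotype-variability pipeline and write report files
#'
#' Produces a growth-assay style summary table: per line n, mean, CV,
#' variance, a Levene test of variance homogeneity against the reference
#' line (p-value plus star code), and percent reduction of the mean relative
#' to the reference. With a single line only the summary columns are
#' produced. A line with zero variance yields a warning and an NA test row
#' rather than an error. When `genotype` and `treatment` columns with at
#' least two levels each are present, the adjusted-rank-transform factorial
#' test is added to the JSON report.
#'
#' @param traits Data frame with columns `line` and `value` (or a path to a
#'   TSV with those columns).
#' @param reference_line Label of the reference line (e.g. the wild-type).
#' @param out_dir Output directory (created if needed).
#' @param levene_center Passed to [levene_test()]. Default `"mean"`.
#' @return A list with `summary` (the per-line tibble) and `tests` (list of
#'   test results), invisibly; files `phenotype_summary.tsv` and
#'   `phenotype_tests.json` are written to `out_dir`.
#' @export
run_phenotype_pipeline <- function(traits, reference_line, out_dir,
                                   levene_center = "mean") {
  if (is.character(traits) && length(traits) == 1) {
    traits <- readr::read_tsv(traits, show_col_types = FALSE, progress = FALSE)
  }
  if (!all(c("line", "value") %in% names(traits))) {
    abort("`traits` must have columns line and value")
  }
  lines <- unique(traits$line)
  if (!reference_line %in% lines) {
    abort(sprintf("reference line '%s' not present in trait table", reference_line))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ref_values <- traits$value[traits$line == reference_line]
  ref_mean <- mean(ref_values)

  rows <- lapply(lines, function(ln) {
    v <- traits$value[traits$line == ln]
    s <- summarize_trait(v)
    s$line <- ln
    if (ln == reference_line || length(lines) == 1) {
      s$levene_p <- NA_real_
      s$levene_stars <- NA_character_
      s$percent_reduction <- NA_real_
    } else {
      lev <- tryCatch(
        levene_test(c(ref_values, v),
                    rep(c(reference_line, ln), c(length(ref_values), length(v))),
                    center = levene_center),
        error = function(e) {
          warn(sprintf("Levene test failed for line '%s': %s", ln,
                       conditionMessage(e)))
          NULL
        }
      )
      s$levene_p <- if (is.null(lev)) NA_real_ else lev$p.value
      s$levene_stars <- if (is.null(lev)) NA_character_ else
        significance_stars(lev$p.value)
      s$percent_reduction <- round_half_up(percent_reduction(ref_mean, s$mean), 1)
    }
    s
  })
  summary_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- summary_tbl[, c("line", "n", "mean", "cv", "variance",
                                 "levene_p", "levene_stars",
                                 "percent_reduction")]
  readr::write_tsv(summary_tbl, file.path(out_dir, "phenotype_summary.tsv"),
                   progress = FALSE)

  tests <- list(reference_line = reference_line, levene_center = levene_center)
  if (all(c("genotype", "treatment") %in% names(traits)) &&
      length(unique(traits$genotype)) >= 2 &&
      length(unique(traits$treatment)) >= 2) {
    art <- tryCatch(
      adjusted_rank_transform(traits, value, genotype, treatment),
      error = function(e) {
        warn(sprintf("factorial test skipped: %s", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(art)) tests$adjusted_rank_transform <- art
  }
  jsonlite::write_json(tests, file.path(out_dir, "phenotype_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary_tbl, tests = tests))
}
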