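#' Configuration for the expression simulator
#'
#' The generator draws a true log2(FPKM + 1) level per gene, shared across
#' samples, then adds independent replicate noise on that log scale:
#' standard deviation `replicate_noise_sd` for stable genes and
#' `noise_multiplier * replicate_noise_sd` for the genes in a sample's
#' hypervariable set (a random subset of size
#' `round(hypervariable_fraction * n_genes)`). FPKM is recovered as
#' `max(2^x - 1, 0)`, so the caller's divergence statistic is exactly the
#' simulated log-scale difference for floor-passing genes.
#'
#' Defaults emulate the study design the analysis expects: four samples
#' (wild-type and mutant under long-day and short-day photoperiods), two
#' biological replicates each, ~20,000 genes of which ~88% clear the 0.5
#' FPKM floor, and a mutant long-day sample in which 10% of genes carry
#' 4-fold inflated replicate noise.
#'
#' @param n_genes Number of genes. Default 20000.
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the per-gene
#'   true log2(FPKM + 1) level. Defaults 3 and 2.
#' @param replicate_noise_sd Replicate noise sd on the log2 scale for stable
#'   genes. Default 0.15.
#' @param samples Tibble with columns `label`, `genotype`, `photoperiod`,
#'   `hypervariable_fraction` (in \[0, 1)), `noise_multiplier` (>= 1) and
#'   optionally `overlap_with` / `overlap_fraction` to share part of a
#'   sample's hypervariable set with an earlier sample's.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 20000,
                                  baseline_log2_mean = 3,
                                  baseline_log2_sd = 2,
                                  replicate_noise_sd = 0.15,
                                  samples = NULL,
                                  seed = 1L) {
  if (is.null(samples)) {
    samples <- tibble::tibble(
      label = c("wt_ld", "mut_ld", "wt_sd", "mut_sd"),
      genotype = c("wild-type", "mutant", "wild-type", "mutant"),
      photoperiod = c("long-day", "long-day", "short-day", "short-day"),
      hypervariable_fraction = c(0, 0.10, 0, 0),
      noise_multiplier = c(1, 4, 1, 1)
    )
  }
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    abort("`n_genes` must be a positive integer")
  }
  check_positive_scalar(replicate_noise_sd, "replicate_noise_sd")
  if (!is.numeric(baseline_log2_sd) || baseline_log2_sd < 0) {
    abort("`baseline_log2_sd` must be non-negative")
  }
  required <- c("label", "genotype", "photoperiod",
                "hypervariable_fraction", "noise_multiplier")
  if (!all(required %in% names(samples))) {
    abort(sprintf("`samples` must have columns: %s",
                  paste(required, collapse = ", ")))
  }
  if (anyDuplicated(samples$label) > 0) abort("sample labels must be unique")
  if (any(samples$hypervariable_fraction < 0) ||
      any(samples$hypervariable_fraction >= 1)) {
    abort("`hypervariable_fraction` must be in [0, 1)")
  }
  if (any(samples$noise_multiplier < 1)) {
    abort("`noise_multiplier` must be >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1) abort("`seed` must be an integer")
  structure(
    list(
      n_genes = as.integer(n_genes),
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      replicate_noise_sd = replicate_noise_sd,
      samples = tibble::as_tibble(samples),
      seed = as.integer(seed)
    ),
    class = "expression_sim_config"
  )
}

#' Simulate a replicated expression table with known hypervariable genes
#'
#' @param config An [expression_sim_config()].
#' @return A list of class `expression_sim` with elements `table` (tidy
#'   expression table), `truth` (named list: per-sample hypervariable gene
#'   ids), `sample_info` (sample, genotype, photoperiod) and `config`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  true_level <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  samples <- config$samples
  has_overlap <- all(c("overlap_with", "overlap_fraction") %in% names(samples))
  truth <- list()
  parts <- vector("list", nrow(samples) * 2L)
  part <- 0L
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    n_h <- round(row$hypervariable_fraction * n)
    hyper <- character(0)
    if (n_h > 0) {
      if (has_overlap && !is.na(row$overlap_with) &&
          row$overlap_with %in% names(truth)) {
        donor <- truth[[row$overlap_with]]
        n_shared <- min(round(row$overlap_fraction * n_h), length(donor))
        shared <- sample(donor, n_shared)
        rest <- sample(setdiff(genes, donor), n_h - n_shared)
        hyper <- c(shared, rest)
      } else {
        hyper <- sample(genes, n_h)
      }
    }
    truth[[row$label]] <- sort(hyper)
    noise_sd <- rep(config$replicate_noise_sd, n)
    noise_sd[genes %in% hyper] <- row$noise_multiplier * config$replicate_noise_sd
    for (r in c("R1", "R2")) {
      x <- true_level + rnorm(n, 0, noise_sd)
      part <- part + 1L
      parts[[part]] <- tibble::tibble(
        gene_id = genes,
        sample = row$label,
        replicate = r,
        fpkm = pmax(2^x - 1, 0)
      )
    }
  }
  table <- dplyr::bind_rows(parts)
  structure(
    list(
      table = table,
      truth = truth,
      sample_info = samples[, c("label", "genotype", "photoperiod")] |>
        dplyr::rename(sample = "label"),
      config = config
    ),
    class = "expression_sim"
  )
}

#' Configuration for the trait simulator
#'
#' Each line's individual measurements are drawn from
#' Normal(mean, (cv * mean)^2), redrawing any non-positive value (truncation
#' by redraw, which preserves the target mean approximately). Default line
#' parameters are anchored to published root-length populations: a uniform
#' wild-type (mean 40.53 mm, CV 0.052), two over-expressing lines with
#' inflated variability (CV ~0.16) and a knockout close to wild-type.
#'
#' Alternatively `factorial` builds a 2x2 genotype-by-treatment design from
#' additive effects plus an optional interaction, for factorial-test
#' simulations.
#'
#' @param lines Tibble with columns `label`, `mean` (> 0), `cv` (>= 0).
#' @param n_per_line Individuals per line; default 40.
#' @param factorial Optional list with `base_mean`, `genotype_effect`,
#'   `treatment_effect`, `interaction_effect`, `cv`; overrides `lines`.
#' @param seed Integer seed.
#' @return An object of class `trait_sim_config`.
#' @export
trait_sim_config <- function(lines = NULL, n_per_line = 40,
                             factorial = NULL, seed = 1L) {
  if (!is.null(factorial)) {
    needed <- c("base_mean", "genotype_effect", "treatment_effect",
                "interaction_effect", "cv")
    missing_f <- setdiff(needed, names(factorial))
    if (length(missing_f) > 0) {
      abort(sprintf("`factorial` is missing: %s", paste(missing_f, collapse = ", ")))
    }
    g <- c("wild-type", "mutant")
    tr <- c("control", "stress")
    grid <- expand.grid(genotype = g, treatment = tr,
                        stringsAsFactors = FALSE)
    grid$mean <- factorial$base_mean +
      factorial$genotype_effect * (grid$genotype == "mutant") +
      factorial$treatment_effect * (grid$treatment == "stress") +
      factorial$interaction_effect *
        (grid$genotype == "mutant" & grid$treatment == "stress")
    lines <- tibble::tibble(
      label = paste(grid$genotype, grid$treatment, sep = "_"),
      genotype = grid$genotype,
      treatment = grid$treatment,
      mean = grid$mean,
      cv = factorial$cv
    )
  }
  if (is.null(lines)) {
    lines <- tibble::tibble(
      label = c("wild_type", "overexpressor_1", "overexpressor_2", "knockout"),
      mean = c(40.53, 31.89, 34.65, 41.81),
      cv = c(0.052, 0.164, 0.161, 0.080)
    )
  }
  if (!all(c("label", "mean", "cv") %in% names(lines))) {
    abort("`lines` must have columns label, mean, cv")
  }
  if (any(lines$mean <= 0)) abort("line means must be positive")
  if (any(lines$cv < 0)) abort("line CVs must be non-negative")
  if (!is.numeric(n_per_line) || n_per_line < 2) {
    abort("`n_per_line` must be at least 2")
  }
  structure(
    list(
      lines = tibble::as_tibble(lines),
      n_per_line = as.integer(n_per_line),
      seed = as.integer(seed)
    ),
    class = "trait_sim_config"
  )
}

#' Simulate trait populations
#'
#' @param config A [trait_sim_config()].
#' @return A tibble with columns `line`, `individual`, `value` plus any
#'   factor columns (`genotype`, `treatment`, ...) present in the line
#'   table.
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "trait_sim_config"))
  set.seed(config$seed)
  lines <- config$lines
  n <- config$n_per_line
  extra_cols <- setdiff(names(lines), c("label", "mean", "cv"))
  out <- vector("list", nrow(lines))
  for (i in seq_len(nrow(lines))) {
    m <- lines$mean[[i]]
    s <- lines$cv[[i]] * m
    if (s == 0) {
      v <- rep(m, n)
    } else {
      v <- rnorm(n, m, s)
      bad <- which(v <= 0)
      while (length(bad) > 0) { # redraw, do not clip
        v[bad] <- rnorm(length(bad), m, s)
        bad <- bad[v[bad] <= 0]
      }
    }
    row <- tibble::tibble(
      line = lines$label[[i]],
      individual = seq_len(n),
      value = v
    )
    for (col in extra_cols) row[[col]] <- lines[[col]][[i]]
    out[[i]] <- row
  }
  dplyr::bind_rows(out)
}

#' Write a small deterministic fixture bundle
#'
#' Writes a 200-gene expression table with its sample-info sidecar, a trait
#' table, a qRT-PCR table (8 target genes plus a UBC-style reference over 6
#' individuals in 4 lines) and a JSON manifest of the simulation ground
#' truth. Repeated calls with the same seed are byte-identical.
#'
#' @param out_dir Writable directory (created if needed).
#' @param seed Integer seed. Default 42.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixture_bundle <- function(out_dir, seed = 42L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expr_cfg <- expression_sim_config(n_genes = 200, seed = seed)
  sim <- simulate_expression(expr_cfg)
  expr_path <- file.path(out_dir, "expression.tsv")
  write_expression_table(sim$table, expr_path)
  info_path <- file.path(out_dir, "sample_info.tsv")
  write_sample_info(sim$sample_info, info_path)

  trait_cfg <- trait_sim_config(seed = seed + 1L)
  traits <- simulate_traits(trait_cfg)
  trait_path <- file.path(out_dir, "traits.tsv")
  readr::write_tsv(traits, trait_path, progress = FALSE)

  # qPCR: 4 noisy and 4 stable target genes, 6 individuals, 4 lines;
  # noisy genes get inflated individual-to-individual spread in the
  # over-expressing lines only.
  set.seed(seed + 2L)
  qpcr_lines <- c("wild_type", "overexpressor_1", "overexpressor_2",
                  "overexpressor_3")
  target_genes <- c(paste0("VAR", 1:4), paste0("STB", 1:4))
  rows <- list()
  for (ln in qpcr_lines) {
    for (g in target_genes) {
      noisy <- startsWith(g, "VAR") && ln != "wild_type"
      sd_log <- if (noisy) 1.5 else 0.2
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, line = ln, individual = 1:6,
        value = 2^(5 + rnorm(6, 0, sd_log))
      )
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene = "UBC", line = ln, individual = 1:6,
      value = 2^(8 + rnorm(6, 0, 0.1))
    )
  }
  qpcr <- dplyr::bind_rows(rows)
  qpcr$value <- round(qpcr$value, 6)
  qpcr_path <- file.path(out_dir, "qpcr.tsv")
  readr::write_tsv(qpcr, qpcr_path, progress = FALSE)

  manifest <- list(
    seed = seed,
    expression = list(
      n_genes = expr_cfg$n_genes,
      replicate_noise_sd = expr_cfg$replicate_noise_sd,
      samples = expr_cfg$samples,
      hypervariable = sim$truth
    ),
    traits = list(
      lines = trait_cfg$lines,
      n_per_line = trait_cfg$n_per_line
    ),
    qpcr = list(
      reference_gene = "UBC",
      noisy_genes = paste0("VAR", 1:4),
      stable_genes = paste0("STB", 1:4)
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(c(
    expression = expr_path, sample_info = info_path,
    traits = trait_path, qpcr = qpcr_path, manifest = manifest_path
  ))
}
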