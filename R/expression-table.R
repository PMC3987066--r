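#' Validate a gene expression table
#'
#' An expression table is a tidy tibble with one row per
#' (gene, sample, replicate) and columns `gene_id`, `sample`, `replicate`
#' and `fpkm`. Values must be non-negative, finite FPKM; every gene must
#' have an entry for every (sample, replicate) column; missing entries are
#' an error, never silently treated as zero or NA.
#'
#' @param table A data frame to validate.
#' @return The input, invisibly, if valid. Otherwise an error.
#' @export
validate_expression_table <- function(table) {
  required <- c("gene_id", "sample", "replicate", "fpkm")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "expression table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyNA(table$gene_id) || anyNA(table$sample) || anyNA(table$replicate)) {
    abort("expression table keys (gene_id, sample, replicate) contain NA")
  }
  if (anyNA(table$fpkm)) {
    abort("expression table contains missing FPKM values; missing entries are an error")
  }
  if (any(!is.finite(table$fpkm))) {
    abort("expression table contains non-finite FPKM values")
  }
  if (any(table$fpkm < 0)) {
    abort("expression table contains negative FPKM values")
  }
  keys <- paste(table$gene_id, table$sample, table$replicate, sep = "\r")
  if (anyDuplicated(keys) > 0) {
    abort("duplicate (gene_id, sample, replicate) entries in expression table")
  }
  n_genes <- length(unique(table$gene_id))
  cols <- unique(paste(table$sample, table$replicate, sep = "\r"))
  if (nrow(table) != n_genes * length(cols)) {
    abort("expression table is incomplete: every gene must have a value for every (sample, replicate)")
  }
  invisible(table)
}

#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of transcript, exon model, per million
#' mapped fragments) is computed as
#' \deqn{FPKM_g = c_g \times 10^9 / (L_g \times M)}
#' where \eqn{c_g} is the fragment count of gene g, \eqn{L_g} its exon-model
#' length in bases and \eqn{M} the total number of mapped fragments in the
#' library. Paired-end fragments, not reads, are the counting unit.
#'
#' @param counts Data frame with columns `gene_id` and `count`
#'   (non-negative fragment counts).
#' @param gene_models Data frame with columns `gene_id` and
#'   `exon_model_length` (positive integer bases).
#' @param total_mapped_fragments Single positive number: mapped fragments in
#'   the library.
#' @return The `counts` tibble with an added `fpkm` column.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), count = c(50, 0))
#' models <- tibble::tibble(gene_id = c("g1", "g2"),
#'                          exon_model_length = c(2000L, 500L))
#' compute_fpkm(counts, models, total_mapped_fragments = 5e6)
compute_fpkm <- function(counts, gene_models, total_mapped_fragments) {
  stopifnot(is.data.frame(counts), is.data.frame(gene_models))
  if (!all(c("gene_id", "count") %in% names(counts))) {
    abort("`counts` must have columns gene_id and count")
  }
  if (!all(c("gene_id", "exon_model_length") %in% names(gene_models))) {
    abort("`gene_models` must have columns gene_id and exon_model_length")
  }
  if (!is.numeric(total_mapped_fragments) || length(total_mapped_fragments) != 1 ||
      !is.finite(total_mapped_fragments) || total_mapped_fragments <= 0) {
    abort("`total_mapped_fragments` must be a single positive number")
  }
  if (any(!is.finite(counts$count)) || any(counts$count < 0)) {
    abort("fragment counts must be non-negative and finite")
  }
  if (any(gene_models$exon_model_length < 1)) {
    abort("exon_model_length must be at least 1 base")
  }
  idx <- match(counts$gene_id, gene_models$gene_id)
  if (anyNA(idx)) {
    missing_genes <- counts$gene_id[is.na(idx)]
    abort(sprintf(
      "no gene model for gene(s): %s",
      paste(head(missing_genes, 5), collapse = ", ")
    ))
  }
  len <- gene_models$exon_model_length[idx]
  dplyr::mutate(
    tibble::as_tibble(counts),
    fpkm = .data$count * 1e9 / (as.numeric(len) * as.numeric(total_mapped_fragments))
  )
}

#' Read a tab-separated expression table
#'
#' File dialect: UTF-8 tab-separated text, Unix newlines; first column
#' `gene_id`; every further column named `<sample>__<replicate>`. Sample
#' factor levels (genotype, photoperiod) live in a sidecar file, see
#' [read_sample_info()].
#'
#' @param path Path to the file.
#' @return A tidy expression table (see [validate_expression_table()]).
#' @export
read_expression_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) {
    abort(sprintf("'%s' is empty; expected a header line", path))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "gene_id") {
    abort(sprintf("line 1: first column must be 'gene_id', found '%s'", header[[1]]))
  }
  col_names <- header[-1]
  parts <- strsplit(col_names, "__", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    abort(sprintf(
      "line 1: column '%s' is not of the form <sample>__<replicate>",
      col_names[bad[[1]]]
    ))
  }
  samples <- vapply(parts, `[[`, character(1), 1)
  replicates <- vapply(parts, `[[`, character(1), 2)

  n_col <- length(header)
  body <- lines[-1]
  if (length(body) == 0) {
    return(tibble::tibble(
      gene_id = character(0), sample = character(0),
      replicate = character(0), fpkm = numeric(0)
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ragged <- which(lengths(fields) != n_col)
  if (length(ragged) > 0) {
    abort(sprintf(
      "line %d: expected %d tab-separated fields, found %d",
      ragged[[1]] + 1L, n_col, lengths(fields)[ragged[[1]]]
    ))
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1)
  dup <- which(duplicated(gene_ids))
  if (length(dup) > 0) {
    abort(sprintf(
      "line %d: duplicate gene id '%s'", dup[[1]] + 1L, gene_ids[dup[[1]]]
    ))
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L)
  for (j in seq_len(n_col - 1L)) {
    raw <- vapply(fields, `[[`, character(1), j + 1L)
    v <- suppressWarnings(as.numeric(raw))
    bad_num <- which(is.na(v))
    if (length(bad_num) > 0) {
      abort(sprintf(
        "line %d: value '%s' in column '%s' is not a number",
        bad_num[[1]] + 1L, raw[bad_num[[1]]], col_names[[j]]
      ))
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      abort(sprintf(
        "line %d: negative FPKM value %s in column '%s'",
        neg[[1]] + 1L, raw[neg[[1]]], col_names[[j]]
      ))
    }
    values[, j] <- v
  }
  out <- tibble::tibble(
    gene_id = rep(gene_ids, times = n_col - 1L),
    sample = rep(samples, each = length(gene_ids)),
    replicate = rep(replicates, each = length(gene_ids)),
    fpkm = as.vector(values)
  )
  validate_expression_table(out)
  out
}

#' Write an expression table to tab-separated text
#'
#' Inverse of [read_expression_table()] up to float formatting (values are
#' written with 10 significant digits). Column order is deterministic:
#' samples and replicates sorted lexicographically; gene order is preserved.
#'
#' @param table A valid expression table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  validate_expression_table(table)
  genes <- unique(table$gene_id)
  cols <- dplyr::distinct(table, .data$sample, .data$replicate)
  cols <- dplyr::arrange(cols, .data$sample, .data$replicate)
  col_labels <- if (nrow(cols) == 0) character(0) else
    paste0(cols$sample, "__", cols$replicate)
  header <- c("gene_id", col_labels)
  if (length(genes) == 0) {
    writeLines(paste(header, collapse = "\t"), path, useBytes = TRUE)
    return(invisible(path))
  }
  mat <- matrix("", nrow = length(genes), ncol = nrow(cols))
  for (j in seq_len(nrow(cols))) {
    sub <- table[table$sample == cols$sample[[j]] &
                   table$replicate == cols$replicate[[j]], ]
    mat[, j] <- sprintf("%.10g", sub$fpkm[match(genes, sub$gene_id)])
  }
  rows <- paste(genes, apply(mat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(paste(header, collapse = "\t"), rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write the sample-information sidecar
#'
#' Tab-separated file with columns `sample`, `genotype`, `photoperiod`
#' declaring the factor levels carried by each sample label.
#'
#' @param path File path.
#' @return A tibble with one row per sample.
#' @export
read_sample_info <- function(path) {
  info <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  required <- c("sample", "genotype", "photoperiod")
  if (!all(required %in% names(info))) {
    abort("sample info must have columns sample, genotype, photoperiod")
  }
  if (anyDuplicated(info$sample) > 0) {
    abort("duplicate sample labels in sample info")
  }
  info
}

#' @rdname read_sample_info
#' @param info Sample-information tibble.
#' @export
write_sample_info <- function(info, path) {
  readr::write_tsv(info, path, progress = FALSE)
  invisible(path)
}
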