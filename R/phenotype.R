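#' Summary statistics for one trait population
#'
#' Mean, unbiased sample variance (n - 1 denominator), standard deviation,
#' coefficient of variation CV = sd / mean, and median (midpoint rule for
#' even n). The CV is the within-population variability measure used for
#' growth traits.
#'
#' @param values Numeric vector of individual measurements (n >= 2).
#' @return One-row tibble: `n`, `mean`, `variance`, `sd`, `cv`, `median`.
#' @export
#' @examples
#' summarize_trait(c(38.2, 41.0, 40.1, 42.7))
summarize_trait <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be a finite numeric vector")
  }
  n <- length(values)
  if (n < 2) {
    abort("at least 2 measurements are required for variance-based summaries")
  }
  m <- mean(values)
  if (m <= 0) {
    abort("mean is not positive; the coefficient of variation is undefined")
  }
  v <- var(values)
  tibble::tibble(
    n = n,
    mean = m,
    variance = v,
    sd = sqrt(v),
    cv = sqrt(v) / m,
    median = median(values)
  )
}

#' Per-group trait summaries
#'
#' Data-frame-first wrapper around [summarize_trait()]: one summary row per
#' combination of the grouping columns.
#'
#' @param data Data frame of individual measurements.
#' @param value Column holding the measurement (tidy-eval).
#' @param ... Grouping columns (tidy-eval), e.g. `line`.
#' @return A tibble with the grouping columns plus the summary columns.
#' @export
trait_summary_table <- function(data, value, ...) {
  data |>
    dplyr::group_by(...) |>
    dplyr::reframe(summarize_trait(dplyr::pick({{ value }})[[1]]))
}

#' Percent reduction relative to a reference mean
#'
#' `100 * (1 - test_mean / reference_mean)`. Full precision is kept
#' internally; round only when reporting (see [round_half_up()]).
#'
#' @param reference_mean Single positive reference mean.
#' @param test_mean Numeric vector of test means.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent_reduction(40.7, 31.9) # 21.62...
percent_reduction <- function(reference_mean, test_mean) {
  check_positive_scalar(reference_mean, "reference_mean")
  100 * (1 - test_mean / reference_mean)
}

#' Levene's test for homogeneity of variances
#'
#' Computes absolute deviations from the group center (mean by default,
#' median for the Brown-Forsythe variant) and the statistic
#' \deqn{W = \frac{N-k}{k-1} \cdot
#'   \frac{\sum_i n_i (\bar Z_i - \bar Z)^2}{\sum_i \sum_j (Z_{ij} - \bar Z_i)^2}}
#' referred to the F distribution with (k - 1, N - k) degrees of freedom.
#'
#' @param values Numeric vector of measurements.
#' @param group Group labels, same length as `values`; at least two groups
#'   with n >= 2 each.
#' @param center `"mean"` (classic Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return One-row tibble: `method`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
levene_test <- function(values, group, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(values) != length(group)) {
    abort("`values` and `group` must have the same length")
  }
  if (any(!is.finite(values))) abort("`values` must be finite")
  g <- factor(group)
  k <- nlevels(g)
  if (k < 2) abort("Levene's test needs at least 2 groups")
  n_i <- tabulate(g)
  if (any(n_i < 2)) abort("every group needs at least 2 observations")
  centre_fn <- if (center == "mean") mean else median
  centres <- tapply(values, g, centre_fn)
  z <- abs(values - centres[as.integer(g)])
  if (all(z == 0)) {
    abort("all absolute deviations are zero (constant groups); Levene's test is degenerate")
  }
  n <- length(values)
  zbar_i <- tapply(z, g, mean)
  zbar <- mean(z)
  between <- sum(n_i * (zbar_i - zbar)^2)
  within <- sum((z - zbar_i[as.integer(g)])^2)
  w <- if (within == 0) Inf else ((n - k) / (k - 1)) * between / within
  p <- if (is.finite(w)) pf(w, k - 1, n - k, lower.tail = FALSE) else 0
  test_result(
    method = sprintf("Levene (%s-centered)", center),
    statistic = w, df1 = k - 1, df2 = n - k, p_value = p
  )
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard Royston-approximation routine, with the
#' result in the package's tidy test format.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all identical.
#' @return One-row tibble: `method`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
shapiro_wilk <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be a finite numeric vector")
  }
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (var(values) == 0) {
    abort("all values are identical; normality test is degenerate")
  }
  res <- shapiro.test(values)
  test_result(
    method = "Shapiro-Wilk",
    statistic = unname(res$statistic), p_value = res$p.value
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with mid-ranks for ties. The reported statistic is
#' U = min(U_a, U_b). The p-value is exact (full enumeration of rank
#' assignments) when n_a + n_b <= 12 and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction is
#' used. Identical samples give p = 1 by symmetry.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return One-row tibble: `method`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("both groups must be non-empty")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("values must be finite")
  na <- length(a)
  nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  ra <- sum(r[seq_len(na)])
  ua <- ra - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  has_ties <- anyDuplicated(pooled) > 0
  n <- na + nb

  if (!has_ties && n <= 12) {
    # exact: U depends only on which ranks go to group a
    all_u <- combn(n, na, FUN = sum) - na * (na + 1) / 2
    total <- length(all_u)
    p <- (sum(all_u <= u) + sum(all_u >= na * nb - u)) / total
    p <- min(1, p)
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      delta <- max(0, abs(u - mu) - 0.5) # continuity correction
      p <- min(1, 2 * pnorm(-delta / sqrt(sigma2)))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  test_result(method = method, statistic = u, p_value = p)
}

# Type-II two-way ANOVA with interaction via residual sums of squares of
# nested least-squares fits. Returns per-effect SS, df, F and p, with the
# error term from the full factorial model.
two_way_anova_type2 <- function(y, f_a, f_b) {
  stopifnot(is.factor(f_a), is.factor(f_b))
  n <- length(y)
  a <- nlevels(f_a)
  b <- nlevels(f_b)
  rss <- function(formula_rhs) {
    x <- model.matrix(formula_rhs, data = data.frame(A = f_a, B = f_b))
    sum(lm.fit(x, y)$residuals^2)
  }
  rss_full <- rss(~ A * B)
  rss_ab <- rss(~ A + B)
  rss_a <- rss(~ A)
  rss_b <- rss(~ B)
  ss <- c(A = rss_b - rss_ab, B = rss_a - rss_ab, `A:B` = rss_ab - rss_full)
  ss <- pmax(ss, 0)
  df <- c(A = a - 1, B = b - 1, `A:B` = (a - 1) * (b - 1))
  df_e <- n - a * b
  mse <- rss_full / df_e
  tol <- 1e-10 * max(1, sum(y^2))
  f_stat <- numeric(3)
  p <- numeric(3)
  for (i in 1:3) {
    if (ss[[i]] <= tol) {
      f_stat[[i]] <- 0
      p[[i]] <- 1
    } else if (mse <= tol / max(1, df_e)) {
      f_stat[[i]] <- Inf
      p[[i]] <- 0
    } else {
      f_stat[[i]] <- (ss[[i]] / df[[i]]) / mse
      p[[i]] <- pf(f_stat[[i]], df[[i]], df_e, lower.tail = FALSE)
    }
  }
  list(ss = ss, df = df, df_error = df_e, f = f_stat, p = p)
}

#' Adjusted rank transform test for a two-factor design
#'
#' Nonparametric factorial procedure. Main effects: all raw observations are
#' ranked together (mid-ranks for ties) and a two-way ANOVA is run on the
#' ranks. Interaction: the estimated main effects are first removed,
#' \deqn{Y'_{ijk} = Y_{ijk} - \bar Y_{i\cdot} - \bar Y_{\cdot j} + \bar Y,}
#' the adjusted values are ranked, and the interaction is tested by a
#' two-way ANOVA on those ranks with ((a-1)(b-1), N-ab) degrees of freedom.
#' Unbalanced designs use type-II sums of squares. When the interaction sum
#' of squares is numerically zero (purely additive data), F = 0 and p = 1.
#'
#' @param data Data frame with one row per observation.
#' @param value Measurement column (tidy-eval).
#' @param factor_a,factor_b The two crossed factor columns (tidy-eval).
#'   Every cell must contain at least 2 observations.
#' @return Tibble with one row per effect (`factor_a`, `factor_b`,
#'   `interaction`): `effect`, `method`, `statistic`, `df1`, `df2`,
#'   `p.value`.
#' @export
adjusted_rank_transform <- function(data, value, factor_a, factor_b) {
  y <- dplyr::pull(data, {{ value }})
  f_a <- factor(dplyr::pull(data, {{ factor_a }}))
  f_b <- factor(dplyr::pull(data, {{ factor_b }}))
  if (any(!is.finite(y))) abort("measurements must be finite")
  if (nlevels(f_a) < 2 || nlevels(f_b) < 2) {
    abort("both factors need at least 2 levels")
  }
  cell_n <- table(f_a, f_b)
  if (any(cell_n < 2)) {
    abort("every factor-level combination (cell) needs at least 2 observations")
  }
  # main effects: ANOVA on ranks of the raw data
  main <- two_way_anova_type2(rank(y), f_a, f_b)
  # interaction: remove marginal means, rank the adjusted values, ANOVA
  y_adj <- y - ave(y, f_a) - ave(y, f_b) + mean(y)
  int <- two_way_anova_type2(rank(y_adj), f_a, f_b)

  name_a <- rlang::as_label(rlang::enquo(factor_a))
  name_b <- rlang::as_label(rlang::enquo(factor_b))
  tibble::tibble(
    effect = c(name_a, name_b, "interaction"),
    method = "adjusted rank transform",
    statistic = c(main$f[[1]], main$f[[2]], int$f[[3]]),
    df1 = as.numeric(c(main$df[[1]], main$df[[2]], int$df[[3]])),
    df2 = as.numeric(main$df_error),
    p.value = c(main$p[[1]], main$p[[2]], int$p[[3]])
  )
}

#' Scale qRT-PCR expression relative to a reference gene
#'
#' Per individual, target-gene values are divided by the reference-gene
#' value; then, per gene (and line, when a `line` column is present), all
#' normalized values are divided by their minimum so the lowest expression
#' is exactly 1.
#'
#' @param data Data frame with columns `gene`, `individual`, `value` and
#'   optionally `line`.
#' @param reference_gene Name of the reference gene present in `data`
#'   (e.g. the UBC gene).
#' @return Tibble of the target genes with added columns `normalized` and
#'   `scaled`.
#' @export
qpcr_relative_scale <- function(data, reference_gene) {
  required <- c("gene", "individual", "value")
  if (!all(required %in% names(data))) {
    abort("`data` must have columns gene, individual, value")
  }
  has_line <- "line" %in% names(data)
  keys <- if (has_line) c("line", "individual") else "individual"
  ref <- data[data$gene == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0) {
    abort(sprintf("reference gene '%s' not found in `data`", reference_gene))
  }
  if (any(ref$value <= 0)) {
    abort("reference-gene values must be strictly positive")
  }
  targets <- tibble::as_tibble(data[data$gene != reference_gene, , drop = FALSE])
  ref_small <- ref[, c(keys, "value")]
  names(ref_small)[names(ref_small) == "value"] <- ".ref_value"
  joined <- dplyr::left_join(targets, ref_small, by = keys)
  if (anyNA(joined$.ref_value)) {
    abort("some individuals lack a reference-gene measurement")
  }
  joined$normalized <- joined$value / joined$.ref_value
  joined$.ref_value <- NULL
  grouping <- if (has_line) c("gene", "line") else "gene"
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::mutate(scaled = .data$normalized / min(.data$normalized)) |>
    dplyr::ungroup()
}

#' Frequency distribution with half-open bins
#'
#' Bins are `[origin + i*w, origin + (i+1)*w)`; counts sum to the number of
#' observations. The median uses the same midpoint rule as
#' [summarize_trait()].
#'
#' @param values Numeric vector.
#' @param bin_width Positive bin width.
#' @param origin Left edge of bin 0 (default 0).
#' @return A list with `bins` (tibble: `bin_start`, `bin_end`, `midpoint`,
#'   `count`, spanning the observed range including empty bins) and
#'   `median`.
#' @export
frequency_distribution <- function(values, bin_width, origin = 0) {
  check_positive_scalar(bin_width, "bin_width")
  if (length(values) == 0) {
    return(list(
      bins = tibble::tibble(
        bin_start = numeric(0), bin_end = numeric(0),
        midpoint = numeric(0), count = integer(0)
      ),
      median = NA_real_
    ))
  }
  if (any(!is.finite(values))) abort("`values` must be finite")
  idx <- floor((values - origin) / bin_width)
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), integer(1))
  list(
    bins = tibble::tibble(
      bin_start = origin + rng * bin_width,
      bin_end = origin + (rng + 1) * bin_width,
      midpoint = origin + (rng + 0.5) * bin_width,
      count = counts
    ),
    median = median(values)
  )
}
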