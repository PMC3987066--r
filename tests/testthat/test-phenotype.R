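test_that("trait summaries use the unbiased variance and CV = sd/mean", {
  s <- summarize_trait(c(5, 5, 5, 5))
  expect_equal(s$variance, 0)
  expect_equal(s$cv, 0)

  s2 <- summarize_trait(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$variance, 1)
  expect_equal(s2$cv, 0.5)
  expect_equal(s2$median, 2)

  expect_error(summarize_trait(c(1)), "at least 2")
  expect_error(summarize_trait(c(-3, 1)), "undefined")
})

test_that("CV is scale invariant", {
  set.seed(8)
  x <- runif(30, 10, 50)
  for (c_scale in c(0.5, 2, 17)) {
    expect_equal(summarize_trait(c_scale * x)$cv, summarize_trait(x)$cv,
                 tolerance = 1e-12)
  }
})

test_that("grouped trait summaries match per-group calls", {
  df <- tibble::tibble(
    line = rep(c("wt", "mut"), each = 4),
    value = c(1, 2, 3, 4, 10, 20, 30, 40)
  )
  out <- trait_summary_table(df, value, line)
  expect_equal(nrow(out), 2)
  expect_equal(out$mean[out$line == "wt"], 2.5)
  expect_equal(out$cv[out$line == "mut"],
               summarize_trait(c(10, 20, 30, 40))$cv)
})

test_that("percent reduction reproduces worked examples at one decimal", {
  expect_equal(round_half_up(percent_reduction(40.7, 31.9), 1), 21.6)
  expect_equal(round_half_up(percent_reduction(4.67, 3.35), 1), 28.3)
  expect_equal(percent_reduction(13.7, 13.7), 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("Levene W matches the hand-evaluated formula", {
  # groups (1,2,3) and (2,4,6), mean centers: Z-bars 2/3 and 4/3,
  # between = 2/3, within = 10/3, W = 4 * (2/3)/(10/3) = 0.8
  res <- levene_test(c(1, 2, 3, 2, 4, 6), rep(c("a", "b"), each = 3),
                     center = "mean")
  expect_equal(res$statistic, 0.8)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$p.value, pf(0.8, 1, 4, lower.tail = FALSE))

  # exact copies have identical dispersion
  res0 <- levene_test(c(1, 5, 9, 1, 5, 9), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)

  expect_error(levene_test(c(2, 2, 3, 3), c("a", "a", "b", "b")), "degenerate")
  expect_error(levene_test(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Levene agrees with the car implementation for both centers", {
  skip_if_not_installed("car")
  set.seed(21)
  y <- c(rnorm(15, 0, 1), rnorm(20, 3, 2), rnorm(12, -1, 0.5))
  g <- rep(c("a", "b", "c"), c(15, 20, 12))
  for (ctr in c("mean", "median")) {
    ours <- levene_test(y, g, center = ctr)
    theirs <- car::leveneTest(y, factor(g),
                              center = if (ctr == "mean") mean else median)
    expect_equal(ours$statistic, theirs[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p.value, theirs[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Levene is invariant under shifting a single group", {
  set.seed(22)
  y <- rnorm(60, 10, 2)
  g <- rep(c("a", "b", "c"), each = 20)
  base <- levene_test(y, g)
  y2 <- y + (g == "b") * 137.5
  shifted <- levene_test(y2, g)
  expect_equal(shifted$statistic, base$statistic, tolerance = 1e-9)
})

test_that("Shapiro-Wilk wrapper validates input and detects non-normality", {
  expect_error(shapiro_wilk(rep(3, 10)), "identical")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")

  set.seed(31)
  bimodal <- c(rnorm(20, 0, 0.25), rnorm(20, 5, 0.25))
  expect_lt(shapiro_wilk(bimodal)$p.value, 0.05)

  # p-values roughly uniform under the null
  set.seed(32)
  p_vals <- replicate(200, shapiro_wilk(rnorm(30))$p.value)
  ks <- suppressWarnings(stats::ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Mann-Whitney exact p comes from full enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1) # 2 of the 20 rank arrangements

  # identical multisets: U = n^2/2, p = 1 by symmetry
  res_id <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(res_id$statistic, 8)
  expect_equal(res_id$p.value, 1)
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(41)
  # exact regime, tie-free
  for (i in 1:5) {
    a <- sample(seq(0.1, 100, by = 0.1), 5)
    b <- sample(setdiff(seq(0.1, 100, by = 0.1), a), 6)
    ours <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic,
                 min(ref$statistic, length(a) * length(b) - ref$statistic))
  }
  # approximate regime with ties
  a <- c(rnorm(30), rnorm(5))
  b <- rnorm(40, 0.7)
  a[1:3] <- b[1:3] # force ties
  ours <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(42)
  a <- runif(12, 1, 5)
  b <- runif(15, 2, 6)
  base <- mann_whitney_u(a, b)
  for (f in list(function(x) x^3, log, function(x) exp(x / 3))) {
    tr <- mann_whitney_u(f(a), f(b))
    expect_equal(tr$statistic, base$statistic)
    expect_equal(tr$p.value, base$p.value)
  }
})

test_that("Mann-Whitney detects a 2-SD shift at n = 40 essentially always", {
  set.seed(43)
  rejections <- replicate(200, {
    mann_whitney_u(rnorm(40), rnorm(40, 2))$p.value < 0.001
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("ART interaction matches a brute-force ANOVA on the adjusted ranks", {
  df <- tibble::tibble(
    value = c(1, 2, 3, 4, 5, 6, 11, 12),
    a = rep(c("a1", "a2"), each = 4),
    b = rep(c("b1", "b2", "b1", "b2"), each = 2)
  )
  res <- adjusted_rank_transform(df, value, a, b)
  int <- res[res$effect == "interaction", ]

  y_adj <- df$value - ave(df$value, df$a) - ave(df$value, df$b) + mean(df$value)
  oracle <- brute_balanced_anova(rank(y_adj), df$a, df$b)
  expect_equal(int$statistic, oracle$f_ab, tolerance = 1e-10)
  expect_equal(int$df1, 1)
  expect_equal(int$df2, 4)

  # main effects: brute-force ANOVA on ranks of the raw data
  oracle_main <- brute_balanced_anova(rank(df$value), df$a, df$b)
  expect_equal(res$statistic[res$effect == "a"], oracle_main$f_a,
               tolerance = 1e-10)
  expect_equal(res$statistic[res$effect == "b"], oracle_main$f_b,
               tolerance = 1e-10)
})

test_that("ART agrees with a type-II ANOVA oracle on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(51)
  df <- tibble::tibble(
    a = sample(c("a1", "a2"), 40, replace = TRUE, prob = c(0.35, 0.65)),
    b = sample(c("b1", "b2"), 40, replace = TRUE),
    value = rnorm(40, 5)
  )
  # guarantee every cell has >= 2
  df <- dplyr::bind_rows(
    df,
    tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2")) |>
      dplyr::slice(rep(1:4, 2)) |>
      dplyr::mutate(value = rnorm(8, 5))
  )
  res <- adjusted_rank_transform(df, value, a, b)

  y_adj <- df$value - ave(df$value, df$a) - ave(df$value, df$b) + mean(df$value)
  fit <- lm(rank(y_adj) ~ a * b, data = df)
  car_tab <- car::Anova(fit, type = 2)
  expect_equal(res$statistic[res$effect == "interaction"],
               car_tab["a:b", "F value"], tolerance = 1e-9)
  fit_main <- lm(rank(value) ~ a * b, data = df)
  car_main <- car::Anova(fit_main, type = 2)
  expect_equal(res$statistic[res$effect == "a"], car_main["a", "F value"],
               tolerance = 1e-9)
})

test_that("purely additive cell means give interaction F = 0", {
  df <- tidyr::crossing(
    a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:3
  ) |>
    dplyr::mutate(value = 10 + 2 * (a == "a2") + 5 * (b == "b2"))
  res <- adjusted_rank_transform(df, value, a, b)
  int <- res[res$effect == "interaction", ]
  expect_equal(int$statistic, 0)
  expect_equal(int$p.value, 1)
})

test_that("ART interaction is invariant under adding row and column constants", {
  set.seed(52)
  df <- tidyr::crossing(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:10) |>
    dplyr::mutate(value = rnorm(40, 20, 3))
  base <- adjusted_rank_transform(df, value, a, b)
  df2 <- df |>
    dplyr::mutate(value = value + 100 * (a == "a2") - 35 * (b == "b2"))
  shifted <- adjusted_rank_transform(df2, value, a, b)
  expect_equal(
    shifted$statistic[shifted$effect == "interaction"],
    base$statistic[base$effect == "interaction"],
    tolerance = 1e-9
  )
})

test_that("ART rejects designs with empty or singleton cells", {
  df <- tibble::tibble(
    a = c("a1", "a1", "a2", "a2", "a1"),
    b = c("b1", "b1", "b1", "b1", "b2"),
    value = 1:5
  )
  expect_error(adjusted_rank_transform(df, value, a, b), "at least 2")
})

test_that("qPCR scaling normalizes to the reference then min-scales to 1", {
  df <- tibble::tibble(
    gene = rep(c("tgt", "UBC"), each = 3),
    individual = rep(1:3, 2),
    value = c(2, 4, 8, 1, 1, 1)
  )
  out <- qpcr_relative_scale(df, "UBC")
  expect_equal(out$scaled, c(1, 2, 4))

  # raw (10, 20) with reference (2, 2): normalized (5, 10), scaled (1, 2)
  df2 <- tibble::tibble(
    gene = rep(c("tgt", "UBC"), each = 2),
    individual = rep(1:2, 2),
    value = c(10, 20, 2, 2)
  )
  out2 <- qpcr_relative_scale(df2, "UBC")
  expect_equal(out2$normalized, c(5, 10))
  expect_equal(out2$scaled, c(1, 2))

  # all individuals equal: everything scales to 1
  df3 <- tibble::tibble(
    gene = rep(c("tgt", "UBC"), each = 3),
    individual = rep(1:3, 2),
    value = c(7, 7, 7, 2, 2, 2)
  )
  expect_equal(qpcr_relative_scale(df3, "UBC")$scaled, c(1, 1, 1))

  df_bad <- df
  df_bad$value[[4]] <- 0
  expect_error(qpcr_relative_scale(df_bad, "UBC"), "positive")
})

test_that("qPCR scaling is per gene-and-line", {
  df <- tibble::tibble(
    gene = rep(c("tgt", "UBC"), each = 4),
    line = rep(rep(c("ov", "wt"), each = 2), 2),
    individual = rep(1:2, 4),
    value = c(3, 6, 10, 40, 1, 1, 1, 1)
  )
  out <- qpcr_relative_scale(df, "UBC")
  expect_equal(out$scaled[out$line == "ov"], c(1, 2))
  expect_equal(out$scaled[out$line == "wt"], c(1, 4))
})

test_that("frequency distribution uses half-open bins and the midpoint median", {
  fd <- frequency_distribution(c(1, 1, 2, 9), bin_width = 1, origin = 0)
  expect_equal(sum(fd$bins$count), 4)
  expect_equal(fd$bins$count[fd$bins$bin_start == 1], 2)
  expect_equal(fd$bins$count[fd$bins$bin_start == 2], 1)
  expect_equal(fd$bins$count[fd$bins$bin_start == 9], 1)
  expect_equal(fd$median, 1.5)

  empty <- frequency_distribution(numeric(0), 1)
  expect_equal(nrow(empty$bins), 0)
  expect_true(is.na(empty$median))

  single <- frequency_distribution(c(2.1, 2.2, 2.9), bin_width = 5, origin = 0)
  expect_equal(nrow(single$bins), 1)
  expect_equal(single$bins$count, 3L)
})

test_that("significance stars follow the 0.05 / 0.01 / 0.001 convention", {
  expect_equal(
    significance_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
    c("", "*", "**", "***", NA)
  )
})
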