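#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero
#' ("half-up" for positive values), the convention used when reporting
#' percentages and coefficients of variation. Base [round()] rounds half to
#' even, which disagrees with printed tables on exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(0.1645, 3)
#' round_half_up(21.62, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Significance star codes
#'
#' Maps p-values to the star convention used in the growth-assay tables:
#' `***` below 0.001, `**` below 0.01, `*` below 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  stopifnot(is.numeric(p))
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# shared constructor for hypothesis-test result rows
test_result <- function(method, statistic, df1 = NA_real_, df2 = NA_real_,
                        p_value) {
  tibble::tibble(
    method = method,
    statistic = statistic,
    df1 = df1,
    df2 = df2,
    p.value = p_value
  )
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
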