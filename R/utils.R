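#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.5645 at 3 decimals
#' becomes 0.565), matching how per-item validity tables are conventionally
#' printed. Base R's [round()] uses IEEE round-half-to-even, which would print
#' 0.564 for the same value.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3, the table convention).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(0.56495, 3) # 0.565
#' round_half_up(0.56949, 3) # 0.569
#' @export
round_half_up <- function(x, digits = 3) {
  m <- 10^digits
  # sqrt(eps) guard absorbs representation error in x * m without
  # promoting values genuinely below the .5 boundary
  trunc(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / m
}

#' Retention percentage, truncated to one decimal
#'
#' Percentage of items retained out of those entering a selection round,
#' truncated (not rounded) to one decimal place: 52 of 56 gives 92.8, and
#' 56 of 114 gives 49.1. Truncation is the convention used in published
#' Delphi flow summaries, where 92.857% is reported as 92.8%.
#'
#' @param retained Number of items retained.
#' @param entering Number of items entering the round.
#' @return Percentage in `[0, 100]`, truncated to 1 decimal.
#' @export
retention_pct <- function(retained, entering) {
  stopifnot(entering > 0, retained >= 0, retained <= entering)
  floor(retained / entering * 1000 + 1e-9) / 10
}

# shared argument checks -----------------------------------------------------

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != trunc(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
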