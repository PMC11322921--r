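# Report arithmetic: rounding, percentages, adapter parameter count.

#' Round half away from zero
#'
#' Plain half-up rounding at a fixed number of decimals (R's `round()` uses
#' banker's rounding, which disagrees with how benchmark tables are
#' conventionally printed).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a total, printed-table style
#'
#' `100 * count / total`, rounded half-up to one decimal. A zero total gives
#' `NA` (the undefined-percentage marker).
#'
#' @param count,total Non-negative numerics.
#' @param digits Decimal places (default 1, matching report tables).
#' @return Numeric percentage or `NA`.
#' @export
#' @examples
#' pct_half_up(38470, 44954) # 85.6
#' pct_half_up(1300613, 1339260) # 97.1
pct_half_up <- function(count, total, digits = 1) {
  ifelse(total > 0, round_half_up(100 * count / total, digits), NA_real_)
}

#' Add printed percentages to a failure-mode tally
#'
#' Takes a tally with columns `accurate`, `removal`, `addition`,
#' `alteration`, `total` and appends `*_pct` columns, each the percentage of
#' the count over `total` (additions are reported over the same ground-truth
#' denominator) at one decimal, half-up.
#'
#' @param tally A data frame of tallies.
#' @return The tally tibble with `accurate_pct`, `removal_pct`,
#'   `addition_pct`, `alteration_pct` columns appended.
#' @export
#' @examples
#' tally_percentages(tibble::tibble(
#'   accurate = 38470, removal = 2242, addition = 1015,
#'   alteration = 4242, total = 44954
#' ))
tally_percentages <- function(tally) {
  tally %>%
    as_tibble() %>%
    mutate(
      accurate_pct = pct_half_up(.data$accurate, .data$total),
      removal_pct = pct_half_up(.data$removal, .data$total),
      addition_pct = pct_half_up(.data$addition, .data$total),
      alteration_pct = pct_half_up(.data$alteration, .data$total)
    )
}

#' Trainable parameter count of a prefix-adapter fine-tune
#'
#' For adaption-prompt fine-tuning with prompts of length `K` prepended at
#' the top `L` transformer layers of a model with token embedding dimension
#' `C`, the number of trainable parameters is `K * L * C`.
#'
#' @param K Prompt length (tokens).
#' @param L Number of adapted layers.
#' @param C Token embedding dimension.
#' @return The integer parameter count.
#' @export
#' @examples
#' adapter_param_count(10, 30, 4096) # 1228800
adapter_param_count <- function(K, L, C) {
  for (v in list(K, L, C)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      abort("K, L and C must be non-negative integers")
    }
  }
  as.integer(K) * as.integer(L) * as.integer(C)
}

#' Render a parameter count in millions
#'
#' @param n A parameter count.
#' @return A string such as `"1.2 million"` (one decimal, half-up).
#' @export
format_param_count <- function(n) {
  sprintf("%.1f million", round_half_up(n / 1e6, 1))
}
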