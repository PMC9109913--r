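#' Round a copy-number estimate to an integer
#'
#' Rounds to the nearest integer with ties (fraction exactly 0.5) rounded
#' away from zero — the spreadsheet ROUND convention, which at the upper
#' benign/pathogenic boundary (7.5) rounds toward the pathogenic call.
#' Banker's rounding is available as an alternative.
#'
#' @param cn_estimate Non-negative numeric vector.
#' @param ties `"away"` (default) or `"even"`.
#' @return Integer vector.
#' @examples
#' round_cn(c(6.49, 7.5, 6.0))
#' @export
round_cn <- function(cn_estimate, ties = c("away", "even")) {
  ties <- match.arg(ties)
  if (any(!is.finite(cn_estimate)) || any(cn_estimate < 0)) {
    abort("cn_estimate must be finite and non-negative")
  }
  if (ties == "away") as.integer(floor(cn_estimate + 0.5))
  else as.integer(round(cn_estimate))
}

#' Classify an integer copy number as benign or pathogenic
#'
#' The triplicate-region block count is 3 per allele, so the normal
#' diploid copy number is 6; a gain or loss of a single block (CN 5 or 7)
#' is benign, while a deviation of two or more blocks is pathogenic.  The
#' normal copy number and tolerated deviation are parameters so the rule
#' transfers to other segmental duplications.
#'
#' @param cn_integer Integer copy-number vector (e.g. from [round_cn()]).
#' @param normal_cn Normal copy number (default 6).
#' @param tolerance Largest benign absolute deviation in blocks
#'   (default 1).
#' @return Character vector, `"benign"` or `"pathogenic"`.
#' @examples
#' classify_cn(c(5, 6, 7, 8, 4))
#' @export
classify_cn <- function(cn_integer, normal_cn = 6, tolerance = 1) {
  if (any(cn_integer < 0)) abort("cn_integer must be non-negative")
  if_else(abs(cn_integer - normal_cn) <= tolerance, "benign", "pathogenic")
}

#' Add integer copy number and pathogenicity label columns
#'
#' @param data Tibble with a `cn_estimate` column.
#' @inheritParams round_cn
#' @inheritParams classify_cn
#' @return The input with `cn_integer` and `label` columns appended.
#' @export
classify_runs <- function(data, normal_cn = 6, tolerance = 1,
                          ties = c("away", "even")) {
  ties <- match.arg(ties)
  data |>
    mutate(
      cn_integer = round_cn(.data$cn_estimate, ties = ties),
      label = classify_cn(.data$cn_integer, normal_cn, tolerance)
    )
}
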