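#' Coefficient of variation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation; the
#' denominator is switchable to the population form.
#'
#' @param values Numeric vector of at least two copy-number estimates with
#'   positive mean.
#' @param denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return The %CV as a single number.
#' @examples
#' percent_cv(c(6.0, 6.2))
#' @export
percent_cv <- function(values, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (length(values) < 2) abort("percent_cv needs at least two values")
  m <- mean(values)
  if (m == 0) abort("percent_cv undefined: mean is zero")
  s <- sd(values)
  if (denominator == "n") {
    n <- length(values)
    s <- s * sqrt((n - 1) / n)
  }
  100 * s / m
}

# Order runs for duplicate selection: most droplets first, well ID as the
# deterministic tie-break.
order_by_droplets <- function(runs) {
  runs[order(-runs$n_total, runs$well), , drop = FALSE]
}

#' Intra-assay (within-experiment) variability
#'
#' For every (sample, assay, experiment) group with at least two passing
#' runs, forms one duplicate pair — the two runs with the highest total
#' droplet counts — and computes the pair mean, SD, and %CV of the
#' copy-number estimate.  The per-assay summary is the unweighted mean of
#' the pair %CVs (reproducibility).
#'
#' @param runs Tibble of passing runs with `sample_id`, `assay_id`,
#'   `experiment_id`, `well_id` or `well`, `n_total`, `cn_estimate`.
#' @return A list with `pairs` (one row per duplicate pair: the two wells,
#'   mean, sd, pct_cv) and `summary` (per-assay `n_pairs` and
#'   `mean_pct_cv`).
#' @export
intra_assay <- function(runs) {
  runs <- standardize_well_column(runs)
  pairs <- runs |>
    group_by(.data$sample_id, .data$assay_id, .data$experiment_id) |>
    filter(n() >= 2) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) return(tibble())
      g <- head(order_by_droplets(g), 2)
      tibble(
        well_a = g$well[1], well_b = g$well[2],
        cn_a = g$cn_estimate[1], cn_b = g$cn_estimate[2],
        mean = mean(g$cn_estimate), sd = sd(g$cn_estimate),
        pct_cv = percent_cv(g$cn_estimate)
      )
    }) |>
    ungroup()
  summary <- replicate_summary(pairs)
  list(pairs = pairs, summary = summary)
}

replicate_summary <- function(pairs) {
  if (nrow(pairs) == 0 || !"pct_cv" %in% names(pairs)) {
    return(tibble(assay_id = character(), n_pairs = integer(),
                  mean_pct_cv = double()))
  }
  pairs |>
    group_by(.data$assay_id) |>
    summarise(n_pairs = n(), mean_pct_cv = mean(.data$pct_cv),
              .groups = "drop")
}

standardize_well_column <- function(runs) {
  if (!"well" %in% names(runs) && "well_id" %in% names(runs)) {
    runs$well <- runs$well_id
  }
  runs
}

#' Select the inter-assay run pair for one sample and assay
#'
#' Returns the two runs with the highest accepted droplet counts drawn
#' from two separate experiments: over all cross-experiment pairs the one
#' maximizing first the smaller of the two droplet totals, then their sum,
#' with well IDs as the final deterministic tie-break.  When every run
#' shares one experiment, no pair exists.
#'
#' @param runs Passing runs for a single sample and assay, with
#'   `experiment_id`, `n_total`, `well` (or `well_id`), `cn_estimate`.
#' @return A two-row tibble (the selected pair, ordered by droplet count)
#'   or NULL when no cross-experiment pair exists.
#' @export
select_inter_assay_runs <- function(runs) {
  runs <- standardize_well_column(runs)
  if (nrow(runs) < 2 || length(unique(runs$experiment_id)) < 2) return(NULL)
  idx <- which(
    outer(runs$experiment_id, runs$experiment_id, FUN = "!="),
    arr.ind = TRUE
  )
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  a <- runs$n_total[idx[, 1]]
  b <- runs$n_total[idx[, 2]]
  key <- order(-pmin(a, b), -(a + b),
               runs$well[idx[, 1]], runs$well[idx[, 2]])
  best <- idx[key[1], ]
  order_by_droplets(runs[unname(best), , drop = FALSE])
}

#' Inter-assay (between-experiment) variability
#'
#' For every sample and assay with passing runs in at least two separate
#' experiments, selects the run pair via [select_inter_assay_runs()] and
#' computes the pair mean, SD and %CV.  The per-assay summary is the
#' unweighted mean of pair %CVs (repeatability).
#'
#' @inheritParams intra_assay
#' @return A list with `pairs` and `summary`, as in [intra_assay()].
#' @export
inter_assay <- function(runs) {
  runs <- standardize_well_column(runs)
  pairs <- runs |>
    group_by(.data$sample_id, .data$assay_id) |>
    dplyr::group_modify(function(g, key) {
      sel <- select_inter_assay_runs(g)
      if (is.null(sel)) return(tibble())
      tibble(
        experiment_a = sel$experiment_id[1], experiment_b = sel$experiment_id[2],
        well_a = sel$well[1], well_b = sel$well[2],
        cn_a = sel$cn_estimate[1], cn_b = sel$cn_estimate[2],
        mean = mean(sel$cn_estimate), sd = sd(sel$cn_estimate),
        pct_cv = percent_cv(sel$cn_estimate)
      )
    }) |>
    ungroup()
  summary <- replicate_summary(pairs)
  list(pairs = pairs, summary = summary)
}

#' Per-sample copy number for method comparison
#'
#' Collapses a sample's passing runs (within one assay) to a single
#' copy-number value for the concordance analyses.  The default averages
#' the two runs chosen by [select_inter_assay_runs()], falling back to the
#' run with the most droplets when all runs share one experiment; the
#' alternative uses the best run outright.
#'
#' @param runs Passing runs tibble.
#' @param rule `"inter_pair_mean"` (default) or `"best_run"`.
#' @return A tibble with one row per (sample, assay): `sample_id`,
#'   `assay_id`, `n_runs`, `cn_estimate` and, when present in the input,
#'   the aCGH-assigned copy number `acgh_cn`.
#' @export
sample_cn <- function(runs, rule = c("inter_pair_mean", "best_run")) {
  rule <- match.arg(rule)
  runs <- standardize_well_column(runs)
  runs |>
    group_by(.data$sample_id, .data$assay_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) == 0) return(tibble())
      chosen <- if (rule == "inter_pair_mean") {
        select_inter_assay_runs(g) %||% head(order_by_droplets(g), 1)
      } else {
        head(order_by_droplets(g), 1)
      }
      out <- tibble(n_runs = nrow(g), cn_estimate = mean(chosen$cn_estimate))
      if ("acgh_cn" %in% names(g)) out$acgh_cn <- g$acgh_cn[1]
      out
    }) |>
    ungroup()
}

#' Summary statistics per aCGH copy-number group
#'
#' Groups per-sample estimates by the array-CGH-assigned copy number and
#' reports the range, mean, standard deviation, and %CV of the estimates
#' in each group.
#'
#' @param samples Tibble with columns `acgh_cn` and `cn_estimate`.
#' @return A tibble with one row per copy-number group: `acgh_cn`, `n`,
#'   `min`, `max`, `mean`, `sd`, `pct_cv` (SD and %CV are NA for
#'   singleton groups).
#' @export
cn_group_summary <- function(samples) {
  if (nrow(samples) == 0) {
    return(tibble(acgh_cn = integer(), n = integer(), min = double(),
                  max = double(), mean = double(), sd = double(),
                  pct_cv = double()))
  }
  samples |>
    filter(!is.na(.data$acgh_cn)) |>
    group_by(.data$acgh_cn) |>
    summarise(
      n = n(),
      min = min(.data$cn_estimate), max = max(.data$cn_estimate),
      mean = mean(.data$cn_estimate),
      sd = if (n() > 1) sd(.data$cn_estimate) else NA_real_,
      pct_cv = if (n() > 1) percent_cv(.data$cn_estimate) else NA_real_,
      .groups = "drop"
    ) |>
    arrange(.data$acgh_cn)
}
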