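#' Run-level filter criteria
#'
#' Encodes the run-level quality rules: a run is removed when any single
#' droplet cluster has 100 or fewer accepted droplets, when the total
#' accepted droplet count is 10,000 or less, or when the run carries an
#' exclusion flag.  The defaults express the kept side of those inclusive
#' bounds (smallest cluster must reach 101 droplets, total must reach
#' 10,001).
#'
#' @param min_cluster_droplets Minimum droplets in the smallest of the
#'   four clusters for a run to be kept.
#' @param min_total_droplets Minimum total accepted droplets for a run to
#'   be kept.
#' @param excluded_flags Exclusion-flag values that remove a run.
#' @param ntc_max_positive Maximum tolerated positive droplets per channel
#'   in a no-template control.
#' @return A list of class `filter_criteria`.
#' @export
filter_criteria <- function(min_cluster_droplets = 101,
                            min_total_droplets = 10001,
                            excluded_flags = EXCLUSION_FLAGS,
                            ntc_max_positive = 2) {
  if (min_cluster_droplets < 1 || min_total_droplets < 1) {
    abort("Droplet-count thresholds must be positive")
  }
  structure(list(
    min_cluster_droplets = as.integer(min_cluster_droplets),
    min_total_droplets = as.integer(min_total_droplets),
    excluded_flags = excluded_flags,
    ntc_max_positive = as.integer(ntc_max_positive)
  ), class = "filter_criteria")
}

#' Filter runs by droplet counts and exclusion flags
#'
#' Splits quantified runs into kept and removed sets.  Removal reasons are
#' assigned in a fixed priority order so reports are deterministic:
#' exclusion flags first, then an under-populated cluster, then a low
#' total droplet count.  Kept runs get `qc_status = "pass"`; removed runs
#' get `qc_status = "fail:<reason>"`.
#'
#' @param runs Run tibble carrying at least the four cluster counts and
#'   `n_total`; `exclusion_flags` (list column) is optional.
#' @param criteria A [filter_criteria()] object.
#' @return A list with tibbles `kept` and `removed`; `removed` has a
#'   `reason` column (`"flag:<flag>"`, `"cluster"`, or `"total"`).
#' @export
filter_runs <- function(runs, criteria = filter_criteria()) {
  if (nrow(runs) == 0) {
    empty <- mutate(runs, qc_status = character(0))
    return(list(kept = empty, removed = mutate(empty, reason = character(0))))
  }
  flags <- if ("exclusion_flags" %in% names(runs)) runs$exclusion_flags
           else rep(list(character()), nrow(runs))
  hit_flag <- purrr::map_chr(flags, function(f) {
    hit <- intersect(f, criteria$excluded_flags)
    if (length(hit) > 0) hit[1] else NA_character_
  })
  min_cluster <- pmin(runs$n_pp, runs$n_pn, runs$n_np, runs$n_nn)
  low_cluster <- min_cluster < criteria$min_cluster_droplets
  low_total <- runs$n_total < criteria$min_total_droplets
  reason <- dplyr::case_when(
    !is.na(hit_flag) ~ paste0("flag:", hit_flag),
    low_cluster ~ "cluster",
    low_total ~ "total",
    .default = NA_character_
  )
  removed <- runs[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  removed$qc_status <- paste0("fail:", removed$reason)
  kept <- runs[is.na(reason), , drop = FALSE]
  if (nrow(kept) > 0) kept$qc_status <- "pass"
  else kept$qc_status <- character(0)
  list(kept = as_tibble(kept), removed = as_tibble(removed))
}

#' Keep only samples that passed in both assays
#'
#' A sample survives only when it has at least one passing run in each of
#' the two assays; samples run successfully in only one assay (or none)
#' are excluded.
#'
#' @param runs Tibble of passing runs with `sample_id` and `assay_id`.
#' @param assays The two required assay IDs.
#' @return The subset of `runs` belonging to surviving samples.
#' @export
require_both_assays <- function(runs, assays = c("exon_IV", "exon_VIII")) {
  stopifnot(length(assays) == 2)
  keep <- runs |>
    filter(.data$assay_id %in% assays) |>
    distinct(.data$sample_id, .data$assay_id) |>
    dplyr::count(.data$sample_id) |>
    filter(.data$n == 2) |>
    pull(.data$sample_id)
  filter(runs, .data$sample_id %in% keep)
}

#' Check no-template control wells
#'
#' An NTC fails when more than `max_positive` droplets are positive on
#' either channel (FAM positives are `n_pp + n_pn`; HEX positives are
#' `n_pp + n_np`).
#'
#' @param counts Cluster-count tibble for NTC wells.
#' @param max_positive Maximum tolerated positives per channel.
#' @return The input with logical `ntc_pass` and integer
#'   `n_fam_positive`, `n_hex_positive` columns.
#' @export
check_ntc <- function(counts, max_positive = 2) {
  counts |>
    mutate(
      n_fam_positive = .data$n_pp + .data$n_pn,
      n_hex_positive = .data$n_pp + .data$n_np,
      ntc_pass = .data$n_fam_positive <= max_positive &
        .data$n_hex_positive <= max_positive
    )
}
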