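#' Per-channel intensity thresholds
#'
#' A droplet is called positive on a channel when its amplitude is
#' *strictly greater* than the cutoff; an amplitude exactly equal to the
#' cutoff counts as negative (conservative toward non-detection).
#' Thresholds are intended to be set per plate, assay and channel.
#'
#' @param fam_cutoff,hex_cutoff Amplitude cutoffs (fluorescence units).
#' @param provenance `"manual"` or `"auto"`.
#' @return A one-row tibble with columns `fam_cutoff`, `hex_cutoff`,
#'   `provenance`.
#' @export
thresholds <- function(fam_cutoff, hex_cutoff, provenance = "manual") {
  if (!is.finite(fam_cutoff) || !is.finite(hex_cutoff)) {
    abort("Threshold cutoffs must be finite")
  }
  provenance <- match.arg(provenance, c("manual", "auto"))
  tibble(fam_cutoff = fam_cutoff, hex_cutoff = hex_cutoff,
         provenance = provenance)
}

#' Assign droplets to the four fluorescence groups
#'
#' Counts, per well, the droplets in each of the four two-channel groups:
#' FAM+/HEX+ (`n_pp`), FAM+/HEX- (`n_pn`), FAM-/HEX+ (`n_np`) and
#' FAM-/HEX- (`n_nn`).  Positivity is strict inequality against the
#' cutoff; see [thresholds()].
#'
#' @param droplets Tibble with columns `well`, `fam`, `hex` (e.g. from
#'   [read_amplitudes()] or [simulate_well()]).
#' @param t A [thresholds()] row.
#' @return A tibble with one row per well: the four group counts and
#'   `n_total`; counts always sum to the number of input droplets.
#' @examples
#' d <- tibble::tibble(well = "A01",
#'                     fam = c(8000, 8000, 900, 900),
#'                     hex = c(8000, 900, 8000, 900))
#' assign_clusters(d, thresholds(4500, 4500))
#' @export
assign_clusters <- function(droplets, t) {
  if (nrow(droplets) == 0) {
    abort("No droplets to assign (empty input is distinct from all-negative)")
  }
  stopifnot(all(c("well", "fam", "hex") %in% names(droplets)))
  droplets |>
    mutate(fam_pos = .data$fam > t$fam_cutoff,
           hex_pos = .data$hex > t$hex_cutoff) |>
    group_by(.data$well) |>
    summarise(
      n_pp = sum(.data$fam_pos & .data$hex_pos),
      n_pn = sum(.data$fam_pos & !.data$hex_pos),
      n_np = sum(!.data$fam_pos & .data$hex_pos),
      n_nn = sum(!.data$fam_pos & !.data$hex_pos),
      .groups = "drop"
    ) |>
    mutate(n_total = .data$n_pp + .data$n_pn + .data$n_np + .data$n_nn)
}

#' Suggest an intensity threshold for one channel
#'
#' Partitions the 1-D amplitude distribution into two groups by k-means
#' with deterministic initialization at the 5th and 95th percentiles, and
#' proposes the midpoint of the recovered cluster centers as the cutoff.
#' The separation score is the distance between centers in units of the
#' RMS within-cluster standard deviation; a score below
#' `separation_floor` marks the suggestion unreliable, and apparently
#' single-cluster data (low separation combined with extreme cluster-size
#' imbalance) yields no cutoff at all.
#'
#' @param droplets Tibble with a `fam` and/or `hex` column, or a numeric
#'   vector of amplitudes.
#' @param channel `"fam"` or `"hex"` (ignored for a numeric vector).
#' @param separation_floor Minimum separation score considered reliable.
#' @param max_imbalance Cluster-size ratio beyond which, together with low
#'   separation, the data are treated as a single cluster.
#' @return A one-row tibble: `cutoff` (NA when no cutoff can be
#'   suggested), `center_neg`, `center_pos`, `separation`, `reliable`.
#' @export
suggest_thresholds <- function(droplets, channel = c("fam", "hex"),
                               separation_floor = 3,
                               max_imbalance = 0.995) {
  channel <- match.arg(channel)
  x <- if (is.numeric(droplets)) droplets else droplets[[channel]]
  if (length(x) < 200) {
    abort("At least 200 droplets are required to suggest a threshold")
  }
  init <- unname(stats::quantile(x, c(0.05, 0.95)))
  if (init[1] == init[2]) init[2] <- init[2] + 1e-8
  km <- stats::kmeans(x, centers = matrix(init, ncol = 1), iter.max = 100)
  ord <- order(km$centers[, 1])
  centers <- km$centers[ord, 1]
  sizes <- km$size[ord]
  sds <- vapply(ord, function(k) {
    v <- x[km$cluster == k]
    if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  pooled <- sqrt(mean(sds^2))
  separation <- if (pooled > 0) (centers[2] - centers[1]) / pooled else Inf
  reliable <- is.finite(separation) && separation >= separation_floor
  single <- !reliable && (max(sizes) / sum(sizes) > max_imbalance)
  tibble(
    cutoff = if (single) NA_real_ else mean(centers),
    center_neg = centers[1], center_pos = centers[2],
    separation = separation, reliable = reliable
  )
}

#' Auto-derive a thresholds row from droplet data
#'
#' Convenience wrapper running [suggest_thresholds()] on both channels.
#' Errors if either channel's suggestion is flagged unreliable, unless
#' `allow_unreliable = TRUE`.
#'
#' @inheritParams suggest_thresholds
#' @param allow_unreliable Keep going when a channel's separation score is
#'   below the floor?
#' @return A [thresholds()] row with `provenance = "auto"`.
#' @export
auto_thresholds <- function(droplets, separation_floor = 3,
                            allow_unreliable = FALSE) {
  f <- suggest_thresholds(droplets, "fam", separation_floor)
  h <- suggest_thresholds(droplets, "hex", separation_floor)
  if (!allow_unreliable && (!f$reliable || !h$reliable)) {
    abort("Automatic threshold unreliable (cluster separation below floor); set thresholds manually")
  }
  if (is.na(f$cutoff) || is.na(h$cutoff)) {
    abort("No threshold could be derived: a channel looks single-cluster")
  }
  thresholds(f$cutoff, h$cutoff, provenance = "auto")
}
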