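#' Run the full copy-number pipeline on a plate
#'
#' Wires the stages end to end: cluster calling (auto thresholds per
#' assay unless supplied), Poisson quantification, run-level QC
#' filtering, NTC checks, the both-assay sample rule (when two assays are
#' present), replicate variability, integer classification, and — when
#' aCGH-assigned copy numbers are available — the concordance battery.
#' Every excluded run appears in exactly one exclusion report.
#'
#' @param amplitudes Long droplet tibble (`well`, `fam`, `hex`), e.g.
#'   from [read_amplitudes()] or [simulate_plate()].
#' @param plate Plate-config tibble, e.g. from [read_plate_config()].
#' @param t Optional [thresholds()] row; derived per assay with
#'   [auto_thresholds()] when NULL.
#' @param criteria [filter_criteria()] for run filtering and NTC checks.
#' @param normal_cn,tolerance Classification parameters.
#' @param sample_cn_rule Per-sample aggregation rule, see [sample_cn()].
#' @param both_assays Apply [require_both_assays()]? Defaults to TRUE
#'   when the plate contains two distinct assays.
#' @return A list of class `cn_pipeline`: `runs` (all quantified runs
#'   with QC status), `kept`, `removed`, `ntc`, `intra`, `inter`,
#'   `samples` (per-sample classified calls), `concordance` (or NULL),
#'   `thresholds`.
#' @export
run_pipeline <- function(amplitudes, plate, t = NULL,
                         criteria = filter_criteria(),
                         normal_cn = 6, tolerance = 1,
                         sample_cn_rule = "inter_pair_mean",
                         both_assays = NULL) {
  stopifnot(all(c("well", "fam", "hex") %in% names(amplitudes)))
  missing_cfg <- setdiff(unique(amplitudes$well), plate$well)
  if (length(missing_cfg) > 0) {
    abort(sprintf("Wells without a plate-config entry: %s",
                  paste(missing_cfg, collapse = ", ")))
  }
  ntc_wells <- plate$well[plate$is_ntc]
  sample_amp <- filter(amplitudes, !(.data$well %in% ntc_wells))
  if (nrow(sample_amp) == 0) abort("No sample wells to analyse")

  # thresholds per assay (pooled over that assay's wells) unless supplied
  assay_of <- stats::setNames(plate$assay_id, plate$well)
  sample_amp$assay_id <- assay_of[sample_amp$well]
  thresholds_used <- list()
  counts <- sample_amp |>
    dplyr::group_split(.data$assay_id) |>
    purrr::map(function(g) {
      tt <- t %||% auto_thresholds(g)
      thresholds_used[[g$assay_id[1]]] <<- tt
      assign_clusters(select(g, -"assay_id"), tt)
    }) |>
    bind_rows()

  runs <- counts |>
    quantify_wells() |>
    left_join(plate, by = "well")

  split <- filter_runs(runs, criteria)
  kept <- split$kept
  if (!is.null(both_assays)) {
    apply_both <- both_assays
  } else {
    apply_both <- length(intersect(unique(kept$assay_id),
                                   c("exon_IV", "exon_VIII"))) == 2
  }
  if (apply_both) kept <- require_both_assays(kept)

  ntc <- NULL
  if (length(ntc_wells) > 0) {
    ntc_amp <- filter(amplitudes, .data$well %in% ntc_wells)
    tt <- t %||% thresholds_used[[1]]
    ntc <- assign_clusters(ntc_amp, tt) |>
      check_ntc(max_positive = criteria$ntc_max_positive)
  }

  intra <- intra_assay(kept)
  inter <- inter_assay(kept)
  if (nrow(kept) > 0) {
    samples <- kept |>
      sample_cn(rule = sample_cn_rule) |>
      classify_runs(normal_cn = normal_cn, tolerance = tolerance)
  } else {
    samples <- tibble(sample_id = character(), assay_id = character(),
                      n_runs = integer(), cn_estimate = double(),
                      acgh_cn = integer(), cn_integer = integer(),
                      label = character())
  }

  concord <- NULL
  if ("acgh_cn" %in% names(samples) && sum(!is.na(samples$acgh_cn)) >= 3 &&
      length(unique(samples$acgh_cn[!is.na(samples$acgh_cn)])) > 1) {
    concord <- cn_concordance(select(samples, -"cn_integer", -"label"),
                              normal_cn = normal_cn, tolerance = tolerance)
  }

  structure(list(
    runs = runs, kept = kept, removed = split$removed, ntc = ntc,
    intra = intra, inter = inter, samples = samples,
    concordance = concord, thresholds = thresholds_used
  ), class = "cn_pipeline")
}

#' @export
print.cn_pipeline <- function(x, ...) {
  cat("ddPCR copy-number pipeline\n")
  cat(sprintf("  runs: %d quantified, %d kept, %d removed\n",
              nrow(x$runs), nrow(x$kept), nrow(x$removed)))
  if (!is.null(x$ntc)) {
    cat(sprintf("  NTC wells: %d (%d passing)\n",
                nrow(x$ntc), sum(x$ntc$ntc_pass)))
  }
  cat(sprintf("  samples classified: %d (%d benign, %d pathogenic)\n",
              nrow(x$samples), sum(x$samples$label == "benign"),
              sum(x$samples$label == "pathogenic")))
  if (!is.null(x$concordance)) {
    cat("\n")
    print(x$concordance)
  }
  invisible(x)
}
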