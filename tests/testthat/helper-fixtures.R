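# Shared fixtures built in code: small run tables and simulated wells.

# A quantified run row with controllable counts and metadata.
make_run <- function(well = "A01", sample_id = "S1", assay_id = "exon_VIII",
                     experiment_id = "E1", n_pp = 2000, n_pn = 6000,
                     n_np = 2000, n_nn = 5000, cn_estimate = NULL,
                     exclusion_flags = character(), acgh_cn = 6L) {
  counts <- tibble::tibble(well = well, n_pp = n_pp, n_pn = n_pn,
                           n_np = n_np, n_nn = n_nn,
                           n_total = n_pp + n_pn + n_np + n_nn)
  run <- quantify_wells(counts)
  if (!is.null(cn_estimate)) run$cn_estimate <- cn_estimate
  run$sample_id <- sample_id
  run$assay_id <- assay_id
  run$experiment_id <- experiment_id
  run$is_ntc <- FALSE
  run$exclusion_flags <- list(exclusion_flags)
  run$acgh_cn <- acgh_cn
  run
}

make_runs <- function(...) dplyr::bind_rows(...)

# Simulate a well and push it through calling + quantification with the
# known simulator cluster geometry (cutoffs at the 4500 midpoint).
simulate_and_quantify <- function(config, well = "A01") {
  sim <- simulate_well(config, well = well)
  counts <- assign_clusters(sim$droplets, thresholds(4500, 4500))
  quantify_wells(counts)
}

default_thresholds <- function() thresholds(4500, 4500)
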