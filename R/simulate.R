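#' Simulator configuration for one ddPCR well
#'
#' Defines the generative model for a duplexed copy-number well: target and
#' reference molecules are partitioned independently into droplets
#' (Poisson occupancy), a droplet is positive on a channel when it holds at
#' least one effective molecule, and fluorescence amplitudes are drawn from
#' Gaussian negative/positive clusters on each channel.
#'
#' The target rate is tied to the reference through the true copy number:
#' `lambda_target = lambda_ref * true_cn / 2`, i.e. a diploid reference.
#' With tandem-copy linkage `linkage_fraction = L`, a fraction `L` of the
#' target molecules stays physically joined in indivisible blocks of three
#' (undigested tandem copies), which co-partition: singles arrive at rate
#' `lambda_target * (1 - L)` and 3-copy blocks at rate
#' `lambda_target * L / 3`, and a block turns its droplet positive once.
#' `rain_fraction` replaces that proportion of amplitudes, per channel,
#' with draws from a uniform band between the negative and positive
#' cluster means (the droplet keeps its true occupancy class in the truth
#' record).
#'
#' @param n_droplets Number of droplets in the well (default 20000, the
#'   theoretical partition count of the droplet generator).
#' @param lambda_ref Mean reference copies per droplet (> 0).
#' @param true_cn True target copy number per diploid genome.
#' @param rain_fraction Proportion of droplets with intermediate "rain"
#'   amplitudes, in `[0, 1)`.
#' @param linkage_fraction Proportion of target copies joined in tandem
#'   3-copy blocks, in `[0, 1]`.
#' @param fam_neg,fam_pos,hex_neg,hex_pos Length-2 numeric `c(mean, sd)`
#'   amplitude-cluster parameters (arbitrary fluorescence units).
#' @param seed Integer seed; identical configurations give bit-identical
#'   wells.
#' @return A list of class `sim_config`.
#' @seealso [simulate_well()], [simulate_plate()]
#' @export
sim_config <- function(n_droplets = 20000,
                       lambda_ref = 0.5,
                       true_cn = 6,
                       rain_fraction = 0,
                       linkage_fraction = 0,
                       fam_neg = c(1000, 100),
                       fam_pos = c(8000, 300),
                       hex_neg = c(1000, 100),
                       hex_pos = c(8000, 300),
                       seed = 1L) {
  cfg <- list(
    n_droplets = as.integer(n_droplets), lambda_ref = lambda_ref,
    true_cn = true_cn, rain_fraction = rain_fraction,
    linkage_fraction = linkage_fraction,
    fam_neg = fam_neg, fam_pos = fam_pos,
    hex_neg = hex_neg, hex_pos = hex_pos,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_droplets) || cfg$n_droplets < 1) {
    abort("n_droplets must be a positive integer")
  }
  if (!is.finite(cfg$lambda_ref) || cfg$lambda_ref <= 0) {
    abort("lambda_ref must be > 0")
  }
  if (!is.finite(cfg$true_cn) || cfg$true_cn < 0) {
    abort("true_cn must be >= 0")
  }
  if (cfg$rain_fraction < 0 || cfg$rain_fraction >= 1) {
    abort("rain_fraction must be in [0, 1)")
  }
  if (cfg$linkage_fraction < 0 || cfg$linkage_fraction > 1) {
    abort("linkage_fraction must be in [0, 1]")
  }
  for (cl in c("fam_neg", "fam_pos", "hex_neg", "hex_pos")) {
    p <- cfg[[cl]]
    if (length(p) != 2 || !all(is.finite(p)) || p[2] < 0) {
      abort(sprintf("%s must be c(mean, sd) with sd >= 0", cl))
    }
  }
  if (cfg$fam_pos[1] <= cfg$fam_neg[1] || cfg$hex_pos[1] <= cfg$hex_neg[1]) {
    abort("Positive-cluster mean must exceed negative-cluster mean on each channel")
  }
  invisible(cfg)
}

# Draw amplitudes for one channel given per-droplet positivity, cluster
# parameters, and the uniform rain band.
draw_channel <- function(positive, neg, pos, rain_fraction) {
  n <- length(positive)
  amp <- numeric(n)
  amp[!positive] <- rnorm(sum(!positive), neg[1], neg[2])
  amp[positive] <- rnorm(sum(positive), pos[1], pos[2])
  if (rain_fraction > 0) {
    is_rain <- runif(n) < rain_fraction
    amp[is_rain] <- runif(sum(is_rain), neg[1], pos[1])
  }
  amp
}

#' Simulate one duplexed ddPCR well
#'
#' @param config A [sim_config()].
#' @param well Well label for the output tibble.
#' @return A list with `droplets` (tibble `well`, `fam`, `hex`, one row per
#'   droplet) and `truth` (one-row tibble recording the generative
#'   parameters, the effective target rate, and the realised positive
#'   counts per channel).
#' @examples
#' w <- simulate_well(sim_config(n_droplets = 2000, seed = 7))
#' head(w$droplets)
#' w$truth
#' @export
simulate_well <- function(config, well = "A01") {
  validate_sim_config(config)
  well <- normalize_well_id(well)
  withr::with_seed(config$seed, {
    n <- config$n_droplets
    lambda_target <- config$lambda_ref * config$true_cn / 2
    L <- config$linkage_fraction
    # singles and indivisible 3-copy blocks partition independently
    k_single <- rpois(n, lambda_target * (1 - L))
    k_block <- rpois(n, lambda_target * L / 3)
    target_pos <- (k_single + k_block) > 0
    ref_pos <- rpois(n, config$lambda_ref) > 0
    droplets <- tibble(
      well = well,
      fam = draw_channel(target_pos, config$fam_neg, config$fam_pos,
                         config$rain_fraction),
      hex = draw_channel(ref_pos, config$hex_neg, config$hex_pos,
                         config$rain_fraction)
    )
    # effective Poisson rate of target-positive droplets
    lambda_eff <- lambda_target * (1 - L) + lambda_target * L / 3
    truth <- tibble(
      well = well, n_droplets = n,
      true_cn = config$true_cn, lambda_ref = config$lambda_ref,
      lambda_target = lambda_target, lambda_target_effective = lambda_eff,
      rain_fraction = config$rain_fraction,
      linkage_fraction = L, seed = config$seed,
      n_target_positive = sum(target_pos), n_ref_positive = sum(ref_pos)
    )
    list(droplets = droplets, truth = truth)
  })
}

#' Simulate a plate of wells
#'
#' Each entry of `configs` simulates one well; an optional no-template
#' control (NTC) well is appended with zero target and reference molecules
#' plus an optional per-droplet false-positive rate.
#'
#' @param configs Named list of [sim_config()] objects; names are well IDs.
#' @param sample_ids,assay_ids,experiment_ids Optional character vectors
#'   (recycled) for the plate-config metadata; defaults are `S<well>`,
#'   `"exon_VIII"` and `"E1"`.
#' @param acgh_cn Optional integer vector of array-CGH-assigned copy
#'   numbers (defaults to the rounded true copy number).
#' @param include_ntc Append an NTC well after the sample wells?
#' @param ntc_well Well ID for the NTC.
#' @param ntc_n_droplets Droplet count of the NTC well.
#' @param ntc_false_positive_rate Probability that an empty NTC droplet
#'   still reads positive on a channel (default 0).
#' @param seed Seed for the NTC well draws.
#' @return A list with `amplitudes` (long droplet tibble), `plate` (a
#'   plate-config tibble as from [read_plate_config()]) and `truth`.
#' @export
simulate_plate <- function(configs,
                           sample_ids = NULL,
                           assay_ids = "exon_VIII",
                           experiment_ids = "E1",
                           acgh_cn = NULL,
                           include_ntc = TRUE,
                           ntc_well = "H12",
                           ntc_n_droplets = 15000,
                           ntc_false_positive_rate = 0,
                           seed = 1L) {
  wells <- normalize_well_id(names(configs))
  if (length(wells) == 0) abort("configs must be a non-empty named list")
  if (anyDuplicated(wells)) abort("Duplicate well IDs in configs")
  sims <- purrr::map2(configs, wells, simulate_well)
  amplitudes <- bind_rows(purrr::map(sims, "droplets"))
  truth <- bind_rows(purrr::map(sims, "truth"))
  plate <- tibble(
    well = wells,
    sample_id = if (is.null(sample_ids)) paste0("S", wells)
                else rep_len(sample_ids, length(wells)),
    assay_id = rep_len(assay_ids, length(wells)),
    experiment_id = rep_len(experiment_ids, length(wells)),
    is_ntc = FALSE,
    exclusion_flags = rep(list(character()), length(wells)),
    acgh_cn = if (is.null(acgh_cn))
                as.integer(round(purrr::map_dbl(configs, "true_cn")))
              else rep_len(as.integer(acgh_cn), length(wells))
  )
  if (include_ntc) {
    ntc_well <- normalize_well_id(ntc_well)
    if (ntc_well %in% wells) abort("NTC well collides with a sample well")
    template <- configs[[1]]
    ntc <- withr::with_seed(seed, {
      n <- as.integer(ntc_n_droplets)
      fam_pos <- runif(n) < ntc_false_positive_rate
      hex_pos <- runif(n) < ntc_false_positive_rate
      tibble(
        well = ntc_well,
        fam = draw_channel(fam_pos, template$fam_neg, template$fam_pos, 0),
        hex = draw_channel(hex_pos, template$hex_neg, template$hex_pos, 0)
      )
    })
    amplitudes <- bind_rows(amplitudes, ntc)
    plate <- bind_rows(plate, tibble(
      well = ntc_well, sample_id = NA_character_, assay_id = NA_character_,
      experiment_id = NA_character_, is_ntc = TRUE,
      exclusion_flags = list(character()), acgh_cn = NA_integer_
    ))
  }
  list(amplitudes = amplitudes, plate = plate, truth = truth)
}
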