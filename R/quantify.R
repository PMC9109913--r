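#' Poisson copies-per-partition estimate
#'
#' In digital PCR the number of molecules per droplet is Poisson, so the
#' mean occupancy is recovered from the fraction of negative droplets:
#' `lambda = -ln(n_negative / n_total)`.  The delta-method variance of the
#' estimator is `(exp(lambda) - 1) / n_total`.
#'
#' @param n_negative Number of negative droplets on the channel
#'   (vectorized).
#' @param n_total Total accepted droplets (vectorized).
#' @return A tibble with columns `lambda` and `var_lambda`.
#' @examples
#' estimate_lambda(7358, 20000)
#' @export
estimate_lambda <- function(n_negative, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_negative < 0 | n_negative > n_total)) {
    abort("n_negative must lie in [0, n_total]")
  }
  if (any(n_negative == 0)) {
    abort("All droplets positive; sample too concentrated for Poisson quantification (saturation)")
  }
  lambda <- -log(n_negative / n_total)
  tibble(lambda = lambda, var_lambda = (exp(lambda) - 1) / n_total)
}

#' Quantify wells from cluster counts
#'
#' Converts the four droplet-group counts of each well to copies per
#' partition on both channels, the target:reference ratio, a copy-number
#' estimate (`reference_ploidy * ratio`, i.e. doubling the ratio against a
#' diploid reference), a 95% confidence interval, and concentrations in
#' copies/uL.  Target-negative droplets are `n_np + n_nn`;
#' reference-negative droplets are `n_pn + n_nn`.
#'
#' The confidence interval is a delta-method interval on the log of the
#' rate ratio (`z = 1.96` at the default level), which keeps the bounds
#' non-negative.  The droplet volume enters concentration reporting only;
#' the copy-number estimate is volume-free.
#'
#' @param counts Cluster-count tibble from [assign_clusters()] or
#'   [read_cluster_counts()].
#' @param droplet_volume_nl Droplet volume in nanolitres (QX200
#'   convention: 0.85 nL).
#' @param reference_ploidy Copy number of the reference gene per genome
#'   (2 for a diploid autosomal reference such as EIF2C1).
#' @param conf_level Confidence level for the interval.
#' @return The input tibble extended with `lambda_target`, `lambda_ref`,
#'   `ratio`, `cn_estimate`, `ci_low`, `ci_high`, `concentration_target`,
#'   `concentration_ref`.
#' @examples
#' counts <- tibble::tibble(well = "A01", n_pp = 2331, n_pn = 8194,
#'                          n_np = 1900, n_nn = 7575)
#' counts$n_total <- with(counts, n_pp + n_pn + n_np + n_nn)
#' quantify_wells(counts)
#' @export
quantify_wells <- function(counts, droplet_volume_nl = 0.85,
                           reference_ploidy = 2, conf_level = 0.95) {
  stopifnot(all(c("n_pp", "n_pn", "n_np", "n_nn") %in% names(counts)))
  if (!"n_total" %in% names(counts)) {
    counts <- mutate(counts,
                     n_total = .data$n_pp + .data$n_pn + .data$n_np + .data$n_nn)
  }
  if (any(counts$n_total <= 0)) abort("Wells with zero droplets cannot be quantified")
  target_neg <- counts$n_np + counts$n_nn
  ref_neg <- counts$n_pn + counts$n_nn
  for (side in list(c("target", "FAM"), c("reference", "HEX"))) {
    neg <- if (side[1] == "target") target_neg else ref_neg
    if (any(neg == 0)) {
      bad <- counts$well[neg == 0]
      abort(sprintf(
        "Saturation on the %s (%s) channel in well(s) %s: all droplets positive",
        side[1], side[2], paste(bad, collapse = ", ")
      ))
    }
  }
  lt <- estimate_lambda(target_neg, counts$n_total)
  lr <- estimate_lambda(ref_neg, counts$n_total)
  if (any(lr$lambda == 0)) {
    bad <- counts$well[lr$lambda == 0]
    abort(sprintf(
      "Reference failure in well(s) %s: no reference-positive droplets, ratio undefined",
      paste(bad, collapse = ", ")
    ))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  ratio <- lt$lambda / lr$lambda
  cn <- reference_ploidy * ratio
  # delta method on log(lambda_t / lambda_r); zero target lambda gets a
  # degenerate [0, 0] interval
  se_log <- sqrt(ifelse(lt$lambda > 0, lt$var_lambda / lt$lambda^2, 0) +
                   lr$var_lambda / lr$lambda^2)
  ci_low <- ifelse(lt$lambda > 0, cn * exp(-z * se_log), 0)
  ci_high <- ifelse(lt$lambda > 0, cn * exp(z * se_log), 0)
  vol_ul <- droplet_volume_nl * 1e-3
  counts |>
    mutate(
      lambda_target = lt$lambda, lambda_ref = lr$lambda,
      ratio = ratio, cn_estimate = cn,
      ci_low = ci_low, ci_high = ci_high,
      concentration_target = lt$lambda / vol_ul,
      concentration_ref = lr$lambda / vol_ul
    )
}
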